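#' Extract the reference segment for a candidate region
#'
#' Projects the read onto the reference through a merged match: the segment
#' spans `[r_s - q_s - pad, r_e + (read_len - q_e) + pad)` clipped to the
#' reference, where the padding absorbs small indels.
#'
#' @param M One-row merged-match data frame (see [merge_matches()]).
#' @param read_len Read length.
#' @param ref Reference sequence the merged match lies on.
#' @param pad Fixed margin in bases (default 20).
#' @return List with `segment` (string) and `start` (0-based position of
#'   the segment on the reference), or `NULL` when the clipped segment is
#'   empty.
#' @export
extract_segment <- function(M, read_len, ref, pad = 20) {
  start <- max(0, M$r_s - M$q_s - pad)
  end <- min(nchar(ref), M$r_e + (read_len - M$q_e) + pad)
  if (end <= start) return(NULL)
  list(segment = substr(ref, start + 1, end), start = start)
}

#' Base-level extension of one candidate region
#'
#' When the merged match spans the same number of bases on query and
#' reference, the read is compared by Hamming distance against the
#' length-matched projection; if that distance exceeds `0.05 * read_len`
#' (more than one indel may hide behind equal spans) a Smith-Waterman
#' alignment is additionally computed and the higher-scoring result kept.
#' Unequal spans go straight to Smith-Waterman. Scoring is +1 match, -4
#' mismatch, gap open 6, gap extend 1; unaligned read ends are soft-clipped.
#'
#' @param read Read sequence, already oriented to the reference strand.
#' @param segment,seg_start Segment from [extract_segment()].
#' @param M One-row merged-match data frame.
#' @return List: `score`, `cigar`, `ref_start` (0-based), `edit`
#'   (NM over aligned columns), `n_mismatch`, `method` ("hamming" or "sw"),
#'   `aligned`; or `NULL` if nothing aligned.
#' @export
extend_candidate <- function(read, segment, seg_start, M) {
  len <- nchar(read)
  equal_spans <- (M$q_e - M$q_s) == (M$r_e - M$r_s)
  ham <- NULL
  if (equal_spans) {
    proj <- M$r_s - M$q_s - seg_start  # read start within the segment
    h <- cpp_hamming(read, segment, proj)
    if (h$ok) {
      ham <- list(score = h$score, cigar = sprintf("%dM", len),
                  ref_start = seg_start + proj, edit = h$n_mismatch,
                  n_mismatch = h$n_mismatch, method = "hamming",
                  aligned = TRUE)
      if (h$n_mismatch <= 0.05 * len) return(ham)
    }
  }
  sw <- cpp_sw_align(read, segment)
  if (!sw$aligned) return(ham)
  res <- list(score = sw$score,
              cigar = sw$cigar,
              ref_start = seg_start + sw$r_s,
              edit = sw$edit,  # soft-clipped bases excluded from NM
              n_mismatch = sw$n_mismatch, method = "sw", aligned = TRUE)
  if (!is.null(ham) && ham$score >= res$score) ham else res
}

# candidate merged matches of one read: find, rescue, merge, rank
read_candidates <- function(read, index, rescue_level = 2,
                            absolute = FALSE) {
  res <- candidate_matches(read, index, rescue_level, absolute)
  list(merged = rank_candidates(merge_matches(res$matches)),
       masked_fraction = res$masked_fraction)
}

# extend the ranked candidates of one read; returns the best alignment and
# the MAPQ inputs. Early stops: a perfect match ends the loop; after an
# edit-distance-1 alignment no further base-level calls are made.
extend_best <- function(read, index, merged, max_candidates = 20,
                        dropoff = 0.5, pad = 20) {
  if (nrow(merged) == 0L) return(NULL)
  S1 <- merged$score[1L]
  keep <- merged$score >= dropoff * S1
  keep[1L] <- TRUE
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) > max_candidates)
    merged <- merged[seq_len(max_candidates), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(merged))) {
    M <- merged[i, ]
    ref <- index$refs[[M$r_id + 1L]]
    r <- if (M$o == 1) revcomp(read) else read
    seg <- extract_segment(M, nchar(read), ref, pad = pad)
    if (is.null(seg)) next
    res <- extend_candidate(r, seg$segment, seg$start, M)
    if (is.null(res)) next
    res$r_id <- M$r_id
    res$o <- M$o
    if (is.null(best) || res$score > best$score) best <- res
    if (res$edit == 0) break
    if (res$edit == 1) break
  }
  if (is.null(best)) return(NULL)
  best$S1 <- S1
  best$S2 <- if (nrow(merged) >= 2L) max(merged$score[2L], 0) else 0
  best$n_top <- merged$n[1L]
  best
}

#' Align reads in single-end mode
#'
#' Candidate regions are merged matches ranked by score; at most
#' `max_candidates` within `dropoff` of the best are extended at base level
#' (see [extend_candidate()]), with rescue of heavily masked reads and
#' early stopping on perfect and edit-distance-1 alignments. The best
#' Smith-Waterman score wins; MAPQ derives from the top two merged-match
#' scores via [mapq()].
#'
#' @param reads Named character vector of read sequences.
#' @param index A [build_index()] result (with reference sequences
#'   attached).
#' @param max_candidates Maximum candidates extended per read (default 20).
#' @param dropoff Score drop-off fraction relative to the best candidate
#'   (default 0.5).
#' @param rescue_level,absolute See [rescue_candidates()].
#' @param pad Segment padding in bases.
#' @return Data frame of alignment records: `qname`, `flag`, `rname`,
#'   `pos` (0-based), `mapq`, `cigar`, `strand`, `score`, `edit`,
#'   `seq` (forward-strand read). Unmapped reads have `flag = 4`.
#' @export
align_single <- function(reads, index, max_candidates = 20, dropoff = 0.5,
                         rescue_level = 2, absolute = FALSE, pad = 20) {
  stopifnot(inherits(index, "strobe_index"))
  if (is.null(index$refs))
    stop("index has no reference sequences attached; rebuild or load with `references=`")
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    read <- toupper(reads[[i]])
    qname <- names(reads)[i]
    unmapped <- data.frame(qname = qname, flag = 4L, rname = "*",
                           pos = NA_real_, mapq = 0L, cigar = "*",
                           strand = "*", score = NA_real_, edit = NA_real_,
                           seq = read, stringsAsFactors = FALSE)
    cand <- read_candidates(read, index, rescue_level, absolute)
    best <- extend_best(read, index, cand$merged,
                        max_candidates = max_candidates, dropoff = dropoff,
                        pad = pad)
    if (is.null(best)) return(unmapped)
    data.frame(qname = qname,
               flag = if (best$o == 1) 16L else 0L,
               rname = index$ref_names[best$r_id + 1L],
               pos = best$ref_start, mapq = mapq(best$S1, best$S2, best$n_top),
               cigar = best$cigar,
               strand = if (best$o == 1) "-" else "+",
               score = best$score, edit = best$edit, seq = read,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
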