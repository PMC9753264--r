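# ---- CIGAR helpers -------------------------------------------------------

cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "")
    return(data.frame(len = numeric(0), op = character(0)))
  lens <- as.numeric(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

# reference bases consumed by a CIGAR
cigar_ref_len <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

# read bases consumed by a CIGAR
cigar_read_len <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

# ---- SAM writing ---------------------------------------------------------

#' Render alignment records as SAM lines
#'
#' Produces @HD/@SQ/@PG headers followed by one record per row of `aln`
#' (the output of [align_single()] or [align_paired()]). Positions are
#' converted from the package's 0-based convention to SAM's 1-based here
#' and nowhere else. Reverse-strand records carry the reverse-complemented
#' sequence; unmapped reads keep their sequence. NM and AS tags are
#' emitted for aligned records.
#'
#' @param aln Alignment data frame.
#' @param index The `strobe_index` aligned against (for @SQ lines).
#' @param qual Base quality string recycled per read, or "*".
#' @param pg_command Command line recorded in the @PG header.
#' @return Character vector of SAM lines.
#' @export
sam_lines <- function(aln, index, qual = "*", pg_command = "strobemap") {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", index$ref_names,
                   as.integer(index$ref_lens)),
           sprintf("@PG\tID:strobemap\tPN:strobemap\tVN:%s\tCL:%s",
                   as.character(utils::packageVersion("strobemap")),
                   pg_command))
  if (nrow(aln) == 0L) return(hdr)
  paired <- "mate" %in% names(aln)
  recs <- vapply(seq_len(nrow(aln)), function(i) {
    r <- aln[i, ]
    mapped <- !bitwAnd(r$flag, 4L)
    seq_out <- if (mapped && r$strand == "-") revcomp(r$seq) else r$seq
    q <- if (qual == "*") "*" else {
      qq <- substr(strrep(qual, ceiling(nchar(r$seq) / nchar(qual))), 1,
                   nchar(r$seq))
      if (mapped && r$strand == "-") paste(rev(strsplit(qq, "")[[1]]),
                                           collapse = "") else qq
    }
    fields <- c(r$qname, r$flag,
                if (mapped) r$rname else "*",
                if (mapped) format(r$pos + 1, scientific = FALSE) else 0,
                r$mapq,
                if (mapped) r$cigar else "*",
                if (paired && !is.na(r$rnext)) r$rnext else "*",
                if (paired && !is.na(r$pnext)) format(r$pnext + 1,
                                                      scientific = FALSE)
                else 0,
                if (paired) format(r$tlen, scientific = FALSE) else 0,
                seq_out, q)
    line <- paste(fields, collapse = "\t")
    if (mapped)
      line <- paste0(line, sprintf("\tNM:i:%d\tAS:i:%d",
                                   as.integer(r$edit), as.integer(r$score)))
    line
  }, character(1))
  c(hdr, recs)
}

#' Write SAM lines to a file
#'
#' @param lines Character vector from [sam_lines()].
#' @param path Output path.
#' @export
write_sam <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

# minimal SAM record table: qname, flag, rname, pos (0-based), mapq, cigar.
# SAM bodies are plain TSV; header lines start with '@'.
parse_sam <- function(sam) {
  lines <- if (length(sam) == 1L && file.exists(sam)) readLines(sam) else sam
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L)
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = numeric(0),
                      mapq = integer(0), cigar = character(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  data.frame(qname = vapply(f, `[[`, "", 1L),
             flag = as.integer(vapply(f, `[[`, "", 2L)),
             rname = vapply(f, `[[`, "", 3L),
             pos = as.numeric(vapply(f, `[[`, "", 4L)) - 1,
             mapq = as.integer(vapply(f, `[[`, "", 5L)),
             cigar = vapply(f, `[[`, "", 6L),
             stringsAsFactors = FALSE)
}

#' Evaluate alignment accuracy against simulation truth
#'
#' A read counts as aligned when its SAM record lacks flag 4, and as
#' correct when it is placed on the truth reference and its reported
#' reference interval overlaps the truth interval by at least
#' `min_overlap` bases.
#'
#' @param sam SAM file path or character vector of SAM lines (primary
#'   records only).
#' @param truth Truth data frame from [simulate_reads()] (columns
#'   `read_id`, `mate`, `rname`, `start`, `end`, `strand`).
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return List: `summary` (one-row data frame with `n_reads`,
#'   `pct_aligned`, `pct_correct` of aligned reads) and `by_mapq`
#'   (per-MAPQ breakdown).
#' @export
evaluate_accuracy <- function(sam, truth, min_overlap = 1) {
  rec <- parse_sam(sam)
  key <- function(qname, mate) paste0(qname, "/", mate)
  rec$mate <- ifelse(bitwAnd(rec$flag, 128L) > 0L, 2L,
                     ifelse(bitwAnd(rec$flag, 64L) > 0L, 1L, 0L))
  tr_mate <- if ("mate" %in% names(truth)) truth$mate else 0L
  tmap <- match(key(rec$qname, rec$mate), key(truth$read_id, tr_mate))
  if (anyNA(tmap))
    stop("SAM contains read ids absent from the truth table")
  aligned <- bitwAnd(rec$flag, 4L) == 0L
  ref_end <- rec$pos + vapply(rec$cigar, cigar_ref_len, numeric(1),
                              USE.NAMES = FALSE)
  ov <- pmin(ref_end, truth$end[tmap]) - pmax(rec$pos, truth$start[tmap])
  correct <- aligned & rec$rname == truth$rname[tmap] & ov >= min_overlap
  by_mapq <- do.call(rbind, lapply(sort(unique(rec$mapq[aligned])),
    function(q) {
      sel <- aligned & rec$mapq == q
      data.frame(mapq = q, n = sum(sel),
                 pct_correct = 100 * mean(correct[sel]))
    }))
  list(summary = data.frame(
         n_reads = nrow(rec),
         pct_aligned = 100 * mean(aligned),
         pct_correct = if (any(aligned)) 100 * mean(correct[aligned])
                       else 0),
       by_mapq = by_mapq)
}
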