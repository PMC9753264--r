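#' Find seed matches of a read against an index
#'
#' Generates read seeds in both orientations, looks each up in the index,
#' and emits one match per reference occurrence of every seed at or below
#' the abundance cutoff. While streaming over matches, the running minimum
#' of `d` — the absolute difference between reference and query seed span —
#' is maintained, and a match is kept iff its `d` does not exceed the
#' minimum observed so far. This one-pass filter is order-dependent by
#' design: early matches with larger `d` survive if seen before the minimum
#' drops.
#'
#' Query coordinates of reverse-orientation matches are reported on the
#' reverse-complemented read, so that query and reference coordinates
#' increase together within an orientation.
#'
#' @param read Read sequence.
#' @param index A [build_index()] result.
#' @param keep_max Keep seeds with occurrence count `<= keep_max`; defaults
#'   to the index abundance cutoff `A`.
#' @return List: `matches` (data frame `r_id`, `r_s`, `r_e`, `q_s`, `q_e`,
#'   `o`, `d`), `n_seeds`, `masked_fraction` (masked seed instances over all
#'   seed instances), `seed_counts` (per-seed reference abundance, 0 for
#'   absent).
#' @export
find_matches <- function(read, index, keep_max = NULL) {
  stopifnot(inherits(index, "strobe_index"))
  if (is.null(keep_max)) keep_max <- index$A
  res <- cpp_find_matches(index$ptr, toupper(read), as.numeric(keep_max))
  list(matches = res$matches,
       n_seeds = res$n_seeds,
       masked_fraction = if (res$n_seeds > 0) res$n_masked / res$n_seeds
                         else 0,
       seed_counts = res$seed_counts)
}

#' Relaxed-threshold seed retrieval for repeat-dense reads
#'
#' Rescue mode, intended for reads whose seed set was mostly masked
#' (callers trigger it when more than 30\% of seed instances were). Seeds
#' are reconsidered under a higher abundance threshold: all seeds with
#' occurrence count below `rescue_level * A` are accepted (or below the
#' absolute `rescue_level` when `absolute = TRUE`); if fewer than 5 seeds
#' qualify, a hard threshold of 1000 is used instead.
#'
#' @inheritParams find_matches
#' @param rescue_level Multiplier on the abundance cutoff `A` (default 2),
#'   or an absolute abundance when `absolute = TRUE`.
#' @param absolute Interpret `rescue_level` as an absolute count.
#' @return Same shape as [find_matches()].
#' @export
rescue_candidates <- function(read, index, rescue_level = 2,
                              absolute = FALSE) {
  stopifnot(inherits(index, "strobe_index"))
  probe <- find_matches(read, index)
  thr <- if (absolute) rescue_level else rescue_level * index$A
  n_qualifying <- sum(probe$seed_counts > 0 & probe$seed_counts < thr)
  if (n_qualifying < 5) thr <- 1000
  res <- find_matches(read, index, keep_max = thr - 1)
  res$masked_fraction <- probe$masked_fraction
  res
}

# matches for one read with the 30%-masked rescue trigger applied
candidate_matches <- function(read, index, rescue_level = 2,
                              absolute = FALSE) {
  res <- find_matches(read, index)
  if (res$masked_fraction > 0.3) {
    res <- rescue_candidates(read, index, rescue_level = rescue_level,
                             absolute = absolute)
  }
  m <- res$matches
  res$matches <- m[order(m$q_s, m$q_e, m$r_id, m$r_s, m$o), , drop = FALSE]
  res
}

#' Merge seed matches into candidate mapping regions
#'
#' Sweeps over matches in ascending query order, maintaining a list of open
#' merged matches. A match `m'` joins a merged match whose last-added match
#' is `m` iff (i) both are on the same reference and orientation, (ii)
#' `m.q_s < m'.q_s <= m.q_e` and (iii) `m.r_s < m'.r_s <= m.r_e` (overlap
#' on query and reference), and (iv) the four strobes are consistently
#' ordered — either staggered on both query and reference or nested on
#' both. Inconsistent orderings (e.g. staggered on the query but nested on
#' the reference, a signature of local repeats) start separate merged
#' matches. A merged match closes once the sweep passes its query end;
#' duplicate matches are dropped before merging.
#'
#' @param matches Data frame as returned by [find_matches()], sorted by
#'   ascending `q_s` (an error otherwise).
#' @return Data frame with one row per merged match: `r_id`, `o`, `q_s`,
#'   `q_e`, `r_s`, `r_e` (extremal coordinates), `n` (matches merged),
#'   `a`, `b` (query/reference spans) and `score`
#'   (`(min(a,b) - |a-b|) * n`).
#' @export
merge_matches <- function(matches) {
  cols <- c("r_id", "r_s", "r_e", "q_s", "q_e", "o")
  stopifnot(all(cols %in% names(matches)))
  empty <- data.frame(r_id = integer(), o = integer(), q_s = numeric(),
                      q_e = numeric(), r_s = numeric(), r_e = numeric(),
                      n = integer(), a = numeric(), b = numeric(),
                      score = numeric())
  if (nrow(matches) == 0L) return(empty)
  if (is.unsorted(matches$q_s)) stop("matches must be sorted by query start")
  m <- matches[!duplicated(matches[cols]), , drop = FALSE]

  open <- list()
  out <- vector("list", nrow(m))
  n_out <- 0L
  close_merged <- function(M) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- M
  }
  for (i in seq_len(nrow(m))) {
    qs <- m$q_s[i]; qe <- m$q_e[i]
    rs <- m$r_s[i]; re <- m$r_e[i]
    rid <- m$r_id[i]; o <- m$o[i]
    keep <- rep(TRUE, length(open))
    joined <- FALSE
    for (j in seq_along(open)) {
      M <- open[[j]]
      if (M$q_e < qs) {               # closed: sweep has passed it
        close_merged(M)
        keep[j] <- FALSE
        next
      }
      if (joined || M$r_id != rid || M$o != o) next
      L <- M$last                      # c(q_s, q_e, r_s, r_e) of last match
      if (!(L[1] < qs && qs <= L[2] && L[3] < rs && rs <= L[4])) next
      staggered <- qs < L[2] && L[2] < qe && rs < L[4] && L[4] < re
      nested    <- qe < L[2] && re < L[4]
      if (!(staggered || nested)) next
      M$q_e <- max(M$q_e, qe); M$r_e <- max(M$r_e, re)
      M$n <- M$n + 1L
      M$last <- c(qs, qe, rs, re)
      open[[j]] <- M
      joined <- TRUE
    }
    open <- open[keep]
    if (!joined) {
      open[[length(open) + 1L]] <- list(
        r_id = rid, o = o, q_s = qs, q_e = qe, r_s = rs, r_e = re,
        n = 1L, last = c(qs, qe, rs, re))
    }
  }
  for (M in open) close_merged(M)
  out <- out[seq_len(n_out)]
  res <- data.frame(
    r_id = vapply(out, `[[`, integer(1), "r_id"),
    o = vapply(out, `[[`, numeric(1), "o"),
    q_s = vapply(out, `[[`, numeric(1), "q_s"),
    q_e = vapply(out, `[[`, numeric(1), "q_e"),
    r_s = vapply(out, `[[`, numeric(1), "r_s"),
    r_e = vapply(out, `[[`, numeric(1), "r_e"),
    n = vapply(out, `[[`, integer(1), "n"))
  res$a <- res$q_e - res$q_s
  res$b <- res$r_e - res$r_s
  res$score <- score_merged(res)
  res
}

#' Merged-match score
#'
#' `S_M = (min(a, b) - |a - b|) * n`: only the smaller of the query and
#' reference spans counts, a difference between the two spans is penalised,
#' and the score scales with the number of merged matches. May be negative
#' when the span difference exceeds the smaller span.
#'
#' @param a Query span (or a merged-match data frame, in which case `b` and
#'   `n` are taken from its columns).
#' @param b Reference span.
#' @param n Number of matches merged.
#' @return Numeric score(s).
#' @export
score_merged <- function(a, b = NULL, n = NULL) {
  if (is.data.frame(a)) {
    n <- a$n; b <- a$b; a <- a$a
  }
  (pmin(a, b) - abs(a - b)) * n
}

#' Mapping quality from the top two candidate scores
#'
#' `MAPQ = 40 (1 - S2/S1) * min(1, n/10) * ln(S1)`, rounded down and clamped
#' to \[0, 60\]; `S1 <= 0` yields 0. A read with a single candidate is
#' scored with `S2 = 0`.
#'
#' @param S1,S2 Top two candidate scores (`S1 >= S2`).
#' @param n_top Number of merged seed matches in the top candidate.
#' @return Integer MAPQ in \[0, 60\].
#' @export
mapq <- function(S1, S2, n_top) {
  if (length(S1) == 0L || is.na(S1) || S1 <= 0) return(0L)
  if (is.na(S2)) S2 <- 0
  v <- 40 * (1 - S2 / S1) * min(1, n_top / 10) * log(S1)
  as.integer(max(0, min(60, floor(v))))
}

# rank merged matches: descending score, ties by (r_id, r_s) for determinism
rank_candidates <- function(merged) {
  merged[order(-merged$score, merged$r_id, merged$r_s), , drop = FALSE]
}

#' Extension-free mapping of reads
#'
#' Reports the best merged match per read without base-level alignment, in a
#' PAF-like table. Query coordinates are given on the forward read.
#'
#' @param reads Named character vector of read sequences (names become
#'   query ids; unnamed reads get `read1`, `read2`, ...).
#' @param index A [build_index()] result.
#' @param rescue_level,absolute Rescue parameters, see
#'   [rescue_candidates()].
#' @return Data frame with columns `qname`, `qlen`, `q_s`, `q_e`, `strand`,
#'   `rname`, `rlen`, `r_s`, `r_e`, `n_matches`, `score`, `mapq`; unmapped
#'   reads carry `strand = "*"` and NA coordinates.
#' @export
map_extension_free <- function(reads, index, rescue_level = 2,
                               absolute = FALSE) {
  stopifnot(inherits(index, "strobe_index"))
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    read <- toupper(reads[[i]])
    qlen <- nchar(read)
    unmapped <- data.frame(qname = names(reads)[i], qlen = qlen,
                           q_s = NA_real_, q_e = NA_real_, strand = "*",
                           rname = "*", rlen = NA_real_, r_s = NA_real_,
                           r_e = NA_real_, n_matches = 0L, score = NA_real_,
                           mapq = 0L, stringsAsFactors = FALSE)
    res <- candidate_matches(read, index, rescue_level, absolute)
    if (nrow(res$matches) == 0L) return(unmapped)
    merged <- rank_candidates(merge_matches(res$matches))
    best <- merged[1L, ]
    S2 <- if (nrow(merged) >= 2L) max(merged$score[2L], 0) else 0
    qs <- best$q_s; qe <- best$q_e
    if (best$o == 1) { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
    data.frame(qname = names(reads)[i], qlen = qlen, q_s = qs, q_e = qe,
               strand = if (best$o == 1) "-" else "+",
               rname = index$ref_names[best$r_id + 1L],
               rlen = index$ref_lens[[best$r_id + 1L]],
               r_s = best$r_s, r_e = best$r_e, n_matches = best$n,
               score = best$score,
               mapq = mapq(best$score, S2, best$n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
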