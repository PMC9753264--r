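#' Insert-size model
#'
#' @param mu Mean template length.
#' @param sigma Standard deviation (floored at 1).
#' @param n_observations Number of concordant pairs used.
#' @return Object of class `insert_size_model`.
#' @export
insert_size_model <- function(mu = 300, sigma = 100, n_observations = 0L) {
  structure(list(mu = mu, sigma = max(sigma, 1), n_observations = n_observations),
            class = "insert_size_model")
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat(sprintf("insert_size_model: mu=%.1f sigma=%.1f (n=%d pairs)\n",
              x$mu, x$sigma, x$n_observations))
  invisible(x)
}

# template-length observations from candidate lists of mate pairs:
# both mates must have a unique best merged match, on the same reference,
# in FR orientation. The template is measured by projecting the full read
# extents through the merged matches (exact for error-free seeds).
concordant_spans <- function(cands1, cands2, len1, len2) {
  spans <- numeric(0)
  for (i in seq_along(cands1)) {
    m1 <- cands1[[i]]$merged
    m2 <- cands2[[i]]$merged
    if (nrow(m1) == 0L || nrow(m2) == 0L) next
    if (nrow(m1) > 1L && m1$score[2L] == m1$score[1L]) next
    if (nrow(m2) > 1L && m2$score[2L] == m2$score[1L]) next
    b1 <- m1[1L, ]; b2 <- m2[1L, ]
    if (b1$r_id != b2$r_id || b1$o == b2$o) next
    fwd <- if (b1$o == 0) b1 else b2
    rev <- if (b1$o == 0) b2 else b1
    if (fwd$r_s > rev$r_s) next
    p1s <- b1$r_s - b1$q_s; p1e <- b1$r_e + (len1[i] - b1$q_e)
    p2s <- b2$r_s - b2$q_s; p2e <- b2$r_e + (len2[i] - b2$q_e)
    spans <- c(spans, max(p1e, p2e) - min(p1s, p2s))
  }
  spans
}

fit_insert_model <- function(spans, max_pairs = 500, min_pairs = 100) {
  if (length(spans) < min_pairs) {
    warning("too few concordant pairs for insert-size estimation; ",
            "falling back to defaults mu=300, sigma=100")
    return(insert_size_model(300, 100, 0L))
  }
  spans <- spans[seq_len(min(length(spans), max_pairs))]
  med <- stats::median(spans)
  dev <- stats::mad(spans)
  keep <- abs(spans - med) <= 10 * max(dev, 1)
  spans <- spans[keep]
  insert_size_model(mean(spans), stats::sd(spans), length(spans))
}

#' Estimate the insert-size distribution from read pairs
#'
#' Scans pairs until enough concordant observations are found: a pair
#' counts when both mates have a unique best merged match on the same
#' reference in FR orientation. The template lengths of the first
#' `max_pairs` such pairs, after discarding observations outside the
#' median plus/minus 10 MAD, give the moment estimates; the model is
#' frozen thereafter. With fewer than `min_pairs` observations the
#' documented defaults (mu 300, sigma 100) are returned with a warning.
#'
#' @param r1,r2 Character vectors of mate sequences.
#' @param index A [build_index()] result.
#' @param max_pairs Pairs used for estimation (default 500).
#' @param min_pairs Minimum concordant pairs before falling back.
#' @return An [insert_size_model()].
#' @export
estimate_insert_size <- function(r1, r2, index, max_pairs = 500,
                                 min_pairs = 100) {
  stopifnot(length(r1) == length(r2))
  spans <- numeric(0)
  for (i in seq_along(r1)) {
    c1 <- read_candidates(toupper(r1[[i]]), index)
    c2 <- read_candidates(toupper(r2[[i]]), index)
    spans <- c(spans, concordant_spans(list(c1), list(c2),
                                       nchar(r1[[i]]), nchar(r2[[i]])))
    if (length(spans) >= max_pairs) break
  }
  fit_insert_model(spans, max_pairs, min_pairs)
}

# proper-pair predicate on two placements (lists with r_id, o, r_s, r_e):
# same reference, opposite orientation, FR, distance below mu + 10 sigma.
# Symmetric in its two arguments.
proper_pair_ok <- function(p1, p2, model) {
  if (is.null(p1) || is.null(p2)) return(FALSE)
  if (p1$r_id != p2$r_id || p1$o == p2$o) return(FALSE)
  fwd <- if (p1$o == 0) p1 else p2
  rev <- if (p1$o == 0) p2 else p1
  if (fwd$r_s > rev$r_s) return(FALSE)
  span <- max(p1$r_e, p2$r_e) - min(p1$r_s, p2$r_s)
  span < model$mu + 10 * model$sigma
}

#' Joint score of a candidate placement for a read pair
#'
#' The joint map-location count is `C_ij = n_i + n_j` when the two merged
#' matches form a proper pair under the insert model, otherwise the mates
#' count individually. Given the mates' Smith-Waterman scores, the pair
#' alignment score is `SW_i + SW_j + log N(d_ij; mu, sigma)` for proper
#' pairs (natural log of the normal density at the template length) and
#' `SW_i + SW_j - 10` for individually placed mates; -10 corresponds to a
#' template more than four standard deviations from the mean.
#'
#' @param M_i,M_j One-row merged-match data frames for mate 1 and mate 2.
#' @param model An [insert_size_model()].
#' @param sw_i,sw_j Smith-Waterman scores of the two extended mates
#'   (optional; `S_ij` is NA without them).
#' @param d_ij Template length; defaults to the outer span of the two
#'   merged matches.
#' @return List with `C_ij`, `S_ij` and `proper_pair`.
#' @export
score_pair <- function(M_i, M_j, model, sw_i = NULL, sw_j = NULL,
                       d_ij = NULL) {
  proper <- proper_pair_ok(M_i, M_j, model)
  C <- if (proper) M_i$n + M_j$n else max(M_i$n, M_j$n)
  S <- NA_real_
  if (!is.null(sw_i) && !is.null(sw_j)) {
    if (proper) {
      if (is.null(d_ij))
        d_ij <- max(M_i$r_e, M_j$r_e) - min(M_i$r_s, M_j$r_s)
      S <- sw_i + sw_j + stats::dnorm(d_ij, model$mu, model$sigma, log = TRUE)
    } else {
      S <- sw_i + sw_j - 10
    }
  }
  list(C_ij = C, S_ij = S, proper_pair = proper)
}

# extend one mate at one merged match; returns extend_candidate() output
# augmented with placement info, or NULL
extend_at <- function(read, index, M, pad = 20) {
  ref <- index$refs[[M$r_id + 1L]]
  r <- if (M$o == 1) revcomp(read) else read
  seg <- extract_segment(M, nchar(read), ref, pad = pad)
  if (is.null(seg)) return(NULL)
  res <- extend_candidate(r, seg$segment, seg$start, M)
  if (is.null(res)) return(NULL)
  res$r_id <- M$r_id
  res$o <- M$o
  res$ref_end <- res$ref_start + cigar_ref_len(res$cigar)
  res
}

#' Rescue an unseeded mate near its placed partner
#'
#' Aligns the mate without merged matches by Smith-Waterman against the
#' genomic window up to `mu + 5 sigma` bases away from the placed mate in
#' the expected (FR) direction and orientation. The rescue is accepted if
#' its score reaches at least half the read length, otherwise the mate is
#' reported unmapped.
#'
#' @param placed List describing the placed mate: `r_id`, `o`,
#'   `ref_start`, `ref_end` (0-based, half-open).
#' @param read Sequence of the unplaced mate (forward, as sequenced).
#' @param model An [insert_size_model()].
#' @param index A [build_index()] result.
#' @param min_score_frac Acceptance floor as a fraction of read length.
#' @return An alignment list like [extend_candidate()]'s (with `r_id`,
#'   `o`, `ref_end`), or `NULL` when rescue fails.
#' @export
mate_rescue <- function(placed, read, model, index, min_score_frac = 0.5) {
  ref <- index$refs[[placed$r_id + 1L]]
  w <- ceiling(model$mu + 5 * model$sigma)
  if (placed$o == 0) {           # mate expected downstream, reverse strand
    lo <- placed$ref_start
    hi <- min(nchar(ref), placed$ref_start + w)
    r <- revcomp(read)
    o <- 1L
  } else {                        # mate expected upstream, forward strand
    lo <- max(0, placed$ref_end - w)
    hi <- placed$ref_end
    r <- read
    o <- 0L
  }
  if (hi <= lo) return(NULL)
  seg <- substr(ref, lo + 1, hi)
  sw <- cpp_sw_align(r, seg)
  if (!sw$aligned || sw$score < min_score_frac * nchar(read)) return(NULL)
  list(score = sw$score, cigar = sw$cigar, ref_start = lo + sw$r_s,
       edit = sw$edit, n_mismatch = sw$n_mismatch, method = "sw",
       aligned = TRUE, r_id = placed$r_id, o = o,
       ref_end = lo + sw$r_s + cigar_ref_len(sw$cigar))
}

#' Align read pairs
#'
#' Candidate pair placements are enumerated from the mates' merged matches,
#' ranked by the joint seed count `C` (proper combinations first, then
#' individually placed candidates), and extended in rank order; the pair
#' with the best joint score `S_ij` (see [score_pair()]) wins. A mate with
#' no merged matches is rescued near its partner with [mate_rescue()].
#' The joint MAPQ derives from the top two `S_ij` via [mapq()] and is
#' assigned to both mates.
#'
#' @param r1,r2 Named character vectors of mate-1 and mate-2 sequences
#'   (names of `r1` become the query names).
#' @param index A [build_index()] result with references attached.
#' @param model An [insert_size_model()]; estimated from the input pairs
#'   when `NULL`.
#' @param max_candidates Maximum candidate pair placements extended.
#' @param rescue_level,absolute,pad See [align_single()].
#' @return Data frame of alignment records (two rows per pair) with the
#'   columns of [align_single()] plus `mate`, `proper`, `rnext`, `pnext`,
#'   `tlen`.
#' @export
align_paired <- function(r1, r2, index, model = NULL, max_candidates = 20,
                         rescue_level = 2, absolute = FALSE, pad = 20) {
  stopifnot(inherits(index, "strobe_index"), length(r1) == length(r2))
  if (is.null(index$refs))
    stop("index has no reference sequences attached; rebuild or load with `references=`")
  if (is.null(names(r1))) names(r1) <- paste0("pair", seq_along(r1))
  r1 <- toupper(r1); r2 <- toupper(r2)

  cands1 <- lapply(r1, read_candidates, index = index,
                   rescue_level = rescue_level, absolute = absolute)
  cands2 <- lapply(r2, read_candidates, index = index,
                   rescue_level = rescue_level, absolute = absolute)
  if (is.null(model))
    model <- fit_insert_model(concordant_spans(cands1, cands2,
                                               nchar(r1), nchar(r2)))

  rows <- vector("list", 2L * length(r1))
  for (i in seq_along(r1)) {
    res <- align_one_pair(r1[[i]], r2[[i]], cands1[[i]]$merged,
                          cands2[[i]]$merged, index, model,
                          max_candidates, pad)
    rows[[2L * i - 1L]] <- pair_record(names(r1)[i], 1L, r1[[i]], res$a1,
                                       res$a2, res$proper, res$mapq, index)
    rows[[2L * i]] <- pair_record(names(r1)[i], 2L, r2[[i]], res$a2,
                                  res$a1, res$proper, res$mapq, index)
  }
  do.call(rbind, rows)
}

# core per-pair placement: returns list(a1, a2, proper, mapq)
align_one_pair <- function(read1, read2, m1, m2, index, model,
                           max_candidates, pad) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  if (n1 == 0L && n2 == 0L)
    return(list(a1 = NULL, a2 = NULL, proper = FALSE, mapq = 0L))
  lim1 <- min(n1, max_candidates); lim2 <- min(n2, max_candidates)
  rows1 <- lapply(seq_len(lim1), function(i) as.list(m1[i, ]))
  rows2 <- lapply(seq_len(lim2), function(j) as.list(m2[j, ]))
  ext1 <- vector("list", lim1); ext2 <- vector("list", lim2)
  get_ext <- function(mate, idx) {
    if (mate == 1L) {
      if (is.null(ext1[[idx]]))
        ext1[[idx]] <<- list(val = extend_at(read1, index, rows1[[idx]], pad))
      ext1[[idx]]$val
    } else {
      if (is.null(ext2[[idx]]))
        ext2[[idx]] <<- list(val = extend_at(read2, index, rows2[[idx]], pad))
      ext2[[idx]]$val
    }
  }
  # best individual placement of a mate, extending top candidates lazily;
  # returns the extension together with the candidate index used
  best_individual <- function(mate, lim) {
    best <- NULL; best_idx <- NA_integer_
    for (idx in seq_len(min(lim, 3L))) {
      e <- get_ext(mate, idx)
      if (!is.null(e) && (is.null(best) || e$score > best$score)) {
        best <- e; best_idx <- idx
      }
    }
    list(ext = best, idx = best_idx)
  }

  # one-sided pairs: place the seeded mate, rescue the other
  if (n1 == 0L || n2 == 0L) {
    seeded_read <- if (n1 == 0L) read2 else read1
    other_read <- if (n1 == 0L) read1 else read2
    merged <- if (n1 == 0L) m2 else m1
    best <- extend_best(seeded_read, index, merged,
                        max_candidates = max_candidates, pad = pad)
    if (is.null(best))
      return(list(a1 = NULL, a2 = NULL, proper = FALSE, mapq = 0L))
    best$ref_end <- best$ref_start + cigar_ref_len(best$cigar)
    resc <- mate_rescue(best, other_read, model, index)
    q <- mapq(best$S1, best$S2, best$n_top)
    proper <- !is.null(resc) &&
      proper_pair_ok(list(r_id = best$r_id, o = best$o, r_s = best$ref_start,
                          r_e = best$ref_end),
                     list(r_id = resc$r_id, o = resc$o, r_s = resc$ref_start,
                          r_e = resc$ref_end), model)
    if (n1 == 0L)
      return(list(a1 = resc, a2 = best, proper = proper, mapq = q))
    return(list(a1 = best, a2 = resc, proper = proper, mapq = q))
  }

  # enumerate candidate pair placements ranked by joint seed count:
  # proper (i, j) combinations count n_i + n_j, individuals their own n
  grid <- expand.grid(i = seq_len(lim1), j = seq_len(lim2))
  same_ref <- m1$r_id[grid$i] == m2$r_id[grid$j]
  opp <- m1$o[grid$i] != m2$o[grid$j]
  fs <- ifelse(m1$o[grid$i] == 0, m1$r_s[grid$i], m2$r_s[grid$j])
  rs <- ifelse(m1$o[grid$i] == 0, m2$r_s[grid$j], m1$r_s[grid$i])
  span <- pmax(m1$r_e[grid$i], m2$r_e[grid$j]) -
          pmin(m1$r_s[grid$i], m2$r_s[grid$j])
  ok <- same_ref & opp & fs <= rs & span < model$mu + 10 * model$sigma
  cand <- data.frame(
    i = c(grid$i[ok], seq_len(lim1), rep(NA_integer_, lim2)),
    j = c(grid$j[ok], rep(NA_integer_, lim1), seq_len(lim2)),
    C = c(m1$n[grid$i[ok]] + m2$n[grid$j[ok]], m1$n[seq_len(lim1)],
          m2$n[seq_len(lim2)]),
    joint = c(rep(TRUE, sum(ok)), rep(FALSE, lim1 + lim2)))
  cand <- cand[order(-cand$C, !cand$joint), , drop = FALSE]
  keep <- cand$C >= 0.5 * cand$C[1L]   # drop-off relative to best candidate
  keep[1L] <- TRUE
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) > max_candidates)
    cand <- cand[seq_len(max_candidates), , drop = FALSE]

  best_i <- NULL; best_j <- NULL  # lazy individual fallbacks
  # scores are tracked per distinct placement (final alignment coordinates
  # of the two mates): fragments of one locus, or an individually scored
  # copy of the winning placement, must not masquerade as the second-best
  # candidate when computing MAPQ
  S_by_key <- numeric(0)
  picks <- list()
  for (cc in seq_len(nrow(cand))) {
    i <- cand$i[cc]; j <- cand$j[cc]
    if (cand$joint[cc]) {
      e1 <- get_ext(1L, i); e2 <- get_ext(2L, j)
      if (is.null(e1) || is.null(e2)) next
      d <- max(e1$ref_end, e2$ref_end) - min(e1$ref_start, e2$ref_start)
      S <- e1$score + e2$score +
        stats::dnorm(d, model$mu, model$sigma, log = TRUE)
      a1 <- e1; a2 <- e2; proper <- TRUE
    } else {
      if (!is.na(i)) {
        e1 <- get_ext(1L, i)
        if (is.null(best_j)) best_j <- best_individual(2L, lim2)
        e2 <- best_j$ext
      } else {
        if (is.null(best_i)) best_i <- best_individual(1L, lim1)
        e1 <- best_i$ext
        e2 <- get_ext(2L, j)
      }
      if (is.null(e1) && is.null(e2)) next
      s1 <- if (is.null(e1)) 0 else e1$score
      s2 <- if (is.null(e2)) 0 else e2$score
      S <- s1 + s2 - 10
      a1 <- e1; a2 <- e2; proper <- FALSE
    }
    place <- function(e) if (is.null(e)) "-"
                         else paste(e$r_id, e$ref_start, e$o, sep = ":")
    key <- paste(place(a1), place(a2))
    if (is.na(S_by_key[key]) || S > S_by_key[key]) {
      S_by_key[key] <- S
      picks[[key]] <- list(a1 = a1, a2 = a2, proper = proper)
    }
    # early stops: a perfect pair ends the search; after a combined edit
    # distance of 1 no further base-level calls are made
    if (!is.null(e1) && !is.null(e2) &&
        (e1$edit + e2$edit) <= 1 && proper) break
  }
  if (length(S_by_key) == 0L)
    return(list(a1 = NULL, a2 = NULL, proper = FALSE, mapq = 0L))
  ord <- order(-S_by_key)
  S_best <- S_by_key[ord[1L]]
  S_second <- if (length(S_by_key) >= 2L) S_by_key[ord[2L]] else -Inf
  pick <- picks[[names(S_by_key)[ord[1L]]]]
  # verify properness on the final alignment coordinates
  if (pick$proper && !is.null(pick$a1) && !is.null(pick$a2)) {
    pick$proper <- proper_pair_ok(
      list(r_id = pick$a1$r_id, o = pick$a1$o, r_s = pick$a1$ref_start,
           r_e = pick$a1$ref_end),
      list(r_id = pick$a2$r_id, o = pick$a2$o, r_s = pick$a2$ref_start,
           r_e = pick$a2$ref_end), model)
  }
  n_top <- max(m1$n[1L], m2$n[1L])
  q <- mapq(S_best, if (is.finite(S_second)) max(S_second, 0) else 0, n_top)
  list(a1 = pick$a1, a2 = pick$a2, proper = pick$proper, mapq = q)
}

# build one output row for a mate; `aln` may be NULL (unmapped)
pair_record <- function(qname, mate, read, aln, mate_aln, proper, q,
                        index) {
  flag <- 1L + if (mate == 1L) 64L else 128L
  if (is.null(aln)) flag <- flag + 4L
  if (is.null(mate_aln)) flag <- flag + 8L
  if (!is.null(aln) && aln$o == 1) flag <- flag + 16L
  if (!is.null(mate_aln) && mate_aln$o == 1) flag <- flag + 32L
  both <- !is.null(aln) && !is.null(mate_aln)
  if (proper && both) flag <- flag + 2L
  tlen <- 0
  if (both && aln$r_id == mate_aln$r_id) {
    lo <- min(aln$ref_start, mate_aln$ref_start)
    hi <- max(aln$ref_end, mate_aln$ref_end)
    tlen <- if (aln$ref_start <= mate_aln$ref_start) hi - lo else lo - hi
    if (aln$ref_start == mate_aln$ref_start && mate == 2L)
      tlen <- -(hi - lo)
  }
  data.frame(
    qname = qname, mate = mate,
    flag = flag,
    rname = if (is.null(aln)) "*" else index$ref_names[aln$r_id + 1L],
    pos = if (is.null(aln)) NA_real_ else aln$ref_start,
    mapq = if (is.null(aln)) 0L else q,
    cigar = if (is.null(aln)) "*" else aln$cigar,
    strand = if (is.null(aln)) "*" else if (aln$o == 1) "-" else "+",
    score = if (is.null(aln)) NA_real_ else aln$score,
    edit = if (is.null(aln)) NA_real_ else aln$edit,
    seq = read,
    proper = proper && both,
    rnext = if (is.null(mate_aln)) "*"
            else if (!is.null(aln) && aln$r_id == mate_aln$r_id) "="
            else index$ref_names[mate_aln$r_id + 1L],
    pnext = if (is.null(mate_aln)) NA_real_ else mate_aln$ref_start,
    tlen = tlen,
    stringsAsFactors = FALSE)
}
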