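#' Seed census: occurrence counts of distinct seeds
#'
#' @param counts Integer vector of occurrences per distinct seed (optionally
#'   named by hash); every entry must be >= 1.
#' @param median_span Optional median seed span in bases (randstrobes).
#' @return Object of class `seed_census` with fields `counts`, `N` (total
#'   seeds) and `M` (distinct seeds).
#' @export
seed_census <- function(counts, median_span = NA_real_) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("empty census")
  if (any(counts < 1 | counts != floor(counts)))
    stop("census counts must be positive integers")
  structure(list(counts = counts, N = sum(counts), M = length(counts),
                 median_span = median_span),
            class = "seed_census")
}

#' @export
print.seed_census <- function(x, ...) {
  cat(sprintf("seed_census: N=%s seeds, M=%s distinct, E-hits=%.4g\n",
              format(x$N, big.mark = ","), format(x$M, big.mark = ","),
              ehits(x)))
  invisible(x)
}

#' E-hits: expected occurrence count of a randomly sampled seed
#'
#' For occurrence counts \eqn{x_1, \dots, x_M} over \eqn{N = \sum x_i} seed
#' instances, E-hits is \eqn{\frac{1}{N}\sum_i x_i^2} — the expected number
#' of reference hits of a seed drawn uniformly from the multiset of seeds,
#' and hence (for uniformly sampled reads) the expected match count of an
#' error-free read seed. Equals 1 iff all seeds are unique.
#'
#' @param census A [seed_census()] or a raw vector of counts.
#' @return Numeric >= 1.
#' @export
ehits <- function(census) {
  if (!inherits(census, "seed_census")) census <- seed_census(census)
  sum(census$counts^2) / census$N
}

#' Fraction of seed instances that would be hard masked
#'
#' The fraction of seed *instances* whose hash occurs strictly more than
#' `threshold` times in the reference. Instance weighting (rather than
#' distinct-hash weighting) matches the sampling model behind [ehits()].
#'
#' @inheritParams ehits
#' @param threshold Occurrence cutoff (default 1000).
#' @return Numeric in \[0, 1\].
#' @export
hard_masked_fraction <- function(census, threshold = 1000) {
  if (!inherits(census, "seed_census")) census <- seed_census(census)
  sum(census$counts[census$counts > threshold]) / census$N
}

#' Seed census of a reference under a chosen seeding method
#'
#' Computes canonical-hash seed counts for plain k-mers, window minimizers,
#' open syncmers, or randstrobe seeds, over one or more sequences. For
#' randstrobes the median seed span is recorded alongside.
#'
#' @param seq Character vector of sequences (one census over all of them).
#' @param method One of "kmers", "minimizers", "syncmers", "randstrobes".
#' @param k k-mer/strobe length.
#' @param w Minimizer window (minimizers only).
#' @param s,t Syncmer parameters (syncmers only); `s` defaults to `k - 4`,
#'   `t` to the central offset.
#' @param profile [seed_profile()] for randstrobes.
#' @return A [seed_census()].
#' @export
census_of <- function(seq, method = c("kmers", "minimizers", "syncmers",
                                      "randstrobes"),
                      k = 20, w = 9, s = k - 4, t = NULL,
                      profile = seed_profile(k = k)) {
  method <- match.arg(method)
  spans <- NULL
  hashes <- unlist(lapply(seq, function(x) {
    switch(method,
      kmers = cpp_kmer_hashes(x, as.integer(k)),
      minimizers = cpp_minimizers(x, as.integer(k), as.integer(w))$hash,
      syncmers = open_syncmers(x, k = k, s = s, t = t)$hash,
      randstrobes = {
        df <- reference_seeds(x, profile)
        spans <<- c(spans, df$q_e - df$q_s)
        df$hash
      })
  }), use.names = FALSE)
  if (length(hashes) == 0L) stop("no seeds produced: sequence shorter than k?")
  tab <- table(hashes)
  seed_census(as.numeric(tab),
              median_span = if (is.null(spans)) NA_real_
                            else stats::median(spans))
}

#' Seed-repetitiveness comparison across seeding methods
#'
#' Runs [census_of()] for each requested method over the same references
#' and tabulates total seeds, distinct seeds, E-hits and the hard-masked
#' fraction (instance-weighted; see [hard_masked_fraction()]).
#'
#' @param references Sequences, `DNAStringSet`, or FASTA path.
#' @param methods Methods to compare.
#' @param read_length Read length selecting the randstrobe profile.
#' @param k,w Parameters forwarded to [census_of()].
#' @param mask_threshold Hard-mask occurrence cutoff.
#' @return Data frame with one row per method: `method`, `params`,
#'   `median_span`, `N`, `M`, `ehits`, `hard_masked_frac`.
#' @export
seed_stats <- function(references,
                       methods = c("kmers", "minimizers", "syncmers",
                                   "randstrobes"),
                       read_length = 150, k = 20, w = 9,
                       mask_threshold = 1000) {
  if (is.character(references) && length(references) == 1L &&
      !grepl("^[ACGTNacgtn]+$", references) && file.exists(references))
    references <- read_fasta(references)
  if (inherits(references, "DNAStringSet"))
    references <- as.character(references)
  profile <- choose_profile(read_length)
  rows <- lapply(methods, function(m) {
    cen <- census_of(references, method = m, k = k, w = w, profile = profile)
    params <- switch(m,
      kmers = sprintf("k=%d", k),
      minimizers = sprintf("k=%d,w=%d", k, w),
      syncmers = sprintf("k=%d,s=%d,t=%d", k, k - 4,
                         ceiling((k - (k - 4) + 1) / 2)),
      randstrobes = sprintf("k=%d,s=%d,w=[%d,%d],p=%d", profile$k,
                            profile$s, profile$w_min, profile$w_max,
                            profile$p))
    data.frame(method = m, params = params,
               median_span = if (is.na(cen$median_span)) k
                             else cen$median_span,
               N = cen$N, M = cen$M, ehits = ehits(cen),
               hard_masked_frac = hard_masked_fraction(cen, mask_threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
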