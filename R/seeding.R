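#' Seeding parameter profile
#'
#' Bundles the tunables of syncmer-randstrobe seeding. `s_delta = k - s`
#' fixes the inner s-mer length, `t = ceiling((k-s+1)/2)` is the (1-based)
#' central selection offset required for strand-symmetric syncmers, and the
#' syncmer-count window bounds derive from the offsets `l` and `u` as
#' `w_min = k %/% (k-s+1) + l` (floored at 1) and
#' `w_max = k %/% (k-s+1) + u`. `max_seed_len` caps the seed span in bases.
#'
#' @param k Strobe (syncmer) length in bases.
#' @param s_delta k minus the inner s-mer length; `k - s_delta + 1` must be
#'   odd so that syncmer selection is strand-symmetric.
#' @param p Skew-mask width in bits (1-64) for randstrobe linking.
#' @param l,u Lower/upper window offsets in syncmer counts.
#' @param max_seed_len Hard cap on seed span in bases.
#' @return Object of class `seed_profile`.
#' @export
seed_profile <- function(k = 20, s_delta = 4, p = 8, l = 1, u = 7,
                         max_seed_len = 100L) {
  s <- k - s_delta
  stopifnot(k >= 4, k <= 31, s >= 1, s <= k, p >= 1, p <= 64)
  win <- k - s + 1
  if (win %% 2 == 0)
    warning("k - s + 1 is even: syncmer selection is not strand-symmetric")
  t <- ceiling(win / 2)
  w_min <- max(1L, k %/% win + l)
  w_max <- k %/% win + u
  if (w_min > w_max) stop("w_min exceeds w_max: check l and u")
  max_seed_len <- max(as.integer(max_seed_len), k + 1L)
  structure(list(k = as.integer(k), s = as.integer(s), t = as.integer(t),
                 p = as.integer(p), l = as.integer(l), u = as.integer(u),
                 w_min = as.integer(w_min), w_max = as.integer(w_max),
                 max_seed_len = max_seed_len),
            class = "seed_profile")
}

#' @export
print.seed_profile <- function(x, ...) {
  cat(sprintf(
    "seed_profile: k=%d s=%d t=%d p=%d window=[%d,%d] syncmers (l=%d,u=%d) max_seed_len=%d\n",
    x$k, x$s, x$t, x$p, x$w_min, x$w_max, x$l, x$u, x$max_seed_len))
  invisible(x)
}

#' Choose a seeding profile from the median read length
#'
#' Returns the parameter tuple (k, s_delta, p, l, u) appropriate for a given
#' median read length, with the seed-span cap defaulting to the median read
#' length minus 50 (floored at k+1).
#'
#' @param median_read_len Median read length in bases (>= 1).
#' @return A [seed_profile()].
#' @export
choose_profile <- function(median_read_len) {
  stopifnot(median_read_len >= 1)
  x <- median_read_len
  tup <-
    if (x <= 75)       c(20, 4, 8, -4, 2)
    else if (x <= 125) c(20, 4, 8, -2, 2)
    else if (x <= 175) c(20, 4, 8, 1, 7)
    else if (x <= 275) c(20, 4, 8, 4, 13)
    else if (x <= 375) c(22, 4, 8, 2, 12)
    else               c(23, 6, 8, 2, 12)
  seed_profile(k = tup[1], s_delta = tup[2], p = tup[3], l = tup[4],
               u = tup[5], max_seed_len = max(round(x) - 50, tup[1] + 1))
}

#' Canonical open syncmers of a sequence
#'
#' Scans every decodable k-mer, hashes its `k - s + 1` constituent s-mers
#' canonically, and selects the k-mer iff the minimum s-mer hash occurs at
#' offset `t` (1-based; ties broken toward the smallest offset). The stored
#' hash is the canonical k-mer hash, so syncmer selection and hashes are
#' identical between a sequence and its reverse complement when `k - s + 1`
#' is odd and `t` is central.
#'
#' @param seq Nucleotide string.
#' @param k Syncmer length.
#' @param s Inner s-mer length.
#' @param t 1-based selection offset; defaults to the central position.
#' @return Data frame with columns `pos` (0-based) and `hash` (hex),
#'   sorted by position.
#' @export
open_syncmers <- function(seq, k = 20, s = 16, t = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, s <= k)
  if (is.null(t)) t <- ceiling((k - s + 1) / 2)
  cpp_syncmers(seq, as.integer(k), as.integer(s), as.integer(t))
}

#' Randstrobe partner selection, masked-sum variant
#'
#' Reference implementation of the original randstrobe sampling function:
#' the partner minimising `(h(k1) + h(k')) & mask`, where the mask keeps the
#' `p` leftmost bits. Provided for comparison; indexing uses the skewed
#' variant [link_randstrobe_skew()].
#'
#' @param k1_hash Hash (hex) of the anchor strobe.
#' @param window Character vector of candidate hashes (hex), nearest first.
#' @param p Mask width in bits.
#' @return 1-based index of the chosen candidate within `window` (first on
#'   ties).
#' @export
link_randstrobe_sum <- function(k1_hash, window, p = 8) {
  cpp_link_sum(as_hash_hex(k1_hash), vapply(window, as_hash_hex, ""),
               as.integer(p)) + 1L
}

#' Randstrobe partner selection, skewed bit-count variant
#'
#' Selects the partner minimising the number of set bits among the `p`
#' leftmost bits of `h(k1) XOR h(k')`. Because the criterion takes only
#' `p + 1` distinct values, ties are common and resolve to the first
#' (nearest) candidate, skewing the sampling toward short seeds.
#'
#' @inheritParams link_randstrobe_sum
#' @return 1-based index of the chosen candidate within `window`.
#' @export
link_randstrobe_skew <- function(k1_hash, window, p = 8) {
  cpp_link_skew(as_hash_hex(k1_hash), vapply(window, as_hash_hex, ""),
                as.integer(p)) + 1L
}

#' Symmetric strobemer hash
#'
#' Combines two strobe hashes as `h1 %/% 2 + h2 %/% 2`: order-invariant,
#' never overflowing 64 bits, so a strobemer built from the forward and the
#' reverse-complement direction hashes identically.
#'
#' @param h1,h2 Strobe hashes (hex or numeric).
#' @return 16-character hex string.
#' @export
strobemer_hash <- function(h1, h2) {
  cpp_strobemer_hash(as_hash_hex(h1), as_hash_hex(h2))
}

#' Randstrobe seeds of a reference sequence
#'
#' For each syncmer (anchor), the candidate window holds the `w_min`-th
#' through `w_max`-th syncmers downstream, truncated to those within the
#' seed-span cap; the partner is chosen by [link_randstrobe_skew()] and the
#' seed hash by [strobemer_hash()]. Anchors with an empty window (sequence
#' end, N runs, span cap) emit a single-syncmer fallback seed flagged
#' `is_single`.
#'
#' @param seq Nucleotide string.
#' @param profile A [seed_profile()].
#' @return Data frame: `hash`, `q_s`, `q_e` (0-based half-open span),
#'   `offset` (partner start minus anchor start), `is_single`.
#' @export
reference_seeds <- function(seq, profile = seed_profile()) {
  stopifnot(inherits(profile, "seed_profile"))
  df <- cpp_seeds(seq, profile$k, profile$s, profile$t, profile$w_min,
                  profile$w_max, profile$p, profile$max_seed_len, FALSE)
  df[c("hash", "q_s", "q_e", "offset", "is_single")]
}

#' Randstrobe seeds of a read, both orientations
#'
#' Canonical syncmers are computed once; forward-orientation seeds link
#' anchors left to right, reverse-orientation seeds link right to left
#' (equivalent to forward seeding of the reverse complement). Coordinates
#' `q_s`/`q_e` are reported on the forward read for both orientations.
#'
#' @inheritParams reference_seeds
#' @param read Read sequence (forward, as sequenced).
#' @return Data frame: `hash`, `q_s`, `q_e`, `offset`, `o` (0 forward,
#'   1 reverse), `is_single`.
#' @export
read_seeds <- function(read, profile = seed_profile()) {
  stopifnot(inherits(profile, "seed_profile"))
  cpp_seeds(read, profile$k, profile$s, profile$t, profile$w_min,
            profile$w_max, profile$p, profile$max_seed_len, TRUE)
}
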