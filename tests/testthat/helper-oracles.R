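# Brute-force oracles and small utilities shared across the test files.
# These deliberately recompute results from first principles (string
# materialisation, exhaustive scans, textbook DP) rather than calling the
# code paths they are used to check.

as_hex52 <- function(x) {
  q <- numeric(4)
  for (i in 4:1) { q[i] <- x %% 65536; x <- x %/% 65536 }
  sprintf("%04x%04x%04x%04x", as.integer(q[1]), as.integer(q[2]),
          as.integer(q[3]), as.integer(q[4]))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# bits (length 64, most significant first) of a 16-digit hex hash
hex_bits <- function(h) {
  nib <- match(strsplit(tolower(h), "")[[1]], c(0:9, letters[1:6])) - 1L
  as.integer(unlist(lapply(nib, function(v) bitwAnd(bitwShiftR(v, 3:0), 1L))))
}

# canonical hash of the k-mer starting at 0-based pos (string-based)
oracle_canonical_hash <- function(seq, pos, k) {
  km <- substr(seq, pos + 1, pos + k)
  hash64(min(encode_kmer(km), encode_kmer(revcomp(km))))
}

# open syncmers by materialising every s-mer string
oracle_syncmers <- function(seq, k, s, t) {
  n <- nchar(seq)
  pos <- integer(0); hash <- character(0)
  if (n >= k) {
    for (j in 0:(n - k)) {
      window <- substr(seq, j + 1, j + k)
      if (grepl("[^ACGT]", window)) next
      shash <- vapply(0:(k - s), function(w)
        oracle_canonical_hash(window, w, s), "")
      if (which(shash == min(shash))[1] == t) {  # hex sorts like the integer
        pos <- c(pos, j)
        hash <- c(hash, oracle_canonical_hash(seq, j, k))
      }
    }
  }
  data.frame(pos = as.numeric(pos), hash = hash, stringsAsFactors = FALSE)
}

# window minimizers by per-window argmin scan
oracle_minimizers <- function(seq, k, w) {
  n <- nchar(seq)
  nk <- n - k + 1
  if (nk < w) return(data.frame(pos = numeric(0), hash = character(0)))
  kh <- rep(NA_character_, nk)
  for (j in 0:(nk - 1)) {
    km <- substr(seq, j + 1, j + k)
    if (!grepl("[^ACGT]", km)) kh[j + 1] <- oracle_canonical_hash(seq, j, k)
  }
  pos <- integer(0); hash <- character(0)
  for (j in 1:(nk - w + 1)) {
    win <- kh[j:(j + w - 1)]
    if (anyNA(win)) next
    sel <- j + which(win == min(win))[1] - 1L
    if (!length(pos) || pos[length(pos)] != sel - 1L) {
      pos <- c(pos, sel - 1L)
      hash <- c(hash, kh[sel])
    }
  }
  data.frame(pos = as.numeric(pos), hash = hash, stringsAsFactors = FALSE)
}

# skewed linking criterion evaluated bit by bit
oracle_link_skew <- function(k1_hash, window, p) {
  vals <- vapply(window, function(h) {
    sum(bitwXor(hex_bits(k1_hash)[1:p], hex_bits(h)[1:p]))
  }, numeric(1))
  unname(which(vals == min(vals))[1])   # first index on ties
}

oracle_link_sum <- function(k1_hash, window, p) {
  # add hex digits with carry, then compare the masked top-p bits
  add_hex <- function(a, b) {
    an <- match(strsplit(a, "")[[1]], c(0:9, letters[1:6])) - 1L
    bn <- match(strsplit(b, "")[[1]], c(0:9, letters[1:6])) - 1L
    out <- integer(16); carry <- 0L
    for (i in 16:1) {
      v <- an[i] + bn[i] + carry
      out[i] <- v %% 16L; carry <- v %/% 16L
    }
    paste(c(0:9, letters[1:6])[out + 1L], collapse = "")
  }
  keys <- vapply(window, function(h) {
    s <- add_hex(tolower(k1_hash), tolower(h))
    paste(hex_bits(s)[1:p], collapse = "")
  }, "")
  unname(which(keys == min(keys))[1])
}

# reference randstrobes by direct window evaluation over oracle syncmers
oracle_reference_seeds <- function(seq, profile) {
  sy <- open_syncmers(seq, profile$k, profile$s, profile$t)
  n <- nrow(sy)
  out <- list()
  for (j in seq_len(n)) {
    cand <- integer(0)
    for (w in profile$w_min:profile$w_max) {
      m <- j + w
      if (m > n) break
      if (sy$pos[m] + profile$k - sy$pos[j] > profile$max_seed_len) break
      cand <- c(cand, m)
    }
    if (!length(cand)) {
      out[[j]] <- data.frame(hash = strobemer_hash(sy$hash[j], sy$hash[j]),
                             q_s = sy$pos[j], q_e = sy$pos[j] + profile$k,
                             offset = 0L, is_single = 1L,
                             stringsAsFactors = FALSE)
    } else {
      pickrel <- oracle_link_skew(sy$hash[j], sy$hash[cand], profile$p)
      m <- cand[pickrel]
      out[[j]] <- data.frame(hash = strobemer_hash(sy$hash[j], sy$hash[m]),
                             q_s = sy$pos[j], q_e = sy$pos[m] + profile$k,
                             offset = as.integer(sy$pos[m] - sy$pos[j]),
                             is_single = 0L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# textbook local alignment with affine gaps; the opening penalty covers the
# first gap base. Returns the optimal score only.
oracle_sw_score <- function(q, r, match = 1, mismatch = 4, gap_open = 6,
                            gap_ext = 1) {
  n <- nchar(q); m <- nchar(r)
  qc <- strsplit(toupper(q), "")[[1]]; rc <- strsplit(toupper(r), "")[[1]]
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - gap_open, E[i, j - 1] - gap_ext)
    F[i, j] <- max(H[i - 1, j] - gap_open, F[i - 1, j] - gap_ext)
    sub <- if (qc[i - 1] == rc[j - 1] && qc[i - 1] != "N") match
           else -mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
  }
  max(H)
}

# re-score an emitted alignment from its CIGAR against the reference
rescore_cigar <- function(cigar, read, ref, pos, match = 1, mismatch = 4,
                          gap_open = 6, gap_ext = 1) {
  ops <- strobemap:::cigar_ops(cigar)
  qi <- 0; ri <- pos; score <- 0
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]
    switch(ops$op[i],
      S = { qi <- qi + len },
      M = {
        qs <- substr(read, qi + 1, qi + len)
        rs <- substr(ref, ri + 1, ri + len)
        mm <- sum(strsplit(qs, "")[[1]] != strsplit(rs, "")[[1]])
        score <- score + (len - mm) * match - mm * mismatch
        qi <- qi + len; ri <- ri + len
      },
      I = { score <- score - gap_open - (len - 1) * gap_ext; qi <- qi + len },
      D = { score <- score - gap_open - (len - 1) * gap_ext; ri <- ri + len })
  }
  score
}

# independent replay of the streaming lowest-d match filter using exported
# building blocks (read_seeds + index_lookup) instead of the C++ path
oracle_find_matches <- function(read, index, keep_max) {
  seeds <- read_seeds(read, index$profile)
  len <- nchar(read)
  dmin <- Inf
  rows <- list()
  for (i in seq_len(nrow(seeds))) {
    lk <- index_lookup(index, seeds$hash[i])
    if (lk$status == "absent") next
    if (lk$count > keep_max) next
    qs <- seeds$q_s[i]; qe <- seeds$q_e[i]
    if (seeds$o[i] == 1) { t1 <- len - qe; qe <- len - qs; qs <- t1 }
    for (j in seq_len(nrow(lk$records))) {
      d <- abs((lk$records$r_e[j] - lk$records$r_s[j]) - (qe - qs))
      if (d < dmin) dmin <- d
      if (d <= dmin)
        rows[[length(rows) + 1L]] <- data.frame(
          r_id = lk$records$r_id[j], r_s = lk$records$r_s[j],
          r_e = lk$records$r_e[j], q_s = qs, q_e = qe, o = seeds$o[i],
          d = d)
    }
  }
  if (!length(rows))
    return(data.frame(r_id = integer(0), r_s = numeric(0), r_e = numeric(0),
                      q_s = numeric(0), q_e = numeric(0), o = integer(0),
                      d = numeric(0)))
  do.call(rbind, rows)
}
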