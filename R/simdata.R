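# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Divergence presets for mutated-haplotype simulations
#'
#' Four presets of increasing divergence between the sampled haplotype and
#' the reference. `sim3` (0.1\% SNPs, 0.01\% indels) approximates the
#' variation level of a human population sample; `sim4` is a high-diversity
#' setting.
#'
#' @param name One of "sim1", "sim2", "sim3", "sim4".
#' @return List with `snp_rate` and `indel_rate`.
#' @export
sim_preset <- function(name = c("sim3", "sim1", "sim2", "sim4")) {
  name <- match.arg(name)
  switch(name,
         sim1 = list(snp_rate = 1e-4, indel_rate = 1e-5),
         sim2 = list(snp_rate = 5e-4, indel_rate = 5e-5),
         sim3 = list(snp_rate = 1e-3, indel_rate = 1e-4),
         sim4 = list(snp_rate = 1e-2, indel_rate = 1e-3))
}

#' Simulate an i.i.d. uniform random genome
#'
#' @param length Genome length in bases (>= 1).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return Named character vector of length 1.
#' @export
simulate_genome <- function(length, seed) {
  if (length < 1) stop("genome length must be >= 1")
  with_seed(seed, {
    g <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
    c(sim = g)
  })
}

#' Simulate a repetitive genome of diverged unit copies
#'
#' One random unit is drawn, then each of `n_copies` is mutated
#' independently at per-base substitution rate `divergence` and the copies
#' concatenated — an in-miniature version of a repeat-dominated genome
#' whose copies share roughly `(1 - divergence)^2` pairwise identity.
#'
#' @param n_copies Number of copies.
#' @param unit_len Length of the repeated unit.
#' @param divergence Per-copy substitution rate in \[0, 0.5\].
#' @param seed RNG seed.
#' @return Named character vector of length 1.
#' @export
simulate_repeats <- function(n_copies, unit_len, divergence, seed) {
  stopifnot(n_copies >= 1, unit_len >= 1, divergence >= 0, divergence <= 0.5)
  with_seed(seed, {
    unit <- sample(c("A", "C", "G", "T"), unit_len, replace = TRUE)
    copies <- vapply(seq_len(n_copies), function(i) {
      b <- unit
      hit <- which(runif(unit_len) < divergence)
      if (length(hit))
        b[hit] <- vapply(b[hit], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
      paste(b, collapse = "")
    }, "")
    c(repeats = paste(copies, collapse = ""))
  })
}

#' Mutate a reference into a haplotype with an exact liftover map
#'
#' Introduces SNPs (never identity substitutions) at `snp_rate` and indels
#' at `indel_rate` per base; indel lengths are geometric (`rgeom(p) + 1`,
#' default p = 0.5, mean 2), insertions and deletions equally likely. The
#' returned liftover is a block map from haplotype to reference
#' coordinates, exact for all non-inserted positions.
#'
#' @param ref Reference sequence (character scalar, or named vector of
#'   length 1).
#' @param snp_rate,indel_rate Per-base event rates in \[0, 1\].
#' @param seed RNG seed.
#' @param indel_geom_p Geometric length parameter.
#' @return List: `haplotype` (string) and `liftover` (data frame with
#'   0-based `hap_start`, `ref_start`, `len` of collinear blocks).
#' @export
mutate_genome <- function(ref, snp_rate, indel_rate, seed,
                          indel_geom_p = 0.5) {
  stopifnot(snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  seqchr <- toupper(unname(ref[[1]]))
  n <- nchar(seqchr)
  with_seed(seed, {
    bases <- strsplit(seqchr, "")[[1]]
    snp_pos <- which(runif(n) < snp_rate & bases %in% c("A", "C", "G", "T"))
    if (length(snp_pos))
      bases[snp_pos] <- vapply(bases[snp_pos], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    snp_seq <- paste(bases, collapse = "")
    ev_pos <- which(runif(n) < indel_rate)          # 1-based event anchors
    ev_ins <- runif(length(ev_pos)) < 0.5
    ev_len <- stats::rgeom(length(ev_pos), indel_geom_p) + 1L
    blocks <- list(); pieces <- list()
    cur_ref <- 0; cur_hap <- 0                      # 0-based cursors
    for (e in seq_along(ev_pos)) {
      at <- ev_pos[e] - 1                            # event at ref position
      if (at < cur_ref) next                         # swallowed by a deletion
      seg <- at - cur_ref
      if (seg > 0) {
        blocks[[length(blocks) + 1L]] <-
          c(hap_start = cur_hap, ref_start = cur_ref, len = seg)
        pieces[[length(pieces) + 1L]] <-
          substr(snp_seq, cur_ref + 1, cur_ref + seg)
        cur_hap <- cur_hap + seg; cur_ref <- cur_ref + seg
      }
      if (ev_ins[e]) {
        ins <- paste(sample(c("A", "C", "G", "T"), ev_len[e],
                            replace = TRUE), collapse = "")
        pieces[[length(pieces) + 1L]] <- ins
        cur_hap <- cur_hap + ev_len[e]
      } else {
        cur_ref <- min(n, cur_ref + ev_len[e])
      }
    }
    if (cur_ref < n) {
      blocks[[length(blocks) + 1L]] <-
        c(hap_start = cur_hap, ref_start = cur_ref, len = n - cur_ref)
      pieces[[length(pieces) + 1L]] <- substr(snp_seq, cur_ref + 1, n)
    }
    lift <- as.data.frame(do.call(rbind, blocks))
    list(haplotype = paste(unlist(pieces), collapse = ""), liftover = lift)
  })
}

# map 0-based haplotype positions to reference positions; positions inside
# insertions clamp to the start of the next aligned block
liftover_pos <- function(lift, pos) {
  idx <- findInterval(pos, lift$hap_start)
  idx[idx < 1L] <- 1L
  off <- pos - lift$hap_start[idx]
  out <- lift$ref_start[idx] + pmin(off, lift$len[idx])
  out
}

#' Simulate reads from a haplotype with reference-coordinate truth
#'
#' Read start positions are uniform over the haplotype and strands uniform;
#' paired mode draws the template length from Normal(`insert_mu`,
#' `insert_sigma`) truncated to at least `read_len`, placing mate 1 at the
#' left end forward and mate 2 at the right end reverse-complemented (roles
#' swap on minus-strand templates). Substitution sequencing errors are
#' applied at `error_rate` per base. Truth intervals are reported in
#' reference coordinates through the liftover map.
#'
#' @param haplotype Sequence reads are drawn from.
#' @param liftover Block map from [mutate_genome()], or `NULL` for identity.
#' @param n_reads Number of reads (pairs in paired mode).
#' @param read_len Read length.
#' @param paired Simulate read pairs.
#' @param insert_mu,insert_sigma Template length distribution (paired).
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @param rname Reference name recorded in the truth table.
#' @return List: `r1`, `r2` (named character vectors; `r2` is `NULL` for
#'   single-end) and `truth` (data frame `read_id`, `mate`, `rname`,
#'   `start`, `end`, `strand`).
#' @export
simulate_reads <- function(haplotype, liftover = NULL, n_reads = 1000,
                           read_len = 150, paired = FALSE, insert_mu = 300,
                           insert_sigma = 40, error_rate = 0.001, seed = 1,
                           rname = "sim") {
  hap <- toupper(unname(haplotype[[1]]))
  L <- nchar(hap)
  if (read_len > L) stop("read length exceeds genome length")
  if (is.null(liftover))
    liftover <- data.frame(hap_start = 0, ref_start = 0, len = L)
  add_errors <- function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- which(runif(length(b)) < error_rate)
    if (length(hit))
      b[hit] <- vapply(b[hit], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(b, collapse = "")
  }
  with_seed(seed, {
    ids <- sprintf("r%06d", seq_len(n_reads))
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    if (!paired) {
      starts <- floor(runif(n_reads, 0, L - read_len + 1))
      frags <- substring(hap, starts + 1, starts + read_len)
      reads <- ifelse(strands == "-", revcomp(frags), frags)
      reads <- vapply(reads, add_errors, "", USE.NAMES = FALSE)
      names(reads) <- ids
      truth <- data.frame(read_id = ids, mate = 0L, rname = rname,
                          start = liftover_pos(liftover, starts),
                          end = liftover_pos(liftover, starts + read_len),
                          strand = strands, stringsAsFactors = FALSE)
      list(r1 = reads, r2 = NULL, truth = truth)
    } else {
      ins <- pmax(read_len, pmin(L, round(rnorm(n_reads, insert_mu,
                                                insert_sigma))))
      starts <- floor(runif(n_reads, 0, L - ins + 1))
      left <- substring(hap, starts + 1, starts + read_len)
      right <- revcomp(substring(hap, starts + ins - read_len + 1,
                                 starts + ins))
      r1 <- ifelse(strands == "+", left, right)
      r2 <- ifelse(strands == "+", right, left)
      r1 <- vapply(r1, add_errors, "", USE.NAMES = FALSE)
      r2 <- vapply(r2, add_errors, "", USE.NAMES = FALSE)
      names(r1) <- ids; names(r2) <- ids
      t1s <- ifelse(strands == "+", starts, starts + ins - read_len)
      t2s <- ifelse(strands == "+", starts + ins - read_len, starts)
      truth <- rbind(
        data.frame(read_id = ids, mate = 1L, rname = rname,
                   start = liftover_pos(liftover, t1s),
                   end = liftover_pos(liftover, t1s + read_len),
                   strand = strands, stringsAsFactors = FALSE),
        data.frame(read_id = ids, mate = 2L, rname = rname,
                   start = liftover_pos(liftover, t2s),
                   end = liftover_pos(liftover, t2s + read_len),
                   strand = ifelse(strands == "+", "-", "+"),
                   stringsAsFactors = FALSE))
      list(r1 = r1, r2 = r2, truth = truth)
    }
  })
}

#' Write reads to FASTQ (Phred+33, constant quality)
#'
#' @param reads Named character vector.
#' @param path Output path.
#' @param qual_char Quality character applied to every base.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  lines <- as.vector(rbind(paste0("@", names(reads)),
                           unname(reads),
                           "+",
                           strrep(qual_char, nchar(reads))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path.
#' @param n Maximum number of records (Inf for all).
#' @return Named character vector of sequences.
#' @export
read_fastq <- function(path, n = Inf) {
  lines <- if (is.finite(n)) readLines(path, n = 4 * n) else readLines(path)
  if (length(lines) == 0L) stop("empty FASTQ file")
  ids <- sub("\\s.*$", "", sub("^@", "", lines[seq(1, length(lines), 4)]))
  seqs <- lines[seq(2, length(lines), 4)]
  names(seqs) <- ids
  seqs
}
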