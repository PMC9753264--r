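test_that("generators are deterministic given the seed", {
  expect_identical(simulate_genome(5000, seed = 701),
                   simulate_genome(5000, seed = 701))
  expect_identical(simulate_repeats(5, 300, 0.1, seed = 702),
                   simulate_repeats(5, 300, 0.1, seed = 702))
  g <- simulate_genome(3000, seed = 703)
  expect_identical(mutate_genome(g, 0.01, 0.001, seed = 704),
                   mutate_genome(g, 0.01, 0.001, seed = 704))
  expect_identical(
    simulate_reads(g, n_reads = 20, seed = 705, read_len = 100),
    simulate_reads(g, n_reads = 20, seed = 705, read_len = 100))
  expect_error(simulate_genome(0, seed = 1), ">= 1")
})

test_that("random genomes have near-uniform base composition", {
  g <- simulate_genome(1e6, seed = 707)[[1]]
  comp <- table(strsplit(g, "")[[1]]) / 1e6
  expect_true(all(abs(comp - 0.25) < 0.005))
})

test_that("undiverged repeats multiply the k-mer census exactly", {
  g <- simulate_repeats(6, 2000, 0, seed = 709)
  # copies are concatenated, so junction k-mers exist; census per copy
  unit <- substr(g[[1]], 1, 2000)
  cen_unit <- census_of(unit, "kmers", k = 20)
  expect_equal(ehits(cen_unit), 1)
  cen <- census_of(g[[1]], "kmers", k = 20)
  expect_gt(ehits(cen), 5.9)                    # ~6 up to junction effects
})

test_that("diverged repeat copies land in the expected identity band", {
  g <- simulate_repeats(10, 5000, 0.10, seed = 711)[[1]]
  copies <- vapply(0:9, function(i) substr(g, i * 5000 + 1, (i + 1) * 5000),
                   "")
  id <- function(a, b)
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  pw <- c(id(copies[1], copies[2]), id(copies[3], copies[7]),
          id(copies[5], copies[10]))
  # two independently mutated copies agree where neither mutated (plus
  # coincidental agreement): identity near (1-d)^2 + small correction
  expect_true(all(pw > 0.80 & pw < 0.90))
})

test_that("mutation respects rates and produces an exact liftover", {
  g <- simulate_genome(100000, seed = 713)
  mut0 <- mutate_genome(g, 0, 0, seed = 714)
  expect_identical(mut0$haplotype, g[[1]])
  expect_equal(nrow(mut0$liftover), 1)
  expect_equal(mut0$liftover$len, 100000)

  mut <- mutate_genome(g, 0.01, 0.001, seed = 715)
  hap <- mut$haplotype
  # realized SNP rate within a binomial confidence band
  lift <- mut$liftover
  same <- 0; diff <- 0
  for (b in seq_len(nrow(lift))) {
    h <- substr(hap, lift$hap_start[b] + 1, lift$hap_start[b] + lift$len[b])
    r <- substr(g[[1]], lift$ref_start[b] + 1,
                lift$ref_start[b] + lift$len[b])
    eq <- strsplit(h, "")[[1]] == strsplit(r, "")[[1]]
    same <- same + sum(eq); diff <- diff + sum(!eq)
  }
  rate <- diff / (same + diff)
  expect_lt(abs(rate - 0.01), 4 * sqrt(0.01 * 0.99 / 100000))
  # block positions map haplotype back to reference exactly
  idx <- c(1, 5, nrow(lift))
  for (b in idx) {
    p <- lift$hap_start[b] + 2
    expect_equal(strobemap:::liftover_pos(lift, p), lift$ref_start[b] + 2)
  }
})

test_that("error-free reads from an unmutated genome are exact substrings", {
  g <- simulate_genome(20000, seed = 717)
  sim <- simulate_reads(g, n_reads = 30, read_len = 100, error_rate = 0,
                        seed = 718)
  for (i in seq_len(30)) {
    tr <- sim$truth[i, ]
    window <- substr(g[[1]], tr$start + 1, tr$end)
    read <- sim$r1[[i]]
    expect_identical(if (tr$strand == "-") revcomp(read) else read, window)
    # exact string search recovers the truth interval
    hit <- regexpr(window, g[[1]], fixed = TRUE)
    expect_equal(as.integer(hit) - 1L, tr$start)
  }
})

test_that("paired simulation matches the insert-size model", {
  g <- simulate_genome(100000, seed = 719)
  sim <- simulate_reads(g, n_reads = 10000, read_len = 100, paired = TRUE,
                        insert_mu = 300, insert_sigma = 40,
                        error_rate = 0, seed = 720)
  t1 <- sim$truth[sim$truth$mate == 1L, ]
  t2 <- sim$truth[sim$truth$mate == 2L, ]
  ins <- pmax(t1$end, t2$end) - pmin(t1$start, t2$start)
  expect_lt(abs(mean(ins) - 300), 3 * 40 / sqrt(10000) + 0.5)
  # both mates always fit inside the template
  expect_true(all(ins >= 100))
})

test_that("accuracy evaluation scores constructed SAM records correctly", {
  truth <- data.frame(read_id = c("a", "b", "c"), mate = 0L, rname = "chr",
                      start = c(100, 500, 900), end = c(250, 650, 1050),
                      strand = "+", stringsAsFactors = FALSE)
  sam_ok <- c("@HD\tVN:1.6",
              "a\t0\tchr\t101\t60\t150M\t*\t0\t0\t*\t*",
              "b\t16\tchr\t501\t60\t150M\t*\t0\t0\t*\t*",
              "c\t0\tchr\t901\t60\t150M\t*\t0\t0\t*\t*")
  ev <- evaluate_accuracy(sam_ok, truth)
  expect_equal(ev$summary$pct_aligned, 100)
  expect_equal(ev$summary$pct_correct, 100)
  # all unmapped
  sam_un <- c("a\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
              "b\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
              "c\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*")
  ev2 <- evaluate_accuracy(sam_un, truth)
  expect_equal(ev2$summary$pct_aligned, 0)
  # placements shifted by a read length never overlap the truth
  sam_sh <- c("a\t0\tchr\t251\t60\t150M\t*\t0\t0\t*\t*",
              "b\t0\tchr\t651\t60\t150M\t*\t0\t0\t*\t*",
              "c\t0\tchr\t1051\t60\t150M\t*\t0\t0\t*\t*")
  ev3 <- evaluate_accuracy(sam_sh, truth)
  expect_equal(ev3$summary$pct_correct, 0)
  # unknown read ids are an error
  truth_bad <- truth[1:2, ]
  expect_error(evaluate_accuracy(sam_ok, truth_bad), "absent")
})
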