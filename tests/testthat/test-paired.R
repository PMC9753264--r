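test_that("insert-size estimation recovers the simulated distribution", {
  g <- random_seq(100000, seed = 601)
  ix <- build_index(c(chr = g), read_length = 150)
  sim <- simulate_reads(g, n_reads = 250, read_len = 150, paired = TRUE,
                        insert_mu = 350, insert_sigma = 40,
                        error_rate = 0.001, seed = 602, rname = "chr")
  m <- estimate_insert_size(sim$r1, sim$r2, ix)
  expect_lt(abs(m$mu - 350) / 350, 0.05)
  expect_lt(abs(m$sigma - 40) / 40, 0.25)
  expect_gte(m$n_observations, 100)
})

test_that("discordant or missing pairs fall back to documented defaults", {
  g <- random_seq(30000, seed = 603)
  ix <- build_index(c(chr = g), read_length = 150)
  junk1 <- vapply(1:5, function(i) random_seq(150), "")
  junk2 <- vapply(1:5, function(i) random_seq(150), "")
  expect_warning(m <- estimate_insert_size(junk1, junk2, ix), "fall")
  expect_equal(m$mu, 300)
  expect_equal(m$sigma, 100)
})

test_that("constant insert size gives the mean with a floored sigma", {
  g <- random_seq(100000, seed = 605)
  ix <- build_index(c(chr = g), read_length = 150)
  sim <- simulate_reads(g, n_reads = 150, read_len = 150, paired = TRUE,
                        insert_mu = 300, insert_sigma = 0,
                        error_rate = 0, seed = 606, rname = "chr")
  m <- estimate_insert_size(sim$r1, sim$r2, ix)
  expect_equal(m$mu, 300)
  expect_gte(m$sigma, 1)                        # positive floor
})

test_that("pair scoring applies the insert-size likelihood and -10 rule", {
  model <- insert_size_model(mu = 300, sigma = 50)
  Mf <- list(r_id = 0L, o = 0L, r_s = 1000, r_e = 1150, n = 10L)
  Mr <- list(r_id = 0L, o = 1L, r_s = 1150, r_e = 1300, n = 8L)
  ps <- score_pair(Mf, Mr, model, sw_i = 150, sw_j = 150)
  expect_true(ps$proper_pair)
  expect_equal(ps$C_ij, 18)
  d <- 1300 - 1000
  expect_equal(ps$S_ij, 300 + dnorm(d, 300, 50, log = TRUE))
  # at the mode the penalty is exactly -ln(sigma * sqrt(2*pi))
  expect_equal(ps$S_ij, 300 - log(50 * sqrt(2 * pi)))

  # mates a chromosome apart: individual scoring with -10
  Mr2 <- Mr; Mr2$r_id <- 1L
  ps2 <- score_pair(Mf, Mr2, model, sw_i = 150, sw_j = 150)
  expect_false(ps2$proper_pair)
  expect_equal(ps2$S_ij, 150 + 150 - 10)

  # distance mu + 11 sigma is no longer proper
  Mr3 <- Mr
  Mr3$r_s <- 1000 + 300 + 11 * 50 - 150
  Mr3$r_e <- Mr3$r_s + 150
  ps3 <- score_pair(Mf, Mr3, model, sw_i = 150, sw_j = 150)
  expect_false(ps3$proper_pair)
  # while mu + 9 sigma still is
  Mr4 <- Mr
  Mr4$r_s <- 1000 + 300 + 9 * 50 - 150
  Mr4$r_e <- Mr4$r_s + 150
  expect_true(score_pair(Mf, Mr4, model)$proper_pair)
})

test_that("the proper-pair predicate is symmetric in the two mates", {
  model <- insert_size_model(300, 50)
  set.seed(607)
  for (rep in 1:20) {
    p1 <- list(r_id = sample(0:1, 1), o = sample(0:1, 1),
               r_s = sample(500:2000, 1))
    p1$r_e <- p1$r_s + 150
    p2 <- list(r_id = sample(0:1, 1), o = sample(0:1, 1),
               r_s = sample(500:2000, 1))
    p2$r_e <- p2$r_s + 150
    expect_identical(strobemap:::proper_pair_ok(p1, p2, model),
                     strobemap:::proper_pair_ok(p2, p1, model))
  }
})

test_that("mate rescue aligns an unseeded mate near its partner", {
  g <- random_seq(50000, seed = 609)
  ix <- build_index(c(chr = g), read_length = 150)
  model <- insert_size_model(300, 30)
  placed <- list(r_id = 0L, o = 0L, ref_start = 10000, ref_end = 10150)
  mate <- revcomp(substr(g, 10151, 10300))      # error-free mate downstream
  res <- mate_rescue(placed, mate, model, ix)
  expect_false(is.null(res))
  expect_equal(res$score, 150)                  # perfect rescue
  expect_equal(res$ref_start, 10150)
  expect_identical(res$o, 1L)
  # random garbage fails the acceptance floor
  expect_null(mate_rescue(placed, random_seq(150), model, ix))
  # a window clipped to nothing yields no rescue
  placed_edge <- list(r_id = 0L, o = 1L, ref_start = 0, ref_end = 0)
  expect_null(mate_rescue(placed_edge, mate, model, ix))
})

test_that("paired alignment places error-free proper pairs with true TLEN", {
  g <- random_seq(100000, seed = 611)
  ix <- build_index(c(chr = g), read_length = 150)
  sim <- simulate_reads(g, n_reads = 60, read_len = 150, paired = TRUE,
                        insert_mu = 300, insert_sigma = 30,
                        error_rate = 0, seed = 612, rname = "chr")
  aln <- align_paired(sim$r1, sim$r2, ix,
                      model = insert_size_model(300, 30))
  expect_true(all(aln$flag >= 64L))
  expect_true(all(bitwAnd(aln$flag, 4L) == 0L))
  expect_true(all(aln$proper))
  ev <- evaluate_accuracy(sam_lines(aln, ix), sim$truth)
  expect_equal(ev$summary$pct_correct, 100)
  # |TLEN| equals the simulated template length
  t1 <- aln[aln$mate == 1L, ]
  truth1 <- sim$truth[sim$truth$mate == 1L, ]
  truth2 <- sim$truth[sim$truth$mate == 2L, ]
  ins <- pmax(truth1$end, truth2$end) - pmin(truth1$start, truth2$start)
  expect_equal(abs(t1$tlen), ins)
  # flags are mirrored between mates
  t2 <- aln[aln$mate == 2L, ]
  expect_identical(bitwAnd(t1$flag, 16L) > 0, bitwAnd(t2$flag, 32L) > 0)
})

test_that("the pair term disambiguates a repeat-buried mate", {
  unit <- random_seq(2000, seed = 613)
  bgA <- random_seq(20000, seed = 614)
  bgB <- random_seq(20000, seed = 615)
  # identical repeat copies at two loci; only copy A has unique flanks the
  # other mate can anchor to
  g <- paste0(bgA, unit, bgB, unit)
  ix <- build_index(c(chr = g), read_length = 150)
  model <- insert_size_model(400, 40)
  r1 <- substr(g, 20000 - 149, 20000)            # unique, just left of copy A
  r2 <- revcomp(substr(unit, 101, 250))          # inside the repeat
  aln <- align_paired(c(p = r1), c(p = r2), ix, model = model)
  a2 <- aln[aln$mate == 2L, ]
  expect_equal(a2$pos, 20000 + 100)              # copy A, not copy B
  expect_true(all(aln$proper))
})

test_that("pairs with no seeds on either mate are flagged unmapped", {
  g <- random_seq(30000, seed = 617)
  ix <- build_index(c(chr = g), read_length = 150)
  aln <- align_paired(c(x = strrep("N", 150)), c(x = strrep("N", 150)), ix,
                      model = insert_size_model(300, 50))
  expect_true(all(bitwAnd(aln$flag, 4L) > 0))
  expect_true(all(bitwAnd(aln$flag, 8L) > 0))
  expect_true(all(aln$rname == "*"))
})
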