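test_that("biallelic filtering keeps exactly the two-allele loci", {
  calls <- cbind(c(0L, 1L, 1L, 0L),   # biallelic: kept
                 c(0L, 1L, 2L, 0L),   # triallelic: dropped
                 c(0L, 0L, 0L, NA))   # monomorphic: dropped
  loci <- data.frame(contig = "c1", pos = c(100L, 200L, 300L),
                     ref = "A", alt = c("T", "T,G", "T"))
  gm <- genotype_matrix(calls, loci, sprintf("s%d", 1:4))
  bi <- biallelic_loci(gm)
  expect_equal(bi$loci$pos, 100L)
  expect_equal(ncol(bi$calls), 1L)
})

test_that("pair_ld reproduces the canonical association extremes", {
  ## perfect association
  gm <- gm_from_calls(cbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L)))
  r <- pair_ld(gm, 1, 2)
  expect_equal(r$D, 0.25)
  expect_equal(r$D_prime, 1)
  expect_equal(r$r2, 1)
  expect_equal(r$distance, 100L)
  ## independence
  gm2 <- gm_from_calls(cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)))
  r2 <- pair_ld(gm2, 1, 2)
  expect_equal(r2$D, 0)
  expect_equal(r2$D_prime, 0)
  expect_equal(r2$r2, 0)
  ## monomorphic after exclusion errors
  gm3 <- gm_from_calls(cbind(c(0L, 1L, 1L, NA), c(1L, 0L, 0L, 0L)))
  gm3$calls[2:3, 2] <- NA
  expect_error(pair_ld(gm3, 1, 2), "undefined-statistic")
})

test_that("pair_ld matches the haplotype-count oracle on a fixed table", {
  ## haplotype counts n00=3, n01=1, n10=1, n11=5
  a <- c(rep(0L, 3), rep(0L, 1), rep(1L, 1), rep(1L, 5))
  b <- c(rep(0L, 3), rep(1L, 1), rep(0L, 1), rep(1L, 5))
  gm <- gm_from_calls(cbind(a, b))
  got <- pair_ld(gm, 1, 2)
  want <- oracle_ld(a, b)
  expect_equal(got$D, want$D, tolerance = 1e-12)
  expect_equal(got$D_prime, want$D_prime, tolerance = 1e-12)
  expect_equal(got$r2, want$r2, tolerance = 1e-12)
  expect_equal(got$D, 0.14)
})

test_that("r2 and D' are invariant under allele-label swap; D flips sign", {
  set.seed(3)
  for (rep in 1:20) {
    gm <- random_biallelic_gm(8, 2)
    base <- pair_ld(gm, 1, 2)
    sw <- gm$calls
    sw[, 1] <- 1L - sw[, 1]
    swapped <- pair_ld(gm_from_calls(sw), 1, 2)
    expect_equal(swapped$r2, base$r2, tolerance = 1e-12)
    expect_equal(swapped$D_prime, base$D_prime, tolerance = 1e-12)
    expect_equal(abs(swapped$D), abs(base$D), tolerance = 1e-12)
  }
})

test_that("pair enumeration respects the distance window and contigs", {
  calls <- matrix(rep(c(0L, 0L, 1L, 1L), 3), ncol = 3)
  gm <- genotype_matrix(calls,
                        data.frame(contig = "c1", pos = c(100L, 600L, 20000L),
                                   ref = "A", alt = "T"),
                        sprintf("s%d", 1:4))
  prs <- enumerate_pairs(gm, 10000)
  expect_equal(nrow(prs), 1L)
  expect_equal(prs$distance, 500L)
  ## different contigs: no pairs
  gm2 <- genotype_matrix(calls[, 1:2],
                         data.frame(contig = c("c1", "c2"), pos = c(100L, 200L),
                                    ref = "A", alt = "T"),
                         sprintf("s%d", 1:4))
  expect_equal(nrow(enumerate_pairs(gm2)), 0L)
  ## 10 loci within 1 kb: all 45 pairs
  set.seed(11)
  gm3 <- random_biallelic_gm(8, 10, miss_prob = 0)
  gm3$loci$pos <- seq(100L, 1000L, by = 100L)
  expect_equal(nrow(enumerate_pairs(gm3, 10000)), 45L)
})

test_that("enumeration matches per-pair computation, with and without missing", {
  set.seed(29)
  for (miss in c(0, 0.15)) {
    gm <- random_biallelic_gm(10, 8, miss_prob = miss)
    prs <- enumerate_pairs(gm, 10000)
    for (q in seq_len(nrow(prs))) {
      i <- match(prs$pos_i[q], gm$loci$pos)
      j <- match(prs$pos_j[q], gm$loci$pos)
      single <- pair_ld(gm, i, j)
      expect_equal(prs$r2[q], single$r2, tolerance = 1e-12)
      expect_equal(prs$D_prime[q], single$D_prime, tolerance = 1e-12)
      expect_equal(abs(prs$D[q]), abs(single$D), tolerance = 1e-12)
    }
  }
})

test_that("undefined pairs are skipped and counted", {
  calls <- cbind(c(0L, 1L, 1L, NA), c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L))
  calls[2:3, 2] <- NA  # locus 2 monomorphic once NA rows drop at locus 1
  gm <- gm_from_calls(calls)
  prs <- enumerate_pairs(gm, 10000)
  expect_gte(attr(prs, "n_skipped"), 1L)
})

test_that("bin means follow the (kw, (k+1)w] convention", {
  prs <- data.frame(contig = "c1", pos_i = 1L, pos_j = 1L,
                    distance = c(40, 60, 100, 101),
                    D = 0, D_prime = 0, r2 = c(0.2, 0.4, 0.6, 0.9))
  bm <- bin_means(prs, "r2", bin_width = 100)
  ## distance = 100 falls in the first bin
  expect_equal(bm$bin_center, c(50, 150))
  expect_equal(bm$mean, c(mean(c(0.2, 0.4, 0.6)), 0.9))
  expect_equal(bm$n_pairs, c(3L, 1L))
  ## constant statistic: every bin mean is that constant
  prs$r2 <- 0.7
  expect_true(all(bin_means(prs, "r2", 100)$mean == 0.7))
  expect_equal(nrow(bin_means(prs[0, ], "r2")), 0L)
})

test_that("decay interval applies the half-maximum border rule", {
  binned <- data.frame(bin_center = c(100, 200, 300, 400, 500, 600),
                       mean = c(0.8, 0.7, 0.35, 0.5, 0.3, 0.2),
                       n_pairs = 10L)
  di <- decay_interval(binned)
  expect_equal(di$M, 0.8)
  expect_equal(di$H, 0.4)
  expect_equal(di$left_border, 300)
  expect_equal(di$right_border, 400)
  expect_false(di$censored)
  ## constant series: no bin below half-max, censored to the left
  const <- data.frame(bin_center = c(100, 200, 300), mean = 0.5, n_pairs = 5L)
  dc <- decay_interval(const)
  expect_equal(dc$H, 0.25)
  expect_true(is.na(dc$left_border))
  expect_true(dc$censored)
  expect_equal(dc$right_border, 300)
  ## strictly decreasing series crossing H = 0.45 once: left border is the
  ## first sub-H center, right border the center just before it
  dec <- data.frame(bin_center = seq(100, 800, 100),
                    mean = c(0.9, 0.8, 0.6, 0.5, 0.47, 0.46, 0.3, 0.2),
                    n_pairs = 5L)
  dd <- decay_interval(dec)
  expect_equal(dd$left_border, 700)
  expect_equal(dd$right_border, 600)
})

test_that("the fitted curve recovers a closed-form exponential half-life", {
  x <- seq(1, 10000, by = 7)
  prs <- data.frame(contig = "c1", pos_i = 0L, pos_j = x, distance = x,
                    D = 0, D_prime = exp(-x / 1000), r2 = exp(-x / 1000))
  fit <- fit_decay_curve(prs, "r2")
  expect_false(fit$censored)
  expect_lt(abs(fit$decay_distance - 1000 * log(2)), 0.05 * 1000 * log(2))
  ## constant statistic never crosses: censored
  prs$r2 <- 0.6
  fitc <- fit_decay_curve(prs, "r2")
  expect_true(fitc$censored)
  expect_true(is.na(fitc$decay_distance))
})

test_that("decay estimates are invariant under duplicating every pair", {
  x <- seq(1, 10000, by = 13)
  set.seed(5)
  prs <- data.frame(contig = "c1", pos_i = 0L, pos_j = x, distance = x,
                    D = 0, D_prime = 0,
                    r2 = pmin(1, pmax(0, exp(-x / 1500) + rnorm(length(x), 0, 0.03))))
  doubled <- rbind(prs, prs)
  f1 <- fit_decay_curve(prs, "r2")
  f2 <- fit_decay_curve(doubled, "r2")
  expect_equal(f1$decay_distance, f2$decay_distance, tolerance = 1e-6)
  b1 <- decay_interval(bin_means(prs, "r2"))
  b2 <- decay_interval(bin_means(doubled, "r2"))
  expect_identical(b1, b2)
})

test_that("too few pairs raise an insufficient-data error", {
  prs <- data.frame(contig = "c1", pos_i = 0L, pos_j = 1:5, distance = 1:5,
                    D = 0, D_prime = 0.5, r2 = 0.5)
  expect_error(fit_decay_curve(prs, "r2"), "insufficient-data")
})
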