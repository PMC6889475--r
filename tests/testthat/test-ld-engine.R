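test_that("maf follows the dosage definition and excludes missing samples", {
  expect_equal(maf(c(0, 1, 2, 2)), 0.375)
  expect_equal(maf(c(2, 2, 2, 2)), 0)
  expect_equal(maf(c(0, 1, NA, 2)), 0.5)
  expect_error(maf(c(NA, NA)), "all genotypes are missing")
})

test_that("r2_dosage matches a Pearson-correlation oracle and handles degenerate input", {
  expect_equal(r2_dosage(c(0, 1, 2, 2), c(0, 1, 2, 2)), 1.0)
  expect_equal(r2_dosage(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0.0)
  ## frozen from the squared stats::cor of these vectors
  expect_equal(r2_dosage(c(0, 1, 2, 0, 1), c(0, 1, 1, 0, 2)),
               0.41326530612244888, tolerance = 1e-12)
  ## monomorphic locus among complete samples -> skipped, not an error
  r <- r2_dosage(c(1, 1, 1, 1), c(0, 1, 2, 0))
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "monomorphic")
  ## fewer complete samples than min_informative -> skipped
  r2 <- r2_dosage(c(0, 1, NA, NA), c(0, 1, 1, 0))
  expect_true(is.na(r2))
  expect_equal(attr(r2, "reason"), "low_informative")
})

test_that("r2_dosage agrees with the cor() oracle on random vectors", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    x <- rbinom(n, 2, runif(1, 0.1, 0.9))
    y <- rbinom(n, 2, runif(1, 0.1, 0.9))
    if (runif(1) < 0.5) {
      flip <- runif(n) < 0.3
      y[!flip] <- x[!flip]   # induce correlation for some draws
    }
    x[runif(n) < 0.1] <- NA
    y[runif(n) < 0.1] <- NA
    expected <- oracle_r2(x, y)
    got <- r2_dosage(x, y)
    if (is.na(expected)) expect_true(is.na(got)) else
      expect_equal(as.numeric(got), expected, tolerance = 1e-12)
  }
})

test_that("both estimators are symmetric and invariant to allele relabeling", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    x <- rbinom(n, 2, runif(1, 0.2, 0.8))
    y <- rbinom(n, 2, runif(1, 0.2, 0.8))
    keep <- runif(n) < 0.6
    y[keep] <- x[keep]
    for (f in list(r2_dosage, r2_em)) {
      a <- as.numeric(f(x, y)); b <- as.numeric(f(y, x))
      expect_equal(a, b, tolerance = 1e-12)
      fl <- as.numeric(f(2 - x, y))
      if (!is.na(a)) {
        expect_equal(a, fl, tolerance = 1e-9)
        expect_true(a >= 0 && a <= 1)
      }
    }
  }
})

test_that("r2_em is exact for perfectly coupled loci", {
  x <- c(0, 0, 1, 1, 2, 2)
  expect_equal(as.numeric(r2_em(x, x)), 1.0, tolerance = 1e-12)
})

test_that("r2_em equals direct haplotype counting when phase is determined", {
  ## no sample heterozygous at both loci -> gametes are unambiguous
  x <- c(0, 0, 1, 2, 2, 1, 0, 2)
  y <- c(0, 0, 0, 2, 1, 0, 1, 2)
  stopifnot(!any(x == 1 & y == 1))
  expect_equal(as.numeric(r2_em(x, y)), oracle_hap_count_r2(x, y),
               tolerance = 1e-9)
  set.seed(303)
  found <- 0
  while (found < 20) {
    n <- sample(8:40, 1)
    x <- rbinom(n, 2, runif(1, 0.2, 0.8))
    y <- rbinom(n, 2, runif(1, 0.2, 0.8))
    y[x == 1 & y == 1] <- 0   # remove double heterozygotes
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(as.numeric(r2_em(x, y)), oracle_hap_count_r2(x, y),
                 tolerance = 1e-9)
    found <- found + 1
  }
})

test_that("r2_em matches an exhaustive 1-D likelihood grid with double heterozygotes", {
  set.seed(404)
  found <- 0
  while (found < 25) {
    n <- sample(15:60, 1)
    x <- rbinom(n, 2, runif(1, 0.25, 0.75))
    y <- rbinom(n, 2, runif(1, 0.25, 0.75))
    keep <- runif(n) < 0.5
    y[keep] <- x[keep]
    if (!any(x == 1 & y == 1)) next
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(as.numeric(r2_em(x, y)), oracle_em_grid_r2(x, y),
                 tolerance = 1e-3)
    found <- found + 1
  }
})

test_that("pairwise_ld retains same-chromosome pairs above the base threshold", {
  d <- c(0, 1, 2, 2, 0, 1)
  gm <- genotype_matrix(cbind(d, d, d), chrom = rep("1", 3),
                        pos = c(100, 500, 900))
  p <- pairwise_ld(gm, ld_params())
  expect_equal(nrow(p), 3L)
  expect_equal(p$r2, rep(1, 3))
  expect_equal(p$pos_a, c(100, 100, 500))
  expect_equal(p$pos_b, c(500, 900, 900))

  gm2 <- genotype_matrix(cbind(d, d), chrom = c("1", "2"), pos = c(100, 100))
  expect_equal(nrow(pairwise_ld(gm2, ld_params())), 0L)
})

test_that("pairwise_ld respects the bp window and ties at the threshold are kept", {
  d1 <- c(0, 1, 2, 2, 0, 1)
  gm <- genotype_matrix(cbind(d1, d1, d1), chrom = rep("1", 3),
                        pos = c(100, 500, 5000))
  p <- pairwise_ld(gm, ld_params(window_bp = 1000))
  expect_equal(nrow(p), 1L)           # only 100-500 is within the window
  p_all <- pairwise_ld(gm, ld_params(window_bp = 0))  # unlimited
  expect_equal(nrow(p_all), 3L)

  ## a pair with r^2 exactly at the threshold is retained (inclusive rule)
  x <- c(0, 1, 2, 0, 1); y <- c(0, 1, 1, 0, 2)
  r2 <- as.numeric(r2_dosage(x, y))
  gm3 <- genotype_matrix(cbind(x, y), chrom = c("1", "1"), pos = c(10, 20))
  p3 <- pairwise_ld(gm3, ld_params(base_threshold = r2))
  expect_equal(nrow(p3), 1L)
  expect_equal(p3$r2, r2)
})

test_that("pairwise_ld equals the naive all-pairs oracle on random matrices", {
  set.seed(505)
  for (i in 1:30) {
    gm <- random_genotypes(sample(10:60, 1), sample(5:25, 1),
                           n_chrom = sample(1:3, 1), missing_rate = 0.05)
    params <- ld_params(window_bp = sample(c(0, 5e5), 1))
    got <- pairwise_ld(gm, params)
    want <- oracle_pairwise(gm, params)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$pos_a, want$pos_a)
    expect_equal(got$pos_b, want$pos_b)
    expect_equal(got$r2, want$r2, tolerance = 1e-10)
  }
})

test_that("mean r-squared between independent loci shrinks as samples grow", {
  set.seed(606)
  mean_r2 <- vapply(c(10, 50, 200), function(n) {
    mean(replicate(500, {
      x <- rbinom(n, 2, 0.5)
      y <- rbinom(n, 2, 0.5)
      r <- r2_dosage(x, y)
      if (is.na(r)) 0 else as.numeric(r)
    }))
  }, 0)
  expect_true(mean_r2[1] > mean_r2[2])
  expect_true(mean_r2[2] > mean_r2[3])
})

test_that("monomorphic and low-informative pairs are counted, not reported as zero", {
  mono <- rep(2, 6)
  poly <- c(0, 1, 2, 2, 0, 1)
  sparse <- c(0, 1, NA, NA, NA, NA)
  gm <- genotype_matrix(cbind(mono, poly, sparse), chrom = rep("1", 3),
                        pos = c(10, 20, 30))
  p <- pairwise_ld(gm, ld_params())
  expect_equal(nrow(p), 0L)
  expect_equal(attr(p, "n_skipped_monomorphic"), 1L)
  expect_equal(attr(p, "n_skipped_low_informative"), 2L)
})
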