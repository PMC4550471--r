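test_that("error rates follow the clamped truncated normal", {
  expect_identical(withr::with_seed(1, sample_error_rate(5, 0.01, 0)),
                   rep(0.01, 5))
  expect_identical(withr::with_seed(1, sample_error_rate(100, -1)), rep(0, 100))
  e <- withr::with_seed(2, sample_error_rate(1e5, 0.01, 1e-6))
  se <- 1e-3 / sqrt(1e5)
  expect_lt(abs(mean(e) - 0.01), 3 * se)  # truncation negligible 10 sd from 0
  expect_true(all(e >= 0))
})

test_that("MAF draws respect their stratum", {
  expect_identical(withr::with_seed(3, sample_maf(10, 0, 0)), rep(0, 10))
  p <- withr::with_seed(4, sample_maf(1e5, 0.05, 0.1))
  expect_true(all(p >= 0.05 & p <= 0.1))
  se <- (0.1 - 0.05) / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(p) - 0.075), 3 * se)
})

test_that("generalized Poisson has the stated mean and dispersion", {
  x <- withr::with_seed(5, rgpois(1e5, mu = 10, lambda = 1))
  se_m <- sqrt(10 / 1e5)
  expect_lt(abs(mean(x) - 10), 3 * se_m)
  expect_lt(abs(var(x) - 10), 4 * sqrt(2 * 100 / 1e5 + 10 / 1e5))
  y <- withr::with_seed(6, rgpois(1e5, mu = 10, lambda = 0.4))
  expect_lt(abs(mean(y) - 10), 3 * sqrt(25 / 1e5))
  expect_lt(abs(var(y) - 25), 0.75)
  expect_true(all(y >= 0))
  expect_error(rgpois(10, 10, 0), "lambda")
  expect_error(rgpois(10, 10, 1.4), "lambda")
  # the branching-process sampler draws the same distribution
  z <- withr::with_seed(7, rgpois(1e5, mu = 10, lambda = 0.4,
                                  method = "branching"))
  expect_lt(abs(mean(z) - 10), 3 * sqrt(25 / 1e5))
  expect_lt(abs(var(z) - 25), 0.75)
  ks <- suppressWarnings(ks.test(y, z))
  expect_gt(ks$p.value, 1e-4)
  # pmf sums to one and matches Poisson at lambda = 1
  pmf <- elrtcall:::gpois_pmf(10, 0)
  expect_equal(sum(pmf), 1, tolerance = 1e-10)
  expect_equal(pmf[1:20], dpois(0:19, 10), tolerance = 1e-12)
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  expect_identical(withr::with_seed(8, sample_genotype(50, 0)), rep(0L, 50))
  expect_identical(withr::with_seed(8, sample_genotype(50, 1)), rep(2L, 50))
  g <- withr::with_seed(9, sample_genotype(1e5, 0.1))
  het <- mean(g == 1L)
  se <- sqrt(0.18 * 0.82 / 1e5)
  expect_lt(abs(het - 0.18), 3 * se)
})

test_that("read draws respect genotype and coverage", {
  expect_identical(withr::with_seed(10, sample_reads(0L, 0L, 0.01)), 0L)
  expect_identical(withr::with_seed(10, sample_reads(rep(2L, 5), rep(7L, 5), 0)),
                   rep(7L, 5))
  x <- withr::with_seed(11, sample_reads(rep(1L, 1e5), rep(20L, 1e5), 0.01))
  se <- sqrt(20 * 0.25 / 1e5)
  expect_lt(abs(mean(x) - 10), 3 * se)
})

test_that("simulated datasets are reproducible and internally consistent", {
  a <- simulate_counts(50, 20, 10, maf_range = c(0.01, 0.05), seed = 12)
  b <- simulate_counts(50, 20, 10, maf_range = c(0.01, 0.05), seed = 12)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  m <- elrtcall:::counts_to_matrices(a$counts)
  expect_true(all(m$variants <= m$totals))
  # null loci have exactly zero MAF in the truth sidecar
  nul <- simulate_counts(200, 10, 5, maf_range = c(0, 0), seed = 13)
  expect_true(all(nul$truth$maf == 0))
  # under the null every variant read is an error draw
  big <- simulate_counts(1e4, 100, 10, error_mean = 0.01, maf_range = c(0, 0),
                         seed = 14)
  mm <- elrtcall:::counts_to_matrices(big$counts)
  frac <- sum(mm$variants) / sum(mm$totals)
  se <- sqrt(0.01 * 0.99 / sum(mm$totals)) + 1e-3 / sqrt(1e4)
  expect_lt(abs(frac - 0.01), 4 * se)
  # constant-coverage mode
  cc <- simulate_counts(10, 5, 2, coverage_model = "constant", seed = 15)
  expect_true(all(elrtcall:::counts_to_matrices(cc$counts)$totals == 2L))
})

test_that("the benchmark grid enumerates 96 SNP and 32 null combinations", {
  g <- study_grid()
  expect_identical(nrow(g), 128L)
  expect_identical(sum(g$type == "snp"), 96L)
  expect_identical(sum(g$type == "null"), 32L)
  expect_true(all(g$n_loci[g$type == "snp"] == 5e3))
  expect_true(all(g$n_loci[g$type == "null"] == 5e5))
  g10 <- study_grid(scale = 0.1)
  expect_true(all(g10$n_loci[g10$type == "snp"] == 500))
  expect_true(all(g10$n_loci[g10$type == "null"] == 5e4))
  expect_identical(anyDuplicated(g$dataset), 0L)
  # every SNP combination has a matching null combination
  key <- function(d) paste(d$error_mean, d$n_samples, d$coverage_mean)
  expect_true(all(key(g[g$type == "snp", ]) %in% key(g[g$type == "null", ])))
})

test_that("the fitted zero fraction grows with coverage", {
  a_hat <- vapply(c(5, 10, 20, 30), function(mu) {
    sim <- simulate_counts(1e4, 100, mu, error_mean = 0.01,
                           maf_range = c(0, 0), seed = 16 + mu)
    st <- elrt(sim$counts, quiet = TRUE)
    suppressWarnings(fit_null(st))$a
  }, 0)
  expect_true(all(diff(a_hat) > 0))
  expect_true(all(a_hat > 0.5))
})
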