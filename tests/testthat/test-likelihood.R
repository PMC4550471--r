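test_that("mixture log-likelihood matches the term-by-term binomial oracle", {
  # p = 0 collapses to the homozygous-reference component
  N <- c(10L, 7L, 0L, 3L)
  X <- c(1L, 0L, 0L, 2L)
  expect_equal(mixture_loglik(N, X, error_rate = 0.1, maf = 0),
               sum(dbinom(X[N > 0], N[N > 0], 0.1, log = TRUE)))
  # all zero variant reads, e = 0, p = 0: probability one
  expect_identical(mixture_loglik(c(5L, 8L), c(0L, 0L), 0, 0), 0)
  # the worked small case
  expect_equal(mixture_loglik(c(10, 10), c(5, 0), 0.25, 0.1),
               oracle_loglik(c(10, 10), c(5, 0), 0.25, 0.1))
  # random parameter sweep, R and C++ routes against the oracle
  set.seed(11)
  for (rep in 1:25) {
    loc <- random_locus()
    e <- runif(1, 0, 0.4); p <- runif(1)
    o <- oracle_loglik(loc$N, loc$X, e, p)
    expect_equal(mixture_loglik(loc$N, loc$X, e, p), o, tolerance = 1e-10)
    expect_equal(elrtcall:::cpp_mixture_loglik(loc$N, loc$X, e, p), o,
                 tolerance = 1e-10)
  }
  expect_error(mixture_loglik(c(2, 2), c(3, 0), 0.1, 0.1), "exceed")
  expect_error(mixture_loglik(c(2, 2), c(1, 0), -0.1, 0.1), "error_rate")
})

test_that("null error MLE is the pooled variant-read fraction", {
  expect_equal(null_error_mle(c(10, 10, 10), c(1, 0, 2)), 0.1)
  expect_equal(null_error_mle(c(4, 6), c(0, 0)), 0)
  expect_equal(null_error_mle(2, 2), 1)  # boundary: all reads variant
  expect_error(null_error_mle(c(0, 0), c(0, 0)), "degenerate")
})

test_that("eLRT statistic agrees with the dense-grid profile oracle", {
  # all-zero variant reads: the profiled likelihood peaks at p = 0
  z <- elrt_stat(rep(10L, 8), rep(0L, 8))
  expect_identical(z$statistic, 0)
  expect_identical(z$maf_hat, 0)
  expect_true(z$is_zero)
  # a locus with real heterozygote signal among reference-homozygotes
  set.seed(21)
  g <- c(rep(1L, 30), rep(0L, 70))
  N <- rep(10L, 100)
  X <- rbinom(100, N, ifelse(g == 1, 0.5, 0.01))
  r <- suppressWarnings(elrt_stat(N, X))
  o <- oracle_elrt(N, X)
  expect_gt(r$statistic, 0)
  expect_gt(r$maf_hat, 0.05)
  expect_equal(r$statistic, o$statistic, tolerance = 1e-4)
  # 200 random small loci: grid-oracle equivalence within 1e-4
  set.seed(22)
  worst <- 0
  for (rep in 1:200) {
    loc <- random_locus()
    r <- suppressWarnings(elrt_stat(loc$N, loc$X))
    o <- oracle_elrt(loc$N, loc$X)
    worst <- max(worst, abs(r$statistic - o$statistic))
  }
  expect_lt(worst, 1e-4)
  expect_error(elrt_stat(c(0L, 0L), c(0L, 0L)), "degenerate")
})

test_that("uniformly heterozygous-like counts carry no testable signal", {
  # when every sample looks heterozygous the pooled error MLE collapses to
  # ~0.5 and the three mixture components coincide, so the profiled
  # likelihood is flat: the statistic must agree with the grid oracle (~0)
  set.seed(23)
  X <- rbinom(60, 10, 0.5)
  r <- suppressWarnings(elrt_stat(rep(10L, 60), X))
  o <- oracle_elrt(rep(10L, 60), X)
  expect_equal(r$statistic, o$statistic, tolerance = 1e-4)
  expect_gt(r$e_tilde, 0.4)
})

test_that("duplicating every sample never decreases the statistic", {
  set.seed(24)
  for (rep in 1:30) {
    loc <- random_locus()
    t1 <- suppressWarnings(elrt_stat(loc$N, loc$X))$statistic
    t2 <- suppressWarnings(elrt_stat(c(loc$N, loc$N), c(loc$X, loc$X)))$statistic
    expect_gte(t2, t1 - 1e-6)
  }
})

test_that("batch elrt() matches the per-locus route and keeps bookkeeping", {
  set.seed(25)
  sim <- simulate_counts(n_loci = 40, n_samples = 15, coverage_mean = 8,
                         maf_range = c(0.05, 0.2), seed = 5)
  st <- elrt(sim$counts, quiet = TRUE)
  expect_identical(nrow(st), 40L)
  expect_identical(st$locus_id, sim$counts$locus_id)
  m <- elrtcall:::counts_to_matrices(sim$counts)
  for (j in c(1, 7, 40)) {
    single <- suppressWarnings(elrt_stat(m$totals[j, ], m$variants[j, ]))
    expect_equal(st$statistic[j], single$statistic)
    expect_equal(st$e_tilde[j], single$e_tilde)
  }
  # zero-coverage samples are tolerated and contribute nothing
  N <- c(5L, 0L, 5L); X <- c(2L, 0L, 0L)
  with_zero <- suppressWarnings(elrt_stat(N, X))
  without <- suppressWarnings(elrt_stat(c(5L, 5L), c(2L, 0L)))
  expect_equal(with_zero$statistic, without$statistic)
})

test_that("full LRT dominates the eLRT and matches a 2-D grid", {
  expect_identical(full_lrt_stat(rep(10L, 5), rep(0L, 5)), 0)
  set.seed(26)
  for (rep in 1:20) {
    loc <- random_locus()
    f <- full_lrt_stat(loc$N, loc$X)
    e <- suppressWarnings(elrt_stat(loc$N, loc$X))$statistic
    expect_gte(f, e - 1e-6)
  }
  set.seed(27)
  for (rep in 1:5) {
    loc <- random_locus(n_max = 8, cov_max = 6)
    expect_equal(full_lrt_stat(loc$N, loc$X), oracle_full_lrt(loc$N, loc$X),
                 tolerance = 2e-3)
  }
})

test_that("calls from eLRT and full LRT seldom disagree", {
  set.seed(28)
  sim <- simulate_counts(n_loci = 100, n_samples = 50, coverage_mean = 10,
                         maf_range = c(0.01, 0.1), seed = 77)
  m <- elrtcall:::counts_to_matrices(sim$counts)
  st <- elrt(sim$counts, quiet = TRUE)
  thr <- qchisq(0.95, 1)
  full <- vapply(seq_len(100), function(j)
    full_lrt_stat(m$totals[j, ], m$variants[j, ]), 0)
  disagree <- mean((st$statistic > thr) != (full > thr))
  expect_lt(disagree, 0.02)
})

test_that("positive null statistics follow a scaled chi-square", {
  sim <- simulate_counts(n_loci = 2e4, n_samples = 100, coverage_mean = 10,
                         error_mean = 0.01, maf_range = c(0, 0), seed = 31)
  st <- elrt(sim$counts, quiet = TRUE)
  pos <- sort(st$statistic[!st$is_zero])
  n <- length(pos)
  expect_gt(n, 100)
  theo <- qchisq(ppoints(n), df = 1)
  idx <- seq(ceiling(n * 0.005), floor(n * 0.995))  # central 99%
  expect_gt(cor(pos[idx], theo[idx]), 0.99)
})
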