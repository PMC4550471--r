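test_that("zero fraction and scale are estimated per the mixture recipe", {
  stats <- c(rep(0, 977), rep(2, 23))
  fit <- fit_null(stats)
  expect_equal(fit$a, 0.977)
  expect_identical(fit$J, 1000L)
  expect_identical(fit$J0, 977L)
  # trimmed mean: values above the threshold are dropped
  fit2 <- fit_null(c(0.5, 1.5, 2.0, 100.0))
  expect_equal(fit2$k, (0.5 + 1.5 + 2.0) / 3)
  expect_equal(fit2$a, 0)
  expect_equal(fit_null(c(0.9, 1.1))$k, 1)
  # a statistic exactly at the threshold is kept (<= rule)
  expect_equal(fit_null(c(15, 1))$k, 8)
  # degenerate all-zero input: continuity-corrected a, limiting k
  expect_warning(fit3 <- fit_null(rep(0, 50)), "falling back")
  expect_equal(fit3$a, 50 / 51)
  expect_equal(fit3$k, 1)
  expect_lt(fit3$a, 1)
  expect_error(fit_null(numeric(0)), "empty null set")
  # exclusion by logical mask and by locus id
  tbl <- tibble::tibble(locus_id = c("a", "b", "c"), statistic = c(0, 5, 0),
                        is_zero = c(TRUE, FALSE, TRUE))
  expect_identical(suppressWarnings(fit_null(tbl, exclude = "b"))$J, 2L)
  expect_identical(suppressWarnings(
    fit_null(tbl, exclude = c(FALSE, TRUE, FALSE)))$J, 2L)
})

test_that("mixture p-values match independent chi-square tails", {
  lim <- limiting_null()
  expect_equal(null_pvalue(3.841459, lim), 0.025, tolerance = 1e-6)
  expect_equal(limiting_pvalue(2.705543), 0.05, tolerance = 1e-6)
  expect_identical(null_pvalue(0, lim), 1)
  # survival function through the gamma representation as independent route
  nul <- elrtcall:::new_elrt_null(a = 0.977, k = 1)
  expect_equal(null_pvalue(10, nul),
               0.023 * pgamma(10 / 2, shape = 0.5, lower.tail = FALSE),
               tolerance = 1e-12)
  # scale divides the statistic
  nul2 <- elrtcall:::new_elrt_null(a = 0.5, k = 2)
  expect_equal(null_pvalue(7.682918, nul2), 0.025, tolerance = 1e-6)
  expect_error(null_pvalue(-1, lim), "non-negative")
  # monotone non-increasing in T
  ts <- sort(c(0, runif(50, 0, 20)))
  p <- null_pvalue(ts, nul)
  expect_true(all(diff(p) <= 1e-15))
  # limiting variant is exactly the (0.5, 1) special case
  expect_equal(limiting_pvalue(ts), null_pvalue(ts, lim))
})

test_that("BH adjustment matches a hand-coded step-up elementwise", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  set.seed(41)
  p <- runif(1000)
  q <- fdr_adjust(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_identical(rank(q), rank(oracle_bh(p)))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("null parameters are recovered from draws of the mixture", {
  set.seed(42)
  J <- 1e5
  a <- 0.977; k <- 1
  stats <- ifelse(runif(J) < a, 0, k * rchisq(J, 1))
  fit <- fit_null(stats)
  expect_lt(abs(fit$a - a), 0.005)
  expect_lt(abs(fit$k - k), 0.05)
})

test_that("held-out null p-values are sub-uniform", {
  set.seed(43)
  J <- 1e5
  stats <- ifelse(runif(J) < 0.977, 0, rchisq(J, 1))
  half <- seq_len(J / 2)
  fit <- fit_null(stats[half])
  p <- null_pvalue(stats[-half], fit)
  for (t in c(0.01, 0.05, 0.1)) {
    expect_lte(mean(p <= t), t * 1.25)
  }
})

test_that("the end-to-end caller controls calls under the global null", {
  sim <- simulate_counts(n_loci = 5000, n_samples = 100, coverage_mean = 10,
                         error_mean = 0.01, maf_range = c(0, 0), seed = 44)
  res <- call_snps(sim$counts, fdr = 0.05, quiet = TRUE)
  expect_lte(sum(res$calls$called), 0.002 * nrow(res$calls))
  expect_true(all(res$calls$q_value >= res$calls$p_value - 1e-15))
  g <- glance(res)
  expect_identical(g$n_loci, 5000L)
  # all-zero statistics produce zero calls
  st <- tibble::tibble(statistic = rep(0, 100), e_tilde = 0, maf_hat = 0,
                       is_zero = TRUE)
  res0 <- suppressWarnings(call_snps(st, fdr = 0.05))
  expect_identical(sum(res0$calls$called), 0L)
  expect_error(call_snps(st, fdr = 1.5), "fdr")
})

test_that("tidy and glance methods expose calibrated quantities", {
  fit <- fit_null(c(rep(0, 90), rchisq(10, 1)))
  td <- tidy(fit)
  expect_identical(td$term, c("zero_fraction", "scale"))
  gl <- glance(fit)
  expect_identical(gl$n_null_loci, 100L)
  expect_output(print(fit), "zero fraction")
})
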