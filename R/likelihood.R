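#' Genotype-mixture log-likelihood for one locus
#'
#' Log-likelihood of per-sample read counts under the Hardy-Weinberg
#' binomial-error model. With variant-allele frequency `maf` = p and a
#' symmetric per-read error rate `error_rate` = e, a sample with N total and
#' X variant reads contributes
#' \deqn{\log\{p^2 B(X,N,1-e) + 2p(1-p)B(X,N,0.5) + (1-p)^2 B(X,N,e)\}}
#' where B is the binomial pmf (with the 0^0 = 1 convention, so e = 0 is
#' well defined). Samples with N = 0 contribute 0.
#'
#' @param totals,variants integer vectors of per-sample total and
#'   variant-read counts for a single locus.
#' @param error_rate e in [0, 1).
#' @param maf p in [0, 1].
#' @return the log-likelihood (a single number, always <= 0).
#' @examples
#' mixture_loglik(c(10, 10), c(5, 0), error_rate = 0.25, maf = 0.1)
#' @export
mixture_loglik <- function(totals, variants, error_rate, maf) {
  check_locus(totals, variants)
  if (error_rate < 0 || error_rate >= 1) {
    stop("`error_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (maf < 0 || maf > 1) stop("`maf` must lie in [0, 1]", call. = FALSE)
  keep <- totals > 0
  if (!any(keep)) return(0)
  N <- totals[keep]; X <- variants[keep]
  lb <- function(q) {
    # log binomial pmf valid at q = 0 and q = 1 (0^0 = 1 convention)
    if (q <= 0) return(ifelse(X == 0, 0, -Inf))
    if (q >= 1) return(ifelse(X == N, 0, -Inf))
    lchoose(N, X) + X * log(q) + (N - X) * log1p(-q)
  }
  le <- lb(error_rate); lh <- lb(0.5); lv <- lb(1 - error_rate)
  lm <- pmax(le, pmax(lh, lv))
  lm[!is.finite(lm)] <- 0
  mix <- (1 - maf)^2 * exp(le - lm) + 2 * maf * (1 - maf) * exp(lh - lm) +
    maf^2 * exp(lv - lm)
  sum(lm + log(mix))
}

check_locus <- function(totals, variants) {
  if (length(totals) != length(variants) || length(totals) < 1L) {
    stop("`totals` and `variants` must be equal-length, non-empty vectors",
         call. = FALSE)
  }
  if (anyNA(totals) || anyNA(variants) || any(totals < 0) || any(variants < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  if (any(variants > totals)) {
    stop("variant reads exceed total reads", call. = FALSE)
  }
  invisible(TRUE)
}

#' Closed-form null MLE of the error rate
#'
#' Under the null hypothesis p = 0 every read at a locus is an error draw, and
#' the error-rate MLE is the pooled variant-read fraction
#' \eqn{\tilde e = \sum_i X_i / \sum_i N_i}.
#'
#' @inheritParams mixture_loglik
#' @return \eqn{\tilde e} in [0, 1].
#' @examples
#' null_error_mle(c(10, 10, 10), c(1, 0, 2))  # 0.1
#' @export
null_error_mle <- function(totals, variants) {
  check_locus(totals, variants)
  sn <- sum(totals)
  if (sn == 0) stop("degenerate locus: all total read counts are zero", call. = FALSE)
  sum(variants) / sn
}

#' Estimated likelihood-ratio test statistic for one locus
#'
#' The eLRT fixes the nuisance error rate at its closed-form null MLE
#' \eqn{\tilde e} and maximizes the profiled log-likelihood over the
#' variant-allele frequency p in [0, 1]:
#' \deqn{T = 2\{\max_p l(\tilde e, p) - l(\tilde e, 0)\}.}
#' Maximization combines a 50-point warm-start grid (log-spaced near 0, where
#' rare-variant optima live) with Brent refinement at absolute tolerance
#' 1e-8; tiny negative round-off is clipped to zero. A statistic below
#' `zero_epsilon` is flagged as exactly zero.
#'
#' @inheritParams mixture_loglik
#' @param zero_epsilon threshold under which T is declared exactly zero.
#' @return a one-row tibble: `statistic`, `e_tilde`, `maf_hat`, `is_zero`.
#' @seealso [elrt()] for whole-table computation, [full_lrt_stat()] for the
#'   jointly maximized statistic.
#' @examples
#' elrt_stat(rep(10, 20), c(rep(5, 4), rep(0, 16)))
#' @export
elrt_stat <- function(totals, variants, zero_epsilon = 1e-8) {
  check_locus(totals, variants)
  if (sum(totals) == 0) {
    stop("degenerate locus: all total read counts are zero", call. = FALSE)
  }
  res <- cpp_elrt_batch(matrix(as.integer(totals), nrow = 1L),
                        matrix(as.integer(variants), nrow = 1L), zero_epsilon)
  if (length(res$high_error_loci)) {
    warning("pooled variant fraction e~ >= 0.5; the symmetric-error model is ",
            "strained at this locus", call. = FALSE)
  }
  tibble::tibble(statistic = res$statistic, e_tilde = res$e_tilde,
                 maf_hat = res$maf_hat, is_zero = res$is_zero)
}

#' eLRT statistics for every locus of a count table
#'
#' Data-frame-first batch version of [elrt_stat()]: computes the closed-form
#' null error MLE and the profiled likelihood-ratio statistic for each row of
#' a wide count table.
#'
#' @param counts a wide count table (see [count_table()]).
#' @param zero_epsilon threshold under which a statistic is exactly zero.
#' @param quiet suppress the summary warning about loci with e~ >= 0.5.
#' @return a tibble with one row per locus: `locus_id`, `statistic`,
#'   `e_tilde`, `maf_hat`, `is_zero`. Loci whose samples all have zero
#'   coverage get NA statistics.
#' @examples
#' sim <- simulate_counts(n_loci = 5, n_samples = 10, coverage_mean = 10,
#'                        maf_range = c(0.2, 0.3), seed = 1)
#' elrt(sim$counts)
#' @export
elrt <- function(counts, zero_epsilon = 1e-8, quiet = FALSE) {
  m <- counts_to_matrices(counts)
  res <- cpp_elrt_batch(m$totals, m$variants, zero_epsilon)
  if (!quiet && length(res$high_error_loci)) {
    warning(length(res$high_error_loci),
            " locus/loci with pooled variant fraction e~ >= 0.5; ",
            "the symmetric-error model is strained there", call. = FALSE)
  }
  tibble::tibble(locus_id = m$locus_id, statistic = res$statistic,
                 e_tilde = res$e_tilde, maf_hat = res$maf_hat,
                 is_zero = res$is_zero)
}

#' Fully maximized likelihood-ratio statistic (validation oracle)
#'
#' Maximizes the log-likelihood jointly over (e, p) in [0, 0.5) x [0, 1] by a
#' coarse grid over e with profile maximization over p at each grid point,
#' followed by Brent refinement in e, and returns
#' \eqn{2\{\max_{e,p} l(e,p) - \max_e l(e,0)\}}. This is the reference the
#' eLRT approximates; it is not used in the calling path.
#'
#' @inheritParams mixture_loglik
#' @param n_grid number of e grid points for the outer maximization.
#' @return the statistic (single non-negative number).
#' @export
full_lrt_stat <- function(totals, variants, n_grid = 201) {
  check_locus(totals, variants)
  sn <- sum(totals)
  if (sn == 0) stop("degenerate locus: all total read counts are zero", call. = FALSE)
  N <- as.integer(totals); X <- as.integer(variants)
  e_hi <- 0.5 - 1e-9
  prof <- function(e) cpp_profile_max(N, X, e)$value
  # numerator: joint max over (e, p)
  egrid <- seq(0, e_hi, length.out = n_grid)
  vals <- vapply(egrid, prof, 0)
  i <- which.max(vals)
  lo <- egrid[max(1L, i - 1L)]; hi <- egrid[min(n_grid, i + 1L)]
  op <- optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-9)
  num <- max(op$objective, vals[i])
  # denominator: max over e at p = 0; the unconstrained MLE is sum X / sum N,
  # capped at the e upper bound
  e0 <- min(sum(X) / sn, e_hi)
  den <- mixture_loglik(N, X, error_rate = e0, maf = 0)
  max(2 * (num - den), 0)
}
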