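#' FDR/power benchmark over the simulation grid
#'
#' Runs the full read-count benchmark: for every SNP parameter combination of
#' [study_grid()] it simulates `snp_loci` SNP loci plus `null_loci` matching
#' null loci, computes eLRT statistics, calibrates the adaptive null on the
#' known-null loci (the simulation analogue of excluding database-known SNPs)
#' and computes calls under both the adaptive and the limiting null at each
#' nominal FDR level, recording empirical FDR and power per dataset.
#'
#' Locus counts default to a desk-scale run (one tenth of the full-scale SNP
#' count, 1/25 of the null count — enough for stable medians across the 96
#' datasets in minutes on one CPU); raise them to the full 5e3/5e5 to
#' reproduce the benchmark at its original size.
#'
#' @param snp_loci SNP loci per dataset.
#' @param null_loci matching null loci per dataset.
#' @param levels nominal FDR levels at which calls are made.
#' @param seed integer seed; dataset i uses `seed + i`.
#' @param trim_threshold passed to [fit_null()].
#' @param progress print one line per dataset.
#' @return tibble with one row per dataset x null model x level:
#'   grid columns, `zero_fraction`, `scale` (adaptive fit), `null_model`,
#'   `nominal_fdr`, `n_called`, `empirical_fdr`, `power`.
#' @export
run_fdr_study <- function(snp_loci = 500, null_loci = 2e4,
                          levels = c(0.01, 0.05, 0.1), seed = 1,
                          trim_threshold = 15, progress = FALSE) {
  g <- study_grid()
  g <- g[g$type == "snp", ]
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    snp <- simulate_counts(
      n_loci = snp_loci, n_samples = g$n_samples[i],
      coverage_mean = g$coverage_mean[i], error_mean = g$error_mean[i],
      maf_range = c(g$maf_low[i], g$maf_high[i]), id_prefix = "S",
      seed = seed + i)
    nul <- simulate_counts(
      n_loci = null_loci, n_samples = g$n_samples[i],
      coverage_mean = g$coverage_mean[i], error_mean = g$error_mean[i],
      maf_range = c(0, 0), id_prefix = "N", seed = seed + 10000L + i)
    counts <- dplyr::bind_rows(snp$counts, nul$counts)
    truth <- c(rep(TRUE, snp_loci), rep(FALSE, null_loci))
    st <- elrt(counts, quiet = TRUE)
    fit <- fit_null(st, exclude = truth, trim_threshold = trim_threshold)
    rows <- list()
    for (model in c("adaptive", "limiting")) {
      nul_d <- if (model == "adaptive") fit else limiting_null()
      q <- fdr_adjust(null_pvalue(st$statistic, nul_d))
      for (lv in levels) {
        called <- q <= lv
        n_called <- sum(called)
        fp <- sum(called & !truth)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          null_model = model, nominal_fdr = lv, n_called = n_called,
          empirical_fdr = if (n_called > 0) fp / n_called else 0,
          power = sum(called & truth) / snp_loci)
      }
    }
    out[[i]] <- dplyr::bind_cols(
      g[rep(i, length(rows)), ],
      tibble::tibble(zero_fraction = fit$a, scale = fit$k),
      dplyr::bind_rows(rows))
    if (progress) {
      message(sprintf("[%2d/%d] %s a=%.3f k=%.3f", i, nrow(g), g$dataset[i],
                      fit$a, fit$k))
    }
  }
  dplyr::bind_rows(out)
}

#' Null-calibration study over the 32 null combinations
#'
#' Simulates each null parameter combination of [study_grid()] (error mean x
#' sample size x mean coverage, MAF = 0) and reports the fitted
#' zero-fraction and scale of the eLRT null mixture per combination.
#'
#' @param null_loci loci per combination (desk-scale default 5e4, enough to
#'   stabilize the trimmed-mean scale estimate at high coverage where
#'   positive null statistics are rare; full scale
#'   is 5e5).
#' @param seed integer seed; combination i uses `seed + i`.
#' @param trim_threshold passed to [fit_null()].
#' @param progress print one line per combination.
#' @return tibble: grid columns plus `zero_fraction`, `scale`, `n_zero`,
#'   `n_positive`.
#' @export
run_null_study <- function(null_loci = 5e4, seed = 1, trim_threshold = 15,
                           progress = FALSE) {
  g <- study_grid()
  g <- g[g$type == "null", ]
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    sim <- simulate_counts(
      n_loci = null_loci, n_samples = g$n_samples[i],
      coverage_mean = g$coverage_mean[i], error_mean = g$error_mean[i],
      maf_range = c(0, 0), seed = seed + i)
    st <- elrt(sim$counts, quiet = TRUE)
    fit <- suppressWarnings(fit_null(st, trim_threshold = trim_threshold))
    out[[i]] <- dplyr::bind_cols(
      g[i, ],
      tibble::tibble(zero_fraction = fit$a, scale = fit$k, n_zero = fit$J0,
                     n_positive = fit$J - fit$J0))
    if (progress) {
      message(sprintf("[%2d/%d] %s a=%.4f k=%.3f", i, nrow(g), g$dataset[i],
                      fit$a, fit$k))
    }
  }
  dplyr::bind_rows(out)
}
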