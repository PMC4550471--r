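#' Generalized Poisson random deviates
#'
#' Over-dispersed counts parameterized by mean `mu` and dispersion
#' `lambda` = mean/variance (so variance = mu/lambda); `lambda = 1` reduces
#' exactly to the Poisson distribution. Internally this is Consul's
#' generalized Poisson with theta = mu*sqrt(lambda), delta = 1 - sqrt(lambda)
#' (mean theta/(1-delta), variance theta/(1-delta)^3), sampled through the
#' Poisson branching-process representation.
#'
#' @param n number of deviates.
#' @param mu mean, > 0.
#' @param lambda dispersion in (0, 1]: mean divided by variance.
#' @param method `"table"` (default) draws from the exact pmf truncated where
#'   its upper tail drops below 1e-12 of the mass — the fast path for the
#'   simulator's millions of coverage draws; `"branching"` uses the exact
#'   Poisson-cascade representation of the branching process. Both sample the
#'   same distribution (the table method up to the negligible truncation).
#' @return non-negative integer vector of length `n`.
#' @examples
#' mean(rgpois(1e4, mu = 10, lambda = 0.4))  # ~10, variance ~25
#' @export
rgpois <- function(n, mu, lambda, method = c("table", "branching")) {
  method <- match.arg(method)
  if (!is.numeric(lambda) || lambda <= 0 || lambda > 1) {
    stop("`lambda` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(mu) || mu <= 0) stop("`mu` must be positive", call. = FALSE)
  theta <- mu * sqrt(lambda)
  delta <- 1 - sqrt(lambda)
  if (method == "branching") {
    x <- rpois(n, theta)
    if (delta > 0) {
      gen <- x
      active <- which(gen > 0L)
      while (length(active)) {
        off <- rpois(length(active), delta * gen[active])
        x[active] <- x[active] + off
        gen[active] <- off
        active <- active[off > 0L]
      }
    }
    return(x)
  }
  pmf <- gpois_pmf(theta, delta)
  sample.int(length(pmf), n, replace = TRUE, prob = pmf) - 1L
}

# Consul's generalized-Poisson pmf P(X = k) = theta (theta + k delta)^(k-1)
#   exp(-theta - k delta) / k!, evaluated in log space and truncated once the
#   remaining upper-tail mass is below 1e-12
gpois_pmf <- function(theta, delta) {
  k_max <- 16L
  repeat {
    k <- 0:k_max
    lp <- log(theta) + (k - 1) * log(theta + k * delta) - theta - k * delta -
      lgamma(k + 1)
    p <- exp(lp)
    if (sum(p) >= 1 - 1e-12) break
    k_max <- k_max * 2L
    if (k_max > 2^20) stop("generalized-Poisson pmf failed to converge")
  }
  p
}

#' Per-locus error rates from a truncated normal
#'
#' `e = max(0, Normal(mean, sd^2))`: the genomewide mapping/sequencing error
#' rate varies slightly from locus to locus around its platform mean
#' (about 0.01 for Illumina HiSeq-class data), clamped at zero.
#'
#' @param n number of loci.
#' @param mean mean of the untruncated normal.
#' @param sd_sq variance of the untruncated normal (default 1e-6).
#' @export
sample_error_rate <- function(n, mean, sd_sq = 1e-6) {
  stopifnot(sd_sq >= 0)
  pmax(0, rnorm(n, mean, sqrt(sd_sq)))
}

#' Per-locus variant-allele frequencies
#'
#' Uniform draws on a MAF stratum; the benchmark strata are U(0.001, 0.01)
#' (rare), U(0.01, 0.05) (less rare) and U(0.05, 0.1) (common), with
#' `low = high = 0` for null (non-SNP) loci.
#'
#' @param n number of loci.
#' @param low,high stratum bounds in [0, 1], `low <= high`.
#' @export
sample_maf <- function(n, low, high) {
  stopifnot(low <= high, low >= 0, high <= 1)
  if (low == high) rep(low, n) else runif(n, low, high)
}

#' Per-sample read coverage
#'
#' Generalized Poisson coverage (see [rgpois()]); `model = "constant"` gives
#' every sample exactly `round(mu)` reads.
#'
#' @param n number of draws.
#' @param mu mean coverage.
#' @param lambda dispersion (mean/variance) in (0, 1].
#' @param model `"gpois"` or `"constant"`.
#' @export
sample_coverage <- function(n, mu, lambda = 0.4, model = c("gpois", "constant")) {
  model <- match.arg(model)
  if (model == "constant") return(rep(as.integer(round(mu)), n))
  rgpois(n, mu, lambda)
}

#' Genotypes under Hardy-Weinberg equilibrium
#'
#' Number of variant-allele copies per (unrelated, diploid) sample:
#' probabilities ((1-p)^2, 2p(1-p), p^2) for 0/1/2 copies, i.e.
#' Binomial(2, p).
#'
#' @param n number of samples.
#' @param maf variant-allele frequency p (scalar or length-n).
#' @return integer vector in {0, 1, 2}.
#' @export
sample_genotype <- function(n, maf) {
  stopifnot(all(maf >= 0), all(maf <= 1))
  rbinom(n, 2L, maf)
}

#' Variant-read counts given genotype and coverage
#'
#' X ~ Binomial(N, q) with q = e for homozygous reference, 0.5 for
#' heterozygous, 1 - e for homozygous variant (symmetric per-read error e).
#'
#' @param genotype variant-allele copies in {0, 1, 2} (vector).
#' @param coverage total reads per sample (vector, >= 0).
#' @param error_rate per-read error rate (scalar or vector).
#' @export
sample_reads <- function(genotype, coverage, error_rate) {
  stopifnot(all(coverage >= 0), all(genotype %in% 0:2))
  q <- ifelse(genotype == 0L, error_rate,
              ifelse(genotype == 1L, 0.5, 1 - error_rate))
  rbinom(length(coverage), coverage, q)
}

#' Simulate a multi-sample read-count dataset
#'
#' Generates loci under the Hardy-Weinberg binomial-error model: per locus an
#' error rate from a truncated normal and a MAF from a uniform stratum (0 for
#' null loci); per sample a generalized-Poisson coverage, an HWE genotype and
#' a binomial variant-read count.
#'
#' @param n_loci number of loci.
#' @param n_samples number of samples.
#' @param coverage_mean mean coverage mu.
#' @param coverage_dispersion lambda = mean/variance in (0, 1]; default 0.4
#'   as estimated from low-coverage human resequencing data.
#' @param coverage_model `"gpois"` or `"constant"`.
#' @param error_mean mean of the truncated-normal error-rate distribution.
#' @param error_sd_sq its variance (default 1e-6); 0 gives a fixed rate.
#' @param maf_range length-2 stratum bounds; `c(0, 0)` simulates null loci.
#' @param samples optional sample names.
#' @param id_prefix prefix for generated locus ids.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @return a list of class `sim_counts`: `counts` (wide count tibble),
#'   `truth` (tibble `locus_id`, `maf`, `error_rate`), `genotypes`
#'   (loci x samples integer matrix) and `config`.
#' @examples
#' sim <- simulate_counts(n_loci = 10, n_samples = 20, coverage_mean = 10,
#'                        maf_range = c(0.01, 0.05), seed = 42)
#' sim$truth
#' @export
simulate_counts <- function(n_loci, n_samples, coverage_mean,
                            coverage_dispersion = 0.4,
                            coverage_model = c("gpois", "constant"),
                            error_mean = 0.01, error_sd_sq = 1e-6,
                            maf_range = c(0, 0), samples = NULL,
                            id_prefix = "L", seed = NULL) {
  coverage_model <- match.arg(coverage_model)
  stopifnot(n_loci >= 1, n_samples >= 1, length(maf_range) == 2)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_counts(
      n_loci = n_loci, n_samples = n_samples, coverage_mean = coverage_mean,
      coverage_dispersion = coverage_dispersion,
      coverage_model = coverage_model, error_mean = error_mean,
      error_sd_sq = error_sd_sq, maf_range = maf_range, samples = samples,
      id_prefix = id_prefix, seed = NULL)))
  }
  e <- sample_error_rate(n_loci, error_mean, error_sd_sq)
  p <- sample_maf(n_loci, maf_range[1], maf_range[2])
  m <- n_loci * n_samples
  N <- matrix(sample_coverage(m, coverage_mean, coverage_dispersion,
                              coverage_model), n_loci, n_samples)
  g <- matrix(sample_genotype(m, rep(p, n_samples)), n_loci, n_samples)
  X <- matrix(sample_reads(as.vector(g), as.vector(N), rep(e, n_samples)),
              n_loci, n_samples)
  ids <- sprintf("%s%06d", id_prefix, seq_len(n_loci))
  structure(list(
    counts = count_table(ids, N, X, samples = samples),
    truth = tibble::tibble(locus_id = ids, maf = p, error_rate = e),
    genotypes = g,
    config = list(n_loci = n_loci, n_samples = n_samples,
                  coverage_mean = coverage_mean,
                  coverage_dispersion = coverage_dispersion,
                  coverage_model = coverage_model, error_mean = error_mean,
                  error_sd_sq = error_sd_sq, maf_range = maf_range,
                  seed = seed)),
    class = "sim_counts")
}

#' @export
print.sim_counts <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Simulated read counts: %d loci x %d samples ",
                     "(coverage %s %g, error mean %g, MAF in [%g, %g])\n"),
              cfg$n_loci, cfg$n_samples, cfg$coverage_model,
              cfg$coverage_mean, cfg$error_mean, cfg$maf_range[1],
              cfg$maf_range[2]))
  invisible(x)
}

#' The benchmark simulation grid
#'
#' Enumerates the standard read-count benchmark: SNP datasets for every
#' combination of error mean in {1e-2, 1e-3}, MAF stratum in
#' {U(0.001,0.01), U(0.01,0.05), U(0.05,0.1)}, sample size in
#' {50, 100, 200, 500} and mean coverage in {5, 10, 20, 30} (96
#' combinations), plus the 32 matching null combinations (MAF = 0). At
#' `scale = 1` each SNP dataset has 5e3 loci and each null dataset 5e5 loci
#' (SNPs are ~1% of loci genomewide); `scale` shrinks both for desk-sized
#' runs.
#'
#' @param scale multiplier on the locus counts (default 1).
#' @param snp_loci,null_loci full-scale locus counts before scaling.
#' @return a tibble with one row per dataset: `dataset`, `type`
#'   (`"snp"`/`"null"`), `error_mean`, `maf_low`, `maf_high`, `n_samples`,
#'   `coverage_mean`, `n_loci`.
#' @export
study_grid <- function(scale = 1, snp_loci = 5e3, null_loci = 5e5) {
  stopifnot(scale > 0)
  strata <- list(c(0.001, 0.01), c(0.01, 0.05), c(0.05, 0.1))
  snp <- expand.grid(error_mean = c(1e-2, 1e-3), stratum = 1:3,
                     n_samples = c(50L, 100L, 200L, 500L),
                     coverage_mean = c(5, 10, 20, 30))
  null <- expand.grid(error_mean = c(1e-2, 1e-3), stratum = 0L,
                      n_samples = c(50L, 100L, 200L, 500L),
                      coverage_mean = c(5, 10, 20, 30))
  g <- rbind(snp, null)
  lo <- c(0, vapply(strata, `[`, 0, 1))[g$stratum + 1L]
  hi <- c(0, vapply(strata, `[`, 0, 2))[g$stratum + 1L]
  tibble::tibble(
    dataset = sprintf("%s_e%g_maf%g-%g_n%d_mu%g",
                      ifelse(g$stratum > 0, "snp", "null"), g$error_mean,
                      lo, hi, g$n_samples, g$coverage_mean),
    type = ifelse(g$stratum > 0, "snp", "null"),
    error_mean = g$error_mean, maf_low = lo, maf_high = hi,
    n_samples = g$n_samples, coverage_mean = g$coverage_mean,
    n_loci = as.integer(round(ifelse(g$stratum > 0, snp_loci, null_loci) * scale)))
}
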