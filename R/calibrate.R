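#' Fit the zero-inflated scaled chi-square null
#'
#' The finite-sample null distribution of the eLRT statistic is modelled as
#' \deqn{D_{a,k} = a \cdot 0 + (1-a) \cdot k\chi^2_1,} a point mass at zero
#' mixed with a scaled chi-square (expectation k). Both parameters are
#' estimated from presumed-null loci: `a` as the fraction J0/J of null
#' statistics that are exactly zero, and `k` as a trimmed mean of the
#' positive null statistics, excluding values above `trim_threshold`
#' (defaults to 15, around the upper 1e-4 quantile of chi-square with 1 df,
#' so almost no non-outliers are dropped).
#'
#' By default every locus is treated as null — in genomewide data the vast
#' majority of loci are not SNPs — and a known-SNP exclusion list refines
#' this. When no positive null statistic exists, a is continuity-corrected to
#' J0/(J+1) and k falls back to 1 so that positive statistics never receive a
#' p-value of exactly zero.
#'
#' @param stats a tibble from [elrt()] (columns `statistic`, `is_zero`,
#'   optionally `locus_id`), or a bare numeric vector of statistics.
#' @param exclude locus ids (or a logical/integer index vector) to exclude
#'   from the null set, e.g. known SNPs.
#' @param trim_threshold statistics above this are excluded from the k
#'   estimate.
#' @param zero_epsilon used only when `stats` is a bare numeric vector.
#' @return an object of class `elrt_null` with fields `a`, `k`, `J`, `J0`,
#'   `trim_threshold`.
#' @examples
#' fit_null(c(rep(0, 977), rchisq(23, 1)))
#' @export
fit_null <- function(stats, exclude = NULL, trim_threshold = 15,
                     zero_epsilon = 1e-8) {
  if (is.data.frame(stats)) {
    statistic <- stats$statistic
    is_zero <- stats$is_zero
    ids <- stats$locus_id
  } else {
    statistic <- as.numeric(stats)
    is_zero <- statistic < zero_epsilon
    ids <- NULL
  }
  if (any(statistic < 0, na.rm = TRUE)) {
    stop("statistics must be non-negative", call. = FALSE)
  }
  keep <- !is.na(statistic)
  if (!is.null(exclude)) {
    if (is.logical(exclude)) {
      keep <- keep & !exclude
    } else if (is.numeric(exclude)) {
      keep[exclude] <- FALSE
    } else {
      if (is.null(ids)) stop("character `exclude` needs locus ids in `stats`",
                             call. = FALSE)
      keep <- keep & !(ids %in% exclude)
    }
  }
  J <- sum(keep)
  if (J == 0L) stop("empty null set: no loci left for calibration", call. = FALSE)
  J0 <- sum(is_zero[keep])
  pos <- statistic[keep & !is_zero]
  trimmed <- pos[pos <= trim_threshold]
  if (length(trimmed) == 0L) {
    warning("no positive null statistics after trimming; ",
            "falling back to the limiting scale k = 1 and a continuity-",
            "corrected zero fraction", call. = FALSE)
    a <- J0 / (J + 1)
    k <- 1
  } else {
    a <- J0 / J
    k <- mean(trimmed)
  }
  new_elrt_null(a = a, k = k, J = J, J0 = J0, trim_threshold = trim_threshold)
}

new_elrt_null <- function(a, k, J = NA_integer_, J0 = NA_integer_,
                          trim_threshold = NA_real_) {
  stopifnot(a >= 0, a <= 1, k > 0)
  structure(list(a = a, k = k, J = as.integer(J), J0 = as.integer(J0),
                 trim_threshold = trim_threshold),
            class = "elrt_null")
}

#' The large-sample limiting null
#'
#' The boundary-parameter limiting distribution of the eLRT statistic: an
#' equal mixture of a point mass at zero and chi-square with 1 df, i.e.
#' \eqn{D_{0.5,1}}. Using it instead of the fitted null gives the
#' conservative variant of the caller.
#'
#' @return an `elrt_null` with a = 0.5, k = 1.
#' @export
limiting_null <- function() new_elrt_null(a = 0.5, k = 1)

#' @export
print.elrt_null <- function(x, ...) {
  cat("Zero-inflated scaled chi-square null D_{a,k}\n")
  cat(sprintf("  a (zero fraction): %.4f\n  k (scale):         %.4f\n", x$a, x$k))
  if (!is.na(x$J)) {
    cat(sprintf("  fitted from J = %d null loci (J0 = %d exactly zero)\n",
                x$J, x$J0))
  }
  invisible(x)
}

#' @export
tidy.elrt_null <- function(x, ...) {
  tibble::tibble(term = c("zero_fraction", "scale"),
                 estimate = c(x$a, x$k))
}

#' @export
glance.elrt_null <- function(x, ...) {
  tibble::tibble(zero_fraction = x$a, scale = x$k, n_null_loci = x$J,
                 n_zero = x$J0, trim_threshold = x$trim_threshold)
}

#' p-values under the mixture null
#'
#' For a positive statistic T the upper-tail probability of
#' \eqn{D_{a,k}} is \eqn{(1-a)\Pr(\chi^2_1 \ge T/k)}; a statistic that is
#' exactly zero (below `zero_epsilon`) gets p-value 1, since the whole
#' mixture mass lies at or above zero.
#'
#' @param statistic non-negative numeric vector of eLRT statistics.
#' @param null an `elrt_null` (from [fit_null()] or [limiting_null()]).
#' @param zero_epsilon statistics below this are treated as exactly zero.
#' @return p-values in [0, 1], non-increasing in `statistic`.
#' @examples
#' null_pvalue(3.841459, limiting_null())  # 0.025
#' @export
null_pvalue <- function(statistic, null, zero_epsilon = 1e-8) {
  stopifnot(inherits(null, "elrt_null"))
  if (any(statistic < 0, na.rm = TRUE)) {
    stop("statistics must be non-negative", call. = FALSE)
  }
  p <- (1 - null$a) * pchisq(statistic / null$k, df = 1, lower.tail = FALSE)
  p[statistic < zero_epsilon] <- 1
  pmin(pmax(p, 0), 1)
}

#' p-values under the limiting null
#'
#' Convenience wrapper: [null_pvalue()] with the fixed \eqn{D_{0.5,1}}
#' mixture.
#'
#' @inheritParams null_pvalue
#' @export
limiting_pvalue <- function(statistic, zero_epsilon = 1e-8) {
  null_pvalue(statistic, limiting_null(), zero_epsilon = zero_epsilon)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (q-values), order-preserving and clipped to
#' [0, 1]. Wraps `stats::p.adjust(method = "BH")`; the method is an explicit
#' choice, not `p.adjust`'s default.
#'
#' @param p_values numeric vector in [0, 1] (NA allowed).
#' @return q-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Call SNPs from a count table
#'
#' The end-to-end caller: computes the eLRT statistic for every locus,
#' calibrates the zero-inflated scaled chi-square null from presumed-null
#' loci (all loci, minus an optional exclusion list of known SNPs), converts
#' statistics to p-values, BH-adjusts them, and calls every locus with
#' q-value at or below the nominal FDR level.
#'
#' @param counts a wide count table (see [count_table()]), or a tibble
#'   already holding `elrt()` output (columns `statistic` and `is_zero`).
#' @param fdr nominal FDR level in (0, 1).
#' @param null_model `"adaptive"` fits \eqn{D_{a,k}} from the data;
#'   `"limiting"` uses the fixed \eqn{D_{0.5,1}}.
#' @param exclude locus ids (or logical/integer index) excluded from null
#'   calibration, e.g. database-known SNPs.
#' @param trim_threshold trimming bound for the scale estimate.
#' @param zero_epsilon exact-zero threshold for statistics.
#' @param quiet suppress per-run warnings from the statistic computation.
#' @return an object of class `snp_calls`: list with `calls` (tibble:
#'   `locus_id`, `statistic`, `e_tilde`, `maf_hat`, `p_value`, `q_value`,
#'   `called`), `null` (`elrt_null`), `nominal_fdr`, `null_model`.
#' @examples
#' sim <- simulate_counts(n_loci = 200, n_samples = 50, coverage_mean = 10,
#'                        maf_range = c(0, 0), seed = 7)
#' res <- call_snps(sim$counts, fdr = 0.05)
#' glance(res)
#' @export
call_snps <- function(counts, fdr = 0.01,
                      null_model = c("adaptive", "limiting"),
                      exclude = NULL, trim_threshold = 15,
                      zero_epsilon = 1e-8, quiet = FALSE) {
  null_model <- match.arg(null_model)
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) {
    stop("`fdr` must lie in (0, 1)", call. = FALSE)
  }
  if (is.data.frame(counts) && all(c("statistic", "is_zero") %in% names(counts))) {
    stats <- counts
    if (!"locus_id" %in% names(stats)) {
      stats$locus_id <- paste0("L", seq_len(nrow(stats)))
    }
  } else {
    stats <- elrt(counts, zero_epsilon = zero_epsilon, quiet = quiet)
  }
  null <- if (null_model == "adaptive") {
    fit_null(stats, exclude = exclude, trim_threshold = trim_threshold,
             zero_epsilon = zero_epsilon)
  } else {
    limiting_null()
  }
  p <- null_pvalue(stats$statistic, null, zero_epsilon = zero_epsilon)
  q <- fdr_adjust(p)
  calls <- tibble::tibble(locus_id = stats$locus_id,
                          statistic = stats$statistic,
                          e_tilde = stats$e_tilde %||% NA_real_,
                          maf_hat = stats$maf_hat %||% NA_real_,
                          is_zero = stats$is_zero,
                          p_value = p, q_value = q,
                          called = !is.na(q) & q <= fdr)
  structure(list(calls = calls, null = null, nominal_fdr = fdr,
                 null_model = null_model),
            class = "snp_calls")
}

#' @export
print.snp_calls <- function(x, ...) {
  cat(sprintf("SNP calls: %d of %d loci called at nominal FDR %.3g (%s null)\n",
              sum(x$calls$called, na.rm = TRUE), nrow(x$calls), x$nominal_fdr,
              x$null_model))
  print(x$null)
  invisible(x)
}

#' @export
tidy.snp_calls <- function(x, ...) x$calls

#' @export
glance.snp_calls <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x$calls),
                 n_called = sum(x$calls$called, na.rm = TRUE),
                 nominal_fdr = x$nominal_fdr,
                 null_model = x$null_model,
                 zero_fraction = x$null$a,
                 scale = x$null$k)
}
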