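#' Confusion counts at a nominal FDR level
#'
#' A locus is called when its q-value is at or below `nominal_fdr`; truth
#' labels mark the true SNPs.
#'
#' @param calls tibble with a `q_value` column (e.g. `tidy(call_snps(...))`).
#' @param truth logical vector (TRUE = true SNP), one per call record.
#' @param nominal_fdr calling threshold on q-values.
#' @return one-row tibble: `tp`, `fp`, `fn`, `tn`.
#' @export
call_confusion <- function(calls, truth, nominal_fdr) {
  q <- if (is.data.frame(calls)) calls$q_value else as.numeric(calls)
  if (length(q) != length(truth)) {
    stop("`calls` and `truth` lengths differ", call. = FALSE)
  }
  truth <- as.logical(truth)
  called <- !is.na(q) & q <= nominal_fdr
  tibble::tibble(tp = sum(called & truth), fp = sum(called & !truth),
                 fn = sum(!called & truth), tn = sum(!called & !truth))
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2pr/(p + r)`; defined as 0 when
#' both are 0.
#'
#' @param precision,recall values in [0, 1].
#' @export
f1_score <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1, na.rm = TRUE),
            all(recall >= 0 & recall <= 1, na.rm = TRUE))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Precision-recall curve and Fmax
#'
#' Sweeps the threshold over the sorted unique p-values (calling everything
#' at or below each threshold) and records precision, recall and F1; `Fmax`
#' is the maximum F1 along the curve.
#'
#' @param p_values finite p-values (lower = stronger call).
#' @param truth logical vector of true-SNP labels.
#' @return an object of class `pr_curve`: tibble with columns `threshold`,
#'   `n_called`, `precision`, `recall`, `f1`, plus attribute `f_max`
#'   (retrieved by `glance()`).
#' @export
pr_curve <- function(p_values, truth) {
  stopifnot(length(p_values) == length(truth), all(is.finite(p_values)))
  truth <- as.logical(truth)
  n_true <- sum(truth)
  ord <- order(p_values)
  p <- p_values[ord]; t <- truth[ord]
  cum_tp <- cumsum(t)
  cum_called <- seq_along(p)
  last <- !duplicated(p, fromLast = TRUE)  # last index of each unique p
  tp <- cum_tp[last]; called <- cum_called[last]
  precision <- tp / called
  recall <- if (n_true > 0) tp / n_true else rep(0, length(tp))
  f1 <- f1_score(precision, recall)
  out <- tibble::tibble(threshold = p[last], n_called = called,
                        precision = precision, recall = recall, f1 = f1)
  structure(out, f_max = if (nrow(out)) max(f1) else 0,
            class = c("pr_curve", class(out)))
}

#' @export
glance.pr_curve <- function(x, ...) {
  tibble::tibble(f_max = attr(x, "f_max"), n_thresholds = nrow(x))
}

#' Transition/transversion ratio
#'
#' Transitions are purine-purine (A<->G) or pyrimidine-pyrimidine (C<->T)
#' substitutions; everything else is a transversion. The ratio is reported
#' for all calls and, when a known-SNP set is supplied, stratified into
#' known and novel calls. A zero transversion count yields NaN.
#'
#' @param ref,alt nucleotide vectors in {A, C, G, T}.
#' @param known optional logical vector marking database-known calls, or a
#'   character vector of known locus ids matched against `locus_id`.
#' @param locus_id needed when `known` is a character vector.
#' @return one-row tibble: `titv_all` and, with `known`, `titv_known`,
#'   `titv_novel`.
#' @export
titv_ratio <- function(ref, alt, known = NULL, locus_id = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("invalid allele at position ", which(!ok)[1], call. = FALSE)
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  is_ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  ratio <- function(ti) {
    tv <- sum(!ti)
    if (tv == 0) NaN else sum(ti) / tv
  }
  out <- tibble::tibble(titv_all = ratio(is_ti))
  if (!is.null(known)) {
    if (is.character(known)) {
      if (is.null(locus_id)) {
        stop("`locus_id` required when `known` is a character set", call. = FALSE)
      }
      known <- locus_id %in% known
    }
    out$titv_known <- ratio(is_ti[known])
    out$titv_novel <- ratio(is_ti[!known])
  }
  out
}

#' Evaluate calls against truth labels
#'
#' Summarizes a call set at its nominal FDR level: empirical FDR (fraction of
#' non-SNPs among calls, 0 by convention when nothing is called), power
#' (recall), precision (1 - FDR), F1 at the nominal level, and Fmax over the
#' precision-recall curve. Ti/Tv ratios are added when `ref`/`alt` columns
#' are present.
#'
#' @param calls a `snp_calls` object or its `calls` tibble (needs `p_value`
#'   and `q_value`).
#' @param truth logical vector of true-SNP labels, or a truth tibble from
#'   [simulate_counts()] / [read_truth()] (matched by `locus_id`, SNP iff
#'   `maf > 0`).
#' @param nominal_fdr calling threshold; defaults to the object's own level.
#' @param known optional known-SNP set for Ti/Tv stratification.
#' @return a one-row metrics tibble.
#' @export
evaluate_calls <- function(calls, truth, nominal_fdr = NULL, known = NULL) {
  if (inherits(calls, "snp_calls")) {
    if (is.null(nominal_fdr)) nominal_fdr <- calls$nominal_fdr
    calls <- calls$calls
  }
  if (is.null(nominal_fdr)) {
    stop("`nominal_fdr` is required when `calls` is a bare tibble", call. = FALSE)
  }
  if (is.data.frame(truth)) {
    idx <- match(calls$locus_id, truth$locus_id)
    if (anyNA(idx)) {
      stop("truth labels missing for ", sum(is.na(idx)), " call loci",
           call. = FALSE)
    }
    truth <- truth$maf[idx] > 0
  }
  cf <- call_confusion(calls, truth, nominal_fdr)
  n_called <- cf$tp + cf$fp
  n_true <- cf$tp + cf$fn
  efdr <- if (n_called > 0) cf$fp / n_called else 0
  precision <- 1 - efdr
  recall <- if (n_true > 0) cf$tp / n_true else 0
  curve <- pr_curve(calls$p_value, truth)
  out <- tibble::tibble(nominal_fdr = nominal_fdr, n_called = n_called,
                        n_true_snps = n_true, empirical_fdr = efdr,
                        power = recall, precision = precision,
                        f1 = f1_score(precision, recall),
                        f_max = attr(curve, "f_max"))
  if (all(c("ref", "alt") %in% names(calls))) {
    called <- !is.na(calls$q_value) & calls$q_value <= nominal_fdr
    if (any(called)) {
      out <- dplyr::bind_cols(out, titv_ratio(
        calls$ref[called], calls$alt[called],
        known = if (is.character(known)) known else known[called],
        locus_id = calls$locus_id[called]))
    }
  }
  out
}
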