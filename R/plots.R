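#' Diagnostic plot for a call set
#'
#' QQ plot of the positive eLRT statistics against the fitted scaled
#' chi-square component: under a well-calibrated null the points follow the
#' identity line. Called loci typically peel off into the upper tail.
#'
#' @param object a `snp_calls` object.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.snp_calls <- function(object, ...) {
  pos <- object$calls$statistic[!object$calls$is_zero &
                                  !is.na(object$calls$statistic)]
  pos <- sort(pos)
  n <- length(pos)
  theo <- object$null$k *
    stats::qchisq((seq_len(n) - 0.5) / n, df = 1)
  df <- tibble::tibble(theoretical = theo, observed = pos)
  ggplot2::ggplot(df, ggplot2::aes(.data$theoretical, .data$observed)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = expression("fitted" ~ k * chi[1]^2 ~ "quantiles"),
      y = "positive eLRT statistics",
      title = sprintf("Null calibration (a = %.3f, k = %.3f)",
                      object$null$a, object$null$k)) +
    ggplot2::theme_minimal()
}

#' Precision-recall plot
#'
#' @param object a `pr_curve` object.
#' @param ... ignored.
#' @return a ggplot with the Fmax point highlighted.
#' @export
autoplot.pr_curve <- function(object, ...) {
  best <- object[which.max(object$f1), ]
  ggplot2::ggplot(object, ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = best, colour = "red") +
    ggplot2::annotate("text", x = best$recall, y = best$precision,
                      label = sprintf("Fmax = %.3f", attr(object, "f_max")),
                      vjust = -1, size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data %||%
NULL
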