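#' Histogram of a simulated dose distribution
#'
#' @param object A `dose_sim`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dose_sim <- function(object, bins = 60, ...) {
  df <- tibble::tibble(dose = object$draws)
  med <- object$summaries[["median"]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            color = "white") +
    ggplot2::geom_vline(xintercept = med, linetype = "dashed") +
    ggplot2::labs(
      title = paste("Simulated dermal dose",
                    if (!is.na(object$metal)) object$metal else ""),
      x = "dose (mg/kg/day)", y = "draws",
      subtitle = sprintf("n_iter = %d, median = %.3g", object$n_iter, med)
    )
}

#' Hazard-quotient bar chart for a risk result
#'
#' @param result A `risk_result` from [characterize()].
#' @return A ggplot (log-scaled quotients against the threshold of 1).
#' @export
plot_hq <- function(result) {
  df <- dplyr::filter(result$table, .data$status == "assessed")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$metal,
                                                      -.data$hq),
                                   y = .data$hq)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = paste("Hazard quotients:", result$stratum),
                  x = NULL, y = "HQ (log scale)")
}

#' Hazard-index bar chart across strata
#'
#' @param strata A tibble from [stratified_risk()].
#' @return A ggplot.
#' @export
plot_hi <- function(strata) {
  df <- dplyr::filter(strata, !is.na(.data$hi))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$stratum,
                                                      -.data$hi),
                                   y = .data$hi)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "hazard index (log scale)")
}

#' Tornado plot of a sensitivity analysis
#'
#' @param object A `sensitivity_result`.
#' @param ... Unused.
#' @return A ggplot of rank correlations ordered by absolute value.
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$rho))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho,
                                   y = stats::reorder(.data$input,
                                                      abs(.data$rho)))) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metal)) +
    ggplot2::labs(x = "Spearman rank correlation with dose", y = NULL)
}
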