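#' Spearman rank correlation
#'
#' Pearson correlation of the two rank vectors, with average ranks for
#' ties. Constant input makes the correlation undefined; `NA` is returned
#' (reported downstream as not-applicable, never as zero).
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return Correlation in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations",
                          call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Rank-correlation sensitivity analysis of a dose simulation
#'
#' Correlates each Monte Carlo input with the simulated dose using
#' Spearman rank correlation, and orders inputs by absolute correlation
#' (the sign is reported separately — body weight influences the dose
#' negatively). Fixed inputs are not-applicable rather than zero. Because
#' averaging time is proportional to exposure duration, ED cancels out of
#' the dose equation; its correlation is reported faithfully (approx. 0)
#' with an explanatory note rather than suppressed.
#'
#' @param sim A `dose_sim` created with `retain_inputs = TRUE`.
#' @return Tibble of class `sensitivity_result`: `metal`, `input`, `rho`,
#'   `abs_rank` (`NA` for fixed inputs), `note`.
#' @export
sensitivity_analysis <- function(sim) {
  if (is.null(sim$inputs)) {
    stop("simulation was run without input retention; rerun ",
         "simulate_dose() with retain_inputs = TRUE", call. = FALSE)
  }
  inputs <- colnames(sim$inputs)
  too_few <- length(sim$draws) < 3
  rho <- vapply(inputs, function(nm) {
    if (too_few || !nm %in% sim$varying) return(NA_real_)
    spearman_rho(sim$inputs[, nm], sim$draws)
  }, numeric(1))
  note <- ifelse(inputs %in% sim$varying,
                 if (too_few) "fewer than 3 draws (not applicable)" else "",
                 "fixed input (not applicable)")
  note[!too_few & inputs == "ED" & inputs %in% sim$varying] <-
    "ED cancels out of the dose equation (AT = ED * 365); near-zero by design"
  out <- tibble::tibble(metal = sim$metal, input = inputs, rho = rho,
                        note = note)
  # rank varying inputs by |rho|, ties broken alphabetically and flagged
  v <- !is.na(out$rho)
  ord <- order(-abs(out$rho[v]), out$input[v])
  rank <- integer(sum(v))
  rank[ord] <- seq_along(ord)
  out$abs_rank <- NA_integer_
  out$abs_rank[v] <- rank
  tied <- v & duplicated(round(abs(out$rho), 12)) |
    v & duplicated(round(abs(out$rho), 12), fromLast = TRUE)
  out$note[tied & v] <- paste(out$note[tied & v],
                              "tied absolute correlation")
  out <- dplyr::arrange(out, is.na(.data$abs_rank), .data$abs_rank)
  class(out) <- c("sensitivity_result", class(out))
  out
}
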