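#' Tidy a fitted distribution
#'
#' @param x A `dist_fit` from [fit_mle()].
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` per parameter.
#' @export
tidy.dist_fit <- function(x, ...) {
  tibble::tibble(term = names(x$spec$params),
                 estimate = unname(x$spec$params))
}

#' @rdname tidy.dist_fit
#' @export
glance.dist_fit <- function(x, ...) {
  tibble::tibble(family = x$spec$family, logLik = x$loglik, nobs = x$n,
                 method = x$method)
}

#' Tidy a goodness-of-fit ranking
#'
#' @param x A `gof_ranking` from [select_best()].
#' @param ... Unused.
#' @return The ranking tibble without the list-column of fit objects.
#' @export
tidy.gof_ranking <- function(x, ...) {
  tibble::as_tibble(x[, setdiff(names(x), "fit")])
}

#' Tidy a dose simulation
#'
#' @param x A `dose_sim` from [simulate_dose()].
#' @param ... Unused.
#' @return Tibble of summary statistics in long form.
#' @export
tidy.dose_sim <- function(x, ...) {
  tibble::tibble(metal = x$metal, statistic = names(x$summaries),
                 value = unname(x$summaries))
}

#' @rdname tidy.dose_sim
#' @export
glance.dose_sim <- function(x, ...) {
  tibble::tibble(metal = x$metal, n_iter = x$n_iter, seed = x$seed,
                 mean = x$summaries[["mean"]],
                 median = x$summaries[["median"]],
                 rejected = sum(x$rejections))
}

#' Tidy a risk characterization
#'
#' @param x A `risk_result` from [characterize()].
#' @param ... Unused.
#' @return Per-metal tibble with stratum, dose, reference dose, hazard
#'   quotient and status.
#' @export
tidy.risk_result <- function(x, ...) {
  dplyr::mutate(x$table, stratum = x$stratum, .before = 1)
}

#' @rdname tidy.risk_result
#' @export
glance.risk_result <- function(x, ...) {
  tibble::tibble(stratum = x$stratum, hi = x$hi,
                 classification = x$classification,
                 rfd_basis = x$rfd_basis,
                 point_estimate = x$point_estimate,
                 n_assessed = sum(x$table$status == "assessed"),
                 n_excluded = length(x$excluded))
}
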