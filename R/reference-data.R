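ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "dermrisk")
  if (path == "") path <- file.path("inst", "extdata", name)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Packaged reference tables
#'
#' Summary statistics of the six assessed metals (Al, Ba, Cd, Cu, Fe, Pb)
#' in 32 retail hair-dye samples (8 brands x 4 colors), the per-brand and
#' per-color mean/SD breakdowns, the per-metal detection limits, and the
#' ingestion and dermal reference doses used for hazard characterization.
#' Concentrations are stored in the units of the source summaries (`unit`
#' column: ppm = mg/kg, ppb = ug/kg); `censored_cell` marks brand/color
#' cells where more than 20% of measurements fell below the detection
#' limit, so no mean/SD is available.
#'
#' @return A tibble.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
reference_pooled <- function() ref_csv("pooled_reference.csv")

#' @rdname reference_tables
#' @export
reference_brand_means <- function() ref_csv("brand_reference.csv")

#' @rdname reference_tables
#' @export
reference_color_means <- function() ref_csv("color_reference.csv")

#' @rdname reference_tables
#' @export
reference_lods <- function() {
  df <- ref_csv("lod_reference.csv")
  df$lod_mgkg <- to_mgkg(df$lod, df$unit)
  df
}

#' @rdname reference_tables
#' @export
reference_rfd <- function() {
  df <- reference_pooled()
  tibble::tibble(metal = df$metal, rfd_ing = df$rfd_ing,
                 rfd_derm = df$rfd_derm)
}

#' Pooled concentration point estimates in mg/kg
#'
#' Median (default) or mean pooled concentrations of the assessed metals,
#' converted to the canonical mg/kg.
#'
#' @param point `"median"` or `"mean"`.
#' @return Named numeric vector, one element per metal.
#' @export
reference_point_concentrations <- function(point = c("median", "mean")) {
  point <- match.arg(point)
  df <- reference_pooled()
  stats::setNames(to_mgkg(df[[point]], df$unit), df$metal)
}

# moment solvers for the non-lognormal reference families ----------------

weibull_from_moments <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  f <- function(k) gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1 - cv2
  k <- stats::uniroot(f, c(0.1, 50), tol = 1e-12)$root
  dist_spec("weibull", shape = k, scale = mean / gamma(1 + 1 / k))
}

# ln X ~ Gamma(shape, rate): E[X] = (rate/(rate-1))^shape (rate > 1),
# E[X^2] = (rate/(rate-2))^shape (rate > 2); needs mean > 1
loggamma_from_moments <- function(mean, sd) {
  if (mean <= 1) {
    stop("loggamma (no shift) cannot represent a mean <= 1", call. = FALSE)
  }
  m2 <- sd^2 + mean^2
  target <- log(m2) / log(mean)
  g <- function(b) log(b / (b - 2)) / log(b / (b - 1)) - target
  b <- stats::uniroot(g, c(2 + 1e-9, 1e6), tol = 1e-12)$root
  dist_spec("loggamma", shape = log(mean) / log(b / (b - 1)), rate = b,
            shift = 0)
}

pareto_from_mean <- function(mean, xmin) {
  stopifnot(mean > xmin, xmin > 0)
  dist_spec("pareto", xmin = xmin, alpha = mean / (mean - xmin))
}

# median exp(location); mean exp(location)/(1 - scale^2) for scale < 1
loglaplace_from_stats <- function(median, mean) {
  stopifnot(mean > median, median > 0)
  dist_spec("loglaplace", location = log(median),
            scale = sqrt(1 - median / mean))
}

#' Per-metal reference concentration distributions
#'
#' One specification per assessed metal, in the family reported for it in
#' the pooled reference table, with parameters matched to the reported
#' summary statistics: lognormals moment-matched to mean/SD (Al, Cu),
#' Weibull moment-matched to mean/SD (Cd), log-gamma moment-matched to
#' mean/SD (Ba, parameterized in ug/kg where its support applies), Pareto
#' with minimum at the reported range minimum and tail index matched to
#' the mean (Fe), and log-Laplace matched to the reported median and mean
#' (Pb). The `unit` column records each specification's scale.
#'
#' @return Tibble with `metal`, `family`, `unit`, and a `spec`
#'   list-column of [dist_spec()] objects.
#' @export
reference_distributions <- function() {
  df <- reference_pooled()
  spec <- purrr::pmap(
    list(df$metal, df$family, df$mean, df$sd, df$median, df$min, df$unit),
    function(metal, family, mean, sd, median, min, unit) {
      switch(family,
        lognormal = moment_matched_lognormal(mean, sd),
        weibull = weibull_from_moments(mean, sd),
        loggamma = {
          # work on the ug/kg scale so all mass sits above 1
          if (unit == "ppm") loggamma_from_moments(mean * 1000, sd * 1000)
          else loggamma_from_moments(mean, sd)
        },
        pareto = pareto_from_mean(mean, min),
        loglaplace = loglaplace_from_stats(median, mean)
      )
    }
  )
  unit <- ifelse(df$family == "loggamma", "ppb", df$unit)
  tibble::tibble(metal = df$metal, family = df$family, unit = unit,
                 spec = spec)
}
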