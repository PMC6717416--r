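#' Parametric distribution specifications
#'
#' A `dist_spec` names a parametric family together with its parameters and
#' carries the full density / cumulative / quantile / sampling contract used
#' throughout the dose simulation. The supported families are the five used
#' for concentration modelling — `lognormal`, `loggamma`, `weibull`,
#' `pareto`, `loglaplace` — plus the generic alternates `normal`, `gamma`
#' and `exponential`.
#'
#' Parameterizations:
#' \describe{
#'   \item{lognormal}{`meanlog`, `sdlog`: log of the variable is
#'     Normal(meanlog, sdlog).}
#'   \item{loggamma}{`shape`, `rate`, optional `shift` (default 0): log of
#'     the (shifted) variable is Gamma(shape, rate); support is
#'     `(shift + 1, Inf)` because the gamma variate is positive.}
#'   \item{weibull}{`shape`, `scale` as in [stats::dweibull()].}
#'   \item{pareto}{Type I with minimum `xmin > 0` and tail index `alpha > 0`.}
#'   \item{loglaplace}{`location`, `scale`: log of the variable is
#'     Laplace(location, scale), so the median is `exp(location)`.}
#'   \item{normal, gamma, exponential}{as in the corresponding `stats`
#'     functions (`gamma` uses shape and rate).}
#' }
#'
#' @param family Family name, one of the eight above.
#' @param ... Named numeric parameters for the family.
#' @return An object of class `dist_spec`: a list with elements `family` and
#'   `params`.
#' @examples
#' sp <- dist_spec("lognormal", meanlog = 0, sdlog = 1)
#' pdist(sp, 1) # 0.5: exp(standard normal) has median 1
#' @export
dist_spec <- function(family, ...) {
  family <- match.arg(family, dist_families())
  params <- c(...)
  if (length(params) && is.null(names(params))) {
    names(params) <- dist_param_names(family)[seq_along(params)]
  }
  if (family == "loggamma" && !"shift" %in% names(params)) {
    params <- c(params, shift = 0)
  }
  missing <- setdiff(dist_param_names(family), names(params))
  if (length(missing)) {
    stop("dist_spec('", family, "') is missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- params[dist_param_names(family)]
  check_dist_params(family, params)
  structure(list(family = family, params = params), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec> ", x$family, "(",
      paste(names(x$params), signif(x$params, 6), sep = " = ",
            collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

dist_families <- function() {
  c("lognormal", "loggamma", "weibull", "pareto", "loglaplace",
    "normal", "gamma", "exponential")
}

dist_param_names <- function(family) {
  switch(family,
    lognormal   = c("meanlog", "sdlog"),
    loggamma    = c("shape", "rate", "shift"),
    weibull     = c("shape", "scale"),
    pareto      = c("xmin", "alpha"),
    loglaplace  = c("location", "scale"),
    normal      = c("mean", "sd"),
    gamma       = c("shape", "rate"),
    exponential = "rate"
  )
}

check_dist_params <- function(family, p) {
  bad <- function(msg) stop("invalid parameters for ", family, ": ", msg,
                            call. = FALSE)
  if (any(!is.finite(p))) bad("all parameters must be finite")
  switch(family,
    lognormal   = if (p[["sdlog"]] < 0) bad("sdlog must be >= 0"),
    loggamma    = if (p[["shape"]] <= 0 || p[["rate"]] <= 0)
                    bad("shape and rate must be > 0"),
    weibull     = if (p[["shape"]] <= 0 || p[["scale"]] <= 0)
                    bad("shape and scale must be > 0"),
    pareto      = if (p[["xmin"]] <= 0 || p[["alpha"]] <= 0)
                    bad("xmin and alpha must be > 0"),
    loglaplace  = if (p[["scale"]] <= 0) bad("scale must be > 0"),
    normal      = if (p[["sd"]] < 0) bad("sd must be >= 0"),
    gamma       = if (p[["shape"]] <= 0 || p[["rate"]] <= 0)
                    bad("shape and rate must be > 0"),
    exponential = if (p[["rate"]] <= 0) bad("rate must be > 0")
  )
  invisible(p)
}

#' Support interval of a distribution specification
#'
#' @param spec A [dist_spec()].
#' @return Numeric length-2 vector `c(lower, upper)` (open at finite ends).
#' @export
dist_support <- function(spec) {
  p <- spec$params
  switch(spec$family,
    lognormal   = c(0, Inf),
    loggamma    = c(p[["shift"]] + 1, Inf),
    weibull     = c(0, Inf),
    pareto      = c(p[["xmin"]], Inf),
    loglaplace  = c(0, Inf),
    normal      = c(-Inf, Inf),
    gamma       = c(0, Inf),
    exponential = c(0, Inf)
  )
}

# Laplace helpers (log scale of the loglaplace family)
dlaplace <- function(x, location, scale) {
  exp(-abs(x - location) / scale) / (2 * scale)
}
plaplace <- function(q, location, scale) {
  z <- (q - location) / scale
  ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
}
qlaplace <- function(p, location, scale) {
  ifelse(p < 0.5,
         location + scale * log(2 * p),
         location - scale * log(2 * (1 - p)))
}

#' Density of a distribution specification
#'
#' Points outside the support have density 0.
#'
#' @param spec A [dist_spec()].
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of densities.
#' @export
ddist <- function(spec, x) {
  p <- spec$params
  out <- switch(spec$family,
    lognormal   = stats::dlnorm(x, p[["meanlog"]], p[["sdlog"]]),
    loggamma    = {
      y <- x - p[["shift"]]
      ifelse(y > 1, stats::dgamma(log(pmax(y, 1)), p[["shape"]],
                                  rate = p[["rate"]]) / y, 0)
    },
    weibull     = stats::dweibull(x, p[["shape"]], p[["scale"]]),
    pareto      = ifelse(x >= p[["xmin"]],
                         p[["alpha"]] * p[["xmin"]]^p[["alpha"]] /
                           x^(p[["alpha"]] + 1), 0),
    loglaplace  = ifelse(x > 0,
                         dlaplace(log(pmax(x, .Machine$double.xmin)),
                                  p[["location"]], p[["scale"]]) / x, 0),
    normal      = stats::dnorm(x, p[["mean"]], p[["sd"]]),
    gamma       = stats::dgamma(x, p[["shape"]], rate = p[["rate"]]),
    exponential = stats::dexp(x, p[["rate"]])
  )
  ifelse(is.finite(out), out, 0)
}

#' Cumulative distribution of a specification
#'
#' @inheritParams ddist
#' @param q Numeric vector of quantile points.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
pdist <- function(spec, q) {
  p <- spec$params
  switch(spec$family,
    lognormal   = stats::plnorm(q, p[["meanlog"]], p[["sdlog"]]),
    loggamma    = {
      y <- q - p[["shift"]]
      ifelse(y > 1, stats::pgamma(log(pmax(y, 1)), p[["shape"]],
                                  rate = p[["rate"]]), 0)
    },
    weibull     = stats::pweibull(q, p[["shape"]], p[["scale"]]),
    pareto      = ifelse(q >= p[["xmin"]],
                         1 - (p[["xmin"]] / q)^p[["alpha"]], 0),
    loglaplace  = ifelse(q > 0, plaplace(log(pmax(q, .Machine$double.xmin)),
                                         p[["location"]], p[["scale"]]), 0),
    normal      = stats::pnorm(q, p[["mean"]], p[["sd"]]),
    gamma       = stats::pgamma(q, p[["shape"]], rate = p[["rate"]]),
    exponential = stats::pexp(q, p[["rate"]])
  )
}

#' Quantile function of a specification
#'
#' @inheritParams ddist
#' @param prob Numeric vector of probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles.
#' @export
qdist <- function(spec, prob) {
  stopifnot(all(prob >= 0 & prob <= 1))
  p <- spec$params
  switch(spec$family,
    lognormal   = stats::qlnorm(prob, p[["meanlog"]], p[["sdlog"]]),
    loggamma    = p[["shift"]] +
      exp(stats::qgamma(prob, p[["shape"]], rate = p[["rate"]])),
    weibull     = stats::qweibull(prob, p[["shape"]], p[["scale"]]),
    pareto      = p[["xmin"]] / (1 - prob)^(1 / p[["alpha"]]),
    loglaplace  = exp(qlaplace(prob, p[["location"]], p[["scale"]])),
    normal      = stats::qnorm(prob, p[["mean"]], p[["sd"]]),
    gamma       = stats::qgamma(prob, p[["shape"]], rate = p[["rate"]]),
    exponential = stats::qexp(prob, p[["rate"]])
  )
}

#' Draw random samples from a specification
#'
#' Reproducible for a fixed `seed`; pass `seed = NULL` to use the current
#' RNG state (the Monte Carlo engine manages its own per-factor streams
#' that way).
#'
#' @inheritParams ddist
#' @param n Number of draws, `>= 1`.
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @return Numeric vector of `n` draws, all within the support.
#' @export
rdist <- function(spec, n, seed = NULL) {
  stopifnot(n >= 1)
  check_dist_params(spec$family, spec$params)
  if (!is.null(seed)) set.seed(seed)
  p <- spec$params
  switch(spec$family,
    lognormal   = stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
    loggamma    = p[["shift"]] +
      exp(stats::rgamma(n, p[["shape"]], rate = p[["rate"]])),
    weibull     = stats::rweibull(n, p[["shape"]], p[["scale"]]),
    pareto      = p[["xmin"]] / (1 - stats::runif(n))^(1 / p[["alpha"]]),
    loglaplace  = exp(qlaplace(stats::runif(n), p[["location"]],
                               p[["scale"]])),
    normal      = stats::rnorm(n, p[["mean"]], p[["sd"]]),
    gamma       = stats::rgamma(n, p[["shape"]], rate = p[["rate"]]),
    exponential = stats::rexp(n, p[["rate"]])
  )
}

#' Analytic mean and standard deviation of a specification
#'
#' Used by the synthetic-data generator and by moment-based initial values
#' for the optimizing fits. Families with non-finite moments (e.g. Pareto
#' with `alpha <= 2`) return `Inf` components.
#'
#' @inheritParams ddist
#' @return Named numeric vector `c(mean, sd)`.
#' @export
dist_moments <- function(spec) {
  p <- spec$params
  m <- switch(spec$family,
    lognormal = {
      mu <- exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2)
      c(mu, mu * sqrt(exp(p[["sdlog"]]^2) - 1))
    },
    loggamma = {
      # E[exp(kG)] = (rate/(rate-k))^shape for rate > k
      mgf <- function(k) if (p[["rate"]] > k)
        (p[["rate"]] / (p[["rate"]] - k))^p[["shape"]] else Inf
      mu <- mgf(1)
      c(p[["shift"]] + mu, sqrt(max(mgf(2) - mu^2, 0)))
    },
    weibull = {
      mu <- p[["scale"]] * gamma(1 + 1 / p[["shape"]])
      c(mu, sqrt(p[["scale"]]^2 * gamma(1 + 2 / p[["shape"]]) - mu^2))
    },
    pareto = {
      a <- p[["alpha"]]
      mu <- if (a > 1) a * p[["xmin"]] / (a - 1) else Inf
      v <- if (a > 2) p[["xmin"]]^2 * a / ((a - 1)^2 * (a - 2)) else Inf
      c(mu, sqrt(v))
    },
    loglaplace = {
      b <- p[["scale"]]
      mu <- if (b < 1) exp(p[["location"]]) / (1 - b^2) else Inf
      e2 <- if (b < 0.5) exp(2 * p[["location"]]) / (1 - 4 * b^2) else Inf
      c(mu, sqrt(max(e2 - mu^2, 0)))
    },
    normal = c(p[["mean"]], p[["sd"]]),
    gamma = c(p[["shape"]] / p[["rate"]], sqrt(p[["shape"]]) / p[["rate"]]),
    exponential = c(1 / p[["rate"]], 1 / p[["rate"]])
  )
  stats::setNames(m, c("mean", "sd"))
}

#' Maximum-likelihood fit of one family
#'
#' Closed-form estimators are used where they exist (lognormal, normal,
#' exponential, Pareto with `xmin` fixed at the sample minimum, log-Laplace
#' via the Laplace MLE on logs); gamma, Weibull and log-gamma maximize the
#' log-likelihood numerically from moment-based starting values.
#'
#' @param x Numeric sample, length `>= 3`, inside the family's support
#'   (positive for the log families; `> 1` for log-gamma).
#' @param family Family name as in [dist_spec()].
#' @return An object of class `dist_fit`: list with `spec` ([dist_spec()]),
#'   `loglik`, `n`, and `method` ("closed-form" or "optim").
#' @examples
#' set.seed(1)
#' fit_mle(rlnorm(200, 0.5, 0.8), "lognormal")
#' @export
fit_mle <- function(x, family) {
  family <- match.arg(family, dist_families())
  x <- as.numeric(x)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x)) stop("sample contains missing values", call. = FALSE)
  logfam <- family %in% c("lognormal", "loggamma", "weibull", "pareto",
                          "loglaplace", "gamma", "exponential")
  if (logfam && any(x <= 0)) {
    stop("support error: family '", family,
         "' requires strictly positive observations", call. = FALSE)
  }
  if (family == "loggamma" && any(x <= 1)) {
    stop("support error: family 'loggamma' (no shift) requires ",
         "observations > 1", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate sample (all values equal): cannot fit a scale family",
         call. = FALSE)
  }
  n <- length(x)
  method <- "closed-form"
  spec <- switch(family,
    lognormal = {
      lx <- log(x)
      dist_spec("lognormal", meanlog = mean(lx),
                sdlog = sqrt(mean((lx - mean(lx))^2)))
    },
    normal = dist_spec("normal", mean = mean(x),
                       sd = sqrt(mean((x - mean(x))^2))),
    exponential = dist_spec("exponential", rate = 1 / mean(x)),
    pareto = {
      xmin <- min(x)
      dist_spec("pareto", xmin = xmin, alpha = n / sum(log(x / xmin)))
    },
    loglaplace = {
      lx <- log(x)
      m <- stats::median(lx)
      dist_spec("loglaplace", location = m, scale = mean(abs(lx - m)))
    },
    gamma = {
      method <- "optim"
      fit_gamma_optim(x)
    },
    loggamma = {
      method <- "optim"
      g <- fit_gamma_optim(log(x))
      dist_spec("loggamma", shape = g$params[["shape"]],
                rate = g$params[["rate"]], shift = 0)
    },
    weibull = {
      method <- "optim"
      fit_weibull_optim(x)
    }
  )
  structure(
    list(spec = spec, loglik = sum(log(pmax(ddist(spec, x), 1e-300))),
         n = n, method = method),
    class = "dist_fit"
  )
}

# Gamma MLE by maximizing the profile over log(shape), log(rate).
fit_gamma_optim <- function(x) {
  m <- mean(x); v <- stats::var(x)
  start <- c(log(max(m^2 / v, 1e-3)), log(max(m / v, 1e-3)))
  nll <- function(par) {
    -sum(stats::dgamma(x, exp(par[1]), rate = exp(par[2]), log = TRUE))
  }
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  dist_spec("gamma", shape = exp(opt$par[1]), rate = exp(opt$par[2]))
}

fit_weibull_optim <- function(x) {
  # shape start from the coefficient of variation, scale from the mean
  cv <- stats::sd(x) / mean(x)
  start <- c(log(max(cv^(-1.086), 1e-3)), log(mean(x)))
  nll <- function(par) {
    -sum(stats::dweibull(x, exp(par[1]), exp(par[2]), log = TRUE))
  }
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  dist_spec("weibull", shape = exp(opt$par[1]), scale = exp(opt$par[2]))
}

#' @export
print.dist_fit <- function(x, ...) {
  cat("<dist_fit> n =", x$n, " logLik =", signif(x$loglik, 6),
      " (", x$method, ")\n", sep = "")
  print(x$spec)
  invisible(x)
}

#' Goodness-of-fit statistics for a fitted specification
#'
#' Kolmogorov–Smirnov and Anderson–Darling statistics against the fitted
#' cumulative distribution, and a chi-square statistic on
#' `ceiling(1 + log2(n))` equal-probability bins under the fitted cdf.
#'
#' @param spec A [dist_spec()].
#' @param x Numeric sample.
#' @return Named list with `ks_stat`, `ad_stat`, `chi2_stat`, `chi2_bins`.
#' @export
gof_stats <- function(spec, x) {
  n <- length(x)
  u <- sort(pdist(spec, sort(x)))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  ks <- max(i / n - u, u - (i - 1) / n)
  ad <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  k <- ceiling(1 + log2(n))
  brk <- qdist(spec, seq(0, 1, length.out = k + 1))
  brk[1] <- -Inf; brk[k + 1] <- Inf
  obs <- as.vector(table(cut(x, brk)))
  expd <- n / k
  chi2 <- sum((obs - expd)^2 / expd)
  list(ks_stat = ks, ad_stat = ad, chi2_stat = chi2, chi2_bins = k)
}

#' Fit candidate families and rank them by goodness of fit
#'
#' Each candidate is fitted by [fit_mle()]; candidates that cannot be
#' fitted (support violations, degenerate samples) are retained in the
#' result with their failure message rather than dropped. Successful fits
#' are ranked by the Kolmogorov–Smirnov statistic (ascending), ties broken
#' by Anderson–Darling then chi-square.
#'
#' @param x Numeric sample of positive concentrations.
#' @param candidates Character vector of family names; the default is the
#'   five families used for the packaged concentration models.
#' @return A tibble of class `gof_ranking` with one row per candidate:
#'   `family`, `ks_stat`, `ad_stat`, `chi2_stat`, `chi2_bins`, `loglik`,
#'   `rank` (`NA` for failures), `error` (`NA` for successes) and a
#'   list-column `fit` of `dist_fit` objects.
#' @examples
#' set.seed(42)
#' select_best(rweibull(300, 2, 1))
#' @export
select_best <- function(x,
                        candidates = c("lognormal", "loggamma", "weibull",
                                       "pareto", "loglaplace")) {
  if (!length(candidates)) stop("no candidate families supplied",
                                call. = FALSE)
  rows <- purrr::map(candidates, function(fam) {
    fit <- tryCatch(fit_mle(x, fam), error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(family = fam, ks_stat = NA_real_, ad_stat = NA_real_,
                     chi2_stat = NA_real_, chi2_bins = NA_integer_,
                     loglik = NA_real_, error = conditionMessage(fit),
                     fit = list(NULL))
    } else {
      g <- gof_stats(fit$spec, x)
      tibble::tibble(family = fam, ks_stat = g$ks_stat, ad_stat = g$ad_stat,
                     chi2_stat = g$chi2_stat, chi2_bins = g$chi2_bins,
                     loglik = fit$loglik, error = NA_character_,
                     fit = list(fit))
    }
  })
  out <- dplyr::bind_rows(rows)
  if (all(!is.na(out$error))) {
    stop("all candidate families failed to fit:\n",
         paste0("  ", out$family, ": ", out$error, collapse = "\n"),
         call. = FALSE)
  }
  out <- dplyr::arrange(out, is.na(.data$ks_stat), .data$ks_stat,
                        .data$ad_stat, .data$chi2_stat)
  out$rank <- ifelse(is.na(out$error), cumsum(is.na(out$error)), NA_integer_)
  class(out) <- c("gof_ranking", class(out))
  out
}

#' Best fitted specification from a ranking
#'
#' @param ranking A `gof_ranking` from [select_best()].
#' @return The rank-1 `dist_fit`.
#' @export
best_fit <- function(ranking) {
  ranking$fit[[which(ranking$rank == 1)]]
}
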