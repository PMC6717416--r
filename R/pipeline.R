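#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one place with
#' explicit defaults, so no constants hide in code. Either a synthetic
#' `design` (default) or a `concentration_path` CSV provides the
#' measurements.
#'
#' @param seed Integer seed governing generation and simulation.
#' @param n_iter Monte Carlo iterations (default 20000; `n_iter = 2000` is
#'   the light preset).
#' @param exclusion_fraction Censored-fraction threshold for dropping a
#'   metal (default 0.20).
#' @param substitution Censored-value substitution rule (default
#'   `"half-lod"`).
#' @param point_estimate `"median"` (default) or `"mean"`.
#' @param rfd_basis `"dermal"` (default) or `"ingestion"`.
#' @param factors [exposure_factors()]; default
#'   [default_exposure_factors()] (stochastic EF, ED, BW).
#' @param candidates Distribution families ranked for each metal.
#' @param design [default_study_design()] used when no CSV is given.
#' @param concentration_path Optional concentration CSV path.
#' @param unit_map Optional unit map for [read_concentration_table()].
#' @param rfd_table Reference doses; default the packaged table.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_iter = 20000,
                            exclusion_fraction = 0.20,
                            substitution = "half-lod",
                            point_estimate = "median",
                            rfd_basis = "dermal",
                            factors = default_exposure_factors(),
                            candidates = c("lognormal", "loggamma",
                                           "weibull", "pareto",
                                           "loglaplace"),
                            design = default_study_design(),
                            concentration_path = NULL,
                            unit_map = NULL,
                            rfd_table = reference_rfd()) {
  structure(
    list(seed = as.integer(seed), n_iter = as.integer(n_iter),
         exclusion_fraction = exclusion_fraction,
         substitution = substitution, point_estimate = point_estimate,
         rfd_basis = rfd_basis, factors = factors,
         candidates = candidates, design = design,
         concentration_path = concentration_path, unit_map = unit_map,
         rfd_table = rfd_table),
    class = "pipeline_config"
  )
}

factor_echo <- function(factors) {
  purrr::map(unclass(factors), function(v) {
    if (inherits(v, "dist_spec")) {
      list(family = v$family, params = as.list(v$params))
    } else {
      v
    }
  })
}

#' Run the full risk-assessment pipeline
#'
#' Stages, in order: ingest (synthetic generation or CSV), censoring
#' policy, concentration summaries, per-metal distribution fitting and
#' selection, Monte Carlo dose simulation (inputs retained), pooled and
#' stratified risk characterization, and rank-correlation sensitivity
#' analysis. A failure stops the run with a stage-named error. With
#' `out_dir`, every result table is written as CSV together with a JSON
#' run manifest (config echo, seeds, decisions, per-stage timings).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Object of class `dermrisk_run`: list with `data`,
#'   `lod_decisions`, `summaries` (pooled/brand/color), `fits`
#'   (per-metal `gof_ranking`s), `doses` (per-metal `dose_sim`s),
#'   `risk_pooled`, `risk_brand`, `risk_color`, `sensitivity`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_iter < 2) {
    warning("n_iter < 2: dose summaries are degenerate", call. = FALSE)
  }
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  tab <- stage("ingest", {
    if (!is.null(config$concentration_path)) {
      read_concentration_table(config$concentration_path,
                               unit_map = config$unit_map,
                               rfd = config$rfd_table)
    } else {
      generate_concentrations(config$design, seed = config$seed,
                              rfd = config$rfd_table)
    }
  })

  lod <- stage("lod_policy", {
    apply_lod_policy(tab, exclusion_fraction = config$exclusion_fraction,
                     substitution = config$substitution)
  })
  excluded <- lod$decisions$metal[lod$decisions$action == "excluded"]
  assessed <- sort(unique(lod$data$metal[lod$data$known_metal &
                                           !is.na(lod$data$concentration)]))
  assessed <- intersect(assessed, config$rfd_table$metal)
  not_assessed <- setdiff(unique(lod$data$metal), assessed)

  summaries <- stage("summarize", {
    list(pooled = summarize_concentrations(lod$data, "pooled"),
         brand = summarize_concentrations(lod$data, "brand"),
         color = summarize_concentrations(lod$data, "color"))
  })

  fits <- stage("fit", {
    out <- purrr::map(assessed, function(m) {
      x <- lod$data$concentration[lod$data$metal == m &
                                    !is.na(lod$data$concentration)]
      select_best(x, candidates = config$candidates)
    })
    stats::setNames(out, assessed)
  })

  doses <- stage("simulate", {
    out <- purrr::map(assessed, function(m) {
      simulate_dose(best_fit(fits[[m]])$spec, config$factors,
                    n_iter = config$n_iter, seed = config$seed,
                    metal = m, retain_inputs = TRUE)
    })
    stats::setNames(out, assessed)
  })

  risk_pooled <- stage("risk", {
    point <- vapply(doses, summarize_dose, numeric(1),
                    point_estimate = config$point_estimate)
    characterize(point, config$rfd_table, stratum = "pooled",
                 rfd_basis = config$rfd_basis,
                 point_estimate = config$point_estimate,
                 excluded = excluded)
  })
  risk_brand <- stage("risk_brand", {
    stratified_risk(lod$data, "brand", config$rfd_table,
                    factors = config$factors, n_iter = config$n_iter,
                    seed = config$seed,
                    point_estimate = config$point_estimate,
                    rfd_basis = config$rfd_basis, excluded = excluded,
                    strata = unique(tab$brand))
  })
  risk_color <- stage("risk_color", {
    stratified_risk(lod$data, "color", config$rfd_table,
                    factors = config$factors, n_iter = config$n_iter,
                    seed = config$seed,
                    point_estimate = config$point_estimate,
                    rfd_basis = config$rfd_basis, excluded = excluded,
                    strata = unique(tab$color))
  })

  sens <- stage("sensitivity", {
    dplyr::bind_rows(purrr::map(doses, sensitivity_analysis))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("dermrisk")),
    seed = config$seed,
    n_iter = config$n_iter,
    config = list(
      exclusion_fraction = config$exclusion_fraction,
      substitution = config$substitution,
      point_estimate = config$point_estimate,
      rfd_basis = config$rfd_basis,
      candidates = config$candidates,
      factors = factor_echo(config$factors),
      source = if (is.null(config$concentration_path)) "synthetic design"
               else config$concentration_path
    ),
    decisions = list(
      excluded_metals = excluded,
      not_assessed = not_assessed,
      fit_winners = purrr::map_chr(fits, function(f)
        f$family[which(f$rank == 1)]),
      rejection_counts = purrr::map(doses, function(d)
        as.list(d$rejections))
    ),
    timings_sec = timings
  )

  run <- structure(
    list(data = lod$data, lod_decisions = lod$decisions,
         summaries = summaries, fits = fits, doses = doses,
         risk_pooled = risk_pooled, risk_brand = risk_brand,
         risk_color = risk_color, sensitivity = sens,
         manifest = manifest),
    class = "dermrisk_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

risk_rows <- function(res) {
  if (is.null(res)) return(tibble::tibble())
  dplyr::mutate(res$table, stratum = res$stratum, hi = res$hi,
                classification = res$classification,
                rfd_basis = res$rfd_basis,
                point_estimate = res$point_estimate,
                .before = 1)
}

stratified_rows <- function(strat) {
  dplyr::bind_rows(purrr::map(strat$result, risk_rows))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, name), progress = FALSE)
  }
  w(run$summaries$pooled, "summary_pooled.csv")
  w(run$summaries$brand, "summary_brand.csv")
  w(run$summaries$color, "summary_color.csv")
  w(run$lod_decisions, "lod_decisions.csv")
  fits <- dplyr::bind_rows(purrr::imap(run$fits, function(f, m) {
    dplyr::mutate(dplyr::select(f, -"fit"), metal = m, .before = 1)
  }))
  w(fits, "fits.csv")
  doses <- dplyr::bind_rows(purrr::imap(run$doses, function(d, m) {
    tibble::tibble(metal = m, !!!as.list(d$summaries))
  }))
  w(doses, "doses.csv")
  w(risk_rows(run$risk_pooled), "risk_pooled.csv")
  w(stratified_rows(run$risk_brand), "risk_brand.csv")
  w(stratified_rows(run$risk_color), "risk_color.csv")
  w(run$sensitivity, "sensitivity.csv")
  jsonlite::write_json(run$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.dermrisk_run <- function(x, ...) {
  cat("<dermrisk_run> seed =", x$manifest$seed, " n_iter =",
      x$manifest$n_iter, "\n")
  cat("assessed metals:", paste(names(x$doses), collapse = ", "), "\n")
  if (length(x$manifest$decisions$excluded_metals)) {
    cat("excluded by censoring policy:",
        paste(x$manifest$decisions$excluded_metals, collapse = ", "), "\n")
  }
  cat("pooled HI =", signif(x$risk_pooled$hi, 4), "(",
      x$risk_pooled$classification, ")\n")
  invisible(x)
}
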