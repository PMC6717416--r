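#' Lognormal specification matched to a mean and SD
#'
#' Returns the lognormal whose analytic mean and standard deviation equal
#' the inputs: `sdlog^2 = log(1 + sd^2/mean^2)`,
#' `meanlog = log(mean) - sdlog^2/2`. `sd = 0` gives the degenerate point
#' mass at `mean` (`sdlog = 0`). This is how reported mean±SD summary
#' cells are turned into generating distributions: concentrations are
#' positive and right-skewed, which the lognormal respects.
#'
#' @param mean Positive mean.
#' @param sd Nonnegative standard deviation.
#' @return A lognormal [dist_spec()].
#' @export
moment_matched_lognormal <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive",
                                          call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("sd must be nonnegative",
                                     call. = FALSE)
  s2 <- log(1 + sd^2 / mean^2)
  dist_spec("lognormal", meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Synthetic study design
#'
#' The default design mirrors the sampled market survey: 8 brands (with
#' country annotations) x 4 colors x 1 replicate = 32 samples per metal.
#' Cell generators for the six assessed metals are lognormals
#' moment-matched to the per-brand mean/SD reference cells (each brand's
#' four colors share its distribution; the per-brand table determines the
#' colors only marginally). Brand cells flagged as heavily censored in the
#' reference (`censored_cell`) are generated from a lognormal with mean
#' and SD equal to the metal's detection limit, so most of their draws
#' fall below it. The four metals excluded from assessment in the source
#' study (Ag, Co, Cr, Mn) are generated with 25% sub-LOD probability
#' (lognormal, sdlog 1, meanlog placed so P(X < LOD) = 0.25), so the
#' censoring policy's exclusion branch is exercised end-to-end.
#'
#' @param stratum_type `"brand"` (default) or `"color"` — which reference
#'   breakdown parameterizes the cells.
#' @param replicates Samples per (brand, color) cell; default 1.
#' @param sub_lod_prob Sub-LOD probability for the four excluded metals.
#' @return Object of class `study_design`: list with `brands` (tibble:
#'   brand, country), `colors`, `replicates`, `cells` (tibble: stratum,
#'   metal, spec list-column, lod), `stratum_type`.
#' @export
default_study_design <- function(stratum_type = c("brand", "color"),
                                 replicates = 1, sub_lod_prob = 0.25) {
  stratum_type <- match.arg(stratum_type)
  stopifnot(replicates >= 1, sub_lod_prob >= 0, sub_lod_prob < 1)
  brands <- tibble::tibble(
    brand = paste0("brand", 1:8),
    country = c("Italy", "Iran", "Spain", "Iran", "Spain", "Iran", "Italy",
                "Germany")
  )
  colors <- c("black", "blonde", "light-brown", "dark-brown")
  lods <- reference_lods()
  lod_of <- stats::setNames(lods$lod_mgkg, lods$metal)
  ref <- if (stratum_type == "brand") reference_brand_means()
         else reference_color_means()
  ref$stratum <- if (stratum_type == "brand") ref$brand else ref$color
  cells <- purrr::pmap(
    list(ref$stratum, ref$metal, ref$mean, ref$sd, ref$unit,
         ref$censored_cell),
    function(stratum, metal, mean, sd, unit, censored_cell) {
      lod <- lod_of[[metal]]
      spec <- if (censored_cell) {
        moment_matched_lognormal(lod, lod)
      } else {
        if (!is.finite(mean) || mean <= 0 || !is.finite(sd) || sd < 0) {
          stop("design error: invalid mean/sd for ", metal, " in ",
               stratum, call. = FALSE)
        }
        moment_matched_lognormal(to_mgkg(mean, unit), to_mgkg(sd, unit))
      }
      tibble::tibble(stratum = stratum, metal = metal, spec = list(spec),
                     lod = lod)
    }
  ) |> dplyr::bind_rows()
  # metals dropped from assessment in the source study: generated with
  # sub-LOD mass so the exclusion branch of the censoring policy runs
  strata <- unique(cells$stratum)
  extra <- tidyr::expand_grid(stratum = strata,
                              metal = c("Ag", "Co", "Cr", "Mn"))
  extra <- dplyr::mutate(extra,
    lod = unname(lod_of[.data$metal]),
    spec = purrr::map(.data$lod, function(l) {
      dist_spec("lognormal",
                meanlog = log(l) - stats::qnorm(sub_lod_prob), sdlog = 1)
    })
  )
  structure(
    list(brands = brands, colors = colors,
         replicates = as.integer(replicates),
         cells = dplyr::bind_rows(cells, extra)[, c("stratum", "metal",
                                                    "spec", "lod")],
         stratum_type = stratum_type),
    class = "study_design"
  )
}

#' Generate a synthetic concentration table
#'
#' One measurement per (brand, color, metal, replicate), drawn from the
#' design's cell distribution; draws below the metal's detection limit are
#' stored as censored with the LOD and no numeric concentration.
#' Deterministic for a fixed seed.
#'
#' @param design A [default_study_design()] (or compatible) object.
#' @param seed Integer seed.
#' @param rfd Optional reference-dose table for unknown-metal flagging
#'   (defaults to the packaged doses).
#' @return A `conc_tbl` tibble.
#' @export
generate_concentrations <- function(design, seed = 1,
                                    rfd = reference_rfd()) {
  set.seed(seed)
  metals <- sort(unique(design$cells$metal))
  rows <- list()
  for (m in metals) {
    for (b in design$brands$brand) {
      for (col in design$colors) {
        stratum <- if (design$stratum_type == "brand") b else col
        cell <- design$cells[design$cells$stratum == stratum &
                               design$cells$metal == m, ]
        if (!nrow(cell)) {
          stop("design error: no cell for ", m, " in ", stratum,
               call. = FALSE)
        }
        vals <- rdist(cell$spec[[1]], design$replicates)
        lod <- cell$lod[[1]]
        cens <- vals < lod
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = paste(b, col, seq_len(design$replicates), sep = "-"),
          brand = b,
          country = design$brands$country[design$brands$brand == b],
          color = col,
          metal = m,
          concentration = ifelse(cens, NA_real_, vals),
          below_lod = cens,
          lod = lod
        )
      }
    }
  }
  as_concentration_table(dplyr::bind_rows(rows), rfd = rfd)
}

#' Default survey generators
#'
#' Field generators for the synthetic questionnaire population: 92.19%
#' use hair dye, 49.5% use chemical dye; color preference weights 33.6%
#' blonde, 27.4% light brown, 19.6% dark brown, 14% black (remainder
#' "other"); brand preference weights from the reported market shares
#' (remainder "other"); starting age, annual application frequency and
#' body weight as moment-matched lognormals (means 19 y, 12 /y, 60 kg; SDs
#' 5, 4, 8).
#'
#' @return Named list of generators understood by [generate_survey()].
#' @export
survey_generators <- function() {
  list(
    uses_dye = 0.9219,
    uses_chemical_dye = 0.495,
    age_start = moment_matched_lognormal(19, 5),
    frequency_per_year = moment_matched_lognormal(12, 4),
    body_weight_kg = moment_matched_lognormal(60, 8),
    color_weights = c(blonde = 0.336, `light-brown` = 0.274,
                      `dark-brown` = 0.196, black = 0.14),
    brand_weights = stats::setNames(
      c(0.197, 0.136, 0.083, 0.068, 0.068, 0.053, 0.053, 0.053),
      paste0("brand", 1:8))
  )
}

#' Generate a synthetic survey population
#'
#' @param n Number of respondents, `>= 1`.
#' @param generators Per-field generators; see [survey_generators()].
#'   Categorical weights must be nonnegative and sum to at most 1 (the
#'   remainder becomes "other").
#' @param seed Integer seed.
#' @return Tibble of respondent records matching the survey schema.
#' @export
generate_survey <- function(n, generators = survey_generators(), seed = 1) {
  stopifnot(n >= 1)
  for (w in generators[c("color_weights", "brand_weights")]) {
    if (any(w < 0) || sum(w) > 1 + 1e-12) {
      stop("design error: categorical weights must be nonnegative and sum ",
           "to <= 1", call. = FALSE)
    }
  }
  set.seed(seed)
  pick <- function(weights) {
    lev <- c(names(weights), "other")
    p <- c(unname(weights), max(1 - sum(weights), 0))
    sample(lev, n, replace = TRUE, prob = p)
  }
  tibble::tibble(
    respondent_id = sprintf("R%04d", seq_len(n)),
    uses_dye = stats::runif(n) < generators$uses_dye,
    uses_chemical_dye = stats::runif(n) < generators$uses_chemical_dye,
    age_start = rdist(generators$age_start, n),
    frequency_per_year = rdist(generators$frequency_per_year, n),
    body_weight_kg = rdist(generators$body_weight_kg, n),
    color_pref = pick(generators$color_weights),
    brand_pref = pick(generators$brand_weights)
  )
}
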