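#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# canonical internal unit is mg/kg (ppm); ppb (ug/kg) inputs divide by 1000
.unit_factors <- c(ppm = 1, ppb = 1e-3, `mg/kg` = 1, `ug/kg` = 1e-3)

#' Convert concentrations between mass-fraction units
#'
#' The package's canonical internal unit is mg/kg (ppm). `to_mgkg()`
#' converts ppm/ppb input to mg/kg; `from_mgkg()` converts back.
#'
#' @param value Numeric vector.
#' @param unit `"ppm"`, `"ppb"`, `"mg/kg"` or `"ug/kg"`.
#' @return Numeric vector in the requested unit.
#' @export
to_mgkg <- function(value, unit) {
  f <- .unit_factors[unit]
  if (anyNA(f)) {
    stop("unknown unit(s): ", paste(unique(unit[is.na(f)]), collapse = ", "),
         call. = FALSE)
  }
  value * unname(f)
}

#' @rdname to_mgkg
#' @export
from_mgkg <- function(value, unit) {
  f <- .unit_factors[unit]
  if (anyNA(f)) {
    stop("unknown unit(s): ", paste(unique(unit[is.na(f)]), collapse = ", "),
         call. = FALSE)
  }
  value / unname(f)
}

conc_required_cols <- c("sample_id", "brand", "color", "metal",
                        "concentration", "below_lod", "lod")

#' Validate a concentration table
#'
#' Checks the invariants of the per-sample measurement table: positive
#' concentrations for uncensored rows, positive detection limits for
#' censored rows, and uniqueness of (brand, color, metal, sample_id).
#' Metals absent from the supplied reference-dose table are allowed but
#' marked in the `known_metal` column.
#'
#' @param df A data frame with columns `sample_id`, `brand`, `color`,
#'   `metal`, `concentration` (mg/kg), `below_lod` (logical), `lod`
#'   (mg/kg, required where `below_lod`), and optionally `country`.
#' @param rfd Optional reference-dose table (see [read_rfd_table()]) used
#'   to flag unknown metals.
#' @return The validated tibble with class `conc_tbl`.
#' @export
as_concentration_table <- function(df, rfd = NULL) {
  df <- tibble::as_tibble(df)
  missing <- setdiff(conc_required_cols, names(df))
  if (length(missing)) {
    stop("concentration table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"country" %in% names(df)) df$country <- NA_character_
  df$below_lod <- as.logical(df$below_lod)
  bad <- which(!df$below_lod & (!is.finite(df$concentration) |
                                  df$concentration <= 0))
  if (length(bad)) {
    stop("non-positive concentration in uncensored row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  badlod <- which(df$below_lod & (!is.finite(df$lod) | df$lod <= 0))
  if (length(badlod)) {
    stop("censored row(s) without a positive LOD: ",
         paste(utils::head(badlod, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(df$brand, df$color, df$metal, df$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (brand, color, metal, sample_id) combinations",
         call. = FALSE)
  }
  df$known_metal <- if (is.null(rfd)) TRUE else df$metal %in% rfd$metal
  if (!"imputed" %in% names(df)) df$imputed <- FALSE
  df <- df[, c("sample_id", "brand", "country", "color", "metal",
               "concentration", "below_lod", "lod", "imputed",
               "known_metal")]
  class(df) <- c("conc_tbl", class(df))
  df
}

#' Read a concentration CSV
#'
#' Expects columns `sample_id`, `brand`, `country`, `color`, `metal`,
#' `value`, `unit` (ppm or ppb), `below_lod`, `lod` (same unit as `value`).
#' All concentrations and detection limits are converted to the canonical
#' mg/kg on ingest. A `unit_map` (named vector, metal to unit) may supply
#' units when the file has no `unit` column.
#'
#' @param path Path to the CSV file.
#' @param unit_map Optional named character vector mapping metal symbols to
#'   `"ppm"` or `"ppb"`; used when the file lacks a `unit` column (and
#'   overriding it when both are present).
#' @param rfd Optional reference-dose table for unknown-metal flagging.
#' @return A `conc_tbl` tibble (see [as_concentration_table()]).
#' @export
read_concentration_table <- function(path, unit_map = NULL, rfd = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  required <- c("sample_id", "brand", "color", "metal", "value", "below_lod")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!nrow(raw)) {
    out <- tibble::tibble(sample_id = character(), brand = character(),
                          country = character(), color = character(),
                          metal = character(), concentration = double(),
                          below_lod = logical(), lod = double())
    return(as_concentration_table(out, rfd = rfd))
  }
  unit <- if (!is.null(unit_map)) {
    u <- unname(unit_map[raw$metal])
    if (anyNA(u)) {
      stop("unit_map has no entry for metal(s): ",
           paste(unique(raw$metal[is.na(u)]), collapse = ", "),
           call. = FALSE)
    }
    u
  } else if ("unit" %in% names(raw)) {
    raw$unit
  } else {
    stop("schema error: missing column(s) unit (or supply unit_map)",
         call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = as.character(raw$sample_id),
    brand = as.character(raw$brand),
    country = if ("country" %in% names(raw)) as.character(raw$country)
              else NA_character_,
    color = as.character(raw$color),
    metal = as.character(raw$metal),
    concentration = to_mgkg(raw$value, unit),
    below_lod = as.logical(raw$below_lod),
    lod = if ("lod" %in% names(raw)) to_mgkg(raw$lod, unit) else NA_real_
  )
  as_concentration_table(out, rfd = rfd)
}

#' Read a reference-dose CSV
#'
#' Columns `metal`, `rfd_ing`, `rfd_derm` (both mg/kg/day). Both doses must
#' be positive.
#'
#' @param path Path to the CSV file.
#' @return Tibble with one row per metal.
#' @export
read_rfd_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("metal", "rfd_ing", "rfd_derm"), names(df))
  if (length(missing)) {
    stop("schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$rfd_ing <= 0) || any(df$rfd_derm <= 0)) {
    stop("reference doses must be positive", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a survey CSV
#'
#' Columns `respondent_id`, `uses_dye`, `uses_chemical_dye`, `age_start`,
#' `frequency_per_year`, `body_weight_kg`, `color_pref`, `brand_pref`.
#'
#' @param path Path to the CSV file.
#' @return Tibble of respondent records.
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("respondent_id", "uses_dye", "uses_chemical_dye",
                "age_start", "frequency_per_year", "body_weight_kg",
                "color_pref", "brand_pref")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$age_start < 0, na.rm = TRUE) ||
      any(df$frequency_per_year < 0, na.rm = TRUE) ||
      any(df$body_weight_kg <= 0, na.rm = TRUE)) {
    stop("validation error: age_start and frequency must be >= 0 and ",
         "body_weight_kg > 0", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Apply the below-detection-limit policy
#'
#' For each metal, if the censored fraction is at least
#' `exclusion_fraction` the metal is excluded from the analysis table
#' entirely (all-or-nothing); otherwise censored values are replaced by the
#' chosen substitution rule and flagged as imputed. Non-censored
#' measurements are never modified.
#'
#' @param table A `conc_tbl` tibble.
#' @param metals Metal symbols to apply the policy to; default all metals
#'   present. Requesting a metal absent from the table is an error.
#' @param exclusion_fraction Censored-fraction threshold at or above which
#'   a metal is dropped; default 0.20.
#' @param substitution Replacement for censored values kept in the table:
#'   `"half-lod"` (default), `"zero"`, or `"full-lod"`.
#' @return A list with `data` (the filtered/imputed `conc_tbl`) and
#'   `decisions` (tibble: `metal`, `n`, `n_censored`, `censored_fraction`,
#'   `action`, `substitution`).
#' @export
apply_lod_policy <- function(table, metals = NULL,
                             exclusion_fraction = 0.20,
                             substitution = c("half-lod", "zero",
                                              "full-lod")) {
  substitution <- match.arg(substitution)
  stopifnot(exclusion_fraction > 0, exclusion_fraction <= 1)
  present <- unique(table$metal)
  if (is.null(metals)) metals <- present
  absent <- setdiff(metals, present)
  if (length(absent)) {
    stop("lookup error: metal(s) not in table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  decisions <- dplyr::filter(table, .data$metal %in% metals) |>
    dplyr::group_by(metal = .data$metal) |>
    dplyr::summarise(n = dplyr::n(), n_censored = sum(.data$below_lod),
                     .groups = "drop") |>
    dplyr::mutate(
      censored_fraction = .data$n_censored / .data$n,
      action = dplyr::case_when(
        .data$censored_fraction >= exclusion_fraction ~ "excluded",
        .data$n_censored > 0 ~ "substituted",
        TRUE ~ "none"
      ),
      substitution = ifelse(.data$action == "substituted", substitution,
                            NA_character_)
    )
  excluded <- decisions$metal[decisions$action == "excluded"]
  out <- dplyr::filter(table, !.data$metal %in% excluded)
  subst_rows <- out$below_lod & out$metal %in% metals
  if (any(subst_rows)) {
    repl <- switch(substitution,
                   `half-lod` = out$lod[subst_rows] / 2,
                   zero = 0,
                   `full-lod` = out$lod[subst_rows])
    out$concentration[subst_rows] <- repl
    out$imputed[subst_rows] <- TRUE
  }
  class(out) <- class(table)
  list(data = out, decisions = decisions)
}

#' Summary statistics of concentrations
#'
#' Summarizes per metal, optionally stratified by brand or color. The 90th
#' percentile uses linear interpolation between order statistics
#' (quantile type 7), recorded in the `quantile_type` attribute.
#'
#' Empty groups are simply absent from the output (they are not reported
#' as zero).
#'
#' @param table A `conc_tbl` tibble (censoring policy already applied:
#'   imputed values are summarized at their substituted value).
#' @param group_by `"pooled"` (default), `"brand"` or `"color"`.
#' @return Tibble with `metal`, the stratum column (unless pooled), and
#'   `n`, `mean`, `sd`, `median`, `min`, `max`, `p90`.
#' @export
summarize_concentrations <- function(table,
                                     group_by = c("pooled", "brand",
                                                  "color")) {
  group_by <- match.arg(group_by)
  keys <- if (group_by == "pooled") "metal" else c(group_by, "metal")
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$concentration),
      sd = stats::sd(.data$concentration),
      median = stats::median(.data$concentration),
      min = min(.data$concentration),
      max = max(.data$concentration),
      p90 = stats::quantile(.data$concentration, 0.9, type = 7,
                            names = FALSE),
      .groups = "drop"
    )
  attr(out, "quantile_type") <- 7L
  out
}
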