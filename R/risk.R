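#' Hazard quotient
#'
#' Ratio of an absorbed daily dose to the reference dose for the same
#' pathway. Values above 1 flag a potentially significant non-carcinogenic
#' risk.
#'
#' @param dose Dose in mg/kg/day, `>= 0`.
#' @param rfd Reference dose in mg/kg/day, `> 0`.
#' @return Unitless hazard quotient, `dose / rfd`.
#' @export
hazard_quotient <- function(dose, rfd) {
  if (any(rfd <= 0)) stop("rfd must be positive", call. = FALSE)
  if (any(dose < 0)) stop("dose must be nonnegative", call. = FALSE)
  dose / rfd
}

#' Chronic hazard index
#'
#' Sum of hazard quotients across chemicals (or pathways). When some
#' metals were excluded by the censoring policy the index is a lower
#' bound for the full mixture; exclusions are reported alongside, never
#' silently folded in as zero.
#'
#' @param hqs Numeric vector of hazard quotients (at least one).
#' @return Unitless hazard index.
#' @export
hazard_index <- function(hqs) {
  if (!length(hqs)) stop("need at least one hazard quotient", call. = FALSE)
  sum(hqs)
}

#' Risk characterization for one stratum
#'
#' Computes per-metal hazard quotients from point doses and the selected
#' reference-dose basis, sums them into the stratum's hazard index, and
#' classifies against the threshold of 1 (strictly greater than 1 is
#' "significant"; at or below 1 is "not-probable").
#'
#' @param doses Named numeric vector of point doses (mg/kg/day), one per
#'   assessed metal.
#' @param rfd_table Tibble with `metal`, `rfd_ing`, `rfd_derm` (see
#'   [reference_rfd()]).
#' @param stratum Stratum label (e.g. `"pooled"`, a brand, or a color).
#' @param rfd_basis `"dermal"` (default; the pathway's basis) or
#'   `"ingestion"`.
#' @param point_estimate `"median"` or `"mean"`, recorded in the result.
#' @param excluded Metals excluded upstream by the censoring policy;
#'   reported as `"excluded (censoring)"` with no quotient.
#' @return Object of class `risk_result`: list with `stratum`, `table`
#'   (tibble: metal, dose, rfd, hq, status), `hi`, `classification`,
#'   `rfd_basis`, `point_estimate`, `excluded`.
#' @export
characterize <- function(doses, rfd_table, stratum = "pooled",
                         rfd_basis = c("dermal", "ingestion"),
                         point_estimate = "median",
                         excluded = character()) {
  rfd_basis <- match.arg(rfd_basis)
  metals <- names(doses)
  if (is.null(metals)) stop("doses must be a named vector", call. = FALSE)
  col <- if (rfd_basis == "dermal") "rfd_derm" else "rfd_ing"
  idx <- match(metals, rfd_table$metal)
  if (anyNA(idx)) {
    stop("missing reference dose for metal(s): ",
         paste(metals[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  rfd <- rfd_table[[col]][idx]
  hq <- hazard_quotient(unname(doses), rfd)
  tab <- tibble::tibble(metal = metals, dose = unname(doses), rfd = rfd,
                        hq = hq, status = "assessed")
  if (length(excluded)) {
    tab <- dplyr::bind_rows(
      tab,
      tibble::tibble(metal = excluded, dose = NA_real_, rfd = NA_real_,
                     hq = NA_real_, status = "excluded (censoring)")
    )
  }
  hi <- hazard_index(hq)
  structure(
    list(stratum = stratum, table = tab, hi = hi,
         classification = if (hi > 1) "significant" else "not-probable",
         rfd_basis = rfd_basis, point_estimate = point_estimate,
         excluded = excluded),
    class = "risk_result"
  )
}

#' @export
print.risk_result <- function(x, ...) {
  cat("<risk_result> stratum:", x$stratum, " basis:", x$rfd_basis,
      " HI =", signif(x$hi, 4), "(", x$classification, ")\n")
  print(x$table)
  if (length(x$excluded)) {
    cat("HI is a lower bound: excluded by censoring policy:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stratified risk characterization
#'
#' Runs the same dose-and-risk pipeline within each brand or color
#' stratum. Each stratum's concentration point estimate per metal (median
#' by default over its measurements) enters the Monte Carlo dose equation
#' as a fixed concentration; exposure-factor draws are shared across
#' metals and strata (same seed and streams), so hazard-quotient ratios
#' between strata reflect concentrations only. Strata whose metals were
#' all excluded are reported as not-assessable.
#'
#' @param table A `conc_tbl` after [apply_lod_policy()] (i.e. the `data`
#'   element; imputed values included, excluded metals absent).
#' @param by `"brand"` or `"color"`.
#' @param rfd_table Reference-dose tibble.
#' @param factors An [exposure_factors()] object.
#' @param n_iter,seed Monte Carlo settings passed to [simulate_dose()].
#' @param point_estimate `"median"` or `"mean"`, applied both to the
#'   stratum concentrations and to the simulated dose.
#' @param rfd_basis `"dermal"` or `"ingestion"`.
#' @param excluded Metals excluded upstream (reported per stratum).
#' @param strata Stratum labels to assess; defaults to those present in
#'   `table`. Supplying the pre-exclusion labels lets strata whose every
#'   metal was dropped be reported as not-assessable instead of vanishing.
#' @return A tibble with one row per stratum: `stratum`, `hi`,
#'   `classification`, `max_hi` (logical, marks the maximal-HI stratum)
#'   and a list-column `result` of `risk_result` objects.
#' @export
stratified_risk <- function(table, by = c("brand", "color"), rfd_table,
                            factors = default_exposure_factors(),
                            n_iter = 20000, seed = 1,
                            point_estimate = c("median", "mean"),
                            rfd_basis = c("dermal", "ingestion"),
                            excluded = character(), strata = NULL) {
  by <- match.arg(by)
  point_estimate <- match.arg(point_estimate)
  rfd_basis <- match.arg(rfd_basis)
  if (is.null(strata)) strata <- sort(unique(table[[by]]))
  strata <- sort(strata)
  if (!length(strata)) stop("no strata found in column ", by, call. = FALSE)
  rows <- purrr::map(strata, function(s) {
    sub <- table[table[[by]] == s & table$known_metal, ]
    sub <- sub[!is.na(sub$concentration), ]
    metals <- sort(unique(sub$metal))
    if (!length(metals)) {
      return(tibble::tibble(stratum = s, hi = NA_real_,
                            classification = "not-assessable",
                            result = list(NULL)))
    }
    cpoints <- vapply(metals, function(m) {
      v <- sub$concentration[sub$metal == m]
      if (point_estimate == "median") stats::median(v) else mean(v)
    }, numeric(1))
    doses <- vapply(metals, function(m) {
      sim <- simulate_dose(cpoints[[m]], factors, n_iter = n_iter,
                           seed = seed, metal = m)
      summarize_dose(sim, point_estimate)
    }, numeric(1))
    res <- characterize(doses, rfd_table, stratum = s,
                        rfd_basis = rfd_basis,
                        point_estimate = point_estimate,
                        excluded = excluded)
    tibble::tibble(stratum = s, hi = res$hi,
                   classification = res$classification, result = list(res))
  })
  out <- dplyr::bind_rows(rows)
  out$max_hi <- if (all(is.na(out$hi))) FALSE
                else !is.na(out$hi) & out$hi == max(out$hi, na.rm = TRUE)
  out
}
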