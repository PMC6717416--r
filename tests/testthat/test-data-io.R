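test_that("unit conversion is exact and round-trips", {
  expect_equal(to_mgkg(185.34, "ppb"), 0.18534)
  expect_equal(to_mgkg(0.54, "ppm"), 0.54)
  x <- c(0.07, 4.51, 185.34, 1e-4)
  expect_equal(from_mgkg(to_mgkg(x, "ppb"), "ppb"), x)
  expect_error(to_mgkg(1, "mol/L"), "unknown unit")
})

test_that("concentration CSV is read, validated and unit-normalized", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::tibble(
    sample_id = c("s1", "s2"), brand = "b1", country = "Iran",
    color = c("black", "blonde"), metal = c("Pb", "Al"),
    value = c(185.34, 0.54), unit = c("ppb", "ppm"),
    below_lod = FALSE, lod = c(10, 0.001)
  )
  readr::write_csv(df, path)
  tab <- read_concentration_table(path)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$concentration[tab$metal == "Pb"], 0.18534)
  expect_equal(tab$concentration[tab$metal == "Al"], 0.54)

  # unit_map overrides the unit column
  tab2 <- read_concentration_table(path, unit_map = c(Pb = "ppm",
                                                      Al = "ppm"))
  expect_equal(tab2$concentration[tab2$metal == "Pb"], 185.34)

  # empty file with a valid header gives an empty table
  readr::write_csv(df[0, ], path)
  expect_equal(nrow(read_concentration_table(path)), 0)

  # schema error names the missing column
  readr::write_csv(df[, setdiff(names(df), "metal")], path)
  expect_error(read_concentration_table(path), "metal")

  # non-positive uncensored concentration is a validation error
  bad <- df
  bad$value[1] <- -1
  readr::write_csv(bad, path)
  expect_error(read_concentration_table(path), "non-positive")
})

test_that("duplicate sample keys and missing LODs are rejected", {
  df <- tibble::tibble(
    sample_id = "s1", brand = "b1", color = "black", metal = "Pb",
    concentration = 0.1, below_lod = FALSE, lod = NA_real_
  )
  expect_error(as_concentration_table(dplyr::bind_rows(df, df)),
               "duplicate")
  cen <- df
  cen$below_lod <- TRUE
  cen$concentration <- NA_real_
  expect_error(as_concentration_table(cen), "LOD")
})

test_that("LOD policy excludes at the threshold and substitutes below it", {
  # 7 of 32 censored (21.9%) at the default 20% threshold: excluded
  tab <- make_conc_tbl(rep(0.3, 32), metal = "Cr",
                       below_lod = rep(c(TRUE, FALSE), c(7, 25)))
  res <- apply_lod_policy(tab, "Cr")
  expect_equal(res$decisions$action, "excluded")
  expect_equal(res$decisions$censored_fraction, 7 / 32)
  expect_false("Cr" %in% res$data$metal)

  # no censoring: table unchanged, no imputations
  tab <- make_conc_tbl(runif(32, 0.1, 1))
  res <- apply_lod_policy(tab)
  expect_equal(res$data$concentration, tab$concentration)
  expect_false(any(res$data$imputed))

  # 3 censored at LOD 0.05 under half-LOD: 0.025 each, flagged imputed
  tab <- make_conc_tbl(runif(32, 0.1, 1),
                       below_lod = rep(c(TRUE, FALSE), c(3, 29)),
                       lod = 0.05)
  res <- apply_lod_policy(tab)
  expect_equal(res$data$concentration[res$data$imputed],
               rep(0.025, 3))
  expect_equal(sum(res$data$imputed), 3)

  # exclusion fires at exactly the 20% fraction (>= threshold)
  tab <- make_conc_tbl(rep(0.3, 10),
                       below_lod = rep(c(TRUE, FALSE), c(2, 8)))
  res <- apply_lod_policy(tab)
  expect_equal(res$decisions$action, "excluded")
  # and not just below it (6/32 = 18.75%)
  tab <- make_conc_tbl(rep(0.3, 32),
                       below_lod = rep(c(TRUE, FALSE), c(6, 26)))
  res <- apply_lod_policy(tab)
  expect_equal(res$decisions$action, "substituted")

  expect_error(apply_lod_policy(tab, "Hg"), "Hg")
})

test_that("LOD policy never touches uncensored rows; exclusion is
           all-or-nothing per metal", {
  set.seed(11)
  tab <- dplyr::bind_rows(
    make_conc_tbl(runif(32, 0.1, 1), metal = "Pb",
                  below_lod = rep(c(TRUE, FALSE), c(3, 29))),
    make_conc_tbl(runif(32, 0.1, 1), metal = "Ag",
                  below_lod = rep(c(TRUE, FALSE), c(9, 23)))
  )
  class(tab) <- c("conc_tbl", class(tab))
  res <- apply_lod_policy(tab)
  uncensored_before <- tab[!tab$below_lod & tab$metal == "Pb", ]
  uncensored_after <- res$data[!res$data$below_lod &
                                 res$data$metal == "Pb", ]
  expect_equal(uncensored_after$concentration,
               uncensored_before$concentration)
  expect_false(any(res$data$metal == "Ag"))
})

test_that("summaries match a brute-force recomputation and type-7
           percentiles", {
  # 90th percentile of 1..10 under linear interpolation of order stats
  tab <- make_conc_tbl(1:10)
  s <- summarize_concentrations(tab)
  sorted <- sort(1:10)
  h <- (10 - 1) * 0.9 + 1 # independent sort-and-interpolate oracle
  oracle <- sorted[floor(h)] + (h - floor(h)) *
    (sorted[ceiling(h)] - sorted[floor(h)])
  expect_equal(s$p90, oracle)
  expect_equal(attr(s, "quantile_type"), 7L)

  # identical values: degenerate spread
  s <- summarize_concentrations(make_conc_tbl(rep(0.4, 3)))
  expect_equal(s$mean, 0.4)
  expect_equal(s$sd, 0)
  expect_equal(s$median, 0.4)
  expect_equal(s$min, s$max)

  # stratified summaries equal brute-force recomputation from raw rows
  set.seed(3)
  tab <- make_conc_tbl(rlnorm(32, -1, 1))
  s <- summarize_concentrations(tab, "brand")
  for (b in unique(tab$brand)) {
    v <- tab$concentration[tab$brand == b]
    row <- s[s$brand == b, ]
    expect_equal(row$n, length(v))
    expect_equal(row$mean, sum(v) / length(v))
    expect_equal(row$median, stats::median(v))
  }
})

test_that("pooling property: equal-n strata pool to the mean of stratum
           means", {
  set.seed(5)
  tab <- make_conc_tbl(rlnorm(32, -1, 0.5))
  pooled <- summarize_concentrations(tab)$mean
  by_brand <- summarize_concentrations(tab, "brand")
  expect_true(all(by_brand$n == 4))
  expect_equal(pooled, mean(by_brand$mean))
})

test_that("survey and reference-dose readers validate their schemas", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(metal = "Pb", rfd_ing = 0.0035,
                                  rfd_derm = 0.00052), path)
  rfd <- read_rfd_table(path)
  expect_equal(rfd$rfd_derm, 0.00052)
  readr::write_csv(tibble::tibble(metal = "Pb", rfd_ing = -1,
                                  rfd_derm = 0.00052), path)
  expect_error(read_rfd_table(path), "positive")

  sv <- generate_survey(20, seed = 1)
  readr::write_csv(sv, path)
  expect_equal(nrow(read_survey_table(path)), 20)
  sv$body_weight_kg[1] <- -5
  readr::write_csv(sv, path)
  expect_error(read_survey_table(path), "body_weight")
})

test_that("packaged reference doses satisfy the dermal <= ingestion
           invariant", {
  rfd <- reference_rfd()
  expect_true(all(rfd$rfd_derm > 0 & rfd$rfd_ing > 0))
  expect_true(all(rfd$rfd_derm <= rfd$rfd_ing))
})
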