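# small in-memory concentration tables used across test files

make_conc_tbl <- function(values, metal = "Pb", below_lod = NULL,
                          lod = 0.05) {
  n <- length(values)
  if (is.null(below_lod)) below_lod <- rep(FALSE, n)
  as_concentration_table(tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    brand = rep(paste0("brand", 1:8), length.out = n),
    country = "x",
    color = rep(c("black", "blonde", "light-brown", "dark-brown"),
                length.out = n),
    metal = metal,
    concentration = ifelse(below_lod, NA_real_, values),
    below_lod = below_lod,
    lod = lod
  ))
}

# deterministic table holding each brand-reference cell mean as the
# measured value (one row per brand x color x metal), mg/kg
brand_mean_conc_tbl <- function() {
  ref <- reference_brand_means()
  ref <- ref[!ref$censored_cell, ]
  rows <- tidyr::expand_grid(
    ref,
    color = c("black", "blonde", "light-brown", "dark-brown")
  )
  as_concentration_table(tibble::tibble(
    sample_id = paste(rows$brand, rows$color, rows$metal, sep = "-"),
    brand = rows$brand,
    country = rows$country,
    color = rows$color,
    metal = rows$metal,
    concentration = to_mgkg(rows$mean, rows$unit),
    below_lod = FALSE,
    lod = NA_real_
  ))
}

fixed_factors <- function() default_exposure_factors(stochastic = FALSE)

# independent rank-then-Pearson oracle for Spearman correlation
rank_pearson <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# asymptotic 1% critical value of the one-sample KS statistic
ks_crit_1pct <- function(n) sqrt(-0.5 * log(0.005)) / sqrt(n)
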