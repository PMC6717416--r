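all_specs <- function() {
  list(
    dist_spec("lognormal", meanlog = 0.5, sdlog = 0.8),
    dist_spec("loggamma", shape = 3, rate = 2),
    dist_spec("weibull", shape = 2, scale = 1.5),
    dist_spec("pareto", xmin = 1, alpha = 2.5),
    dist_spec("loglaplace", location = 0.2, scale = 0.4),
    dist_spec("normal", mean = 1, sd = 2),
    dist_spec("gamma", shape = 2, rate = 3),
    dist_spec("exponential", rate = 0.5)
  )
}

test_that("closed-form evaluation points are reproduced", {
  expect_equal(pdist(dist_spec("lognormal", meanlog = 0, sdlog = 1), 1),
               0.5)
  expect_equal(pdist(dist_spec("loglaplace", location = 0, scale = 1), 1),
               0.5)
  expect_equal(pdist(dist_spec("pareto", xmin = 1, alpha = 2), 2),
               1 - (1 / 2)^2)
})

test_that("density and cdf respect the support boundary", {
  sp <- dist_spec("pareto", xmin = 2, alpha = 1.5)
  expect_equal(ddist(sp, 1), 0)
  expect_equal(pdist(sp, 1), 0)
  lg <- dist_spec("loggamma", shape = 2, rate = 2)
  expect_equal(ddist(lg, 0.5), 0)
  expect_equal(pdist(lg, 0.5), 0)
  expect_true(all(ddist(sp, c(2.5, 5)) > 0))
})

test_that("quantile inverts the cdf on interior probabilities", {
  probs <- seq(0.1, 0.9, by = 0.1)
  for (sp in all_specs()) {
    q <- qdist(sp, probs)
    expect_equal(pdist(sp, q), probs, tolerance = 1e-8,
                 info = sp$family)
  }
})

test_that("invalid parameters fail before any drawing", {
  expect_error(dist_spec("weibull", shape = -1, scale = 1), "invalid")
  expect_error(dist_spec("pareto", xmin = 0, alpha = 2), "invalid")
  expect_error(dist_spec("lognormal", meanlog = 0), "missing parameter")
})

test_that("sampling is seed-deterministic and stays in support", {
  for (sp in all_specs()) {
    a <- rdist(sp, 5, seed = 99)
    b <- rdist(sp, 5, seed = 99)
    expect_identical(a, b, info = sp$family)
    s <- dist_support(sp)
    x <- rdist(sp, 1000, seed = 7)
    expect_true(all(x >= s[1] & x <= s[2]), info = sp$family)
  }
})

test_that("samples agree with closed-form moments", {
  # weibull shape 1 is exponential with mean = scale
  theta <- 2.3
  x <- rdist(dist_spec("weibull", shape = 1, scale = theta), 20000,
             seed = 4)
  expect_lt(abs(mean(x) - theta), 4 * theta / sqrt(20000))
  # loglaplace median is exp(location)
  x <- rdist(dist_spec("loglaplace", location = 0.7, scale = 0.4), 20000,
             seed = 5)
  expect_lt(abs(log(median(x)) - 0.7), 4 * 0.4 * sqrt(1 / 20000) * 2)
})

test_that("log of loglaplace draws is Laplace (moment check)", {
  mu <- 0.3; b <- 0.5
  lx <- log(rdist(dist_spec("loglaplace", location = mu, scale = b),
                  50000, seed = 8))
  expect_lt(abs(mean(lx) - mu), 4 * sqrt(2 * b^2 / 50000))
  expect_lt(abs(var(lx) - 2 * b^2), 0.05)
})

test_that("seeded draws pass a KS check against the generating cdf", {
  # 1% critical value exceeded in at most 5 of 100 seeds, every family
  for (sp in all_specs()) {
    fails <- 0L
    for (s in 1:100) {
      x <- sort(rdist(sp, 10000, seed = s))
      u <- pdist(sp, x)
      i <- seq_along(x)
      ks <- max(i / 10000 - u, u - (i - 1) / 10000)
      if (ks > ks_crit_1pct(10000)) fails <- fails + 1L
    }
    expect_lte(fails, 5, label = paste(sp$family, "KS failures"))
  }
})

test_that("closed-form MLEs match independent oracles", {
  # pareto: alpha-hat = n / sum(log(x/xmin)), xmin at the sample minimum;
  # cross-checked against a coarse grid maximization of the log-likelihood
  x <- rdist(dist_spec("pareto", xmin = 1, alpha = 2.5), 500, seed = 2)
  fit <- fit_mle(x, "pareto")
  expect_equal(fit$spec$params[["xmin"]], min(x))
  expect_equal(fit$spec$params[["alpha"]],
               length(x) / sum(log(x / min(x))))
  grid <- seq(0.5, 6, by = 0.005)
  ll <- vapply(grid, function(a) {
    sum(log(a) + a * log(min(x)) - (a + 1) * log(x))
  }, numeric(1))
  expect_equal(fit$spec$params[["alpha"]], grid[which.max(ll)],
               tolerance = 0.01)

  # loglaplace on {1/e, 1, e}: location 0, scale = mean |log dev| = 2/3
  fit <- fit_mle(c(exp(-1), 1, exp(1)), "loglaplace")
  expect_equal(fit$spec$params[["location"]], 0)
  expect_equal(fit$spec$params[["scale"]], 2 / 3)
})

test_that("lognormal fit recovers generating parameters at n = 10000", {
  x <- rdist(dist_spec("lognormal", meanlog = 0.5, sdlog = 0.8), 10000,
             seed = 31)
  fit <- fit_mle(x, "lognormal")
  expect_lt(abs(fit$spec$params[["meanlog"]] - 0.5), 0.05)
  expect_lt(abs(fit$spec$params[["sdlog"]] - 0.8), 0.05)
})

test_that("optimizing fits agree with an independent fitting library", {
  x <- rdist(dist_spec("weibull", shape = 1.7, scale = 2.2), 2000,
             seed = 12)
  ours <- fit_mle(x, "weibull")
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(unname(ours$spec$params[["shape"]]),
               unname(ref$estimate[["shape"]]), tolerance = 1e-3)
  expect_equal(unname(ours$spec$params[["scale"]]),
               unname(ref$estimate[["scale"]]), tolerance = 1e-3)
  # stationarity sanity contract: no coarse neighbour beats the optimum
  best <- ours$loglik
  for (ds in c(0.95, 1.05)) for (dc in c(0.95, 1.05)) {
    alt <- dist_spec("weibull",
                     shape = ours$spec$params[["shape"]] * ds,
                     scale = ours$spec$params[["scale"]] * dc)
    expect_lte(sum(log(ddist(alt, x))), best + 1e-6)
  }
})

test_that("fit errors are informative", {
  expect_error(fit_mle(c(1, 2), "lognormal"), "at least 3")
  expect_error(fit_mle(rep(2, 10), "weibull"), "degenerate")
  expect_error(fit_mle(c(-1, 1, 2), "lognormal"), "support")
  expect_error(fit_mle(c(0.5, 1.5, 2), "loggamma"), "support")
})

test_that("selection ranks the generating family first for a clear
           weibull sample", {
  wins <- 0L
  for (s in 1:20) {
    x <- rdist(dist_spec("weibull", shape = 2, scale = 1), 5000, seed = s)
    r <- select_best(x)
    if (r$family[which(r$rank == 1)] == "weibull") wins <- wins + 1L
  }
  expect_gte(wins, 16)
})

test_that("selection reports failures and respects single candidates", {
  x <- rdist(dist_spec("lognormal", meanlog = -1, sdlog = 0.5), 100,
             seed = 3)
  r <- select_best(x) # values < 1, so loggamma must fail but be recorded
  expect_true("loggamma" %in% r$family)
  expect_false(is.na(r$error[r$family == "loggamma"]))
  ok <- r[is.na(r$error), ]
  expect_setequal(ok$rank, seq_len(nrow(ok)))
  # ranked ascending in the KS statistic
  expect_false(is.unsorted(ok$ks_stat[order(ok$rank)]))

  single <- select_best(x, candidates = "pareto")
  expect_equal(single$rank, 1L)

  expect_error(select_best(rep(1, 10)), "all candidate families failed")
})

test_that("the generating family ranks top-2 for most reference metals
           at n = 32", {
  rd <- reference_distributions()
  hits <- 0L
  for (i in seq_len(nrow(rd))) {
    x <- rdist(rd$spec[[i]], 32, seed = 700 + i)
    r <- select_best(x)
    rk <- r$rank[r$family == rd$family[i]]
    if (length(rk) && !is.na(rk) && rk <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 4)
})

test_that("gof statistics are nonnegative and chi-square binning follows
           the sample size", {
  x <- rdist(dist_spec("gamma", shape = 2, rate = 1), 200, seed = 6)
  g <- gof_stats(fit_mle(x, "gamma")$spec, x)
  expect_gte(g$ks_stat, 0)
  expect_gte(g$ad_stat, 0)
  expect_gte(g$chi2_stat, 0)
  expect_equal(g$chi2_bins, ceiling(1 + log2(200)))
})

test_that("tidy and glance expose fit results", {
  fit <- fit_mle(rdist(dist_spec("lognormal", meanlog = 0, sdlog = 1),
                       100, seed = 1), "lognormal")
  td <- tidy(fit)
  expect_equal(td$term, c("meanlog", "sdlog"))
  gl <- glance(fit)
  expect_equal(gl$family, "lognormal")
  expect_equal(gl$nobs, 100)
})
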