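test_that("exact Michaelis-Menten data is recovered to machine precision", {
  s <- 10 / 2^(0:7)
  expect_equal(range(s), c(0.078125, 10))
  v <- 714.29 * s / (0.36 + s)
  ds <- kinetic_dataset("wt", s, v)
  for (m in c("lineweaver-burk", "nonlinear")) {
    fit <- suppressWarnings(fit_michaelis_menten(ds, method = m))
    expect_equal(fit$vmax_U_per_mg, 714.29, tolerance = 1e-6)
    expect_equal(fit$km_mM, 0.36, tolerance = 1e-6)
  }
})

test_that("double-reciprocal fit is exact for any positive parameter pair", {
  for (seed in 1:25) {
    p <- with_seed(seed, c(stats::runif(1, 10, 2000), stats::runif(1, 0.01, 5)))
    s <- 10 / 2^(0:7)
    ds <- kinetic_dataset("e", s, p[1] * s / (p[2] + s))
    fit <- suppressWarnings(fit_michaelis_menten(ds))
    expect_equal(fit$vmax_U_per_mg, p[1], tolerance = 1e-8)
    expect_equal(fit$km_mM, p[2], tolerance = 1e-8)
  }
})

test_that("kcat handling distinguishes supplied from derived values", {
  s <- 10 / 2^(0:7)
  ds <- kinetic_dataset("wt", s, 714.29 * s / (0.36 + s))
  sup <- suppressWarnings(fit_michaelis_menten(ds, kcat_per_s = 188.10))
  expect_equal(sup$kcat_source, "supplied")
  expect_equal(sup$efficiency_per_s_per_mM, 188.10 / sup$km_mM)
  der <- suppressWarnings(fit_michaelis_menten(ds, molar_mass_kDa = 39.5))
  expect_equal(der$kcat_source, "derived")
  expect_equal(der$kcat_per_s, der$vmax_U_per_mg * 39.5 / 60)
  none <- suppressWarnings(fit_michaelis_menten(ds))
  expect_true(is.na(none$kcat_per_s))
})

test_that("degenerate kinetic inputs are rejected", {
  expect_error(kinetic_dataset("e", c(1, 2), c(1, 2)), "at least 3")
  expect_error(kinetic_dataset("e", c(1, 1, 1), c(1, 2, 3)), "at least 3")
  expect_error(kinetic_dataset("e", c(-1, 2, 3), c(1, 2, 3)), "positive")
  ds0 <- kinetic_dataset("e", c(1, 2, 4), c(0, 2, 3))
  expect_error(fit_michaelis_menten(ds0), "reciprocal undefined")
  # superlinear rates give a negative 1/v intercept
  dsh <- kinetic_dataset("e", c(1, 2, 4), c(1, 4, 16))
  expect_error(suppressWarnings(fit_michaelis_menten(dsh)),
               "fit not hyperbolic")
})

test_that("noisy replicates: median Km error small, LB agrees with nonlinear", {
  err_lb <- err_nl <- agree <- numeric(200)
  for (i in 1:200) {
    g <- gen_kinetics(seed = i, vmax = 714.29, km = 0.36, noise_cv = 0.02)
    ds <- g$dataset
    lb <- suppressWarnings(fit_michaelis_menten(ds))
    nl <- suppressWarnings(fit_michaelis_menten(ds, method = "nonlinear"))
    err_lb[i] <- abs(lb$km_mM - 0.36) / 0.36
    err_nl[i] <- abs(nl$km_mM - 0.36) / 0.36
    agree[i] <- abs(lb$km_mM - nl$km_mM) / nl$km_mM
  }
  expect_lt(median(err_lb), 0.10)
  expect_lt(median(err_nl), 0.10)
  expect_lt(median(agree), 0.10)
})

test_that("catalytic efficiency and fold changes reproduce the kinetics table", {
  expect_equal(catalytic_efficiency(188.10, 0.36), 522.5, tolerance = 1e-9)
  expect_equal(catalytic_efficiency(187.95, 0.29), 648.1, tolerance = 1e-3)
  expect_equal(catalytic_efficiency(0, 1), 0)
  expect_error(catalytic_efficiency(10, 0), "invalid Km")

  expect_equal(round(fold_change(637.45, 522.50), 2), 1.22)
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(0.45, 0.36), 1.25)
  expect_error(fold_change(1, 0), "undefined ratio")
  # reciprocal folds multiply to one
  for (seed in 1:10) {
    ab <- with_seed(seed, stats::runif(2, 0.1, 10))
    expect_equal(fold_change(ab[1], ab[2]) * fold_change(ab[2], ab[1]), 1)
  }
})

test_that("first-order fit recovers exact exponential decay", {
  tt <- c(5, 10, 20, 40, 60, 90)
  s <- inactivation_series("wt", 60, tt, 100 * exp(-log(2) / 30 * tt))
  est <- estimate_half_life(s)
  expect_equal(est$t_half_min, 30, tolerance = 1e-9)
  expect_equal(est$t_half_min, log(2) / est$k_per_min, tolerance = 1e-12)
})

test_that("nearest-timepoint reads the half-life off the sampling grid", {
  # wild-type 60 C course: 53.28% at 25 min is the closest point to 50%
  wt <- inactivation_series("wt", 60, c(25, 90), c(53.28, 5.34))
  est <- estimate_half_life(wt, method = "nearest-timepoint")
  expect_equal(est$t_half_min, 25)
  expect_true(is.na(est$k_per_min))
  # ties resolve toward the earlier time
  tie <- inactivation_series("e", 60, c(10, 20, 30), c(55, 45, 20))
  expect_equal(estimate_half_life(tie, "nearest-timepoint")$t_half_min, 10)
})

test_that("non-decaying and invalid series are rejected", {
  up <- inactivation_series("e", 50, c(5, 10, 20), c(50, 60, 70))
  expect_error(estimate_half_life(up), "no decay")
  expect_error(inactivation_series("e", 50, c(5, 5, 10), c(1, 2, 3)),
               "strictly increasing")
  expect_error(inactivation_series("e", 50, c(0, 5), c(100, 150)),
               "\\[0, 110\\]")
  expect_warning(inactivation_series("e", 50, c(0, 5), c(100, 105)),
                 "above 100")
})

test_that("noisy decay recovery cross-checks against a grid-search oracle", {
  err <- numeric(200)
  for (i in 1:200) {
    k <- with_seed(i + 5000, stats::runif(1, log(2) / 120, log(2) / 15))
    g <- suppressWarnings(  # noise can push early residuals just over 100%
      gen_decay(seed = i, k_per_min = k, noise_cv = 0.03))
    est <- estimate_half_life(g$series)
    err[i] <- abs(est$t_half_min - log(2) / k) / (log(2) / k)
    if (i <= 20) {   # the dense oracle is slow; spot-check a subset
      oracle <- oracle_halflife_grid(g$series$time_min,
                                     g$series$residual_pct)
      expect_equal(est$t_half_min, oracle, tolerance = 0.05)
    }
  }
  expect_lt(median(err), 0.05)
})

test_that("residual-activity gains difference the printed time courses", {
  wt <- inactivation_series("wt", 50, c(100, 120), c(35, 28.24))
  k64n <- inactivation_series("K64N", 50, c(100, 120), c(70, 66.12))
  k68t <- inactivation_series("K68T", 50, c(100, 120), c(80, 76.44))
  expect_equal(residual_activity_gain(k64n, wt, 120), 37.88)
  expect_equal(residual_activity_gain(k68t, wt, 120), 48.20)
  expect_equal(residual_activity_gain(wt, wt, 120), 0)
  expect_error(residual_activity_gain(k64n, wt, 110), "time not sampled")
})

test_that("CSV readers split by enzyme and temperature", {
  kf <- tempfile(fileext = ".csv")
  g1 <- gen_kinetics(seed = 1, enzyme_id = "wt", file = kf)
  ks <- read_kinetics_csv(kf)
  expect_named(ks, "wt")
  expect_equal(ks$wt$substrate_mM, g1$dataset$substrate_mM)

  df <- rbind(
    data.frame(enzyme_id = "wt", temperature_C = 50,
               time_min = c(5, 10), residual_pct = c(90, 80)),
    data.frame(enzyme_id = "wt", temperature_C = 60,
               time_min = c(5, 10), residual_pct = c(70, 40)))
  cf <- tempfile(fileext = ".csv")
  utils::write.csv(df, cf, row.names = FALSE)
  ss <- read_inactivation_csv(cf)
  expect_length(ss, 2L)
  expect_equal(ss[["wt@60"]]$residual_pct, c(70, 40))
})
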