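# Synthetic generators: invariants, determinism, and calibration against
# configured ground truth.

test_that("catchment generator respects invariants and is seed-reproducible", {
  specs <- generate_catchments(258, seed = 7)
  expect_equal(nrow(specs), 258)
  lu <- specs[, c("LU_D", "LU_C", "LU_FSH", "LU_W", "LU_other")]
  expect_true(all(lu >= 0 & lu <= 100))
  expect_true(all(rowSums(lu) <= 100 + 1e-9))
  expect_true(all(specs$area_km2 > 0))
  expect_true(all(specs$L_TD >= 0 & specs$L_TD <= specs$LU_C))
  # tile drainage positively associated with cultivated fraction
  expect_gt(cor(specs$L_TD, specs$LU_C), 0.5)

  one <- generate_catchments(1, seed = 0)
  expect_equal(nrow(one), 1)
  expect_lte(sum(one[, c("LU_D", "LU_C", "LU_FSH", "LU_W", "LU_other")]), 100 + 1e-9)

  expect_identical(generate_catchments(50, seed = 3), generate_catchments(50, seed = 3))
  expect_error(generate_catchments(0), "n")
})

test_that("daily climate is calendar-complete with sensible degenerate limits", {
  sp <- make_spec()
  cl <- generate_daily_climate(sp, 2001, seed = 3)
  expect_equal(nrow(cl$precip), 365)
  expect_equal(nrow(cl$temp), 12)
  leap <- generate_daily_climate(sp, 2000, seed = 3)
  expect_equal(nrow(leap$precip), 366)

  dry <- generate_daily_climate(make_spec(p_wet = 0), 2001:2003, seed = 3)
  expect_true(all(dry$precip$mm == 0))

  expect_error(generate_daily_climate(sp, integer(0)), "non-empty")
  expect_identical(generate_daily_climate(sp, 2001:2005, seed = 9),
                   generate_daily_climate(sp, 2001:2005, seed = 9))
})

test_that("simulated mean annual precipitation matches the configured target", {
  sp <- make_spec(p_mean = 1200, p_wet = 0.4, p_shape = 0.9)
  cl <- generate_daily_climate(sp, 1951:2050, seed = 5)
  annual <- tapply(cl$precip$mm, format(cl$precip$date, "%Y"), sum)
  se <- sd(annual) / sqrt(length(annual))
  expect_lt(abs(mean(annual) - 1200), 3 * se)
})

test_that("surplus satisfies budget closure, flooring, and AR(1) persistence", {
  sp <- make_spec(LU_C = 40)
  sur <- generate_surplus(sp, 1990:2010, seed = 2)
  assembled <- with(sur, dep + fert + fix + man + hum - crop)
  expect_equal(sur$n_surplus, pmax(assembled, 1), tolerance = 1e-12)

  floored <- generate_surplus(sp, 1990:2010, seed = 2,
                              config = gen_config(surplus_floor = 200))
  expect_true(all(floored$n_surplus >= 200))

  long <- generate_surplus(sp, 1001:2000, seed = 4,
                           config = gen_config(surplus_phi = 0.9))
  r1 <- acf(long$fert, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1 - 0.9), 0.05)
})

test_that("loading is exactly the configured response when noise-free", {
  rec <- make_covariates(200)
  cfg0 <- gen_config(sigma = 0)
  out <- generate_loading(rec, seed = 1, config = cfg0)
  tr <- attr(out, "truth")
  expect_equal(log(out$Q_TN), tr$eta, tolerance = 1e-12)

  # unit elasticity: doubling current-year surplus doubles the load
  cfg1 <- gen_config(sigma = 0, elast_surplus = 1, elast_lag = 0)
  q1 <- generate_loading(rec, seed = 1, config = cfg1)$Q_TN
  rec2 <- rec; rec2$ln_Nsurplus <- log(2 * exp(rec$ln_Nsurplus))
  q2 <- generate_loading(rec2, seed = 1, config = cfg1)$Q_TN
  expect_equal(q2 / q1, rep(2, nrow(rec)), tolerance = 1e-10)

  expect_error(generate_loading(rec[, -match("T_annual", names(rec))]), "T_annual")
})

test_that("log-scale residual variance matches the configured sigma^2", {
  rec <- make_covariates(10000, seed = 3)
  out <- generate_loading(rec, seed = 5, config = gen_config(sigma = 0.5))
  resid <- log(out$Q_TN) - attr(out, "truth")$eta
  # var of a variance estimate: 2 sigma^4 / n
  se <- sqrt(2 * 0.25^2 / 10000)
  expect_lt(abs(var(resid) - 0.25), 4 * se)
})

test_that("generative average sensitivities equal configured targets", {
  rec <- make_covariates(10000, seed = 9)
  cfg <- gen_config(sigma = 0)
  out <- generate_loading(rec, seed = 1, config = cfg)
  fd_sens <- function(v) {
    up <- rec; up[[v]] <- rec[[v]] + 1
    dn <- rec; dn[[v]] <- rec[[v]] - 1
    qu <- generate_loading(up, seed = 1, config = cfg)$Q_TN
    qd <- generate_loading(dn, seed = 1, config = cfg)$Q_TN
    mean(100 * (log(qu) - log(qd)) / 2)
  }
  # linear terms: exact (the precipitation amplitude cancels)
  expect_equal(fd_sens("T_annual"), -6.4, tolerance = 1e-8)
  expect_equal(fd_sens("P_MAM95"), 0.12, tolerance = 1e-8)
  # saturating precipitation: finite-difference the response curve directly
  # at the amplitude calibrated for this sample
  A <- attr(out, "truth")$A
  f <- function(P) A * (1 - exp(-P / 800))
  expect_equal(mean(100 * (f(rec$P_annual + 1) - f(rec$P_annual - 1)) / 2),
               0.17, tolerance = 0.02 * 0.17)
})

test_that("generated loads are conditionally lognormal", {
  rec <- make_covariates(2000, seed = 13)
  out <- generate_loading(rec, seed = 2, config = gen_config(sigma = 0.4))
  z <- log(out$Q_TN) - attr(out, "truth")$eta
  expect_gt(shapiro.test(z)$p.value, 0.01)
})

test_that("ensemble members carry the prescribed biases and structure", {
  sp <- make_spec()
  cfg <- gen_config(hist_years = 1975:2014, future_years = 2015:2060)
  ens <- generate_ensemble(sp, scenarios = c("ssp126", "ssp585"), n_members = 3,
                           seed = 21, config = cfg)
  expect_length(ens, 6)
  yrs <- sort(unique(ens[[1]]$series$temp$year))
  expect_equal(range(yrs), c(1975, 2060))
  # truth twin shares weather noise: temperature differs by exactly the bias
  for (m in ens) {
    dT <- m$series$temp$degC - m$truth$temp$degC
    expect_equal(unique(round(dT, 9)), round(m$temp_bias, 9))
  }
  expect_error(generate_ensemble(sp, "ssp126", n_members = 1), "members")
  expect_error(generate_ensemble(sp, "rcp85", n_members = 4), "scenario")
})

test_that("full simulated table is reproducible and schema-complete", {
  a <- simulate_catchment_years(6, 2000:2006, seed = 3)
  b <- simulate_catchment_years(6, 2000:2006, seed = 3)
  expect_identical(a, b)
  expect_named(a, c("catchment_id", "year", "Q_TN", "P_annual", "P_MAM95",
                    "T_annual", "ln_Nsurplus", "ln_Nsurplus_lag12",
                    "LU_D", "LU_C", "LU_FSH", "L_TD"))
  expect_true(all(a$Q_TN > 0))
  expect_true(all(a$P_annual >= a$P_MAM95))
})
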