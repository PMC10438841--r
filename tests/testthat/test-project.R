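# Covariate derivation, projection, effect decomposition, ensemble
# statistics, and regional aggregation.

# hand-built climate series: given MAM daily values in one year
toy_series <- function(mam_values, year = 2001) {
  dates <- seq(as.Date(paste0(year, "-01-01")), as.Date(paste0(year, "-12-31")),
               by = "day")
  mm <- rep(0, length(dates))
  idx <- which(format(dates, "%m") == "04")[seq_along(mam_values)]
  mm[idx] <- mam_values
  structure(list(watershed_id = "toy",
                 precip = data.frame(date = dates, mm = mm),
                 temp = data.frame(year = year, month = 1:12, degC = 10)),
            class = "climate_series")
}

test_that("covariates follow the sum-of-exceeding-days convention", {
  s <- toy_series(c(10, 96, 100))
  cov <- derive_covariates(s, threshold = 95)
  expect_equal(cov$P_MAM95, 196)          # full amounts of days above 95 mm
  expect_equal(cov$P_annual, 206)
  expect_equal(cov$T_annual, 10)

  cov0 <- derive_covariates(toy_series(c(10, 20, 30)), threshold = 95)
  expect_equal(cov0$P_MAM95, 0)
})

test_that("the extreme threshold is the reference 95th wet-day percentile", {
  s <- generate_daily_climate(make_spec(), 1981:2012, seed = 41)
  cov <- derive_covariates(s, ref_years = 1981:2010)
  yr <- as.integer(format(s$precip$date, "%Y"))
  wet <- s$precip$mm[yr <= 2010 & s$precip$mm > 0.1]
  expect_equal(attr(cov, "threshold"),
               unname(quantile(wet, 0.95, type = 7)))
  expect_equal(cov$year, 1981:2012)
})

test_that("incomplete years are dropped with a message", {
  s <- toy_series(c(1, 2, 3))
  s$precip <- s$precip[-5, ]
  expect_message(cov <- derive_covariates(s, threshold = 95), "incomplete")
  expect_equal(nrow(cov), 0)
})

pins_from <- function(tab) {
  as.list(vapply(c("ln_Nsurplus", "ln_Nsurplus_lag12", "LU_D", "LU_C",
                   "LU_FSH", "L_TD"), function(v) median(tab[[v]]), numeric(1)))
}

test_that("identical climate gives zero change; warming gives the fitted response", {
  pins <- pins_from(tt_tab)
  clim <- data.frame(year = 1:60,
                     P_annual = rep(median(tt_tab$P_annual), 60),
                     P_MAM95 = rep(median(tt_tab$P_MAM95), 60),
                     T_annual = rep(median(tt_tab$T_annual), 60))
  expect_equal(project_member(tt_fit, clim, 1:30, 31:60, pins), 0, tolerance = 1e-12)

  warm <- clim
  warm$T_annual[31:60] <- warm$T_annual[31:60] + 1
  dq <- project_member(tt_fit, warm, 1:30, 31:60, pins)
  expect_lt(dq, -5)                      # ~ -6 % per degree of warming
  expect_gt(dq, -8)

  # invariance to load units
  tab_t <- tt_tab; tab_t$Q_TN <- tab_t$Q_TN / 1000
  fit_t <- nload_gam(tab_t, lambda = tt_fit$lambda)
  expect_equal(project_member(fit_t, warm, 1:30, 31:60, pins), dq, tolerance = 1e-6)
})

test_that("P/T decomposition multiplies exactly for single-year windows", {
  pins <- pins_from(tt_tab)
  clim <- data.frame(year = 1:2,
                     P_annual = c(900, 1100), P_MAM95 = c(40, 80),
                     T_annual = c(10, 12))
  d <- decompose_effects(tt_fit, clim, 1, 2, pins)
  expect_equal(1 + d[["combined"]] / 100,
               (1 + d[["P_only"]] / 100) * (1 + d[["T_only"]] / 100),
               tolerance = 1e-10)

  # +10 % / -10 % compose to about -1 %
  expect_equal(100 * (1.1 * 0.9 - 1), -1, tolerance = 1e-10)

  # 30-y windows: identity within 1 % absolute
  set.seed(42)
  clim30 <- data.frame(year = 1:60,
                       P_annual = runif(60, 800, 1300),
                       P_MAM95 = runif(60, 20, 120),
                       T_annual = runif(60, 8, 14) + c(rep(0, 30), rep(1.5, 30)))
  d30 <- decompose_effects(tt_fit, clim30, 1:30, 31:60, pins)
  lhs <- 1 + d30[["combined"]] / 100
  rhs <- (1 + d30[["P_only"]] / 100) * (1 + d30[["T_only"]] / 100)
  expect_lt(abs(lhs - rhs), 0.01)
})

test_that("agreement flags and tradeoff classes match hand counts", {
  mk <- function(signs) data.frame(member = seq_along(signs),
                                   combined = signs * (10 + seq_along(signs)),
                                   P_only = 5, T_only = -8)
  # 13 of 16 share the (negative) median sign: robust
  s13 <- ensemble_stats(mk(c(rep(-1, 13), rep(1, 3))))
  expect_equal(s13$agreement, 13 / 16)
  expect_true(s13$robust)
  expect_equal(s13$class, "offset")      # median P effect positive, net decrease
  # 12 of 16: stippled
  s12 <- ensemble_stats(mk(c(rep(-1, 12), rep(1, 4))))
  expect_equal(s12$agreement, 0.75)
  expect_false(s12$robust)

  # identical members
  same <- data.frame(member = 1:5, combined = 3, P_only = 4, T_only = -1)
  ss <- ensemble_stats(same)
  expect_equal(ss$agreement, 1)
  expect_equal(ss$median_combined, 3)
  expect_equal(ss$class, "net-increase")

  # compound decrease: both medians negative
  cd <- ensemble_stats(data.frame(member = 1:4, combined = c(-5, -6, -4, -7),
                                  P_only = c(-2, -1, -3, -2), T_only = -4))
  expect_equal(cd$class, "compound-decrease")

  # order invariance, and classes are a partition (one class per watershed)
  df <- mk(c(rep(-1, 10), rep(1, 6)))
  perm <- df[sample(nrow(df)), ]
  expect_equal(ensemble_stats(df), ensemble_stats(perm))
  for (s in list(s13, s12, ss, cd))
    expect_true(s$class %in% c("offset", "compound-decrease", "net-increase"))

  expect_error(ensemble_stats(mk(1)), "2 members")
})

test_that("regional aggregation is load-weighted and bounded", {
  # two watersheds, baseline loads 90 and 10, changes -10 % and +10 %
  r <- aggregate_region(matrix(c(-10, 10), nrow = 2), weights = c(90, 10))
  expect_equal(unname(r$member_changes), -8)

  one <- aggregate_region(matrix(c(-3.2), nrow = 1), weights = 5)
  expect_equal(unname(one$member_changes), -3.2)

  set.seed(43)
  ch <- matrix(rnorm(20 * 4, 0, 5), 20, 4)
  w <- runif(20, 1, 100)
  r4 <- aggregate_region(ch, w)
  manual <- sapply(1:4, function(j) {
    fut <- sum(w * (1 + ch[, j] / 100)); 100 * (fut - sum(w)) / sum(w)
  })
  expect_equal(unname(r4$member_changes), manual, tolerance = 1e-12)
  for (j in 1:4) {
    expect_gte(r4$member_changes[j], min(ch[, j]))
    expect_lte(r4$member_changes[j], max(ch[, j]))
  }
  expect_equal(unname(r4$summary["median"]), unname(quantile(r4$member_changes, 0.5, type = 7)))

  expect_error(aggregate_region(ch[0, , drop = FALSE], numeric(0)), "empty")
  expect_error(aggregate_region(ch, rep(-1, 20)), "positive")
})
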