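# Synthetic catchment, climate, nitrogen-surplus, and loading generators.
#
# The generator encodes a known ground truth: annual loads are conditionally
# lognormal around an additive log-link response with a saturating annual
# precipitation effect, a linear springtime-extreme-precipitation effect, a
# log-linear (negative) temperature effect, elasticities on current and
# lagged log N surplus, and linear land-use terms.  Every downstream stage
# (fitting, selection, sensitivity extraction, bias correction, projection,
# Q10, Monte-Carlo) can therefore be validated against configured truth.

#' Generator configuration
#'
#' Returns the default configuration of the synthetic-data generator.  The
#' defaults define the study conditions: 258 catchments observed 1981--2017,
#' residual standard deviation 0.5 on the log scale, and a log-link response
#' calibrated so that the average relative sensitivities of loading over the
#' generated covariate distribution equal 0.17 %/mm (annual precipitation,
#' saturating above ~1,500 mm), 0.12 %/mm (springtime extreme
#' precipitation), and -6.4 %/degree C (annual temperature).
#'
#' @param ... named overrides of individual defaults.
#' @return A list of generator settings with class `"gen_config"`.
#' @details Key entries:
#' \describe{
#'   \item{sens_P, sens_E, sens_T}{target average relative sensitivities in
#'     % per mm / % per degree C; the precipitation amplitude is calibrated
#'     on the generated covariate sample so its record-averaged
#'     finite-difference sensitivity equals `sens_P` exactly.}
#'   \item{P_sat}{e-folding scale (mm) of the asymptotic-exponential
#'     precipitation response; 800 mm makes the marginal effect fall to
#'     ~15 % of its low-precipitation value by 1,500 mm.}
#'   \item{sigma}{residual SD of ln load (lognormal scatter).}
#'   \item{surplus_floor}{lower floor (kg N ha-1 yr-1) applied to assembled
#'     N surplus so its log is defined.}
#'   \item{wet_threshold}{wet-day threshold in mm (0.1).}
#'   \item{ens_precip_sdlog, ens_temp_sd}{ensemble member bias spread:
#'     multiplicative lognormal for precipitation, additive normal (deg C)
#'     for temperature.}
#'   \item{scenarios}{per-scenario late-century (2070--2099 vs 1988--2017)
#'     warming (deg C) and relative wet-day-mean precipitation change.}
#' }
#' @export
#' @examples
#' cfg <- gen_config(sigma = 0.3)
#' cfg$sigma
gen_config <- function(...) {
  cfg <- list(
    n_catchments   = 258L,
    years          = 1981:2017,
    ref_years      = 1981:2010,
    sigma          = 0.5,
    # log-link response
    intercept      = 6.0,
    sens_P         = 0.17,     # % per mm, average over generated records
    sens_E         = 0.12,     # % per mm (linear)
    sens_T         = -6.4,     # % per deg C (linear)
    P_sat          = 800,      # mm, saturation e-folding scale
    elast_surplus  = 0.8,      # elasticity on ln N surplus (current year)
    elast_lag      = 0.3,      # elasticity on ln N surplus (prev. 2 years)
    slope_LU_D     = 0.020,    # per percent developed
    slope_LU_C     = 0.010,    # per percent cultivated
    slope_LU_FSH   = 0.005,    # per percent forest+shrub
    slope_L_TD     = 0.010,    # per percent tile-drained
    # surplus component model
    surplus_phi    = 0.7,      # AR(1) coefficient of each component
    surplus_cv     = 0.15,     # stationary CV of each component
    surplus_floor  = 1,        # kg N ha-1 yr-1
    # daily climate model
    wet_threshold  = 0.1,      # mm
    wet_persist    = 0.3,      # p(wet|wet) - p(wet|dry)
    temp_month_sd  = 1.5,      # deg C monthly noise
    temp_year_sd   = 0.6,      # deg C shared interannual anomaly
    # ensemble biases and scenario trends
    ens_precip_sdlog = 0.2,
    ens_temp_sd      = 1.5,
    scenarios = list(
      ssp126 = list(dT = 1.8, dP = 0.04),
      ssp245 = list(dT = 3.0, dP = 0.07),
      ssp585 = list(dT = 5.0, dP = 0.12)
    ),
    hist_years   = 1950:2014,
    future_years = 2015:2099
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_invalid("unknown gen_config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$sigma < 0) stop_invalid("sigma must be >= 0")
  class(cfg) <- "gen_config"
  cfg
}

#' Generate synthetic catchment specifications
#'
#' Draws `n` catchments with land-use percentages from a Dirichlet
#' allocation over developed, cultivated, forest+shrub, wetland, and other
#' classes (summing to 100), a tile-drainage percentage positively
#' associated with the cultivated fraction, a lognormal area, and the
#' climate parameters (target mean annual precipitation, wet-day frequency,
#' gamma shape, mean temperature, seasonal amplitude) used by
#' [generate_daily_climate()].
#'
#' @param n number of catchments (>= 1).
#' @param seed integer RNG seed.
#' @param config a [gen_config()] list.
#' @return A data frame with one row per catchment, class `"catchment_spec"`.
#' @export
generate_catchments <- function(n, seed = 1L, config = gen_config()) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop_invalid("'n' must be a single integer >= 1")
  n <- as.integer(n)
  with_seed(child_seed(seed, "catchments"), {
    # Dirichlet via normalized gammas; alphas chosen for a forested/
    # agricultural mix typical of monitored US catchments.
    alpha <- c(dev = 1.2, cult = 2.5, forshr = 3.5, wet = 0.8, other = 1.0)
    g <- matrix(stats::rgamma(n * 5L, shape = rep(alpha, each = n)), nrow = n)
    lu <- 100 * g / rowSums(g)
    spec <- data.frame(
      catchment_id = sprintf("C%03d", seq_len(n)),
      area_km2  = stats::rlnorm(n, log(1000), 0.6),
      LU_D      = lu[, 1L],
      LU_C      = lu[, 2L],
      LU_FSH    = lu[, 3L],
      LU_W      = lu[, 4L],
      LU_other  = lu[, 5L],
      L_TD      = lu[, 2L] * stats::rbeta(n, 2, 4),
      p_mean_mm = pmin(pmax(stats::rlnorm(n, log(1000), 0.25), 450), 2400),
      p_wet     = pmin(pmax(stats::rbeta(n, 8, 16), 0.10), 0.65),
      p_shape   = stats::runif(n, 0.6, 1.1),
      t_mean    = pmin(pmax(stats::rnorm(n, 11, 4.5), 0.5), 21),
      t_amp     = stats::runif(n, 6, 14),
      stringsAsFactors = FALSE
    )
    class(spec) <- c("catchment_spec", "data.frame")
    spec
  })
}

# Scenario ramp: 0 through the baseline midpoint (2003), rising linearly to
# 1 at the late-century midpoint (2085), so the configured dT/dP equal the
# late-century-minus-baseline change in expectation.
scenario_ramp <- function(years) pmin(pmax((years - 2003) / (2085 - 2003), 0), 1)

#' Generate a daily-precipitation / monthly-temperature series
#'
#' Daily precipitation follows a two-state (wet/dry) first-order Markov
#' occurrence process with gamma-distributed wet-day amounts (shifted just
#' above the 0.1 mm wet-day threshold); monthly temperature follows an
#' annual-cycle sinusoid with shared interannual anomalies and monthly
#' noise.  The series is calendar-complete.
#'
#' @param spec one row of a [generate_catchments()] data frame.
#' @param years integer vector of calendar years (non-empty).
#' @param seed integer RNG seed.
#' @param config a [gen_config()] list.
#' @param precip_mult multiplicative bias on wet-day gamma scale (ensemble
#'   members; 1 = unbiased).
#' @param temp_offset additive temperature bias in deg C.
#' @param trend optional list(dT=, dP=) of scenario trends applied through
#'   [scenario_ramp()].
#' @return A `climate_series` object: list with `watershed_id`, `precip`
#'   (data frame `date`, `mm`) and `temp` (data frame `year`, `month`,
#'   `degC`).
#' @export
generate_daily_climate <- function(spec, years, seed = 1L, config = gen_config(),
                                   precip_mult = 1, temp_offset = 0, trend = NULL) {
  if (length(years) < 1L) stop_invalid("'years' must be non-empty")
  years <- sort(as.integer(years))
  spec <- as.list(spec[1L, , drop = FALSE])
  with_seed(child_seed(seed, paste0("climate-", spec$catchment_id)), {
    # occurrence chain: stationary wet probability p_wet with persistence
    r <- config$wet_persist
    p_dw <- spec$p_wet * (1 - r)       # p(wet | dry)
    p_ww <- p_dw + r                   # p(wet | wet)
    dates <- seq(as.Date(paste0(years[1L], "-01-01")),
                 as.Date(paste0(years[length(years)], "-12-31")), by = "day")
    nd <- length(dates)
    u <- stats::runif(nd)
    wet <- logical(nd)
    wet[1L] <- u[1L] < spec$p_wet
    if (spec$p_wet <= 0) {
      wet[] <- FALSE
    } else {
      for (i in 2L:nd) wet[i] <- u[i] < (if (wet[i - 1L]) p_ww else p_dw)
    }
    yr_of_day <- as.integer(format(dates, "%Y"))
    ramp <- if (is.null(trend)) rep(0, nd) else scenario_ramp(yr_of_day)
    dP <- if (is.null(trend)) 0 else trend$dP
    # wet-day mean solves target mean annual precipitation
    base_scale <- max((spec$p_mean_mm / (365.25 * spec$p_wet) - config$wet_threshold) /
                        spec$p_shape, 1e-8)
    mm <- numeric(nd)
    nwet <- sum(wet)
    if (nwet > 0) {
      sc <- base_scale * precip_mult * (1 + dP * ramp[wet])
      mm[wet] <- config$wet_threshold +
        stats::rgamma(nwet, shape = spec$p_shape, scale = sc)
    }
    precip <- data.frame(date = dates, mm = mm)

    ny <- length(years)
    yr_anom <- rep(stats::rnorm(ny, 0, config$temp_year_sd), each = 12L)
    month <- rep(1:12, times = ny)
    yr <- rep(years, each = 12L)
    ramp_m <- if (is.null(trend)) 0 else trend$dT * scenario_ramp(yr)
    degC <- spec$t_mean + yr_anom +
      spec$t_amp * cos(2 * pi * (month - 7) / 12) +
      stats::rnorm(12L * ny, 0, config$temp_month_sd) +
      temp_offset + ramp_m
    temp <- data.frame(year = yr, month = month, degC = degC)
    structure(list(watershed_id = spec$catchment_id, precip = precip, temp = temp),
              class = "climate_series")
  })
}

#' @export
print.climate_series <- function(x, ...) {
  yrs <- range(x$temp$year)
  cat("<climate_series> watershed", x$watershed_id, "years", yrs[1L], "-", yrs[2L],
      "(", nrow(x$precip), "daily precip,", nrow(x$temp), "monthly temp )\n")
  invisible(x)
}

#' Generate an annual nitrogen-surplus series
#'
#' Each budget component (atmospheric deposition, inorganic fertilizer,
#' biological fixation, manure, human waste, crop/livestock uptake) follows
#' a stationary AR(1) process around a land-use-dependent mean; the surplus
#' is assembled as deposition + fertilizer + fixation + manure + human waste
#' - crop uptake and floored at `config$surplus_floor` so its natural log is
#' defined.
#'
#' @inheritParams generate_daily_climate
#' @return A data frame (class `"surplus_series"`) with the six components
#'   (kg N ha-1 yr-1) and the assembled, floored `n_surplus`.
#' @export
generate_surplus <- function(spec, years, seed = 1L, config = gen_config()) {
  if (length(years) < 1L) stop_invalid("'years' must be non-empty")
  years <- sort(as.integer(years))
  spec <- as.list(spec[1L, , drop = FALSE])
  mu <- c(dep  = 8,
          fert = 1.2 * spec$LU_C,
          fix  = 0.4 * spec$LU_C,
          man  = 0.5 * spec$LU_C,
          hum  = 0.8 * spec$LU_D,
          crop = 1.5 * spec$LU_C)
  phi <- config$surplus_phi
  ny <- length(years)
  with_seed(child_seed(seed, paste0("surplus-", spec$catchment_id)), {
    comp <- sapply(names(mu), function(nm) {
      m <- mu[[nm]]
      sd_stat <- config$surplus_cv * max(m, 1e-8)
      x <- numeric(ny)
      x[1L] <- stats::rnorm(1L, m, sd_stat)
      if (ny > 1L) {
        innov <- stats::rnorm(ny - 1L, 0, sd_stat * sqrt(1 - phi^2))
        for (t in 2L:ny) x[t] <- m + phi * (x[t - 1L] - m) + innov[t - 1L]
      }
      pmax(x, 0)
    })
    comp <- matrix(comp, nrow = ny, dimnames = list(NULL, names(mu)))
    surplus_raw <- comp[, "dep"] + comp[, "fert"] + comp[, "fix"] +
      comp[, "man"] + comp[, "hum"] - comp[, "crop"]
    out <- data.frame(catchment_id = spec$catchment_id, year = years, comp,
                      n_surplus = pmax(surplus_raw, config$surplus_floor))
    class(out) <- c("surplus_series", "data.frame")
    out
  })
}

# Noise-free log-link response given assembled covariates and calibrated
# precipitation amplitude A.
response_eta <- function(records, config, A) {
  config$intercept +
    A * (1 - exp(-records$P_annual / config$P_sat)) +
    (config$sens_E / 100) * records$P_MAM95 +
    (config$sens_T / 100) * records$T_annual +
    config$elast_surplus * records$ln_Nsurplus +
    config$elast_lag * records$ln_Nsurplus_lag12 +
    config$slope_LU_D * records$LU_D +
    config$slope_LU_C * records$LU_C +
    config$slope_LU_FSH * records$LU_FSH +
    config$slope_L_TD * records$L_TD
}

#' Attach conditionally lognormal annual loads to covariate records
#'
#' Computes the noise-free additive log-link response and draws
#' `Q_TN = exp(response + N(0, sigma^2))`.  The saturating-precipitation
#' amplitude is calibrated on the supplied records so that the
#' record-averaged central-difference relative sensitivity (h = 1 mm)
#' equals `config$sens_P`; the temperature and extreme-precipitation terms
#' are linear, so their average relative sensitivities equal `config$sens_T`
#' and `config$sens_E` by construction.
#'
#' @param records data frame containing the nine model covariates (see
#'   [read_catchment_table()] for the schema) without `Q_TN`.
#' @param seed integer RNG seed.
#' @param config a [gen_config()] list.
#' @return `records` with a `Q_TN` column (kg N yr-1); the generative truth
#'   (coefficients, amplitude, noise-free response `eta`) is attached as
#'   attribute `"truth"`.
#' @export
generate_loading <- function(records, seed = 1L, config = gen_config()) {
  needed <- setdiff(MODEL_COVARIATES, names(records))
  if (length(needed))
    stop_invalid("records are missing covariates: ", paste(needed, collapse = ", "))
  P <- records$P_annual
  # average central-difference relative slope of A*(1-exp(-P/P_sat)) with
  # h = 1 equals 100 * A * sinh(1/P_sat) * mean(exp(-P/P_sat))
  A <- (config$sens_P / 100) / (sinh(1 / config$P_sat) * mean(exp(-P / config$P_sat)))
  eta <- response_eta(records, config, A)
  out <- records
  out$Q_TN <- with_seed(child_seed(seed, "loading"),
                        exp(eta + stats::rnorm(nrow(records), 0, config$sigma)))
  attr(out, "truth") <- list(
    A = A, eta = eta, sigma = config$sigma,
    sens_P = config$sens_P, sens_E = config$sens_E, sens_T = config$sens_T,
    coef = c(intercept = config$intercept,
             P_MAM95 = config$sens_E / 100, T_annual = config$sens_T / 100,
             ln_Nsurplus = config$elast_surplus,
             ln_Nsurplus_lag12 = config$elast_lag,
             LU_D = config$slope_LU_D, LU_C = config$slope_LU_C,
             LU_FSH = config$slope_LU_FSH, L_TD = config$slope_L_TD)
  )
  out
}

#' Generate a biased "GCM" ensemble for one watershed
#'
#' Each member re-runs the daily climate generator over the historical
#' (1950--2014) and future (2015--2099) periods with a member-specific
#' multiplicative precipitation bias (lognormal around 1), an additive
#' temperature bias (normal around 0 deg C), and scenario-specific linear
#' trends in wet-day mean precipitation and temperature.  A bias-free twin
#' of every member (same weather noise, neutral biases) is retained as
#' ground truth for bias-correction tests.
#'
#' @param spec one row of a [generate_catchments()] data frame (carries the
#'   observed-climate parameters the members perturb).
#' @param scenarios character vector of scenario tags; must be names of
#'   `config$scenarios`.
#' @param n_members number of ensemble members (>= 2).
#' @param seed integer RNG seed.
#' @param config a [gen_config()] list.
#' @return A list of members (class `"climate_ensemble"`), each a list with
#'   `scenario`, `member`, `series` (biased `climate_series` covering
#'   1950--2099), and `truth` (the bias-free twin).
#' @export
generate_ensemble <- function(spec, scenarios = names(gen_config()$scenarios),
                              n_members = 16L, seed = 1L, config = gen_config()) {
  if (n_members < 2) stop_invalid("'n_members' must be >= 2 (ensemble statistics undefined)")
  unknown <- setdiff(scenarios, names(config$scenarios))
  if (length(unknown)) stop_invalid("unknown scenarios: ", paste(unknown, collapse = ", "))
  years <- c(config$hist_years, config$future_years)
  members <- list()
  for (sc in scenarios) {
    trend <- config$scenarios[[sc]]
    for (m in seq_len(n_members)) {
      bseed <- child_seed(seed, paste0("bias-", sc, "-", m))
      biases <- with_seed(bseed, list(
        pm = stats::rlnorm(1L, 0, config$ens_precip_sdlog),
        tb = stats::rnorm(1L, 0, config$ens_temp_sd)
      ))
      wseed <- child_seed(seed, paste0("weather-", sc, "-", m))
      series <- generate_daily_climate(spec, years, seed = wseed, config = config,
                                       precip_mult = biases$pm,
                                       temp_offset = biases$tb, trend = trend)
      truth <- generate_daily_climate(spec, years, seed = wseed, config = config,
                                      precip_mult = 1, temp_offset = 0, trend = trend)
      members[[length(members) + 1L]] <- list(
        scenario = sc, member = m, precip_bias = biases$pm,
        temp_bias = biases$tb, series = series, truth = truth)
    }
  }
  structure(members, class = "climate_ensemble",
            watershed_id = spec$catchment_id[1L])
}

#' Simulate a complete synthetic catchment-year table
#'
#' Chains the generators: catchment specifications, daily climate, covariate
#' derivation (annual precipitation, springtime extreme precipitation above
#' the reference-period 95th wet-day percentile, annual temperature),
#' nitrogen surplus with the two-year lagged term, and conditionally
#' lognormal loads.
#'
#' @param n_catchments number of catchments.
#' @param years calendar years of the record.
#' @param seed integer RNG seed.
#' @param config a [gen_config()] list.
#' @param keep_climate if `TRUE`, the per-catchment `climate_series` list is
#'   attached as attribute `"climate"`.
#' @return A catchment-year data frame with the 12 canonical columns;
#'   attributes `"specs"` (the catchment table) and `"truth"` (generative
#'   ground truth from [generate_loading()]).
#' @export
#' @examples
#' tab <- simulate_catchment_years(5, 1995:2000, seed = 1)
#' head(tab)
simulate_catchment_years <- function(n_catchments = NULL, years = NULL, seed = 1L,
                                     config = gen_config(), keep_climate = FALSE) {
  n_catchments <- n_catchments %||% config$n_catchments
  years <- years %||% config$years
  specs <- generate_catchments(n_catchments, seed = seed, config = config)
  ref_years <- intersect(config$ref_years, years)
  if (length(ref_years) == 0L) ref_years <- years
  rows <- vector("list", n_catchments)
  climates <- if (keep_climate) vector("list", n_catchments) else NULL
  for (i in seq_len(n_catchments)) {
    sp <- specs[i, , drop = FALSE]
    clim <- generate_daily_climate(sp, years, seed = seed, config = config)
    cov <- derive_covariates(clim, ref_years = ref_years,
                             wet_threshold = config$wet_threshold)
    sur <- generate_surplus(sp, c(min(years) - 2L, min(years) - 1L, years),
                            seed = seed, config = config)
    s <- sur$n_surplus[match(cov$year, sur$year)]
    s1 <- sur$n_surplus[match(cov$year - 1L, sur$year)]
    s2 <- sur$n_surplus[match(cov$year - 2L, sur$year)]
    rows[[i]] <- data.frame(
      catchment_id = sp$catchment_id, year = cov$year,
      P_annual = cov$P_annual, P_MAM95 = cov$P_MAM95, T_annual = cov$T_annual,
      ln_Nsurplus = log(s), ln_Nsurplus_lag12 = log((s1 + s2) / 2),
      LU_D = sp$LU_D, LU_C = sp$LU_C, LU_FSH = sp$LU_FSH, L_TD = sp$L_TD,
      stringsAsFactors = FALSE)
    if (keep_climate) climates[[i]] <- clim
  }
  records <- do.call(rbind, rows)
  records <- generate_loading(records, seed = seed, config = config)
  truth <- attr(records, "truth")
  records <- records[, CATCHMENT_YEAR_COLUMNS]
  attr(records, "truth") <- truth
  attr(records, "specs") <- specs
  if (keep_climate) attr(records, "climate") <- climates
  records
}
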