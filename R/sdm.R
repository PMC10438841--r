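# Scaled distribution mapping (SDM) bias correction of ensemble climate
# series against reference observations: multiplicative, gamma-based for
# daily precipitation; additive, normal-based (per calendar month, with
# linear detrending) for monthly temperature.  The defining contract:
# corrected reference-period distributions match the observations, while
# the model-projected quantile changes (relative for precipitation,
# absolute for temperature) are preserved.

year_of <- function(dates) as.integer(format(dates, "%Y"))

clamp_cdf <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))

fit_gamma_wet <- function(x) {
  # MLE via MASS, with a method-of-moments fallback for degenerate samples
  est <- tryCatch(
    suppressWarnings(MASS::fitdistr(x, "gamma")$estimate),
    error = function(e) NULL)
  if (is.null(est) || !all(is.finite(est))) {
    m <- mean(x); v <- stats::var(x)
    est <- c(shape = m^2 / max(v, 1e-12), rate = m / max(v, 1e-12))
  }
  list(shape = unname(est["shape"]), rate = unname(est["rate"]))
}

# Per-calendar-month normal fit after linear detrending.
fit_monthly_normal <- function(temp) {
  out <- vector("list", 12L)
  for (m in 1:12) {
    sub <- temp[temp$month == m, ]
    v <- sub$degC
    if (length(v) >= 3L && stats::var(sub$year) > 0) {
      tr <- stats::lm.fit(cbind(1, sub$year), v)
      detr <- v - tr$fitted.values + mean(v)
    } else detr <- v
    out[[m]] <- list(mean = mean(detr), sd = max(stats::sd(detr), 1e-8))
  }
  out
}

precip_in_years <- function(series, years) {
  series$precip[year_of(series$precip$date) %in% years, , drop = FALSE]
}

temp_in_years <- function(series, years) {
  series$temp[series$temp$year %in% years, , drop = FALSE]
}

#' Fit a scaled-distribution-mapping bias-correction map
#'
#' Compares the reference-period distributions of an observed and a modeled
#' climate series.  For precipitation the map stores wet-day frequencies
#' and gamma fits to wet-day amounts (wet-day threshold 0.1 mm); for
#' temperature it stores per-calendar-month normal fits to linearly
#' detrended monthly values.  Precipitation maps are multiplicative,
#' temperature maps additive.
#'
#' @param obs observed `climate_series`.
#' @param model modeled `climate_series` for the same watershed.
#' @param ref_years reference period (default 1981--2010); both series must
#'   cover at least 20 of these years.
#' @param kind `"precip"` or `"temp"`.
#' @param wet_threshold wet-day threshold in mm.
#' @return An object of class `"sdm_map"`.
#' @export
fit_sdm <- function(obs, model, ref_years = 1981:2010,
                    kind = c("precip", "temp"), wet_threshold = 0.1) {
  kind <- match.arg(kind)
  for (s in list(obs, model)) {
    cov_years <- if (kind == "precip") unique(year_of(s$precip$date)) else unique(s$temp$year)
    if (length(intersect(cov_years, ref_years)) < 20L)
      stop_invalid("series covers fewer than 20 reference years; distribution fit unreliable")
  }
  if (kind == "precip") {
    fit_one <- function(s) {
      pr <- precip_in_years(s, ref_years)
      mm <- pr$mm
      wet <- mm > wet_threshold
      par <- fit_gamma_wet(mm[wet])
      list(wet_freq = mean(wet), shape = par$shape, rate = par$rate,
           n_wet = sum(wet))
    }
    structure(list(kind = "precip", mode = "multiplicative",
                   ref_years = ref_years, wet_threshold = wet_threshold,
                   obs = fit_one(obs), mod = fit_one(model),
                   watershed_id = obs$watershed_id), class = "sdm_map")
  } else {
    structure(list(kind = "temp", mode = "additive", ref_years = ref_years,
                   obs = fit_monthly_normal(temp_in_years(obs, ref_years)),
                   mod = fit_monthly_normal(temp_in_years(model, ref_years)),
                   watershed_id = obs$watershed_id), class = "sdm_map")
  }
}

#' @export
print.sdm_map <- function(x, ...) {
  cat("<sdm_map>", x$kind, "(", x$mode, ") reference",
      min(x$ref_years), "-", max(x$ref_years), "\n")
  invisible(x)
}

#' Apply an SDM map to a segment of a modeled series
#'
#' Quantile-wise correction: each value is mapped through the observed and
#' modeled reference CDFs, preserving the model-projected quantile change
#' relative to the reference period multiplicatively (precipitation) or
#' additively (temperature).  Wet-day frequency is adjusted toward the
#' observed frequency scaled by the model-projected frequency change; CDF
#' values are clamped to [1/(2n), 1 - 1/(2n)] to avoid infinite tails.
#'
#' @param map an [fit_sdm()] result.
#' @param series modeled `climate_series` to correct.
#' @param segment_years years forming the segment (default: all years in
#'   the series); the segment's own distribution is fitted to measure the
#'   projected change.
#' @return The corrected `climate_series` (only the segment rows for the
#'   corrected variable are modified).
#' @export
apply_sdm <- function(map, series, segment_years = NULL) {
  stopifnot(inherits(map, "sdm_map"))
  out <- series
  if (map$kind == "precip") {
    yrs <- segment_years %||% unique(year_of(series$precip$date))
    sel <- year_of(series$precip$date) %in% yrs
    mm <- series$precip$mm[sel]
    wet <- mm > map$wet_threshold
    n_wet <- sum(wet)
    if (n_wet >= 10L) {
      seg <- fit_gamma_wet(mm[wet])
      f_seg <- mean(wet)
      p <- clamp_cdf(stats::pgamma(mm[wet], shape = seg$shape, rate = seg$rate), n_wet)
      # scaled mapping: each raw value carries the quantile-wise
      # observed/modeled reference ratio, so the model-projected relative
      # change at every quantile is preserved
      q_obs <- stats::qgamma(p, shape = map$obs$shape, rate = map$obs$rate)
      q_ref <- stats::qgamma(p, shape = map$mod$shape, rate = map$mod$rate)
      corrected <- mm[wet] * (q_obs / q_ref)
      # enforce rank preservation (quantile-wise corrections are monotone
      # up to fit noise in the far tails)
      corrected <- sort(corrected)[rank(mm[wet], ties.method = "first")]
      # wet-day frequency: observed frequency scaled by projected change
      target_freq <- map$obs$wet_freq * (f_seg / map$mod$wet_freq)
      target_n <- min(round(length(mm) * target_freq), n_wet)
      if (target_n < n_wet) {
        drop_idx <- order(corrected)[seq_len(n_wet - target_n)]
        corrected[drop_idx] <- 0
      }
      mm[wet] <- pmax(corrected, 0)
      out$precip$mm[sel] <- mm
    }
  } else {
    yrs <- segment_years %||% unique(series$temp$year)
    sel <- series$temp$year %in% yrs
    tseg <- series$temp[sel, ]
    seg_fit <- fit_monthly_normal(tseg)
    corrected <- tseg$degC
    for (m in 1:12) {
      msel <- tseg$month == m
      v <- tseg$degC[msel]
      nm <- sum(msel)
      if (nm < 3L) next
      yr <- tseg$year[msel]
      tr <- if (stats::var(yr) > 0) {
        fitv <- stats::lm.fit(cbind(1, yr), v)$fitted.values
        fitv - mean(fitv)
      } else rep(0, nm)
      detr <- v - tr
      sg <- seg_fit[[m]]
      p <- clamp_cdf(stats::pnorm(detr, sg$mean, sg$sd), nm)
      # additive scaled mapping: raw value plus the quantile-wise
      # observed-minus-modeled reference difference; the segment trend
      # rides through untouched
      corr <- v + (stats::qnorm(p, map$obs[[m]]$mean, map$obs[[m]]$sd) -
                     stats::qnorm(p, map$mod[[m]]$mean, map$mod[[m]]$sd))
      # adjustment is linear in the detrended value for normal fits, so
      # ranks are preserved without further enforcement
      corrected[msel] <- corr
    }
    out$temp$degC[sel] <- corrected
  }
  out
}

#' Bias-correct a climate ensemble
#'
#' Fits precipitation and temperature SDM maps for every member against the
#' observations over the reference period and applies them segment-wise
#' (historical and future).  Members that do not cover the reference period
#' are skipped with a logged reason.
#'
#' @param obs observed `climate_series`.
#' @param members a `climate_ensemble` (or plain list of member lists with
#'   a `series` element, or of bare `climate_series`).
#' @param ref_years reference period.
#' @param segments named list of year vectors corrected separately.
#' @param wet_threshold wet-day threshold in mm.
#' @return A list like `members` where each member gains a `corrected`
#'   `climate_series`; attribute `"skipped"` records members left out.
#' @export
correct_ensemble <- function(obs, members, ref_years = 1981:2010,
                             segments = list(historical = 1950:2014,
                                             future = 2015:2099),
                             wet_threshold = 0.1) {
  out <- vector("list", length(members))
  skipped <- character(0)
  for (i in seq_along(members)) {
    mem <- members[[i]]
    series <- if (inherits(mem, "climate_series")) mem else mem$series
    res <- tryCatch({
      pmap <- fit_sdm(obs, series, ref_years, "precip", wet_threshold)
      tmap <- fit_sdm(obs, series, ref_years, "temp")
      corrected <- series
      for (seg in segments) {
        seg_yrs <- intersect(seg, unique(series$temp$year))
        if (!length(seg_yrs)) next
        corrected <- apply_sdm(pmap, corrected, seg_yrs)
        corrected <- apply_sdm(tmap, corrected, seg_yrs)
      }
      list(corrected = corrected, precip_map = pmap, temp_map = tmap)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, sprintf("member %d: %s", i, conditionMessage(res)))
      out[[i]] <- NULL
      next
    }
    if (inherits(mem, "climate_series")) mem <- list(series = mem)
    mem$corrected <- res$corrected
    mem$precip_map <- res$precip_map
    mem$temp_map <- res$temp_map
    out[[i]] <- mem
  }
  keep <- !vapply(out, is.null, logical(1))
  structure(out[keep], skipped = skipped, class = "corrected_ensemble")
}
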