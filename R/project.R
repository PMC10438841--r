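# Turning climate series into model covariates and fitted-model projections:
# period-averaged median loads, precipitation/temperature effect
# decomposition, ensemble agreement and tradeoff classes, and regional
# aggregation.

#' Analysis period definitions
#'
#' 30-year windows used throughout: reference 1981--2010 (bias correction
#' and extreme-precipitation thresholds), baseline 1988--2017, mid-century
#' 2030--2059, late-century 2070--2099.
#'
#' @param baseline,mid_century,late_century,reference year vectors.
#' @return Named list of year vectors.
#' @export
period_definitions <- function(baseline = 1988:2017, mid_century = 2030:2059,
                               late_century = 2070:2099, reference = 1981:2010) {
  list(reference = reference, baseline = baseline,
       mid_century = mid_century, late_century = late_century)
}

#' Derive model covariates from a climate series
#'
#' Per calendar year: `P_annual` is the sum of daily precipitation,
#' `T_annual` the mean of the 12 monthly temperatures, and `P_MAM95` the
#' total precipitation on March--May days whose amount exceeds the 95th
#' percentile of reference-period wet days (wet = above the 0.1 mm
#' threshold; the full amount of exceeding days is counted, not the excess
#' above the threshold).  Years with incomplete daily or monthly coverage
#' are omitted with a message.
#'
#' @param series a `climate_series`.
#' @param ref_years reference period over which the extreme threshold is
#'   computed (default 1981--2010; intersected with available years).
#' @param wet_threshold wet-day threshold in mm.
#' @param percentile extreme percentile of reference wet days (default
#'   0.95).
#' @param threshold optional pre-computed extreme threshold (mm); when
#'   supplied, `ref_years` is ignored.  Use this to carry the observed
#'   reference threshold into future projections.
#' @return Data frame with `year`, `P_annual`, `P_MAM95`, `T_annual`;
#'   attribute `"threshold"` records the extreme threshold used.
#' @export
derive_covariates <- function(series, ref_years = 1981:2010, wet_threshold = 0.1,
                              percentile = 0.95, threshold = NULL) {
  pr <- series$precip
  yr <- year_of(pr$date)
  if (is.null(threshold)) {
    ref <- intersect(ref_years, unique(yr))
    if (!length(ref)) ref <- unique(yr)
    ref_mm <- pr$mm[yr %in% ref]
    wet <- ref_mm[ref_mm > wet_threshold]
    threshold <- if (length(wet)) quantile7(wet, percentile) else Inf
  }
  mon <- as.integer(format(pr$date, "%m"))
  years <- sort(unique(yr))
  # completeness checks
  days_ok <- tapply(pr$mm, yr, length)[as.character(years)] >= days_in_year(years)
  tm <- series$temp
  months_ok <- tapply(tm$month, tm$year, function(m) length(unique(m)) == 12L)
  months_ok <- months_ok[as.character(years)]
  months_ok[is.na(months_ok)] <- FALSE
  keep <- days_ok & months_ok
  if (any(!keep))
    message("omitting ", sum(!keep), " incomplete year(s): ",
            paste(years[!keep], collapse = ", "))
  years <- years[keep]
  p_annual <- vapply(years, function(y) sum(pr$mm[yr == y]), numeric(1))
  is_mam <- mon %in% 3:5
  p_mam95 <- vapply(years, function(y) {
    v <- pr$mm[yr == y & is_mam]
    sum(v[v > threshold])
  }, numeric(1))
  t_annual <- vapply(years, function(y) mean(tm$degC[tm$year == y]), numeric(1))
  structure(data.frame(year = years, P_annual = p_annual, P_MAM95 = p_mam95,
                       T_annual = t_annual),
            threshold = unname(threshold))
}

# Build a covariate frame for a set of years: climate columns from `clim`
# (a derive_covariates frame), non-climate covariates pinned at `pins`
# (a one-row data frame or named list of current values).
pin_covariates <- function(model, clim, years, pins,
                           override = NULL) {
  sel <- clim$year %in% years
  if (!any(sel)) stop_invalid("no climate covariates available for requested years")
  out <- data.frame(P_annual = clim$P_annual[sel],
                    P_MAM95 = clim$P_MAM95[sel],
                    T_annual = clim$T_annual[sel])
  for (v in setdiff(model$covariates, names(out))) {
    if (is.null(pins[[v]])) stop_invalid("no pinned value supplied for covariate '", v, "'")
    out[[v]] <- pins[[v]]
  }
  if (!is.null(override)) for (v in names(override)) out[[v]] <- override[[v]]
  out
}

#' Project the relative change in period-average median load
#'
#' Computes the period average of yearly median predictions for a baseline
#' and a future window and returns `100 * (future - baseline) / baseline`.
#' Non-climate covariates (N surplus, land use, tile drainage) are pinned
#' at supplied current values.
#'
#' @param model a fitted `nload_gam`.
#' @param clim data frame from [derive_covariates()] covering both windows.
#' @param baseline_years,future_years the two 30-y windows.
#' @param pins named list / one-row data frame of current values for the
#'   non-climate covariates.
#' @param effect `"combined"` (default) uses future precipitation and
#'   temperature; `"P_only"` uses future precipitation with baseline-mean
#'   temperature; `"T_only"` uses future temperature with baseline-mean
#'   precipitation.
#' @return Relative change in percent (scalar).
#' @export
project_member <- function(model, clim, baseline_years, future_years, pins,
                           effect = c("combined", "P_only", "T_only")) {
  effect <- match.arg(effect)
  base_frame <- pin_covariates(model, clim, baseline_years, pins)
  fut_frame <- pin_covariates(model, clim, future_years, pins)
  if (effect == "P_only") {
    fut_frame$T_annual <- mean(base_frame$T_annual)
  } else if (effect == "T_only") {
    fut_frame$P_annual <- mean(base_frame$P_annual)
    fut_frame$P_MAM95 <- mean(base_frame$P_MAM95)
  }
  qb <- mean(as.numeric(predict(model, base_frame, type = "median")))
  qf <- mean(as.numeric(predict(model, fut_frame, type = "median")))
  stopifnot(qb > 0)
  100 * (qf - qb) / qb
}

#' Decompose a projected change into precipitation and temperature effects
#'
#' @inheritParams project_member
#' @return Named numeric vector with `combined`, `P_only`, `T_only`
#'   relative changes (%).  For single-year windows the additive log model
#'   satisfies `(1 + combined/100) = (1 + P_only/100) * (1 + T_only/100)`
#'   exactly; over 30-y averages the identity holds approximately.
#' @export
decompose_effects <- function(model, clim, baseline_years, future_years, pins) {
  c(combined = project_member(model, clim, baseline_years, future_years, pins, "combined"),
    P_only = project_member(model, clim, baseline_years, future_years, pins, "P_only"),
    T_only = project_member(model, clim, baseline_years, future_years, pins, "T_only"))
}

#' Ensemble median, sign agreement, and tradeoff class
#'
#' Given per-member combined / P-only / T-only changes for one watershed,
#' computes the ensemble medians, the fraction of members whose combined
#' change shares the sign of the ensemble median (robust when >= 0.80, the
#' stippling rule), and the tradeoff class: `"offset"` when precipitation
#' alone would increase loading but the combined median decreases,
#' `"compound-decrease"` when both decrease, `"net-increase"` when the
#' combined median increases.
#'
#' @param results data frame with columns `member`, `combined`, `P_only`,
#'   `T_only` (one row per member; >= 2 members).
#' @param agree_frac agreement threshold (default 0.80).
#' @return A one-row data frame with medians, `agreement`, `robust`, and
#'   `class`.
#' @export
ensemble_stats <- function(results, agree_frac = 0.80) {
  if (nrow(results) < 2L) stop_invalid("ensemble statistics need >= 2 members")
  med_c <- stats::median(results$combined)
  med_p <- stats::median(results$P_only)
  med_t <- stats::median(results$T_only)
  agreement <- mean(sign(results$combined) == sign(med_c))
  cls <- if (med_c > 0) "net-increase"
  else if (med_p > 0) "offset"
  else "compound-decrease"
  data.frame(median_combined = med_c, median_P_only = med_p,
             median_T_only = med_t, agreement = agreement,
             robust = agreement >= agree_frac, class = cls,
             stringsAsFactors = FALSE)
}

#' Load-weighted regional change across watersheds
#'
#' Per member, the regional change is the change in total regional loading:
#' `100 * (sum of future loads - sum of baseline loads) / sum of baseline
#' loads`, with watershed baseline loads as weights.
#'
#' @param changes matrix or data frame of relative changes (%) with one row
#'   per watershed and one column per member.
#' @param weights positive baseline loads (one per watershed).
#' @return A list with `member_changes` (regional % change per member) and
#'   `summary` (median and quartiles across members).
#' @export
aggregate_region <- function(changes, weights) {
  changes <- as.matrix(changes)
  if (nrow(changes) == 0L) stop_invalid("empty region")
  if (length(weights) != nrow(changes)) stop_invalid("one weight per watershed required")
  if (any(weights <= 0)) stop_invalid("weights must be positive")
  member_changes <- apply(changes, 2L, function(dq)
    100 * (sum(weights * (1 + dq / 100)) - sum(weights)) / sum(weights))
  list(member_changes = member_changes,
       summary = stats::setNames(quantile7(member_changes, c(0.25, 0.5, 0.75)),
                                 c("q25", "median", "q75")))
}
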