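# Conversion of the fitted watershed-scale temperature response into an
# equivalent denitrification Q10.  Nitrogen losses are taken as surplus
# minus riverine loading (all losses attributed to denitrification), with
# loading converted to an areal yield so the two are commensurate.

#' Nitrogen-loss curve over temperature
#'
#' Evaluates the median load prediction along a temperature grid (default
#' -2 to 24 deg C, step 0.5) with all other covariates held at their
#' training medians, converts it to a yield (kg N ha-1 yr-1) using the
#' catchment area, and returns the loss `L(t) = surplus_median - yield(t)`.
#'
#' @param model a fitted `nload_gam` with `T_annual` among its covariates.
#' @param surplus_median median N surplus of the training data
#'   (kg N ha-1 yr-1).
#' @param area_ha representative catchment area in hectares used to convert
#'   the predicted load (kg N yr-1) to a yield.
#' @param t_grid temperature grid in deg C.
#' @return Data frame of class `"loss_curve"` with `t`, `yield`, `loss`.
#'   Refuses (error) if any loss on the grid is non-positive.
#' @export
loss_curve <- function(model, surplus_median, area_ha,
                       t_grid = seq(-2, 24, by = 0.5)) {
  if (!"T_annual" %in% model$covariates)
    stop_invalid("model has no 'T_annual' covariate")
  probs <- model$percentile_probs
  med <- as.data.frame(lapply(model$percentiles, function(q)
    q[which.min(abs(probs - 0.5))]))
  at <- med[rep(1L, length(t_grid)), , drop = FALSE]
  at$T_annual <- t_grid
  q <- as.numeric(predict(model, at, type = "median"))
  yield <- q / area_ha
  loss <- surplus_median - yield
  if (any(loss <= 0))
    stop_invalid("non-positive nitrogen losses on the temperature grid ",
                 "(min loss = ", signif(min(loss), 4),
                 " kg N ha-1 yr-1); the loss ratio is undefined")
  structure(data.frame(t = t_grid, yield = yield, loss = loss),
            class = c("loss_curve", "data.frame"))
}

loss_at <- function(curve, t) {
  stats::approx(curve$t, curve$loss, xout = t, rule = 1)$y
}

#' Q10 at a single temperature
#'
#' `Q10(t) = L(t + 5) / L(t - 5)` for `t` in \[3, 19\] deg C.
#'
#' @param curve a [loss_curve()].
#' @param t temperature(s) in deg C, each in \[3, 19\].
#' @return Q10 value(s).
#' @export
q10_at <- function(curve, t) {
  if (any(t < 3 | t > 19)) stop_invalid("'t' must lie in [3, 19] deg C")
  loss_at(curve, t + 5) / loss_at(curve, t - 5)
}

#' Temperature-pdf-weighted Q10 estimate
#'
#' Averages `Q10(t)` over `t` in \[3, 19\] with weights from a histogram
#' density estimate (1 deg C bins) of the training annual temperatures,
#' using trapezoid-rule quadrature on a 0.5 deg C grid.  The uncertainty
#' range is reported as `(Q10(19), Q10(3))`, the two grid extremes.
#'
#' @param curve a [loss_curve()].
#' @param temps observed annual temperatures of the training data.
#' @param t_step quadrature step in deg C.
#' @return A list of class `"q10_estimate"`: `mean`, `range` (at 19 and
#'   3 deg C), and the evaluation grid with weights.
#' @export
weighted_q10 <- function(curve, temps, t_step = 0.5) {
  if (!length(temps)) stop_invalid("'temps' must be non-empty")
  tg <- seq(3, 19, by = t_step)
  q <- q10_at(curve, tg)
  if (diff(range(temps)) == 0) {
    # degenerate point-mass sample
    t0 <- temps[1L]
    if (t0 < 3 || t0 > 19)
      stop_invalid("temperature density is zero everywhere on [3, 19]")
    est <- q10_at(curve, t0)
    w <- as.numeric(abs(tg - t0) == min(abs(tg - t0)))
  } else {
    breaks <- seq(floor(min(temps)) , ceiling(max(temps)), by = 1)
    h <- graphics::hist(temps, breaks = breaks, plot = FALSE)
    dens <- stats::approx(h$mids, h$density, xout = tg, rule = 1)$y
    dens[is.na(dens)] <- 0
    if (all(dens <= 0))
      stop_invalid("temperature density is zero everywhere on [3, 19]")
    w <- dens
    trapz <- function(y) sum(diff(tg) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    est <- trapz(w * q) / trapz(w)
  }
  structure(list(mean = est, range = c(q10_19C = q10_at(curve, 19),
                                       q10_3C = q10_at(curve, 3)),
                 grid = data.frame(t = tg, q10 = q, weight = w)),
            class = "q10_estimate")
}

#' @export
print.q10_estimate <- function(x, ...) {
  cat(sprintf("Q10 = %.3f  (Q10 at 19 degC = %.3f, at 3 degC = %.3f)\n",
              x$mean, x$range[1L], x$range[2L]))
  invisible(x)
}
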