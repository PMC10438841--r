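# Local-slope and range-averaged sensitivities of predicted loading to the
# climate covariates, on relative (% per unit) and absolute (load per unit)
# scales.
#
# Relative slope is the central finite difference of 100 * ln(median
# prediction) with step h = 1 unit (1 mm or 1 deg C), so that for a linear
# log-link term with coefficient beta the relative slope is exactly
# 100 * beta; the absolute slope is the corresponding finite difference of
# the median prediction itself.

#' Local sensitivity of predicted loading to one covariate
#'
#' Central finite difference (step `h`, default 1 unit) of the median
#' prediction (absolute scale, load units per covariate unit) or of
#' `100 * ln(median)` (relative scale, % per covariate unit), with all
#' other covariates held at the values supplied in `at`.
#'
#' @param model a fitted `nload_gam`.
#' @param covariate covariate name.
#' @param at data frame of full covariate rows at which to evaluate.
#' @param scale `"relative"` (% per unit) or `"absolute"` (load per unit).
#' @param h finite-difference step in covariate units.
#' @return Numeric vector of slopes (one per row of `at`); rows whose
#'   covariates fall outside the training range carry attribute
#'   `"extrapolated"`.
#' @export
local_slope <- function(model, covariate, at, scale = c("relative", "absolute"),
                        h = 1) {
  scale <- match.arg(scale)
  if (!covariate %in% model$covariates)
    stop_invalid("'", covariate, "' is not a model covariate")
  up <- at; up[[covariate]] <- at[[covariate]] + h
  dn <- at; dn[[covariate]] <- at[[covariate]] - h
  pu <- predict(model, up, type = "median")
  pd <- predict(model, dn, type = "median")
  slope <- if (scale == "relative") {
    100 * (log(as.numeric(pu)) - log(as.numeric(pd))) / (2 * h)
  } else {
    (as.numeric(pu) - as.numeric(pd)) / (2 * h)
  }
  ex <- attr(pu, "extrapolated") %||% attr(pd, "extrapolated")
  if (!is.null(ex)) attr(slope, "extrapolated") <- ex
  slope
}

#' Training-distribution-averaged relative sensitivity
#'
#' Evaluates the relative local slope at every training record (each record
#' conditions the remaining covariates at its own values) and averages with
#' uniform weights over records.  The min--max range across the evaluated
#' baselines is reported alongside.
#'
#' @param model a fitted `nload_gam` (must carry its training frame).
#' @param covariate covariate name.
#' @param h finite-difference step.
#' @return A list with `average`, `range` (c(min, max)), and the per-record
#'   `slopes`, all in % per covariate unit.
#' @export
average_sensitivity <- function(model, covariate, h = 1) {
  if (is.null(model$data) || !nrow(model$data))
    stop_invalid("model carries no training frame")
  slopes <- local_slope(model, covariate, model$data, scale = "relative", h = h)
  list(average = mean(slopes), range = range(slopes), slopes = as.numeric(slopes))
}

#' Sensitivity curve along a conditioning covariate
#'
#' Absolute-scale local slope of `target`, evaluated with the target pinned
#' at chosen percentiles of its training distribution, along a grid of a
#' conditioning covariate; all remaining covariates are held at their
#' training medians.  For the additive log-link model this reproduces the
#' characteristic cross-dependencies: the absolute temperature sensitivity
#' grows with precipitation (larger predicted loads) while the absolute
#' precipitation sensitivity falls as temperature rises.
#'
#' @param model a fitted `nload_gam`.
#' @param target covariate whose slope is computed.
#' @param along conditioning covariate spanning the grid.
#' @param pin_probs percentiles (0--1) at which `target` is pinned
#'   (default 0.5 and 0.95).
#' @param grid_length number of grid points over the training range of
#'   `along`.
#' @param scale slope scale, as in [local_slope()].
#' @return A data frame of class `"sensitivity_curve"` with columns
#'   `along`, `value` (grid value), `pin_prob`, `pin_value`, `slope`.
#' @export
sensitivity_curve <- function(model, target, along, pin_probs = c(0.5, 0.95),
                              grid_length = 50L, scale = "absolute") {
  for (v in c(target, along)) {
    if (!v %in% model$covariates) stop_invalid("'", v, "' is not a model covariate")
  }
  probs <- model$percentile_probs
  med_row <- as.data.frame(lapply(model$percentiles, function(q)
    q[which.min(abs(probs - 0.5))]))
  rng <- range(model$percentiles[[along]])
  grid <- seq(rng[1L], rng[2L], length.out = grid_length)
  out <- list()
  for (pp in pin_probs) {
    pin <- model$percentiles[[target]][which.min(abs(probs - pp))]
    at <- med_row[rep(1L, grid_length), , drop = FALSE]
    at[[along]] <- grid
    at[[target]] <- pin
    sl <- local_slope(model, target, at, scale = scale)
    out[[length(out) + 1L]] <- data.frame(
      along = along, value = grid, pin_prob = pp, pin_value = pin,
      slope = as.numeric(sl), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "target") <- target
  attr(res, "scale") <- scale
  class(res) <- c("sensitivity_curve", "data.frame")
  res
}

#' @export
plot.sensitivity_curve <- function(x, ...) {
  pins <- unique(x$pin_prob)
  graphics::plot(range(x$value), range(x$slope), type = "n",
                 xlab = x$along[1L],
                 ylab = paste0(attr(x, "scale"), " slope of ", attr(x, "target")), ...)
  for (i in seq_along(pins)) {
    sub <- x[x$pin_prob == pins[i], ]
    graphics::lines(sub$value, sub$slope, lty = i)
  }
  graphics::legend("topleft", lty = seq_along(pins),
                   legend = sprintf("target @ p%g", 100 * pins), bty = "n")
  invisible(x)
}
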