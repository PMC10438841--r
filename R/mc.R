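# Monte-Carlo propagation of residual (conditional-lognormal) model
# uncertainty into regional load aggregates.

#' Sample loads from the conditional lognormal distribution
#'
#' Draws `load = median * exp(sigma * z)` with `z ~ N(0, 1)`, independent
#' across watersheds/years and draws.  With `sigma2 = 0` every draw equals
#' the median.
#'
#' @param medians vector of strictly positive median predictions.
#' @param sigma2 residual variance of ln load (the fitted model's single
#'   scale parameter).
#' @param n_draws number of Monte-Carlo repetitions (default 1000).
#' @param seed integer seed; the full draw tensor is reproducible.
#' @return A `length(medians) x n_draws` matrix of sampled loads.
#' @export
sample_loads <- function(medians, sigma2, n_draws = 1000L, seed = 1L) {
  if (any(medians <= 0)) stop_invalid("medians must be strictly positive")
  if (length(sigma2) != 1L || is.na(sigma2) || sigma2 < 0)
    stop_invalid("sigma2 must be a single value >= 0")
  if (n_draws < 1L) stop_invalid("n_draws must be >= 1")
  m <- length(medians)
  with_seed(child_seed(seed, "mc-draws"), {
    z <- matrix(stats::rnorm(m * n_draws), m, n_draws)
    medians * exp(sqrt(sigma2) * z)
  })
}

#' Regional change distribution across Monte-Carlo draws
#'
#' For each draw, baseline and future loads are sampled around their median
#' predictions and the regional change is recomputed as the change in total
#' regional loading; the result is the distribution of regional change over
#' draws.
#'
#' @param baseline_medians,future_medians vectors of median loads per
#'   watershed (same region, same order).
#' @param sigma2 residual variance of ln load.
#' @param n_draws number of repetitions.
#' @param seed integer seed.
#' @return A list with `draws` (regional % change per draw) and `summary`
#'   (quantiles q05, q25, median, q75, q95).
#' @export
aggregate_draws <- function(baseline_medians, future_medians, sigma2,
                            n_draws = 1000L, seed = 1L) {
  if (length(baseline_medians) != length(future_medians))
    stop_invalid("baseline and future medians must align per watershed")
  b <- sample_loads(baseline_medians, sigma2, n_draws, seed = child_seed(seed, "base"))
  f <- sample_loads(future_medians, sigma2, n_draws, seed = child_seed(seed, "future"))
  tot_b <- colSums(b)
  tot_f <- colSums(f)
  draws <- 100 * (tot_f - tot_b) / tot_b
  list(draws = draws,
       summary = stats::setNames(quantile7(draws, c(0.05, 0.25, 0.5, 0.75, 0.95)),
                                 c("q05", "q25", "median", "q75", "q95")))
}
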