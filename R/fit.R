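# Penalized-least-squares fit of the additive load model with GCV-selected
# smoothing parameters, effective degrees of freedom, and BIC.

# Solve the penalized normal equations at fixed smoothing parameters and
# return coefficients, per-column influence diagonals, RSS and GCV.
fit_penalized <- function(X, y, penalties, lambda) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  A <- XtX
  if (length(penalties)) {
    for (j in seq_along(penalties)) A <- A + lambda[[j]] * penalties[[j]]
  }
  R <- tryCatch(chol(A), error = function(e)
    stop_invalid("singular penalized system (p = ", p, ", n = ", n,
                 "); check for collinear or constant covariates"))
  beta <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  # edf_j = diag[(X'X + S)^{-1} X'X]
  Ainv_XtX <- backsolve(R, forwardsolve(t(R), XtX))
  infl <- diag(Ainv_XtX)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  edf <- sum(infl)
  list(beta = drop(beta), fitted = fitted, rss = rss, infl = infl,
       edf = edf, gcv = n * rss / (n - edf)^2)
}

select_lambda_gcv <- function(X, y, penalties) {
  ns <- length(penalties)
  # penalties are scale-dependent; normalize the search window per smooth
  # by the ratio of design and penalty magnitudes
  ref <- vapply(penalties, function(S) {
    sum(diag(crossprod(X))) / max(sum(diag(S)), .Machine$double.xmin)
  }, numeric(1))
  lo <- log(ref) - 12; hi <- log(ref) + 14
  obj <- function(loglam) {
    loglam <- pmin(pmax(loglam, lo), hi)
    fit_penalized(X, y, penalties, exp(loglam))$gcv
  }
  if (ns == 1L) {
    opt <- stats::optimize(obj, interval = c(lo, hi))
    return(exp(pmin(pmax(opt$minimum, lo), hi)))
  }
  starts <- list(log(ref), log(ref) + 6, log(ref) - 6)
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-9))
    if (is.null(best) || o$value < best$value) best <- o
  }
  exp(pmin(pmax(best$par, lo), hi))
}

#' Fit a penalized-spline additive model to log annual nitrogen loads
#'
#' Fits `ln(Q_TN) = intercept + sum of term effects + e`, `e ~ N(0, sigma^2)`
#' by penalized least squares.  Smoothing parameters are chosen by
#' generalized cross-validation unless supplied.  The exponential
#' back-transform of the linear predictor is the *median* of the
#' conditionally lognormal load, available through
#' [predict.nload_gam()] / [predict_median()].
#'
#' @param data catchment-year data frame with a strictly positive `Q_TN`
#'   column and all term covariates.
#' @param terms list of [term_smooth()] / [term_linear()] specifications
#'   (default: the nine-covariate model of [default_terms()]).
#' @param lambda optional fixed smoothing parameters (one per smooth, in
#'   term order or named); when `NULL` they are selected by GCV.
#' @return An object of class `"nload_gam"`: coefficients, smoothing
#'   parameters, per-term and total effective degrees of freedom,
#'   `sigma2 = RSS/n`, `BIC = -2 logLik + log(n) (edf + 1)`, training
#'   covariate percentiles (0--100), and the training frame.
#' @seealso [predict.nload_gam()], [average_sensitivity()], [bic()]
#' @export
#' @examples
#' tab <- simulate_catchment_years(30, 1995:2010, seed = 1)
#' fit <- nload_gam(tab)
#' summary(fit)
nload_gam <- function(data, terms = default_terms(), lambda = NULL) {
  if (!"Q_TN" %in% names(data)) stop_invalid("data must contain 'Q_TN'")
  if (any(!is.finite(data$Q_TN)) || any(data$Q_TN <= 0))
    stop_invalid("Q_TN must be strictly positive and finite (log link)")
  d <- build_design(data, terms)
  X <- d$X
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop_invalid("need n > total basis dimension (n = ", n, ", p = ", p, ")")
  y <- log(data$Q_TN)
  ns <- length(d$penalties)
  if (ns == 0L) {
    lambda <- numeric(0)
  } else if (is.null(lambda)) {
    lambda <- select_lambda_gcv(X, y, d$penalties)
  } else {
    if (length(lambda) != ns) stop_invalid("'lambda' must have one entry per smooth")
    if (!is.null(names(lambda)) && all(names(d$penalties) %in% names(lambda)))
      lambda <- lambda[names(d$penalties)]
  }
  lambda <- as.numeric(lambda)
  names(lambda) <- names(d$penalties)
  f <- fit_penalized(X, y, d$penalties, lambda)
  beta <- stats::setNames(f$beta, colnames(X))
  edf_term <- vapply(d$term_cols, function(idx) sum(f$infl[idx]), numeric(1))
  sigma2 <- f$rss / n
  ll <- -0.5 * (n * log(2 * pi * max(sigma2, .Machine$double.xmin)) + n)
  bic_val <- -2 * ll + log(n) * (f$edf + 1)
  covars <- vapply(d$terms, `[[`, "", "name")
  probs <- seq(0, 1, by = 0.01)
  percentiles <- lapply(stats::setNames(covars, covars),
                        function(v) quantile7(data[[v]], probs))
  model_frame <- data[, c("Q_TN", covars), drop = FALSE]
  structure(list(
    coefficients = beta, terms = d$terms, term_cols = d$term_cols,
    smooths = d$smooths, lambda = lambda, edf = f$edf, edf_term = edf_term,
    sigma2 = sigma2, rss = f$rss, n = n, gcv = f$gcv, bic = bic_val,
    logLik = ll, fitted_link = f$fitted, residuals_link = y - f$fitted,
    percentiles = percentiles, percentile_probs = probs,
    covariates = covars, data = model_frame, call = match.call()
  ), class = "nload_gam")
}

#' BIC of a fitted load model
#'
#' `BIC = -2 logLik + log(n) * (edf + 1)`, where the Gaussian log-likelihood
#' is maximized at `sigma2 = RSS/n` and the `+ 1` counts the scale
#' parameter.
#'
#' @param model a fitted `nload_gam`.
#' @return The BIC value (numeric scalar).
#' @export
bic <- function(model) {
  stopifnot(inherits(model, "nload_gam"))
  model$bic
}

#' @export
logLik.nload_gam <- function(object, ...) {
  structure(object$logLik, df = object$edf + 1, nobs = object$n, class = "logLik")
}

# Evaluate the contribution of every term at new covariate values.
eval_terms <- function(object, newdata) {
  n <- nrow(newdata)
  eta <- rep(object$coefficients[["(Intercept)"]], n)
  extrap <- rep(FALSE, n)
  for (tm in object$terms) {
    v <- tm$name
    if (!v %in% names(newdata)) stop_invalid("newdata is missing covariate '", v, "'")
    x <- newdata[[v]]
    if (anyNA(x)) stop_invalid("covariate '", v, "' contains missing values")
    rng <- range(object$percentiles[[v]])
    extrap <- extrap | x < rng[1L] | x > rng[2L]
    idx <- object$term_cols[[v]]
    if (tm$kind == "linear" || is.null(object$smooths[[v]])) {
      eta <- eta + x * object$coefficients[idx]
    } else {
      sm <- object$smooths[[v]]
      B <- eval_bspline(x, sm$knots) %*% sm$Z
      eta <- eta + drop(B %*% object$coefficients[idx])
    }
  }
  list(eta = eta, extrapolated = extrap)
}

#' Predict from a fitted load model
#'
#' @param object a fitted `nload_gam`.
#' @param newdata data frame of covariates; defaults to the training frame.
#' @param type `"link"` for the linear predictor (log scale) or `"median"`
#'   for the back-transformed median load `exp(link)`.
#' @param ... unused.
#' @return Numeric vector of predictions.  If any covariate lies outside
#'   the training range the result carries a logical attribute
#'   `"extrapolated"` flagging those rows (extrapolation is linear beyond
#'   the boundary knots).
#' @export
predict.nload_gam <- function(object, newdata = NULL, type = c("link", "median"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  ev <- eval_terms(object, newdata)
  out <- if (type == "median") exp(ev$eta) else ev$eta
  if (any(ev$extrapolated)) attr(out, "extrapolated") <- ev$extrapolated
  out
}

#' @rdname predict.nload_gam
#' @param model a fitted `nload_gam`.
#' @export
predict_median <- function(model, newdata = NULL) predict(model, newdata, type = "median")

#' @export
fitted.nload_gam <- function(object, ...) object$fitted_link

#' @export
residuals.nload_gam <- function(object, ...) object$residuals_link

#' @export
coef.nload_gam <- function(object, ...) object$coefficients

#' @export
print.nload_gam <- function(x, ...) {
  cat("Penalized-spline additive model for ln(Q_TN)\n")
  cat("  n =", x$n, " covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat(sprintf("  total edf = %.2f   sigma^2 = %.4f   BIC = %.1f\n",
              x$edf, x$sigma2, x$bic))
  invisible(x)
}

#' @export
summary.nload_gam <- function(object, ...) {
  sm_names <- names(object$smooths)
  tab <- data.frame(
    term = names(object$edf_term),
    kind = ifelse(names(object$edf_term) %in% sm_names, "smooth", "linear"),
    edf = round(object$edf_term, 3),
    lambda = ifelse(names(object$edf_term) %in% sm_names,
                    signif(object$lambda[names(object$edf_term)], 4), NA),
    row.names = NULL
  )
  out <- list(terms = tab, n = object$n, edf = object$edf, sigma2 = object$sigma2,
              bic = object$bic, gcv = object$gcv,
              r_squared = 1 - object$rss / sum((log(object$data$Q_TN) -
                                                  mean(log(object$data$Q_TN)))^2))
  class(out) <- "summary.nload_gam"
  out
}

#' @export
print.summary.nload_gam <- function(x, ...) {
  cat("Penalized-spline additive model for ln(Q_TN)\n\n")
  print(x$terms, row.names = FALSE)
  cat(sprintf("\nn = %d   total edf = %.2f   sigma^2 = %.4f (log scale)\n",
              x$n, x$edf, x$sigma2))
  cat(sprintf("R^2(ln Q) = %.3f   GCV = %.5f   BIC = %.1f\n",
              x$r_squared, x$gcv, x$bic))
  invisible(x)
}

#' @export
plot.nload_gam <- function(x, which = names(x$smooths), ...) {
  op <- graphics::par(mfrow = c(1, max(length(which), 1L)))
  on.exit(graphics::par(op))
  for (v in which) {
    sm <- x$smooths[[v]]
    if (is.null(sm)) next
    rng <- range(x$percentiles[[v]])
    grid <- seq(rng[1L], rng[2L], length.out = 200)
    B <- eval_bspline(grid, sm$knots) %*% sm$Z
    f <- drop(B %*% x$coefficients[x$term_cols[[v]]])
    graphics::plot(grid, f, type = "l", xlab = v,
                   ylab = sprintf("partial effect (edf %.1f)", x$edf_term[[v]]), ...)
    graphics::rug(x$data[[v]])
  }
  invisible(x)
}

#' Simulate loads from the conditional lognormal distribution
#'
#' Draws `Q = median * exp(sigma * z)` around the fitted medians, i.e. new
#' responses under the fitted model.
#'
#' @param object a fitted `nload_gam`.
#' @param nsim number of replicate data sets.
#' @param seed integer seed.
#' @param newdata optional covariate frame (default: training frame).
#' @param ... unused.
#' @return A data frame with `nsim` columns of simulated loads.
#' @export
simulate.nload_gam <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  med <- predict(object, newdata, type = "median")
  draws <- sample_loads(as.numeric(med), object$sigma2, n_draws = nsim,
                        seed = seed %||% 1L)
  as.data.frame(draws)
}

#' Persist and restore fitted models as structured text
#'
#' The artifact is JSON at full double precision and contains everything
#' needed for prediction and sensitivity analysis (terms, coefficients,
#' knots, constraint matrices, smoothing parameters, percentiles, training
#' frame).  `read_nload_gam(write_nload_gam(m, f))` predicts identically to
#' the original model.
#'
#' @param model a fitted `nload_gam`.
#' @param path file path.
#' @return `write_nload_gam` returns `path` invisibly; `read_nload_gam`
#'   returns the restored `nload_gam`.
#' @export
write_nload_gam <- function(model, path) {
  stopifnot(inherits(model, "nload_gam"))
  payload <- list(
    format = "nload_gam-1",
    terms = lapply(model$terms, unclass),
    coefficients = as.list(model$coefficients),
    term_cols = model$term_cols,
    smooths = lapply(model$smooths, function(s)
      list(name = s$name, knots = s$knots,
           Z_dim = dim(s$Z), Z_values = as.numeric(s$Z),
           cols = s$cols, basis_size = s$basis_size)),
    lambda = as.list(model$lambda),
    edf = model$edf, edf_term = as.list(model$edf_term),
    sigma2 = model$sigma2, rss = model$rss, n = model$n,
    gcv = model$gcv, bic = model$bic, logLik = model$logLik,
    percentile_probs = model$percentile_probs,
    percentiles = model$percentiles,
    covariates = model$covariates,
    data = as.list(model$data)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_nload_gam
#' @export
read_nload_gam <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(p$format, "nload_gam-1")) stop_invalid("not an nload_gam artifact: ", path)
  terms <- lapply(seq_len(nrow(p$terms) %||% length(p$terms)), function(i) NULL)
  # jsonlite may simplify the term list to a data frame; rebuild either way
  if (is.data.frame(p$terms)) {
    terms <- lapply(seq_len(nrow(p$terms)), function(i)
      structure(as.list(p$terms[i, ]), class = "nload_term"))
  } else {
    terms <- lapply(p$terms, function(tm) structure(tm, class = "nload_term"))
  }
  smooths <- lapply(p$smooths, function(s) {
    s$Z <- matrix(as.numeric(s$Z_values), s$Z_dim[1L], s$Z_dim[2L])
    s$Z_values <- NULL; s$Z_dim <- NULL
    s$cols <- as.integer(s$cols)
    s
  })
  model <- list(
    coefficients = unlist(p$coefficients),
    terms = terms,
    term_cols = lapply(p$term_cols, as.integer),
    smooths = smooths,
    lambda = unlist(p$lambda) %||% numeric(0),
    edf = p$edf, edf_term = unlist(p$edf_term), sigma2 = p$sigma2,
    rss = p$rss, n = p$n, gcv = p$gcv, bic = p$bic, logLik = p$logLik,
    fitted_link = NULL, residuals_link = NULL,
    percentiles = p$percentiles, percentile_probs = p$percentile_probs,
    covariates = p$covariates,
    data = as.data.frame(p$data), call = NULL
  )
  class(model) <- "nload_gam"
  model
}
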