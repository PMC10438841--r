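# Penalized cubic B-spline design machinery.
#
# Smooth terms use cubic B-splines with knots at covariate quantiles, a
# sum-to-zero constraint for identifiability (absorbed by a QR-derived
# reparametrization), and a second-order divided-difference penalty on the
# basis coefficients.  The divided differences are taken with respect to the
# Greville abscissae, so the penalty null space is exactly the linear
# functions of the covariate: as lambda -> Inf a smooth collapses to a line.

#' Term specifications
#'
#' `term_smooth()` declares a penalized cubic B-spline smooth with
#' `basis_size` basis functions (>= 4); `term_linear()` declares an
#' unpenalized linear term.
#'
#' @param name covariate name.
#' @param basis_size number of B-spline basis functions before the
#'   identifiability constraint (default 10).
#' @return A list of class `"nload_term"`.
#' @export
term_smooth <- function(name, basis_size = 10L) {
  if (basis_size < 4) stop_invalid("smooth terms need basis_size >= 4")
  structure(list(name = name, kind = "smooth", basis_size = as.integer(basis_size),
                 penalty_order = 2L), class = "nload_term")
}

#' @rdname term_smooth
#' @export
term_linear <- function(name) {
  structure(list(name = name, kind = "linear", basis_size = 1L,
                 penalty_order = 0L), class = "nload_term")
}

#' Default nine-covariate term specification
#'
#' Smooths on annual precipitation and annual temperature (the covariates
#' with a plausibly nonlinear response), linear terms for springtime extreme
#' precipitation, the two log-surplus terms, the three land-use percentages,
#' and tile drainage.
#'
#' @param k basis size for the smooth terms.
#' @return A list of `nload_term` objects.
#' @export
default_terms <- function(k = 10L) {
  list(
    term_smooth("P_annual", k),
    term_linear("P_MAM95"),
    term_smooth("T_annual", k),
    term_linear("ln_Nsurplus"),
    term_linear("ln_Nsurplus_lag12"),
    term_linear("LU_D"),
    term_linear("LU_C"),
    term_linear("LU_FSH"),
    term_linear("L_TD")
  )
}

# Knot vector for k cubic basis functions: boundary knots at the data range
# (multiplicity 4) and k - 4 interior knots at quantiles.
make_knots <- function(x, k) {
  lo <- min(x); hi <- max(x)
  n_int <- k - 4L
  interior <- if (n_int > 0L) quantile7(x, seq_len(n_int) / (n_int + 1L)) else numeric(0)
  # guard against ties in heavily discretized covariates
  if (n_int > 0L) {
    eps <- 1e-8 * max(hi - lo, 1)
    interior <- pmin(pmax(interior, lo + eps), hi - eps)
    interior <- interior + cumsum(c(0, diff(interior) <= 0)) * eps
  }
  c(rep(lo, 4L), interior, rep(hi, 4L))
}

greville <- function(knots) {
  k <- length(knots) - 4L
  vapply(seq_len(k), function(j) mean(knots[(j + 1L):(j + 3L)]), numeric(1))
}

# Basis evaluation with linear extension beyond the boundary knots, so that
# predictions under (for example) future warming extrapolate the fitted
# smooth with continuous value and first derivative.
eval_bspline <- function(x, knots, deriv = 0L) {
  lo <- knots[4L]; hi <- knots[length(knots) - 3L]
  xin <- pmin(pmax(x, lo), hi)
  B <- splines::splineDesign(knots, xin, ord = 4L, derivs = rep(deriv, length(xin)))
  out_lo <- which(x < lo); out_hi <- which(x > hi)
  if (length(out_lo) || length(out_hi)) {
    for (side in list(list(idx = out_lo, at = lo), list(idx = out_hi, at = hi))) {
      if (!length(side$idx)) next
      if (deriv == 0L) {
        B0 <- splines::splineDesign(knots, side$at, ord = 4L, derivs = 0L)
        B1 <- splines::splineDesign(knots, side$at, ord = 4L, derivs = 1L)
        delta <- x[side$idx] - side$at
        B[side$idx, ] <- rep(1, length(side$idx)) %o% drop(B0) + delta %o% drop(B1)
      } else if (deriv == 1L) {
        B1 <- splines::splineDesign(knots, side$at, ord = 4L, derivs = 1L)
        B[side$idx, ] <- rep(1, length(side$idx)) %o% drop(B1)
      } else {
        B[side$idx, ] <- 0
      }
    }
  }
  B
}

# Second-order divided-difference penalty root: D %*% beta gives the second
# divided differences of the coefficients with respect to the Greville
# abscissae.  crossprod(D) is the penalty; its null space is {1, x}.
diff2_matrix <- function(knots) {
  g <- greville(knots)
  k <- length(g)
  D <- matrix(0, k - 2L, k)
  for (j in seq_len(k - 2L)) {
    g0 <- g[j]; g1 <- g[j + 1L]; g2 <- g[j + 2L]
    D[j, j]      <- 1 / ((g0 - g1) * (g0 - g2))
    D[j, j + 1L] <- 1 / ((g1 - g0) * (g1 - g2))
    D[j, j + 2L] <- 1 / ((g2 - g0) * (g2 - g1))
  }
  D
}

#' Build the design matrix and penalty blocks for an additive model
#'
#' Constructs the intercept column, one column per linear term, and the
#' constrained (sum-to-zero) cubic B-spline columns per smooth term,
#' together with the block-embedded second-order difference penalty matrix
#' of each smooth.  Smooths on covariates with too few distinct values are
#' degraded to linear terms with a warning.
#'
#' @param records data frame holding the covariates.
#' @param terms list of [term_smooth()] / [term_linear()] specifications.
#' @return A list with elements `X` (n x p design), `penalties` (list of
#'   p x p matrices, one per smooth), `term_cols` (named list of column
#'   indices), `smooths` (per-smooth knots and constraint matrix), and
#'   `terms` (possibly degraded specifications).
#' @export
build_design <- function(records, terms) {
  nms <- vapply(terms, `[[`, "", "name")
  missing_cov <- setdiff(nms, names(records))
  if (length(missing_cov))
    stop_invalid("covariates not found in records: ", paste(missing_cov, collapse = ", "))
  n <- nrow(records)
  # degrade rank-deficient smooths
  terms <- lapply(terms, function(tm) {
    if (tm$kind == "smooth") {
      ndist <- length(unique(records[[tm$name]]))
      if (ndist <= tm$basis_size) {
        warning("smooth for '", tm$name, "' degraded to linear (only ", ndist,
                " distinct values for basis_size ", tm$basis_size, ")", call. = FALSE)
        return(term_linear(tm$name))
      }
    }
    tm
  })
  cols <- list(`(Intercept)` = matrix(1, n, 1L))
  term_cols <- list()
  smooths <- list()
  pen_blocks <- list()
  p0 <- 1L
  for (tm in terms) {
    x <- records[[tm$name]]
    if (!is.numeric(x)) stop_invalid("covariate '", tm$name, "' is not numeric")
    if (anyNA(x)) stop_invalid("covariate '", tm$name, "' contains missing values")
    if (tm$kind == "linear") {
      cols[[tm$name]] <- matrix(x, n, 1L, dimnames = list(NULL, tm$name))
      term_cols[[tm$name]] <- p0 + 1L
      p0 <- p0 + 1L
    } else {
      knots <- make_knots(x, tm$basis_size)
      B <- eval_bspline(x, knots)
      C <- colSums(B)                       # sum-to-zero constraint C beta = 0
      Z <- qr.Q(qr(matrix(C, ncol = 1L)), complete = TRUE)[, -1L, drop = FALSE]
      Bz <- B %*% Z
      colnames(Bz) <- paste0("s(", tm$name, ").", seq_len(ncol(Bz)))
      D <- diff2_matrix(knots)
      Sz <- crossprod(D %*% Z)
      idx <- p0 + seq_len(ncol(Bz))
      cols[[tm$name]] <- Bz
      term_cols[[tm$name]] <- idx
      smooths[[tm$name]] <- list(name = tm$name, knots = knots, Z = Z,
                                 cols = idx, basis_size = tm$basis_size)
      pen_blocks[[tm$name]] <- Sz
      p0 <- p0 + ncol(Bz)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X)[1L] <- "(Intercept)"
  p <- ncol(X)
  penalties <- lapply(names(pen_blocks), function(nm) {
    S <- matrix(0, p, p)
    idx <- term_cols[[nm]]
    S[idx, idx] <- pen_blocks[[nm]]
    S
  })
  names(penalties) <- names(pen_blocks)
  list(X = X, penalties = penalties, term_cols = term_cols,
       smooths = smooths, terms = terms)
}
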