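# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  All exported generators route their randomness through this so a
# fixed seed gives byte-identical output regardless of call order.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label; keeps results
# below 2^31 and decorrelates sub-generators that share one user seed.
child_seed <- function(seed, stream) {
  s <- as.double(seed)
  for (ch in utf8ToInt(as.character(stream)))
    s <- (s * 31 + ch) %% 2147483629
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Empirical quantile convention used throughout: linear interpolation of
# order statistics (stats::quantile type 7).  Thresholds such as the extreme
# precipitation cutoff depend on it, so it is fixed here once.
quantile7 <- function(x, probs) stats::quantile(x, probs = probs, type = 7, names = FALSE)

stop_invalid <- function(...) stop(..., call. = FALSE)

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

days_in_year <- function(y) ifelse(is_leap(y), 366L, 365L)

# The 12 canonical columns of a catchment-year table.
CATCHMENT_YEAR_COLUMNS <- c(
  "catchment_id", "year", "Q_TN", "P_annual", "P_MAM95", "T_annual",
  "ln_Nsurplus", "ln_Nsurplus_lag12", "LU_D", "LU_C", "LU_FSH", "L_TD"
)

# Covariate names the default nine-covariate model uses (everything except
# the id/year/response columns).
MODEL_COVARIATES <- setdiff(CATCHMENT_YEAR_COLUMNS, c("catchment_id", "year", "Q_TN"))
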