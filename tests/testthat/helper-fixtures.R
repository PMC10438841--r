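# Shared fixtures, built once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

year_of_test <- function(dates) as.integer(format(dates, "%Y"))

# independent brute-force enumeration: loop over all subsets of the pooled
# candidates, keep those satisfying every per-category count constraint
brute_force_sets <- function(catalog) {
  all_members <- unlist(lapply(catalog, `[[`, "members"), use.names = FALSE)
  n <- length(all_members)
  keep <- list()
  for (mask in 0:(2^n - 1)) {
    set <- all_members[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    ok <- all(vapply(catalog, function(cc) {
      k <- sum(cc$members %in% set)
      k >= (cc$min_allowed %||% 0) && k <= cc$max_allowed
    }, logical(1)))
    if (ok) keep[[length(keep) + 1L]] <- sort(set)
  }
  keep
}

# one-row catchment specification with controllable climate parameters
make_spec <- function(id = "W1", p_mean = 1000, p_wet = 0.35, p_shape = 0.8,
                      t_mean = 10, t_amp = 10, LU_D = 10, LU_C = 30,
                      LU_FSH = 40, L_TD = 10, area_km2 = 1000) {
  data.frame(catchment_id = id, area_km2 = area_km2, LU_D = LU_D, LU_C = LU_C,
             LU_FSH = LU_FSH, LU_W = 5, LU_other = 100 - LU_D - LU_C - LU_FSH - 5,
             L_TD = L_TD, p_mean_mm = p_mean, p_wet = p_wet, p_shape = p_shape,
             t_mean = t_mean, t_amp = t_amp, stringsAsFactors = FALSE)
}

# cheap covariate frame (no climate chain) for loading-model tests
make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  s <- exp(rnorm(n, log(35), 0.3))
  data.frame(
    catchment_id = sprintf("C%04d", seq_len(n)), year = 2000L,
    P_annual = runif(n, 450, 2200),
    P_MAM95 = runif(n, 0, 250),
    T_annual = runif(n, -2, 24),
    ln_Nsurplus = log(s),
    ln_Nsurplus_lag12 = log(s * exp(rnorm(n, 0, 0.1))),
    LU_D = runif(n, 0, 40), LU_C = runif(n, 0, 60),
    LU_FSH = runif(n, 0, 70), L_TD = runif(n, 0, 30),
    stringsAsFactors = FALSE)
}

# medium default-calibrated sample + fits, reused across files
tt_tab <- simulate_catchment_years(25, 1996:2015, seed = 7)
tt_fit <- nload_gam(tt_tab)
tt_cfg0 <- gen_config(sigma = 0)
tt_tab0 <- simulate_catchment_years(20, 1998:2012, seed = 11, config = tt_cfg0)
tt_fit0 <- nload_gam(tt_tab0)
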