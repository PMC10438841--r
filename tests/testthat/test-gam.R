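# Penalized-spline fitting machinery: design construction, exact limits,
# oracle equivalence, BIC, prediction, and persistence.

test_that("design matrix has the documented shape and penalty structure", {
  df <- data.frame(x = 1:10, z = runif(10))
  d <- build_design(df, list(term_linear("x")))
  expect_equal(dim(d$X), c(10, 2))
  expect_length(d$penalties, 0)           # nothing to penalize

  set.seed(1)
  df2 <- data.frame(x = runif(100))
  d2 <- build_design(df2, list(term_smooth("x", 10)))
  expect_equal(ncol(d2$X), 1 + 9)         # identifiability removes one column
  expect_equal(unname(colSums(d2$X[, -1])), rep(0, 9), tolerance = 1e-10)
  S <- d2$penalties[["x"]]
  expect_equal(dim(S), c(10, 10))
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_true(all(eigen(S, only.values = TRUE)$values > -1e-8))

  expect_warning(
    build_design(data.frame(x = rep(1:5, 20)), list(term_smooth("x", 10))),
    "degraded to linear")
  expect_error(build_design(df, list(term_linear("missing"))), "missing")
})

test_that("unpenalized fit reproduces ordinary least squares exactly", {
  set.seed(2)
  n <- 60
  df <- data.frame(x = runif(n), w = rnorm(n))
  df$Q_TN <- exp(1 + 0.5 * df$x - 0.2 * df$w + rnorm(n, 0, 0.1))
  fit <- nload_gam(df, list(term_linear("x"), term_linear("w")))
  ols <- lm(log(Q_TN) ~ x + w, df)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$edf, 3)               # influence trace = parameter count

  # exact linear truth: slope recovered exactly, zero residual variance
  df0 <- data.frame(x = seq(0, 1, length.out = 20))
  df0$Q_TN <- exp(2 * df0$x)
  fit0 <- nload_gam(df0, list(term_linear("x")))
  expect_equal(unname(coef(fit0)["x"]), 2, tolerance = 1e-10)
  expect_lt(fit0$sigma2, 1e-20)

  # smooth at lambda = 0: edf equals the full parameter count
  set.seed(3)
  dfs <- data.frame(x = runif(80))
  dfs$Q_TN <- exp(sin(2 * pi * dfs$x) + rnorm(80, 0, 0.1))
  fits <- nload_gam(dfs, list(term_smooth("x", 8)), lambda = 0)
  expect_equal(fits$edf, 8, tolerance = 1e-8)
})

test_that("penalized fit equals a generic augmented least-squares solve", {
  set.seed(4)
  n <- 50
  df <- data.frame(x = runif(n), w = rnorm(n))
  df$Q_TN <- exp(sin(2 * pi * df$x) + 0.3 * df$w + rnorm(n, 0, 0.2))
  terms <- list(term_smooth("x", 8), term_linear("w"))
  lam <- 3.7
  fit <- nload_gam(df, terms, lambda = lam)

  d <- build_design(df, terms)
  S <- lam * d$penalties[[1]]
  eg <- eigen(S, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-12
  root <- t(eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(eg$values[keep])))
  Xa <- rbind(d$X, root)
  ya <- c(log(df$Q_TN), rep(0, nrow(root)))
  beta_oracle <- qr.coef(qr(Xa), ya)
  expect_equal(unname(coef(fit)), unname(beta_oracle), tolerance = 1e-8)
})

test_that("infinite smoothing collapses a smooth to a straight line", {
  set.seed(5)
  n <- 120
  df <- data.frame(x = runif(n, 0, 10))
  df$Q_TN <- exp(sin(df$x) + rnorm(n, 0, 0.1))
  d <- build_design(df, list(term_smooth("x", 10)))
  lam_big <- 1e10 * sum(diag(crossprod(d$X))) / sum(diag(d$penalties[[1]]))
  fit <- nload_gam(df, list(term_smooth("x", 10)), lambda = lam_big)
  expect_equal(unname(fit$edf_term[["x"]]), 1, tolerance = 1e-3)
  grid <- data.frame(x = seq(0.5, 9.5, length.out = 30))
  eta <- predict(fit, grid, type = "link")
  line <- lm(eta ~ x, grid)
  expect_lt(max(abs(residuals(line))), 1e-4)
})

test_that("BIC follows the Gaussian likelihood with an edf + scale penalty", {
  set.seed(6)
  n <- 100
  df <- data.frame(x = rnorm(n))
  df$Q_TN <- exp(1 + df$x + rnorm(n, 0, 0.5))
  fit <- nload_gam(df, list(term_linear("x")))
  ols <- lm(log(Q_TN) ~ x, df)
  rss <- sum(residuals(ols)^2)
  expected <- n * log(2 * pi * rss / n) + n + log(n) * (2 + 1)
  expect_equal(bic(fit), expected, tolerance = 1e-8)
  # and via the stats generic through logLik
  expect_equal(BIC(fit), expected, tolerance = 1e-8)
  expect_identical(bic(fit), bic(nload_gam(df, list(term_linear("x")))))
})

test_that("a pure-noise covariate raises BIC in nearly all replicates", {
  set.seed(7)
  worse <- replicate(100, {
    n <- 200
    df <- data.frame(x = rnorm(n), z = rnorm(n))
    df$Q_TN <- exp(1 + 0.8 * df$x + rnorm(n, 0, 0.5))
    b1 <- bic(nload_gam(df, list(term_linear("x"))))
    b2 <- bic(nload_gam(df, list(term_linear("x"), term_linear("z"))))
    b2 > b1
  })
  expect_gte(mean(worse), 0.95)
})

test_that("median back-transform obeys the lognormal identities", {
  df <- data.frame(x = 1:30 / 30)
  df$Q_TN <- rep(1, 30) * exp(rnorm(30, 0, 1e-8))
  fit <- nload_gam(df, list(term_linear("x")))
  expect_equal(as.numeric(predict_median(fit, data.frame(x = 0.5))), 1,
               tolerance = 1e-6)
  # exp(link) is the median, so link = ln(1000) maps to 1000
  eta <- predict(fit, data.frame(x = 0.5), type = "link")
  expect_equal(as.numeric(exp(eta)), as.numeric(predict_median(fit, data.frame(x = 0.5))))

  # noise-free default-calibrated data are recovered with R^2 > 0.999
  pred <- predict_median(tt_fit0, tt_tab0)
  truth <- exp(attr(tt_tab0, "truth")$eta)
  r2 <- 1 - sum((log(pred) - log(truth))^2) / sum((log(truth) - mean(log(truth)))^2)
  expect_gt(r2, 0.999)
})

test_that("monotone partial effects give monotone median predictions", {
  probs <- tt_fit$percentile_probs
  med <- as.data.frame(lapply(tt_fit$percentiles, function(q)
    q[which.min(abs(probs - 0.5))]))
  grid <- med[rep(1, 40), ]
  grid$T_annual <- seq(min(tt_tab$T_annual), max(tt_tab$T_annual), length.out = 40)
  p <- as.numeric(predict_median(tt_fit, grid))
  expect_true(all(diff(p) < 0))          # warming decreases loading throughout
})

test_that("model artifacts round-trip through structured text", {
  path <- tempfile(fileext = ".json")
  write_nload_gam(tt_fit, path)
  back <- read_nload_gam(path)
  expect_equal(as.numeric(predict(back, tt_tab, type = "link")),
               as.numeric(predict(tt_fit, tt_tab, type = "link")),
               tolerance = 1e-12)
  expect_equal(back$bic, tt_fit$bic, tolerance = 1e-12)
  expect_equal(back$edf, tt_fit$edf, tolerance = 1e-12)
  expect_equal(coef(back), coef(tt_fit), tolerance = 1e-15)
  unlink(path)
})

test_that("fitted smooths agree with an independent GAM implementation", {
  set.seed(9)
  n <- 500
  df <- data.frame(x = runif(n, 0, 10))
  df$Q_TN <- exp(sin(df$x) + rnorm(n, 0, 0.3))
  fit <- nload_gam(df, list(term_smooth("x", 12)))
  ref <- mgcv::gam(log(Q_TN) ~ s(x, k = 12), data = df, method = "GCV.Cp")
  grid <- data.frame(x = seq(0.5, 9.5, length.out = 60))
  ours <- as.numeric(predict(fit, grid, type = "link"))
  theirs <- as.numeric(predict(ref, grid))
  # different bases and smoothness heuristics: agreement to a few percent
  expect_lt(max(abs(ours - theirs)), 0.1)
  expect_gt(cor(ours, theirs), 0.999)
})

test_that("fit refuses ill-posed inputs with informative errors", {
  df <- data.frame(x = 1:30)
  df$Q_TN <- c(-1, rep(1, 29))
  expect_error(nload_gam(df, list(term_linear("x"))), "positive")
  set.seed(8)
  small <- data.frame(x = runif(12), z = runif(12), Q_TN = exp(rnorm(12)))
  expect_error(nload_gam(small, list(term_smooth("x", 8), term_smooth("z", 8))),
               "n >")
})
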