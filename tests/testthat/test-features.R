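test_that("shortening curve hits its landmarks", {
  fv <- c(dSL = 1.80, sSL = 1.65, TTP = 120)
  expect_equal(eval_shortening_curve(120, fv), 1.65)
  expect_equal(eval_shortening_curve(1e-6, fv), 1.80, tolerance = 1e-6)
  expect_equal(eval_shortening_curve(1e9, fv), 1.80, tolerance = 1e-6)
  expect_error(eval_shortening_curve(0, fv), "t must be")
})

test_that("feature fit round-trips noiseless curves to high precision", {
  tt <- seq(1, 800, by = 2)
  fv <- c(dSL = 1.85, sSL = 1.62, TTP = 150)
  tr <- trace(tt, eval_shortening_curve(tt, fv), "SL")
  est <- coef(fit_features(tr))
  expect_equal(est, fv, tolerance = 1e-8)
  # invariance to uniform resampling of the time grid
  tt2 <- seq(1, 800, by = 7)
  est2 <- coef(fit_features(trace(tt2, eval_shortening_curve(tt2, fv), "SL")))
  expect_equal(est2, fv, tolerance = 1e-8)
})

test_that("feature fit is unbiased under measurement noise", {
  tt <- seq(1, 800, by = 2)
  fv <- c(dSL = 1.85, sSL = 1.62, TTP = 150)
  clean <- eval_shortening_curve(tt, fv)
  set.seed(42)
  est <- t(vapply(1:100, function(i) {
    coef(fit_features(trace(tt, clean + rnorm(length(tt), 0, 0.002), "SL")))
  }, numeric(3)))
  bias <- colMeans(est) - fv
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_true(all(abs(bias) < 4 * pmax(se, c(1e-5, 1e-5, 1e-3))))
  # per-seed recovery stays within a few noise scales
  expect_lt(max(abs(est[, "dSL"] - fv[["dSL"]])), 3 * 0.002)
})

test_that("flat traces are rejected as degenerate", {
  tt <- seq(1, 500, by = 5)
  expect_error(fit_features(trace(tt, rep(1.8, length(tt)), "SL")),
               "degenerate|flat")
})

test_that("gaussian feature density is the MLE and transforms correctly", {
  set.seed(7)
  mu <- c(dSL = 1.8, sSL = 1.6, TTP = 150)
  S <- diag(c(0.02, 0.03, 15)^2)
  X <- MASS::mvrnorm(10000, mu, S)
  colnames(X) <- names(mu)
  d <- fit_feature_density(X, "control")
  se <- sqrt(diag(S) / nrow(X))
  expect_true(all(abs(d$mean - mu) < 3 * se))
  # shift equivariance
  d2 <- fit_feature_density(sweep(X, 2, c(1, 2, 3), "+"), "control")
  expect_equal(unname(d2$mean - d$mean), c(1, 2, 3), tolerance = 1e-10)
  expect_equal(d2$cov, d$cov, tolerance = 1e-12)
})

test_that("rank-deficient features are rejected with advice", {
  X <- matrix(rep(c(1.8, 1.6, 150), each = 5), 5, 3)
  expect_error(fit_feature_density(X), "rank-deficient")
})

test_that("feature sampling is reproducible and converges in moments", {
  d <- structure(list(mean = c(dSL = 1.8, sSL = 1.6, TTP = 150),
                      cov = diag(c(0.02, 0.03, 15)^2), n = 10,
                      group = "control"),
                 class = "feature_density")
  a <- sample_features(d, 50, seed = 1)
  b <- sample_features(d, 50, seed = 1)
  expect_identical(a, b)
  expect_equal(dim(sample_features(d, 0, seed = 1)), c(0L, 3L))
  big <- sample_features(d, 1e5, seed = 2)
  se <- sqrt(diag(d$cov) / 1e5)
  expect_true(all(abs(colMeans(big) - d$mean) < 3 * se))
})
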