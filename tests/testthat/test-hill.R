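test_that("hill fit recovers generating parameters exactly on clean data", {
  ca <- 10^seq(-1.5, 1.5, length.out = 15)
  for (true in list(c(h = 6, ca50 = 2), c(h = 1, ca50 = 0.8),
                    c(h = 10, ca50 = 1.3))) {
    f <- ca^true[["h"]] / (ca^true[["h"]] + true[["ca50"]]^true[["h"]])
    fit <- fit_hill(ca, f)
    expect_equal(fit$h, true[["h"]], tolerance = 1e-6)
    expect_equal(fit$Ca_50, true[["ca50"]], tolerance = 1e-6)
  }
})

test_that("hill fit is invariant to the sampling grid parameterization", {
  # same calcium values whether generated on a linear or pCa-uniform grid
  ca_lin <- seq(0.2, 12, length.out = 20)
  ca_pca <- 10^seq(log10(0.2), log10(12), length.out = 20)
  f <- function(ca) ca^5 / (ca^5 + 1.7^5)
  fit1 <- fit_hill(ca_lin, f(ca_lin))
  fit2 <- fit_hill(ca_pca, f(ca_pca))
  expect_equal(fit1$h, 5, tolerance = 1e-8)
  expect_equal(fit2$h, 5, tolerance = 1e-8)
  expect_equal(fit1$Ca_50, fit2$Ca_50, tolerance = 1e-8)
})

test_that("hill fit rejects degenerate input", {
  expect_error(fit_hill(c(1, 2, 3, 4), rep(0.5, 4)), "degenerate")
  expect_error(fit_hill(c(1, 2, 3), c(0.1, 0.5, 0.9)), "at least 4")
  expect_error(fit_hill(c(-1, 2, 3, 4), c(0.1, 0.4, 0.6, 0.9)), "ca must be")
})
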