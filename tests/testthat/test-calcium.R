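test_that("calcium transient is flat before the stimulus and returns to baseline", {
  p <- sarcomere_params(Ca_amp = 1.2, Ca_diast = 0.15, tau2 = 70)
  cst <- model_constants()
  expect_equal(calcium_transient(cst$t_start, p, cst), p$Ca_diast)
  expect_equal(calcium_transient(0, p, cst), p$Ca_diast)
  expect_equal(calcium_transient(1e6, p, cst), p$Ca_diast, tolerance = 1e-10)
})

test_that("normalizer makes the transient peak equal Ca_amp for any tau pair", {
  cst0 <- model_constants()
  for (tau1 in c(5, 20, 80)) {
    for (tau2 in c(25, 60, 140)) {
      if (tau1 == tau2) next
      p <- sarcomere_params(Ca_amp = 1.0, Ca_diast = 0.1, tau2 = tau2)
      cst <- model_constants(tau1 = tau1)
      peak <- stats::optimize(function(t) calcium_transient(t, p, cst),
                              interval = cst$t_start + c(0, 30 * max(tau1, tau2)),
                              maximum = TRUE, tol = 1e-10)$objective
      expect_equal(peak, p$Ca_amp, tolerance = 1e-6)
    }
  }
})

test_that("degenerate normalization tau1 == tau2 is rejected", {
  p <- sarcomere_params(tau2 = 20)
  cst <- model_constants(tau1 = 20)
  expect_error(calcium_transient(100, p, cst), "tau1 == tau2")
  expect_error(simulate_unloaded(p, cst), "tau1 == tau2")
})
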