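test_that("zero activation leaves the sarcomere at slack length", {
  p <- sarcomere_params(Ca_amp = 1e-9, Ca_diast = 1e-9, SL_slack = 1.83)
  tr <- simulate_unloaded(p, model_constants())
  expect_equal(tr$v, rep(1.83, length(tr$v)), tolerance = 1e-9)
})

test_that("slack scaling: SL_slack = 1.9 is the identity, others rescale", {
  cst <- model_constants()
  tr19 <- simulate_unloaded(sarcomere_params(SL_slack = 1.9), cst)
  tr18 <- simulate_unloaded(sarcomere_params(SL_slack = 1.8), cst)
  expect_equal(tr18$v, tr19$v * (1.8 / 1.9), tolerance = 1e-9)
  expect_true(all(tr19$v <= 1.9 + 1e-9))  # never above resting length
})

test_that("tension units cancel: joint scaling of S_a and passive_alpha", {
  p1 <- sarcomere_params(passive_alpha = 1)
  p3 <- sarcomere_params(passive_alpha = 3)
  c1 <- model_constants()
  c3 <- model_constants(S_a = 3 * c1$S_a)
  tr1 <- simulate_unloaded(p1, c1)
  tr3 <- simulate_unloaded(p3, c3)
  expect_equal(tr1$v, tr3$v, tolerance = 1e-8)
})

test_that("a control twitch lands in the calibrated physiologic regime", {
  tr <- simulate_unloaded(sarcomere_params(), model_constants())
  short <- (tr$v[1] - min(tr$v)) / tr$v[1]
  expect_gt(short, 0.05)
  expect_lt(short, 0.15)
  ttp <- tr$t[which.min(tr$v)]
  expect_gt(ttp, 100)
  expect_lt(ttp, 250)
})

test_that("isometric twitch yields metrics and zero calcium yields none", {
  sim <- simulate_isometric(sarcomere_params(), model_constants())
  m <- sim$metrics
  expect_gt(m$TTP_force, 0)
  expect_gt(m$RT50, 0)
  p0 <- sarcomere_params(Ca_amp = 1e-9, Ca_diast = 1e-9)
  sim0 <- simulate_isometric(p0, model_constants())
  expect_true(is.na(sim0$metrics$RT50))
  # force is the constant passive tension at 10% stretch
  expect_equal(diff(range(sim0$trace$v)), 0, tolerance = 1e-6)
  expect_equal(sim0$trace$v[1], passive_tension(1.10, 1, 10), tolerance = 1e-5)
})

test_that("diastolic calcium level modulates isometric relaxation time", {
  cst <- model_constants()
  rt_rest <- simulate_isometric(sarcomere_params(Ca_diast = 0.2), cst)$metrics$RT50
  rt_zero <- simulate_isometric(sarcomere_params(Ca_diast = 1e-9), cst)$metrics$RT50
  expect_false(isTRUE(all.equal(rt_rest, rt_zero)))
})

test_that("steady force-calcium curve is monotone and halves at Ca_50", {
  fca <- simulate_fca(sarcomere_params(), model_constants())
  expect_true(all(diff(fca$force) >= -1e-3 * max(fca$force)))
  f_at_ca50 <- stats::approx(fca$ca, fca$f_norm, xout = fca$fit$Ca_50)$y
  expect_equal(f_at_ca50, 0.5, tolerance = 0.05)
  # steady state from the sweep matches the algebraic fixed point
  cst <- model_constants()
  ca <- 2
  A_star <- cst$k_on * ca / (cst$k_on * ca + cst$k_off)
  Abar <- permissive_ratio(A_star, 12, 0.45)
  fG <- cst$k_f * Abar^cst$n_G
  G_star <- fG / (fG + cst$k_g)
  fca2 <- simulate_fca(sarcomere_params(), cst, ca_grid = c(0.5, 1, 2, 8))
  expect_equal(fca2$force[3], cst$S_a * G_star, tolerance = 1e-5)
})
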