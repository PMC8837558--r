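test_that("permissive ratio behaves as a Hill function of bound TnC", {
  expect_equal(permissive_ratio(0.45, 12, 0.45), 0.5)
  expect_equal(permissive_ratio(0, 8, 0.5), 0)
  expect_equal(permissive_ratio(1, 2, 1), 0.5)
  A <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(permissive_ratio(A, 6, 0.5)) > 0))
  expect_true(all(permissive_ratio(A, 6, 0.5) < 1))
  expect_error(permissive_ratio(-0.1, 6, 0.5), "A must be")
})

test_that("passive tension vanishes at slack, is C1 there and increasing", {
  expect_equal(passive_tension(1, 1, 10), 0)
  expect_equal(passive_tension(0.9, 1, 10), 1 - exp(1))
  lam <- seq(0.7, 1.3, by = 0.001)
  expect_true(all(diff(passive_tension(lam, 2.5, 10)) > 0))
  expect_true(all(sign(passive_tension(lam, 1, 10)) == sign(lam - 1)))
  # one-sided derivatives at slack both equal alpha * beta
  h <- 1e-7
  d_left <- (passive_tension(1, 3, 10) - passive_tension(1 - h, 3, 10)) / h
  d_right <- (passive_tension(1 + h, 3, 10) - passive_tension(1, 3, 10)) / h
  expect_equal(d_left, 3 * 10, tolerance = 1e-5)
  expect_equal(d_right, 3 * 10, tolerance = 1e-5)
  expect_equal(d_left, d_right, tolerance = 1e-6)
})

test_that("active tension is proportional to S_a, the group fraction and strain factor", {
  p <- sarcomere_params()
  c1 <- model_constants()
  st <- list(G_XB = 2e-4, s = -0.3)
  expect_equal(active_tension(list(G_XB = 0, s = 0), p, c1), 0)
  t1 <- active_tension(st, p, c1)
  c2 <- model_constants(S_a = 2 * c1$S_a)
  expect_equal(active_tension(st, p, c2), 2 * t1)
  # strain factor clips at zero for strongly negative strain
  expect_equal(active_tension(list(G_XB = 1e-3, s = -1.5), p, c1), 0)
})

test_that("group dynamics decay without activation and respect the fixed point", {
  p <- sarcomere_params()
  cst <- model_constants()
  # no permissive units: pure decay of formed groups
  d <- sarcomere_rhs(0, c(G_XB = 0.3, A = 0, s = 0), p,
                     model_constants(), mode = "fixed", ca_const = 0)
  expect_lt(d[[1]][1], 0)
  # full occupancy can only decay
  d <- sarcomere_rhs(0, c(G_XB = 1, A = 0.5, s = 0), p, cst,
                     mode = "fixed", ca_const = 1)
  expect_lte(d[[1]][1], 0)
})

test_that("R and compiled right-hand sides agree along a twitch", {
  p <- sarcomere_params()
  cst <- model_constants()
  tr <- simulate_unloaded(p, cst, seq(0, 400, by = 1))
  ode <- attr(tr, "ode")
  for (i in c(2, 60, 150, 320)) {
    st <- ode[i, c("G_XB", "A", "s")]
    d_r <- sarcomere_rhs(ode[i, "time"], st, p, cst, mode = "unloaded")
    # compiled diagnostics at the same state
    expect_equal(d_r$lam, unname(ode[i, "lam"]), tolerance = 1e-8)
    expect_equal(d_r$Ca, unname(ode[i, "Ca"]), tolerance = 1e-10)
    expect_equal(d_r$Ta, unname(ode[i, "Ta"]), tolerance = 1e-8)
  }
  # integrating the exported R right-hand side with deSolve reproduces the
  # compiled trajectory
  rhs_fun <- function(t, y, parms) sarcomere_rhs(t, y, p, cst)
  out_r <- deSolve::lsoda(ode[1, c("G_XB", "A", "s")], seq(0, 400, by = 1),
                          rhs_fun, parms = NULL, rtol = 1e-8, atol = 1e-11)
  expect_equal(unname(out_r[, "G_XB"]), unname(ode[, "G_XB"]), tolerance = 1e-4)
  expect_equal(unname(out_r[, "s"]), unname(ode[, "s"]), tolerance = 1e-3)
})

test_that("state fractions stay inside [0, 1] along trajectories", {
  cst <- model_constants()
  for (p in list(sarcomere_params(),
                 sarcomere_params(n_A = 3, A_50 = 0.4, Ca_amp = 2,
                                  Ca_diast = 0.4),
                 sarcomere_params(n_A = 20, A_50 = 1.5, passive_alpha = 0.05))) {
    ode <- attr(simulate_unloaded(p, cst), "ode")
    expect_true(all(ode[, "G_XB"] >= -1e-12 & ode[, "G_XB"] <= 1 + 1e-12))
    expect_true(all(ode[, "A"] >= -1e-12 & ode[, "A"] <= 1 + 1e-12))
  }
})
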