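test_that("noiseless synthetic features equal direct extraction", {
  cfg <- synth_config(n_c = 5, n_d = 4, noise_sd = 0)
  gt <- make_ground_truth(cfg, seed = 9)
  cst <- model_constants()
  for (i in c(1, 3)) {
    p <- sarcopop:::row_params(as.numeric(gt$params_c[i, param_names()]),
                               SL_slack = gt$params_c$SL_slack[i])
    tr <- simulate_unloaded(p, cst, cfg$t_grid)
    expect_equal(unname(coef(fit_features(tr))),
                 unname(gt$features_c[i, ]), tolerance = 1e-10)
  }
})

test_that("zero drug shift produces statistically indistinguishable groups", {
  cfg <- synth_config(n_c = 120, n_d = 120,
                      drug_shift = c(n_A = 0, A_50 = 0))
  gt <- make_ground_truth(cfg, seed = 10)
  for (j in 1:3) {
    pv <- suppressWarnings(
      stats::ks.test(gt$features_c[, j], gt$features_d[, j]))$p.value
    expect_gt(pv, 0.01)
  }
})

test_that("default drug shift moves features in the reported directions", {
  gt <- make_ground_truth(synth_config(n_c = 150, n_d = 150), seed = 12)
  dm <- gt$density_d$mean - gt$density_c$mean
  expect_gt(dm[["TTP"]], 0)   # drug prolongs time to peak
  expect_lt(dm[["dSL"]], 0)   # shorter diastolic length
  expect_lt(dm[["sSL"]], 0)   # shorter systolic length
})

test_that("ground-truth shared block is drawn from one distribution", {
  gt <- make_ground_truth(synth_config(n_c = 200, n_d = 200), seed = 13)
  shared <- param_names()[shared_param_idx()]
  for (nm in shared) {
    pv <- suppressWarnings(
      stats::ks.test(gt$params_c[[nm]], gt$params_d[[nm]]))$p.value
    expect_gt(pv, 0.005)
  }
})

test_that("fixture files round-trip and are reproducible byte-for-byte", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  gt <- make_ground_truth(synth_config(n_c = 4, n_d = 4), seed = 14)
  files1 <- write_fixtures(gt, dir1)
  expect_length(grep("trace_", files1), 8)
  tr <- read_trace_csv(file.path(dir1, "trace_c_001.csv"))
  expect_equal(tr$t, gt$traces_c[[1]]$t)
  expect_equal(tr$v, gt$traces_c[[1]]$v)
  d <- read_density_json(file.path(dir1, "density_c.json"))
  expect_equal(d$mean, gt$density_c$mean)
  expect_equal(d$cov, gt$density_c$cov)
  gt2 <- make_ground_truth(synth_config(n_c = 4, n_d = 4), seed = 14)
  write_fixtures(gt2, dir2)
  for (f in basename(files1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})
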