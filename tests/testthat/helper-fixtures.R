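# Shared, lazily built fixtures. The surrogate and the fitted population
# model are expensive relative to the rest of the suite, so they are built
# once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, build(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# Surrogate trained on a moderate prior sample; accuracy checked by its own
# tests, reused by the adversarial-fit tests.
test_surrogate <- function() {
  memo("surrogate", function() {
    ts <- build_training_set(prior_box(), 8000, seed = 101)
    train_surrogate(ts$X, ts$Y, epochs = 600, seed = 101)
  })
}

# Synthetic two-group ground truth with enough cells for stable densities.
test_ground_truth <- function() {
  memo("ground_truth", function() {
    make_ground_truth(synth_config(n_c = 150, n_d = 150), seed = 202)
  })
}

test_slack <- function() {
  gt <- test_ground_truth()
  list(mean = mean(gt$params_c$SL_slack), sd = stats::sd(gt$params_c$SL_slack))
}

# One fully trained population model against the synthetic targets.
test_vpop <- function() {
  memo("vpop", function() {
    gt <- test_ground_truth()
    suppressWarnings(fit_vpop(
      gt$density_c, gt$density_d, test_surrogate(),
      prior = prior_box(), slack = test_slack(),
      config = gan_config(iters = 6000, n_eval = 2000, seed = 303)))
  })
}
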