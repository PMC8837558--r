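# Factorized adversarial inference of two-group parameter populations.
#
# The generator is a triplet of networks sharing one noise source:
#   G1 : z1 -> x1            (Ca_amp, Ca_diast, tau2, passive_alpha; shared)
#   G2 : (z1, z2) -> x2_c    (n_A, A_50, control group)
#   G3 : (z1, z3) -> x2_d    (n_A, A_50, drug group)
# Both groups receive the *same realization* of z1 within a batch, so the
# drug-insensitive block x1 is identical row-for-row across groups by
# construction -- the constraint that drug-free physiology share one
# distribution holds exactly, not approximately.
#
# Four discriminators drive training: D1/D2 classify generated parameter
# vectors against draws from the uniform prior (a soft prior-constraint
# penalty, weighted by lambda_p), while D3/D4 classify surrogate-predicted
# features of generated parameters against draws from the per-group target
# feature densities. Losses are nonsaturating cross-entropy; gradients flow
# to the generators through the frozen surrogate network.

#' Configuration for adversarial population fitting
#'
#' @param batch minibatch size.
#' @param iters generator/discriminator update iterations.
#' @param lr_g,lr_d Adam learning rates for generators and discriminators.
#' @param lambda_p weight of the prior-constraint (D1/D2) terms in the
#'   generator loss; >= 0, default 0.3.
#' @param z_dims noise dimensions for (z1, z2, z3); defaults (4, 2, 2),
#'   matching 4 shared + 2 drug-target parameters.
#' @param g_hidden,d_hidden hidden-layer widths of generators and
#'   discriminators.
#' @param eval_every iterations between convergence evaluations.
#' @param n_eval generated sample size per evaluation.
#' @param patience consecutive non-improving evaluations with clearly
#'   worsened distance before training aborts with a divergence error.
#' @param collapse_tol warn about mode collapse when the generated variance
#'   of any feature falls below this fraction of the target variance.
#' @param seed root seed; all randomness in training flows from it.
#' @param verbose print evaluation summaries.
#' @return List of class `"gan_config"`.
#' @export
gan_config <- function(batch = 128, iters = 4000, lr_g = 1e-3, lr_d = 2e-3,
                       lambda_p = 0.3, z_dims = c(4, 2, 2),
                       g_hidden = c(64, 64, 64), d_hidden = c(128, 128),
                       eval_every = 100, n_eval = 1000, patience = 15,
                       collapse_tol = 0.1, seed = 1, verbose = FALSE) {
  stopifnot(lambda_p >= 0, batch >= 8, iters >= 1, length(z_dims) == 3)
  structure(as.list(environment()), class = "gan_config")
}

# ---- internal helpers -------------------------------------------------------

squash_box <- function(u, box) {
  s <- sigmoid(u)
  sweep(sweep(s, 2, box$high - box$low, "*"), 2, box$low, "+")
}

# derivative dx/du of the squash, elementwise
squash_grad <- function(u, box) {
  s <- sigmoid(u)
  sweep(s * (1 - s), 2, box$high - box$low, "*")
}

std_box <- function(x, box) {
  sweep(sweep(x, 2, box$low), 2, (box$high - box$low) / 2, "/") - 1
}

chol_rinv <- function(S) solve(chol(S))  # (y - mu) %*% Rinv has identity cov

draw_slack <- function(n, slack) {
  if (is.null(slack)) return(rep(1.9, n))
  s <- stats::rnorm(n, slack$mean, slack$sd)
  pmax(s, 0.5 * slack$mean)
}

# Forward pass of the generator triplet. Returns parameter matrices and the
# caches needed for backprop.
gen_forward <- function(gens, z1, z2, z3, box) {
  si <- shared_param_idx(); ti <- target_param_idx()
  f1 <- mlp_forward(gens$G1, z1)
  f2 <- mlp_forward(gens$G2, cbind(z1, z2))
  f3 <- mlp_forward(gens$G3, cbind(z1, z3))
  p <- length(box$low)
  u_c <- matrix(0, nrow(z1), p); u_d <- matrix(0, nrow(z1), p)
  u_c[, si] <- f1$out; u_d[, si] <- f1$out
  u_c[, ti] <- f2$out; u_d[, ti] <- f3$out
  x_c <- squash_box(u_c, box); x_d <- squash_box(u_d, box)
  colnames(x_c) <- colnames(x_d) <- param_names()
  list(f1 = f1, f2 = f2, f3 = f3, u_c = u_c, u_d = u_d, x_c = x_c, x_d = x_d)
}

# Push parameters through the surrogate and apply the slack-length scaling of
# dSL and sSL (features 1 and 2).
push_features <- function(sur, x, slack_factor) {
  y <- predict(sur, x)
  y[, 1] <- y[, 1] * slack_factor
  y[, 2] <- y[, 2] * slack_factor
  y
}

# One discriminator classification step on (real, fake); returns updated
# net/opt and the mean loss.
disc_step <- function(net, opt, real, fake, lr) {
  Xb <- rbind(real, fake)
  yb <- c(rep(1, nrow(real)), rep(0, nrow(fake)))
  fwd <- mlp_forward(net, Xb)
  z <- drop(fwd$out)
  loss <- bce_logits(z, yb)
  dOut <- matrix((sigmoid(z) - yb) / length(yb), ncol = 1)
  gr <- mlp_backward(net, fwd, dOut)
  st <- adam_step(net, opt, gr, lr = lr)
  list(net = st$net, opt = st$opt, loss = loss)
}

# Nonsaturating generator objective for one discriminator: mean softplus(-z).
# Returns the loss and the gradient w.r.t. the discriminator *input*.
gen_term <- function(dnet, X, weight = 1) {
  fwd <- mlp_forward(dnet, X)
  z <- drop(fwd$out)
  loss <- mean(softplus(-z))
  dOut <- matrix(-sigmoid(-z) * weight / length(z), ncol = 1)
  dX <- mlp_backward(dnet, fwd, dOut)$dX
  list(loss = loss, dX = dX)
}

# Kolmogorov-Smirnov distance of a sample against N(mu, sd).
ks_stat_gaussian <- function(x, mu, sd) {
  x <- sort(x)
  n <- length(x)
  Fx <- stats::pnorm(x, mu, sd)
  max(abs(Fx - (seq_len(n) - 0.5) / n)) + 0.5 / n
}

#' Two-sample kernel maximum mean discrepancy
#'
#' Unbiased squared-MMD estimate with a Gaussian kernel (bandwidth from the
#' median pairwise distance of the pooled sample). Used as a multivariate
#' convergence diagnostic between generated and target feature samples.
#'
#' @param x,y numeric matrices with the same number of columns.
#' @return Scalar (can be slightly negative; unbiased estimator).
#' @export
mmd_rbf <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  pool <- rbind(x, y)
  d2 <- as.matrix(stats::dist(pool))^2
  bw <- stats::median(d2[upper.tri(d2)])
  if (bw <= 0) bw <- 1
  K <- exp(-d2 / bw)
  n <- nrow(x); m <- nrow(y)
  Kxx <- K[1:n, 1:n]; Kyy <- K[(n + 1):(n + m), (n + 1):(n + m)]
  Kxy <- K[1:n, (n + 1):(n + m)]
  (sum(Kxx) - sum(diag(Kxx))) / (n * (n - 1)) +
    (sum(Kyy) - sum(diag(Kyy))) / (m * (m - 1)) - 2 * mean(Kxy)
}

# Per-feature KS of generated features against the target Gaussian marginals.
eval_ks <- function(y, target) {
  vapply(seq_len(ncol(y)), function(j)
    ks_stat_gaussian(y[, j], target$mean[[j]], sqrt(target$cov[j, j])),
    numeric(1))
}

# ---- fitting ---------------------------------------------------------------

#' Fit a two-group virtual population by adversarial inference
#'
#' Trains the factorized generator triplet against the control and drug
#' feature densities, under the structural constraint that the
#' drug-insensitive parameter block is shared (identical noise realization)
#' between groups, and a soft prior-constraint penalty keeping generated
#' parameters spread over the uniform prior box. Model outputs inside the
#' adversarial loop come from the differentiable surrogate; validate the
#' result against the true simulator with [population_report()] or
#' [validate_om_report()].
#'
#' Convergence is monitored every `eval_every` iterations by per-feature
#' Kolmogorov-Smirnov distances between generated and target feature
#' marginals (plus a kernel MMD); the returned model carries the generator
#' weights at the best recorded distance.
#'
#' @param target_c,target_d `"feature_density"` objects for the control and
#'   drug groups.
#' @param surrogate a validated `"sarco_surrogate"`.
#' @param prior a [prior_box()].
#' @param slack `NULL` (slack length fixed at 1.9 um) or a list
#'   `list(mean=, sd=)` describing the measured slack-length distribution;
#'   generated `dSL`/`sSL` are scaled by drawn slack lengths over 1.9.
#' @param config a [gan_config()].
#' @param raw_features optional list `list(c =, d =)` of raw feature matrices;
#'   when supplied, discriminator "real" batches are resampled rows instead of
#'   Gaussian draws.
#' @return Object of class `"vpop_gan"`; see [simulate.vpop_gan()],
#'   [coef.vpop_gan()], [summary.vpop_gan()], [plot.vpop_gan()].
#' @export
fit_vpop <- function(target_c, target_d, surrogate, prior = prior_box(),
                     slack = NULL, config = gan_config(),
                     raw_features = NULL) {
  stopifnot(inherits(target_c, "feature_density"),
            inherits(target_d, "feature_density"),
            inherits(surrogate, "sarco_surrogate"),
            inherits(prior, "prior_box"))
  cfg <- config
  set.seed(cfg$seed)
  si <- shared_param_idx(); ti <- target_param_idx()
  p <- length(prior$low)

  gens <- list(
    G1 = mlp_init(c(cfg$z_dims[1], cfg$g_hidden, length(si))),
    G2 = mlp_init(c(cfg$z_dims[1] + cfg$z_dims[2], cfg$g_hidden, length(ti))),
    G3 = mlp_init(c(cfg$z_dims[1] + cfg$z_dims[3], cfg$g_hidden, length(ti))))
  discs <- list(
    D1 = mlp_init(c(p, cfg$d_hidden, 1)),
    D2 = mlp_init(c(p, cfg$d_hidden, 1)),
    D3 = mlp_init(c(3, cfg$d_hidden, 1)),
    D4 = mlp_init(c(3, cfg$d_hidden, 1)))
  gopt <- lapply(gens, adam_init)
  dopt <- lapply(discs, adam_init)

  Rinv_c <- chol_rinv(target_c$cov)
  Rinv_d <- chol_rinv(target_d$cov)
  whiten_c <- function(y) sweep(y, 2, target_c$mean) %*% Rinv_c
  whiten_d <- function(y) sweep(y, 2, target_d$mean) %*% Rinv_d
  real_feat <- function(target, Rinv, raw, m) {
    if (!is.null(raw)) {
      rows <- raw[sample.int(nrow(raw), m, replace = TRUE), , drop = FALSE]
      sweep(rows, 2, target$mean) %*% Rinv
    } else matrix(stats::rnorm(m * 3), m, 3)
  }

  m <- cfg$batch
  hist <- list()
  best <- list(ks = Inf, gens = gens, iter = 0L)
  bad_streak <- 0L

  for (it in seq_len(cfg$iters)) {
    # step-decayed learning rates: late-training annealing settles the
    # adversarial game near its equilibrium instead of oscillating around it
    dec <- if (it > 0.8 * cfg$iters) 0.1 else if (it > 0.5 * cfg$iters) 0.3 else 1
    lr_g <- cfg$lr_g * dec
    lr_d <- cfg$lr_d * dec
    ## ---- shared minibatch (used by discriminator and generator updates) ----
    z1 <- matrix(stats::rnorm(m * cfg$z_dims[1]), m)
    z2 <- matrix(stats::rnorm(m * cfg$z_dims[2]), m)
    z3 <- matrix(stats::rnorm(m * cfg$z_dims[3]), m)
    gf <- gen_forward(gens, z1, z2, z3, prior)
    fac_c <- draw_slack(m, slack) / 1.9
    fac_d <- draw_slack(m, slack) / 1.9
    xstd_c <- std_box(gf$x_c, prior)
    xstd_d <- std_box(gf$x_d, prior)
    yw_c <- whiten_c(push_features(surrogate, gf$x_c, fac_c))
    yw_d <- whiten_d(push_features(surrogate, gf$x_d, fac_d))

    ## ---- discriminator updates ----
    prior_real <- std_box(sample_prior(prior, m), prior)
    st <- disc_step(discs$D1, dopt$D1, prior_real, xstd_c, lr_d)
    discs$D1 <- st$net; dopt$D1 <- st$opt; l_d1 <- st$loss
    st <- disc_step(discs$D2, dopt$D2, prior_real, xstd_d, lr_d)
    discs$D2 <- st$net; dopt$D2 <- st$opt; l_d2 <- st$loss
    st <- disc_step(discs$D3, dopt$D3,
                    real_feat(target_c, Rinv_c, raw_features$c, m),
                    yw_c, lr_d)
    discs$D3 <- st$net; dopt$D3 <- st$opt; l_d3 <- st$loss
    st <- disc_step(discs$D4, dopt$D4,
                    real_feat(target_d, Rinv_d, raw_features$d, m),
                    yw_d, lr_d)
    discs$D4 <- st$net; dopt$D4 <- st$opt; l_d4 <- st$loss

    ## ---- generator update (freshly updated discriminators, same batch) ----
    t3 <- gen_term(discs$D3, yw_c)
    t4 <- gen_term(discs$D4, yw_d)
    t1 <- gen_term(discs$D1, xstd_c, weight = cfg$lambda_p)
    t2 <- gen_term(discs$D2, xstd_d, weight = cfg$lambda_p)
    if (!all(is.finite(c(t1$loss, t2$loss, t3$loss, t4$loss, l_d1, l_d2,
                         l_d3, l_d4))))
      stop("NaN/Inf adversarial loss at iteration ", it,
           "; best checkpoint was iteration ", best$iter)

    # features -> parameters (through whitening, slack scaling, surrogate)
    dy_c <- t3$dX %*% t(Rinv_c)
    dy_c[, 1] <- dy_c[, 1] * fac_c; dy_c[, 2] <- dy_c[, 2] * fac_c
    dx_c <- surrogate_input_gradient(surrogate, gf$x_c, dy_c)
    dy_d <- t4$dX %*% t(Rinv_d)
    dy_d[, 1] <- dy_d[, 1] * fac_d; dy_d[, 2] <- dy_d[, 2] * fac_d
    dx_d <- surrogate_input_gradient(surrogate, gf$x_d, dy_d)
    # prior-constraint path (discriminator input is the standardized box)
    if (cfg$lambda_p > 0) {
      dx_c <- dx_c + sweep(t1$dX, 2, (prior$high - prior$low) / 2, "/")
      dx_d <- dx_d + sweep(t2$dX, 2, (prior$high - prior$low) / 2, "/")
    }
    du_c <- dx_c * squash_grad(gf$u_c, prior)
    du_d <- dx_d * squash_grad(gf$u_d, prior)

    g1 <- mlp_backward(gens$G1, gf$f1, du_c[, si] + du_d[, si])
    g2 <- mlp_backward(gens$G2, gf$f2, du_c[, ti, drop = FALSE])
    g3 <- mlp_backward(gens$G3, gf$f3, du_d[, ti, drop = FALSE])
    st <- adam_step(gens$G1, gopt$G1, g1, lr = lr_g)
    gens$G1 <- st$net; gopt$G1 <- st$opt
    st <- adam_step(gens$G2, gopt$G2, g2, lr = lr_g)
    gens$G2 <- st$net; gopt$G2 <- st$opt
    st <- adam_step(gens$G3, gopt$G3, g3, lr = lr_g)
    gens$G3 <- st$net; gopt$G3 <- st$opt

    ## ---- evaluation ----
    if (it %% cfg$eval_every == 0 || it == cfg$iters) {
      ne <- cfg$n_eval
      ez1 <- matrix(stats::rnorm(ne * cfg$z_dims[1]), ne)
      ez2 <- matrix(stats::rnorm(ne * cfg$z_dims[2]), ne)
      ez3 <- matrix(stats::rnorm(ne * cfg$z_dims[3]), ne)
      ef <- gen_forward(gens, ez1, ez2, ez3, prior)
      ey_c <- push_features(surrogate, ef$x_c, draw_slack(ne, slack) / 1.9)
      ey_d <- push_features(surrogate, ef$x_d, draw_slack(ne, slack) / 1.9)
      ks_c <- eval_ks(ey_c, target_c)
      ks_d <- eval_ks(ey_d, target_d)
      sub <- seq_len(min(400L, ne))
      mmd_c <- mmd_rbf(whiten_c(ey_c)[sub, ],
                       matrix(stats::rnorm(length(sub) * 3), ncol = 3))
      mmd_d <- mmd_rbf(whiten_d(ey_d)[sub, ],
                       matrix(stats::rnorm(length(sub) * 3), ncol = 3))
      ks_mean <- mean(c(ks_c, ks_d))
      # model selection on the worst marginal, so no single feature is
      # sacrificed to improve the average
      ks_worst <- max(c(ks_c, ks_d))
      hist[[length(hist) + 1L]] <- data.frame(
        iter = it, ks_mean = ks_mean,
        ks_c_dSL = ks_c[1], ks_c_sSL = ks_c[2], ks_c_TTP = ks_c[3],
        ks_d_dSL = ks_d[1], ks_d_sSL = ks_d[2], ks_d_TTP = ks_d[3],
        mmd_c = mmd_c, mmd_d = mmd_d,
        d1 = l_d1, d2 = l_d2, d3 = l_d3, d4 = l_d4)
      if (cfg$verbose)
        cat(sprintf("iter %5d  KS %.4f  (MMD %.4f/%.4f)\n",
                    it, ks_mean, mmd_c, mmd_d))
      if (ks_worst < best$ks) {
        best <- list(ks = ks_worst, gens = gens, iter = it,
                     ks_mean = ks_mean)
        bad_streak <- 0L
      } else if (ks_worst > max(3 * best$ks, 0.3)) {
        bad_streak <- bad_streak + 1L
        if (bad_streak >= cfg$patience)
          stop(sprintf(paste0("adversarial training diverged: distance %.3f vs ",
                              "best %.3f for %d evaluations (best at iteration %d)"),
                       ks_worst, best$ks, bad_streak, best$iter))
      } else {
        bad_streak <- 0L
      }
      vr_c <- apply(ey_c, 2, stats::var) / diag(target_c$cov)
      vr_d <- apply(ey_d, 2, stats::var) / diag(target_d$cov)
      if (any(c(vr_c, vr_d) < cfg$collapse_tol))
        warning(sprintf("possible mode collapse at iteration %d: generated feature variance below %.0f%% of target",
                        it, 100 * cfg$collapse_tol))
    }
  }

  structure(list(gens = best$gens, discs = discs, prior = prior,
                 target_c = target_c, target_d = target_d,
                 surrogate = surrogate, slack = slack, config = cfg,
                 history = do.call(rbind, hist), best_iter = best$iter,
                 best_ks = best$ks),
            class = "vpop_gan")
}

#' Adversarial losses of a fitted population model
#'
#' Recomputes, on a fresh batch, the binary-classification losses of the four
#' discriminators and the nonsaturating generator terms (output-matching from
#' D3/D4, prior-constraint from D1/D2 weighted by `lambda_p`). Indistinguishable
#' real/generated batches put a discriminator at chance, i.e. loss near
#' log(2).
#'
#' @param object a `"vpop_gan"`.
#' @param n batch size.
#' @param lambda_p prior-constraint weight; defaults to the training value.
#' @param seed optional seed.
#' @return Named numeric vector: `d1`--`d4`, `gen_output`, `gen_prior`,
#'   `gen_total`.
#' @export
gan_losses <- function(object, n = 256, lambda_p = NULL, seed = NULL) {
  stopifnot(inherits(object, "vpop_gan"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lambda_p)) lambda_p <- object$config$lambda_p
  cfg <- object$config; prior <- object$prior
  z1 <- matrix(stats::rnorm(n * cfg$z_dims[1]), n)
  z2 <- matrix(stats::rnorm(n * cfg$z_dims[2]), n)
  z3 <- matrix(stats::rnorm(n * cfg$z_dims[3]), n)
  gf <- gen_forward(object$gens, z1, z2, z3, prior)
  Rinv_c <- chol_rinv(object$target_c$cov)
  Rinv_d <- chol_rinv(object$target_d$cov)
  yw_c <- sweep(push_features(object$surrogate, gf$x_c,
                              draw_slack(n, object$slack) / 1.9),
                2, object$target_c$mean) %*% Rinv_c
  yw_d <- sweep(push_features(object$surrogate, gf$x_d,
                              draw_slack(n, object$slack) / 1.9),
                2, object$target_d$mean) %*% Rinv_d
  dloss <- function(net, real, fake) {
    z <- drop(mlp_predict(net, rbind(real, fake)))
    bce_logits(z, c(rep(1, nrow(real)), rep(0, nrow(fake))))
  }
  l <- c(
    d1 = dloss(object$discs$D1, std_box(sample_prior(prior, n), prior),
               std_box(gf$x_c, prior)),
    d2 = dloss(object$discs$D2, std_box(sample_prior(prior, n), prior),
               std_box(gf$x_d, prior)),
    d3 = dloss(object$discs$D3, matrix(stats::rnorm(n * 3), n), yw_c),
    d4 = dloss(object$discs$D4, matrix(stats::rnorm(n * 3), n), yw_d))
  gl <- function(net, X) mean(softplus(-drop(mlp_predict(net, X))))
  gen_out <- gl(object$discs$D3, yw_c) + gl(object$discs$D4, yw_d)
  gen_pri <- gl(object$discs$D1, std_box(gf$x_c, prior)) +
    gl(object$discs$D2, std_box(gf$x_d, prior))
  c(l, gen_output = gen_out, gen_prior = gen_pri,
    gen_total = gen_out + lambda_p * gen_pri)
}

# ---- methods ---------------------------------------------------------------

#' Generate parameter populations from a fitted model
#'
#' Draws `nsim` virtual cells per group. The shared block (`Ca_amp`,
#' `Ca_diast`, `tau2`, `passive_alpha`) is identical row-for-row across the
#' two returned populations because both groups are driven by the same `z1`
#' realizations; only `(n_A, A_50)` differ. When a slack-length distribution
#' was supplied to [fit_vpop()], an `SL_slack` column (drawn independently
#' per group: the groups are different cells) is attached.
#'
#' @param object a `"vpop_gan"`.
#' @param nsim number of virtual cells per group.
#' @param seed integer seed; reproducible draws.
#' @param ... unused.
#' @return List with data frames `control` and `drug` (columns
#'   [param_names()], optionally `SL_slack`) and the provenance attributes
#'   `best_iter`, `seed`.
#' @export
simulate.vpop_gan <- function(object, nsim = 1000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- object$config
  z1 <- matrix(stats::rnorm(nsim * cfg$z_dims[1]), nsim)
  z2 <- matrix(stats::rnorm(nsim * cfg$z_dims[2]), nsim)
  z3 <- matrix(stats::rnorm(nsim * cfg$z_dims[3]), nsim)
  gf <- gen_forward(object$gens, z1, z2, z3, object$prior)
  ctl <- as.data.frame(gf$x_c)
  drg <- as.data.frame(gf$x_d)
  if (!is.null(object$slack)) {
    ctl$SL_slack <- draw_slack(nsim, object$slack)
    drg$SL_slack <- draw_slack(nsim, object$slack)
  }
  out <- list(control = ctl, drug = drg)
  attr(out, "best_iter") <- object$best_iter
  attr(out, "seed") <- seed
  out
}

#' @export
print.vpop_gan <- function(x, ...) {
  cat("Two-group adversarial virtual population\n")
  cat(sprintf("  trained %d iterations; best worst-feature KS %.4f at iteration %d\n",
              x$config$iters, x$best_ks, x$best_iter))
  cat(sprintf("  targets: control (n=%d cells), drug (n=%d cells)\n",
              x$target_c$n, x$target_d$n))
  invisible(x)
}

#' Group-mean parameters of a fitted population
#'
#' @param object a `"vpop_gan"`.
#' @param nsim generated sample size used to estimate the means.
#' @param seed seed for the estimate.
#' @param ... unused.
#' @return 2 x 6 matrix (rows `control`, `drug`).
#' @export
coef.vpop_gan <- function(object, nsim = 4000, seed = 1, ...) {
  pops <- simulate(object, nsim = nsim, seed = seed)
  rbind(control = colMeans(pops$control[param_names()]),
        drug = colMeans(pops$drug[param_names()]))
}

#' @export
summary.vpop_gan <- function(object, nsim = 4000, seed = 1, ...) {
  cm <- coef(object, nsim = nsim, seed = seed)
  pops <- simulate(object, nsim = nsim, seed = seed)
  structure(list(coef = cm, shift = cm["drug", ] - cm["control", ],
                 best_ks = object$best_ks, best_iter = object$best_iter,
                 history = object$history,
                 report = population_report(pops, list(c = object$target_c,
                                                       d = object$target_d),
                                            object$surrogate)),
            class = "summary.vpop_gan")
}

#' @export
print.summary.vpop_gan <- function(x, ...) {
  cat("Two-group adversarial virtual population\n")
  cat(sprintf("  best worst-feature KS %.4f at iteration %d\n", x$best_ks, x$best_iter))
  cat("\nGroup-mean parameters:\n")
  print(round(x$coef, 4))
  cat("\nDrug - control mean shift:\n")
  print(round(x$shift, 4))
  cat("\n")
  print(x$report)
  invisible(x)
}

#' Diagnostic plot of a fitted population
#'
#' Overlays generated feature marginals (surrogate pushforward of a generated
#' population) on the target Gaussian marginals for both groups.
#'
#' @param x a `"vpop_gan"`.
#' @param nsim generated sample size.
#' @param seed seed.
#' @param ... passed to [graphics::hist()].
#' @export
plot.vpop_gan <- function(x, nsim = 2000, seed = 1, ...) {
  pops <- simulate(x, nsim = nsim, seed = seed)
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (grp in c("control", "drug")) {
    target <- if (grp == "control") x$target_c else x$target_d
    fac <- if (is.null(x$slack)) rep(1, nsim)
           else pops[[grp]]$SL_slack / 1.9
    y <- push_features(x$surrogate, as.matrix(pops[[grp]][param_names()]), fac)
    for (j in 1:3) {
      nm <- c("dSL", "sSL", "TTP")[j]
      graphics::hist(y[, j], freq = FALSE, breaks = 30,
                     main = paste(grp, nm), xlab = nm, ...)
      xs <- seq(min(y[, j]), max(y[, j]), length.out = 200)
      graphics::lines(xs, stats::dnorm(xs, target$mean[[j]],
                                       sqrt(target$cov[j, j])), col = 2)
    }
  }
  invisible(x)
}

#' Population diagnostics report
#'
#' Summarizes generated parameter populations: per-parameter marginal moments,
#' pairwise correlation matrices per group, feature-space agreement with the
#' targets (per-feature KS distance of the surrogate pushforward), and a flag
#' for the expected coupling between `n_A` and `A_50`.
#'
#' @param pops list with `control` and `drug` parameter data frames (as
#'   returned by [simulate.vpop_gan()]).
#' @param targets list `list(c =, d =)` of `"feature_density"` objects.
#' @param simulator a `"sarco_surrogate"` (or any object with a matching
#'   `predict` method) used to push parameters to features.
#' @return Object of class `"population_report"`.
#' @export
population_report <- function(pops, targets, simulator) {
  stats_for <- function(df, target) {
    X <- as.matrix(df[param_names()])
    fac <- if ("SL_slack" %in% names(df)) df$SL_slack / 1.9 else rep(1, nrow(X))
    y <- push_features(simulator, X, fac)
    list(mean = colMeans(X), sd = apply(X, 2, stats::sd),
         cor = stats::cor(X), ks = eval_ks(y, target))
  }
  sc <- stats_for(pops$control, targets$c)
  sd_ <- stats_for(pops$drug, targets$d)
  coupling <- c(control = sc$cor["n_A", "A_50"], drug = sd_$cor["n_A", "A_50"])
  structure(list(control = sc, drug = sd_, coupling = coupling,
                 coupling_flagged = any(abs(coupling) > 0.3)),
            class = "population_report")
}

#' @export
print.population_report <- function(x, ...) {
  cat("Population report\n")
  for (grp in c("control", "drug")) {
    s <- x[[grp]]
    cat(sprintf("  %s: feature KS (dSL, sSL, TTP) = %s\n", grp,
                paste(sprintf("%.3f", s$ks), collapse = ", ")))
  }
  cat(sprintf("  n_A~A_50 correlation: control %.3f, drug %.3f%s\n",
              x$coupling[["control"]], x$coupling[["drug"]],
              if (x$coupling_flagged) " (coupling flagged)" else ""))
  invisible(x)
}
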