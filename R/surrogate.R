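# Uniform prior over inferred parameters, simulator-backed training sets, and
# the differentiable feed-forward surrogate of the parameter-to-feature map
# used inside adversarial training.

#' Names and grouping of the inferred model parameters
#'
#' The inference operates on six parameters, in this fixed column order:
#' `Ca_amp`, `Ca_diast`, `tau2`, `n_A`, `A_50`, `passive_alpha`. The
#' drug-insensitive (shared) block `x1` comprises the calcium-transient
#' parameters and the passive stiffness scale; the drug-target block `x2` is
#' `(n_A, A_50)`. `SL_slack` is estimated directly from data and is not part
#' of this schema.
#'
#' @return Character vector of the six parameter names.
#' @export
param_names <- function() {
  c("Ca_amp", "Ca_diast", "tau2", "n_A", "A_50", "passive_alpha")
}

#' @rdname param_names
#' @export
shared_param_idx <- function() c(1L, 2L, 3L, 6L)

#' @rdname param_names
#' @export
target_param_idx <- function() c(4L, 5L)

#' Uniform prior box over the inferred parameters
#'
#' @param Ca_amp,Ca_diast,tau2,n_A,A_50,passive_alpha length-2 numeric
#'   `(low, high)` ranges. Defaults are the ranges used for inference:
#'   `Ca_amp` \[0.5, 2\] uM, `Ca_diast` \[0.05, 0.4\] uM, `tau2` \[20, 140\] ms,
#'   `n_A` \[2, 20\], `A_50` \[0.4, 1.5\], `passive_alpha` \[0.05, 7\].
#' @return Object of class `"prior_box"`: list with `low` and `high` named
#'   6-vectors.
#' @export
prior_box <- function(Ca_amp = c(0.5, 2), Ca_diast = c(0.05, 0.4),
                      tau2 = c(20, 140), n_A = c(2, 20),
                      A_50 = c(0.4, 1.5), passive_alpha = c(0.05, 7)) {
  rng <- list(Ca_amp = Ca_amp, Ca_diast = Ca_diast, tau2 = tau2, n_A = n_A,
              A_50 = A_50, passive_alpha = passive_alpha)
  ok <- vapply(rng, function(r) is.numeric(r) && length(r) == 2L && r[1] < r[2],
               logical(1))
  if (!all(ok))
    stop("each range must be numeric (low, high) with low < high: ",
         paste(names(rng)[!ok], collapse = ", "))
  low <- vapply(rng, `[`, numeric(1), 1L)
  high <- vapply(rng, `[`, numeric(1), 2L)
  names(low) <- names(high) <- param_names()
  structure(list(low = low, high = high), class = "prior_box")
}

#' @export
print.prior_box <- function(x, ...) {
  cat("Uniform prior box:\n")
  for (nm in names(x$low))
    cat(sprintf("  %-13s [%g, %g]\n", nm, x$low[[nm]], x$high[[nm]]))
  invisible(x)
}

#' Sample parameters i.i.d. from the prior box
#'
#' @param box a [prior_box()].
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return n x 6 matrix with columns [param_names()].
#' @export
sample_prior <- function(box = prior_box(), n, seed = NULL) {
  stopifnot(inherits(box, "prior_box"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- length(box$low)
  u <- matrix(stats::runif(n * p), n, p)
  x <- sweep(sweep(u, 2L, box$high - box$low, "*"), 2L, box$low, "+")
  colnames(x) <- names(box$low)
  x
}

row_params <- function(x, SL_slack = 1.9) {
  sarcomere_params(Ca_amp = x[[1]], Ca_diast = x[[2]], tau2 = x[[3]],
                   n_A = x[[4]], A_50 = x[[5]], passive_alpha = x[[6]],
                   SL_slack = SL_slack)
}

#' Build a surrogate training set by running the simulator on prior samples
#'
#' Samples parameters from the prior, runs [simulate_unloaded()] for each with
#' `SL_slack` fixed at 1.9 um (the surrogate learns the unscaled map; slack
#' scaling of `dSL`/`sSL` is applied downstream when composing with measured
#' slack lengths), and extracts `(dSL, sSL, TTP)` with [fit_features()]. Rows
#' whose simulation or feature fit fails are dropped and counted.
#'
#' @param box a [prior_box()].
#' @param n number of prior samples.
#' @param seed integer seed for the prior draw.
#' @param constants a [model_constants()] object.
#' @param t_grid simulation time grid (ms).
#' @param max_drop_frac error if more than this fraction of rows is dropped
#'   (default 0.2), which indicates a misconfigured model closure.
#' @return List with `X` (kept prior rows, n_kept x 6), `Y` (n_kept x 3
#'   features), `dropped` (count).
#' @export
build_training_set <- function(box = prior_box(), n, seed = 1,
                               constants = model_constants(),
                               t_grid = seq(0, 800, by = 2),
                               max_drop_frac = 0.2) {
  X <- sample_prior(box, n, seed)
  Y <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("dSL", "sSL", "TTP")))
  for (i in seq_len(n)) {
    Y[i, ] <- tryCatch({
      tr <- simulate_unloaded(row_params(X[i, ]), constants, t_grid)
      coef(fit_features(tr))
    }, error = function(e) c(NA_real_, NA_real_, NA_real_))
  }
  keep <- stats::complete.cases(Y)
  dropped <- sum(!keep)
  if (dropped > max_drop_frac * n)
    stop(sprintf("%d/%d training rows failed (> %.0f%%); model closure looks misconfigured",
                 dropped, n, 100 * max_drop_frac))
  list(X = X[keep, , drop = FALSE], Y = Y[keep, , drop = FALSE],
       dropped = dropped)
}

#' Train the feed-forward surrogate of the parameter-to-feature map
#'
#' Fits a fully connected network (default three tanh hidden layers of 128
#' units) to the simulator training set by minibatch Adam on the mean squared
#' error, with inputs min-max scaled to \[-1, 1\] and outputs standardized.
#' A held-out validation split reports an R-squared per output; training
#' errors out if any falls below `r2_floor`, which usually means more samples
#' or epochs are needed.
#'
#' @param X n x 6 parameter matrix (see [build_training_set()]).
#' @param Y n x 3 feature matrix.
#' @param hidden integer vector of hidden-layer widths.
#' @param epochs number of passes over the training split.
#' @param batch minibatch size.
#' @param lr initial Adam learning rate (step-decayed late in training).
#' @param val_frac fraction held out for validation.
#' @param r2_floor minimum acceptable validation R-squared per output
#'   (default 0.98).
#' @param seed integer seed (weight init + batch shuffling).
#' @param verbose print progress every 50 epochs.
#' @return Object of class `"sarco_surrogate"`: the network, normalization
#'   constants, and `r2` (named validation R-squared per feature).
#' @export
train_surrogate <- function(X, Y, hidden = c(128, 128, 128), epochs = 600,
                            batch = 256, lr = 2e-3, val_frac = 0.1,
                            r2_floor = 0.98, seed = 1, verbose = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 50)
  set.seed(seed)
  n <- nrow(X)
  idx_val <- sample.int(n, max(1L, round(val_frac * n)))
  idx_tr <- setdiff(seq_len(n), idx_val)

  x_lo <- apply(X, 2, min); x_hi <- apply(X, 2, max)
  x_half <- (x_hi - x_lo) / 2
  x_mid <- (x_hi + x_lo) / 2
  y_mu <- colMeans(Y[idx_tr, , drop = FALSE])
  y_sd <- apply(Y[idx_tr, , drop = FALSE], 2, stats::sd)
  if (any(y_sd <= 0)) stop("constant feature column; cannot standardize")

  Xs <- sweep(sweep(X, 2, x_mid), 2, x_half, "/")
  Ys <- sweep(sweep(Y, 2, y_mu), 2, y_sd, "/")

  net <- mlp_init(c(ncol(X), hidden, ncol(Y)), seed = seed)
  opt <- adam_init(net)
  ntr <- length(idx_tr)
  steps_per <- max(1L, floor(ntr / batch))
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * if (ep > 0.85 * epochs) 0.1 else if (ep > 0.6 * epochs) 0.3 else 1
    perm <- sample(idx_tr)
    for (b in seq_len(steps_per)) {
      rows <- perm[((b - 1L) * batch + 1L):min(b * batch, ntr)]
      xb <- Xs[rows, , drop = FALSE]
      yb <- Ys[rows, , drop = FALSE]
      fwd <- mlp_forward(net, xb)
      dOut <- 2 * (fwd$out - yb) / length(yb)
      gr <- mlp_backward(net, fwd, dOut)
      st <- adam_step(net, opt, gr, lr = lr_ep)
      net <- st$net; opt <- st$opt
    }
    if (verbose && ep %% 50 == 0) {
      pv <- mlp_predict(net, Xs[idx_val, , drop = FALSE])
      cat(sprintf("epoch %d val MSE %.5f\n", ep, mean((pv - Ys[idx_val, ])^2)))
    }
  }

  pv <- mlp_predict(net, Xs[idx_val, , drop = FALSE])
  yv <- Ys[idx_val, , drop = FALSE]
  r2 <- 1 - colSums((pv - yv)^2) / colSums(sweep(yv, 2, colMeans(yv))^2)
  names(r2) <- colnames(Y)
  m <- structure(list(net = net, x_mid = x_mid, x_half = x_half,
                      y_mu = y_mu, y_sd = y_sd, r2 = r2,
                      hidden = hidden, n_train = ntr),
                 class = "sarco_surrogate")
  if (any(r2 < r2_floor))
    stop(sprintf("validation R-squared below floor %.3g (%s); increase training samples or epochs",
                 r2_floor,
                 paste(sprintf("%s=%.4f", names(r2), r2), collapse = ", ")))
  m
}

#' @export
print.sarco_surrogate <- function(x, ...) {
  cat(sprintf("Feed-forward surrogate (6 -> %s -> 3), %d training rows\n",
              paste(x$hidden, collapse = "-"), x$n_train))
  cat("  validation R-squared:",
      paste(sprintf("%s %.4f", names(x$r2), x$r2), collapse = ", "), "\n")
  invisible(x)
}

#' Predict features from parameters with the surrogate
#'
#' Deterministic, vectorized over rows of `x`.
#'
#' @param object a `"sarco_surrogate"`.
#' @param x numeric vector (length 6) or n x 6 matrix in [param_names()] order.
#' @param ... unused.
#' @return n x 3 matrix of `(dSL, sSL, TTP)` at `SL_slack` = 1.9 um.
#' @export
predict.sarco_surrogate <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  xs <- sweep(sweep(as.matrix(x), 2, object$x_mid), 2, object$x_half, "/")
  ys <- mlp_predict(object$net, xs)
  y <- sweep(sweep(ys, 2, object$y_sd, "*"), 2, object$y_mu, "+")
  colnames(y) <- names(object$y_mu)
  y
}

# Gradient of sum(dY * predict(m, x)) with respect to x (n x 6). Chain rule
# through output de-standardization and input scaling.
surrogate_input_gradient <- function(m, x, dY) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  xs <- sweep(sweep(as.matrix(x), 2, m$x_mid), 2, m$x_half, "/")
  dOut <- sweep(as.matrix(dY), 2, m$y_sd, "*")
  dXs <- mlp_input_gradient(m$net, xs, dOut)
  sweep(dXs, 2, m$x_half, "/")
}
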