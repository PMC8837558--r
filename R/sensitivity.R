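#' Mean Decrease Accuracy global sensitivity analysis
#'
#' Permutation-importance sensitivity of a model-derived metric to input
#' parameters. A regression model (random forest by default, or linear) is
#' fitted once between parameters and the metric and then frozen; its
#' R-squared is evaluated on a held-out split, and re-evaluated after randomly
#' permuting the values of each parameter column one at a time. The score for
#' parameter j is
#' \deqn{MDA_j = R^2_{base} - \mathrm{mean}_r \max(0, R^2_{perm(j, r)}),}
#' averaged over `n_repeats` independent permutations (one permutation per
#' repeat, shared across columns). The permuted R-squared is clamped at the
#' no-skill level 0: a frozen regressor fed shuffled inputs can be
#' arbitrarily anticorrelated with the target, and counting that below
#' no-skill would inflate importances past the share of variance a
#' parameter explains.
#'
#' @param X n x p parameter matrix (n >= 50), column names used as labels.
#' @param y numeric metric of length n (must not be constant).
#' @param regressor `"rf"` (random forest) or `"linear"`.
#' @param n_repeats permutation repeats per parameter (>= 1, default 10).
#' @param holdout_frac fraction of rows held out for evaluation (default
#'   0.25); evaluating on held-out data avoids the optimistic bias of
#'   training-set R-squared.
#' @param seed integer seed controlling the split and the permutations.
#' @param ... passed to the underlying regressor
#'   (e.g. `ntree` for [randomForest::randomForest()]).
#' @return Object of class `"mda"`: `scores` (named), `spread` (sd over
#'   repeats), `r2_base`, `regressor`.
#' @examples
#' set.seed(1)
#' X <- matrix(runif(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
#' fit <- mda(X, X[, 1] + 0.1 * rnorm(200), regressor = "linear")
#' fit$scores
#' @export
mda <- function(X, y, regressor = c("rf", "linear"), n_repeats = 10,
                holdout_frac = 0.25, seed = 1, ...) {
  regressor <- match.arg(regressor)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), n_repeats >= 1)
  if (nrow(X) < 50) stop("at least 50 rows are required")
  if (stats::sd(y) == 0) stop("degenerate target: metric y is constant")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  set.seed(seed)
  n <- nrow(X)
  idx_te <- sample.int(n, max(2L, round(holdout_frac * n)))
  idx_tr <- setdiff(seq_len(n), idx_te)
  df_tr <- data.frame(y = y[idx_tr], X[idx_tr, , drop = FALSE])
  X_te <- X[idx_te, , drop = FALSE]
  y_te <- y[idx_te]

  fit <- switch(regressor,
    rf = randomForest::randomForest(y ~ ., data = df_tr, ...),
    linear = stats::lm(y ~ ., data = df_tr, ...))
  pred <- function(Xnew) {
    as.numeric(stats::predict(fit, newdata = as.data.frame(Xnew)))
  }
  r2 <- function(p) 1 - sum((y_te - p)^2) / sum((y_te - mean(y_te))^2)
  r2_base <- r2(pred(X_te))

  p <- ncol(X)
  # one permutation per repeat, shared across columns: scores are exactly
  # invariant to column order and fully determined by the seed
  perms <- lapply(seq_len(n_repeats), function(r) sample.int(nrow(X_te)))
  perm_r2 <- matrix(NA_real_, n_repeats, p, dimnames = list(NULL, colnames(X)))
  for (j in seq_len(p)) {
    for (r in seq_len(n_repeats)) {
      Xp <- X_te
      Xp[, j] <- Xp[perms[[r]], j]
      # clamp at the no-skill level: a permuted model that predicts worse
      # than the mean carries no more information than one predicting it
      perm_r2[r, j] <- max(0, r2(pred(Xp)))
    }
  }
  scores <- r2_base - colMeans(perm_r2)
  spread <- apply(perm_r2, 2, stats::sd)
  structure(list(scores = scores, spread = spread, r2_base = r2_base,
                 regressor = regressor, n_repeats = n_repeats),
            class = "mda")
}

#' @export
print.mda <- function(x, ...) {
  cat(sprintf("Mean Decrease Accuracy (%s regressor, base R2 = %.4f, %d repeats)\n",
              x$regressor, x$r2_base, x$n_repeats))
  ord <- order(x$scores, decreasing = TRUE)
  for (j in ord)
    cat(sprintf("  %-14s %+.4f (sd %.4f)\n", names(x$scores)[j],
                x$scores[j], x$spread[j]))
  invisible(x)
}

#' @export
plot.mda <- function(x, ...) {
  ord <- order(x$scores)
  graphics::barplot(x$scores[ord], horiz = TRUE, las = 1,
                    xlab = "Mean decrease in R-squared", ...)
  invisible(x)
}
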