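# Twitch feature extraction: the three-parameter log-Gaussian shortening
# curve, its nonlinear least-squares fit, and per-group multivariate Gaussian
# feature densities.

#' Parametric shortening curve
#'
#' Evaluates the three-parameter descriptor of an unloaded shortening trace,
#' \deqn{SL(t) = (dSL - sSL)\left(1 - e^{-\log^2(t/TTP)}\right) + sSL,}
#' which starts at the diastolic length `dSL`, dips to the systolic length
#' `sSL` exactly at `t = TTP`, and returns to `dSL` as \eqn{t \to 0^+} or
#' \eqn{t \to \infty}.
#'
#' @param t time (ms), strictly positive (vectorized).
#' @param fv named list or vector with `dSL`, `sSL` (um) and `TTP` (ms).
#' @return Sarcomere length (um), same length as `t`.
#' @examples
#' eval_shortening_curve(120, c(dSL = 1.80, sSL = 1.65, TTP = 120))  # 1.65
#' @export
eval_shortening_curve <- function(t, fv) {
  if (any(t <= 0)) stop("t must be > 0")
  fv <- as.list(fv)
  (fv$dSL - fv$sSL) * (1 - exp(-log(t / fv$TTP)^2)) + fv$sSL
}

#' Extract shortening features from a trace
#'
#' Nonlinear least-squares fit of the shortening curve (see
#' [eval_shortening_curve()]) to a sarcomere-length trace, returning the
#' feature triple `(dSL, sSL, TTP)`. Initialization: `dSL` from the first
#' sample, `sSL` from the minimum, `TTP` from the argmin time; `TTP` is
#' bounded inside the positive part of the trace span and `sSL` below `dSL`.
#' Samples at `t <= 0` are dropped (the curve is defined for `t > 0`).
#'
#' @param tr a [trace()] of kind `"SL"` with at least 10 samples spanning the
#'   twitch.
#' @return Object of class `"shortening_fit"`: list with `coef` (named vector
#'   `dSL`, `sSL`, `TTP`), `residual_norm`, and fitted values.
#' @examples
#' tt <- seq(1, 800, by = 2)
#' tr <- trace(tt, eval_shortening_curve(tt, c(dSL = 1.85, sSL = 1.62, TTP = 150)), "SL")
#' coef(fit_features(tr))
#' @export
fit_features <- function(tr) {
  stopifnot(inherits(tr, "trace"))
  keep <- tr$t > 0
  t <- tr$t[keep]; v <- tr$v[keep]
  if (length(t) < 10) stop("at least 10 samples with t > 0 are required")
  if (diff(range(v)) < 1e-9)
    stop("degenerate fit: flat trace (no shortening to fit)")
  imin <- which.min(v)
  init <- list(dSL = v[1], sSL = min(v), TTP = max(t[imin], min(t) * 1.01))
  lower <- c(dSL = min(v) - diff(range(v)), sSL = min(v) - diff(range(v)),
             TTP = min(t))
  upper <- c(dSL = max(v) + diff(range(v)), sSL = max(v),
             TTP = max(t))
  dat <- data.frame(t = t, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ (dSL - sSL) * (1 - exp(-log(t / TTP)^2)) + sSL,
                      data = dat, start = init, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 300, ftol = 1e-15, ptol = 1e-15)),
    error = function(e)
      stop(sprintf(paste0("shortening-curve fit failed (%s); initializer ",
                          "dSL=%.4g sSL=%.4g TTP=%.4g"),
                   conditionMessage(e), init$dSL, init$sSL, init$TTP),
           call. = FALSE))
  cf <- stats::coef(fit)
  if (cf[["dSL"]] <= cf[["sSL"]])
    stop("degenerate fit: fitted dSL <= sSL")
  structure(list(coef = c(dSL = cf[["dSL"]], sSL = cf[["sSL"]],
                          TTP = cf[["TTP"]]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 t = t, fitted = stats::fitted(fit)),
            class = "shortening_fit")
}

#' @export
print.shortening_fit <- function(x, ...) {
  cat(sprintf("Shortening fit: dSL = %.4f um, sSL = %.4f um, TTP = %.4g ms\n",
              x$coef[["dSL"]], x$coef[["sSL"]], x$coef[["TTP"]]))
  invisible(x)
}

#' @export
coef.shortening_fit <- function(object, ...) object$coef

#' Multivariate Gaussian feature density for one group
#'
#' Maximum-likelihood mean and covariance of the `(dSL, sSL, TTP)` features of
#' one cell group.
#'
#' @param features numeric matrix (n x 3) with columns `dSL`, `sSL`, `TTP`;
#'   n >= 4.
#' @param group group label (e.g. `"control"`, `"drug"`).
#' @return Object of class `"feature_density"`: list with `mean` (3-vector),
#'   `cov` (3 x 3), `n`, `group`.
#' @export
fit_feature_density <- function(features, group = "control") {
  features <- as.matrix(features)
  if (nrow(features) < 4) stop("at least 4 feature rows are required")
  if (ncol(features) != 3) stop("features must have 3 columns (dSL, sSL, TTP)")
  if (is.null(colnames(features))) colnames(features) <- c("dSL", "sSL", "TTP")
  mu <- colMeans(features)
  # MLE covariance (divisor n), matching a fitted Gaussian density
  xc <- sweep(features, 2, mu)
  S <- crossprod(xc) / nrow(features)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev)))
    stop("rank-deficient feature covariance; add jitter or more cells")
  structure(list(mean = mu, cov = S, n = nrow(features), group = group),
            class = "feature_density")
}

#' @export
print.feature_density <- function(x, ...) {
  cat(sprintf("Feature density [%s], n = %d cells:\n", x$group, x$n))
  cat(sprintf("  mean: dSL = %.4f um, sSL = %.4f um, TTP = %.4g ms\n",
              x$mean[[1]], x$mean[[2]], x$mean[[3]]))
  cat(sprintf("  sd:   dSL = %.4f, sSL = %.4f, TTP = %.4g\n",
              sqrt(x$cov[1, 1]), sqrt(x$cov[2, 2]), sqrt(x$cov[3, 3])))
  invisible(x)
}

#' Sample feature vectors from a fitted density
#'
#' @param d a `"feature_density"` object.
#' @param n number of samples (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @return n x 3 matrix with columns `dSL`, `sSL`, `TTP`.
#' @export
sample_features <- function(d, n, seed = NULL) {
  stopifnot(inherits(d, "feature_density"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, names(d$mean))))
  x <- MASS::mvrnorm(n, mu = d$mean, Sigma = d$cov)
  x <- matrix(x, ncol = 3, dimnames = list(NULL, names(d$mean)))
  x
}
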