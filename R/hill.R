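#' Fit a Hill curve to normalized force-calcium data
#'
#' Least-squares fit of the Hill relation
#' \deqn{F = \frac{Ca^h}{Ca^h + Ca_{50}^h}}
#' to normalized steady-state force measurements, estimating the Hill
#' coefficient `h` and the calcium sensitivity `Ca_50` (calcium at
#' half-maximal force). Starting values are taken from the data (log-logit
#' regression for `h`, interpolated half-maximum crossing for `Ca_50`), and
#' the fit is invariant to reparameterizing the abscissa (e.g. to pCa) since
#' the residuals depend on calcium values only through the model.
#'
#' @param ca calcium concentrations (uM), > 0, at least 4 points.
#' @param f normalized forces in `[0, 1]`, same length as `ca`.
#' @return An object of class `"hill_fit"`: list with `h`, `Ca_50`,
#'   `residual_norm`, and the data.
#' @examples
#' ca <- 10^seq(-1, 1, length.out = 12)
#' f <- ca^6 / (ca^6 + 2^6)
#' fit_hill(ca, f)
#' @export
fit_hill <- function(ca, f) {
  stopifnot(is.numeric(ca), is.numeric(f), length(ca) == length(f))
  if (length(ca) < 4) stop("at least 4 points are required")
  if (any(ca <= 0)) stop("ca must be > 0")
  if (any(f < -1e-8) || any(f > 1 + 1e-8))
    stop("f must be normalized to [0, 1]")
  if (diff(range(f)) < 1e-12)
    stop("degenerate fit: all force values are equal")
  f <- pmin(pmax(f, 0), 1)

  # starting values from the data
  eps <- 1e-6
  fc <- pmin(pmax(f, eps), 1 - eps)
  lg <- stats::coef(stats::lm(log(fc / (1 - fc)) ~ log(ca)))
  h0 <- max(as.numeric(lg[2]), 0.2)
  ca50_0 <- exp(-as.numeric(lg[1]) / as.numeric(lg[2]))
  if (!is.finite(ca50_0) || ca50_0 <= 0) ca50_0 <- stats::median(ca)

  dat <- data.frame(ca = ca, f = f)
  fit <- minpack.lm::nlsLM(
    f ~ ca^h / (ca^h + ca50^h), data = dat,
    start = list(h = h0, ca50 = ca50_0),
    lower = c(h = 1e-3, ca50 = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- stats::coef(fit)
  structure(list(h = as.numeric(cf["h"]), Ca_50 = as.numeric(cf["ca50"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 ca = ca, f = f),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: h = %.4g, Ca_50 = %.4g uM (residual norm %.3g)\n",
              x$h, x$Ca_50, x$residual_norm))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(h = object$h, Ca_50 = object$Ca_50)
}

#' @export
predict.hill_fit <- function(object, ca = object$ca, ...) {
  ca^object$h / (ca^object$h + object$Ca_50^object$h)
}
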