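#' Biexponential intracellular calcium transient
#'
#' Evaluates the driving calcium transient
#' \deqn{Ca(t) = Ca_{diast} + \frac{Ca_{amp} - Ca_{diast}}{\beta}
#'   \left(e^{-(t - t_{start})/\tau_1} - e^{-(t - t_{start})/\tau_2}\right)}
#' for \eqn{t > t_{start}} and \eqn{Ca(t) = Ca_{diast}} before the stimulus.
#' The normalizer \eqn{\beta} is the signed extremum of the biexponential,
#' \deqn{\beta = r^{-1/(r-1)} - r^{-r/(r-1)}, \qquad r = \tau_1/\tau_2,}
#' so the transient peaks exactly at `Ca_amp` for any \eqn{\tau_1 \neq \tau_2}
#' (the expression is valid on both sides of \eqn{r = 1}).
#'
#' @param t time points (ms), numeric vector, all `>= 0`.
#' @param p a [sarcomere_params()] object (uses `Ca_amp`, `Ca_diast`, `tau2`).
#' @param c a [model_constants()] object (uses `tau1`, `t_start`).
#' @return Calcium concentration (uM), same length as `t`.
#' @examples
#' tt <- seq(0, 600, by = 1)
#' ca <- calcium_transient(tt, sarcomere_params(), model_constants())
#' max(ca)  # equals Ca_amp
#' @export
calcium_transient <- function(t, p = sarcomere_params(), c = model_constants()) {
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0))
  if (isTRUE(all.equal(c$tau1, p$tau2)))
    stop("degenerate calcium-transient normalization: tau1 == tau2")
  u <- t - c$t_start
  out <- rep(p$Ca_diast, length(t))
  on <- u > 0
  if (any(on)) {
    b <- biexp_norm(c$tau1, p$tau2)
    out[on] <- p$Ca_diast + (p$Ca_amp - p$Ca_diast) / b *
      (exp(-u[on] / c$tau1) - exp(-u[on] / p$tau2))
  }
  out
}

# Signed extremum of exp(-u/tau1) - exp(-u/tau2); normalizes the transient
# peak to Ca_amp - Ca_diast exactly.
biexp_norm <- function(tau1, tau2) {
  r <- tau1 / tau2
  r^(-1 / (r - 1)) - r^(-r / (r - 1))
}
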