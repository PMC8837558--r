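#' Permissive-to-nonpermissive ratio of regulatory units
#'
#' Hill relation between the fraction `A` of TnC with bound calcium and the
#' ratio \eqn{\bar A} of regulatory units in permissive states:
#' \deqn{\bar A = \frac{A^{n_A}}{A^{n_A} + A_{50}^{n_A}}.}
#'
#' @param A fraction of calcium-bound TnC, numeric `>= 0` (vectorized).
#' @param n_A Hill coefficient (> 0).
#' @param A_50 half-activation point (> 0).
#' @return \eqn{\bar A} in `[0, 1)`, strictly increasing in `A`.
#' @examples
#' permissive_ratio(0.45, 12, 0.45)  # 0.5 at the midpoint
#' @export
permissive_ratio <- function(A, n_A, A_50) {
  stopifnot(is.numeric(A), n_A > 0, A_50 > 0)
  if (any(A < 0)) stop("A must be >= 0")
  An <- A^n_A
  An / (An + A_50^n_A)
}

#' Passive tension of the sarcomere
#'
#' Piecewise-exponential passive tension as a function of stretch ratio
#' \eqn{\lambda} (relative to slack length):
#' \deqn{T_p(\lambda) = \begin{cases}
#'   \alpha (1 - e^{\beta (1 - \lambda)}) & \lambda < 1 \\
#'   \alpha (e^{\beta (\lambda - 1)} - 1) & \lambda \ge 1
#' \end{cases}}
#' Negative below slack (restoring), zero at slack, positive above; the two
#' branches join with a continuous first derivative \eqn{\alpha\beta} at
#' \eqn{\lambda = 1}.
#'
#' @param lam stretch ratio (> 0), vectorized.
#' @param passive_alpha tension scale (> 0).
#' @param passive_beta exponent (default 10).
#' @return Passive tension in the same relative units as `passive_alpha`.
#' @examples
#' passive_tension(c(0.9, 1, 1.1), 1, 10)
#' @export
passive_tension <- function(lam, passive_alpha, passive_beta = 10) {
  stopifnot(is.numeric(lam), passive_alpha > 0, passive_beta > 0)
  if (any(lam <= 0)) stop("lam must be > 0")
  ifelse(lam < 1,
         passive_alpha * (1 - exp(passive_beta * (1 - lam))),
         passive_alpha * (exp(passive_beta * (lam - 1)) - 1))
}

#' Active tension
#'
#' Active tension generated by formed cross-bridge groups,
#' \eqn{T_a = S_a \, G_{XB} \, \max(0, 1 + s)}: proportional to the scaling
#' constant `S_a`, the formed-group fraction, and a mean-strain factor that
#' vanishes for strongly negative strain.
#'
#' @param state list with elements `G_XB` (in `[0,1]`) and `s` (mean strain).
#' @param p a [sarcomere_params()] object (unused by the default closure but
#'   part of the interface).
#' @param c a [model_constants()] object (uses `S_a`).
#' @return Active tension (relative tension units).
#' @export
active_tension <- function(state, p = sarcomere_params(), c = model_constants()) {
  stopifnot(is.list(state), !is.null(state$G_XB), !is.null(state$s))
  c$S_a * state$G_XB * pmax(0, 1 + state$s)
}

#' Time derivative of the sarcomere model state
#'
#' Reference (R-level) right-hand side of the model. The cross-bridge group
#' fraction follows
#' \deqn{dG_{XB}/dt = f_G(\bar A)(1 - G_{XB}) - g_G(\bar A, s)\, G_{XB}}
#' with \eqn{f_G = k_f \bar A^{n_G}} and \eqn{g_G = k_g (1 + c_s s^2)};
#' TnC calcium binding follows \eqn{dA/dt = k_{on} Ca (1-A) - k_{off} A};
#' mean strain follows \eqn{ds/dt = \kappa_s \, d\lambda/dt - s/\tau_s}.
#'
#' In unloaded mode (`mode = "unloaded"`) the stretch ratio is slaved to the
#' quasi-static balance between active tension and the passive restoring
#' magnitude, \eqn{\lambda = 1 - \log(1 + T_a/\alpha)/\beta}, and
#' \eqn{d\lambda/dt} is eliminated by the chain rule, which makes the strain
#' equation linear in \eqn{ds/dt}. In fixed-length mode `lam_fixed` is used
#' and \eqn{d\lambda/dt = 0}.
#'
#' A compiled translation of this function drives the integrators; this R
#' version is exported as the readable reference and for direct use with
#' [deSolve::lsoda()].
#'
#' @param t time (ms).
#' @param state named numeric vector `c(G_XB=, A=, s=)`.
#' @param p a [sarcomere_params()] object.
#' @param c a [model_constants()] object.
#' @param mode `"unloaded"` or `"fixed"`.
#' @param lam_fixed stretch ratio used when `mode = "fixed"`.
#' @param ca_const if non-`NULL`, clamp calcium at this constant (uM) instead
#'   of the transient (isosarcometric protocol).
#' @return List: derivatives `c(dG_XB, dA, ds)`, then named diagnostics
#'   `lam`, `Ca`, `Ta` (deSolve convention).
#' @export
sarcomere_rhs <- function(t, state, p = sarcomere_params(),
                          c = model_constants(), mode = "unloaded",
                          lam_fixed = 1, ca_const = NULL) {
  if (any(!is.finite(state)))
    stop("integration failure: non-finite state at t = ", t)
  G <- state[[1]]; A <- state[[2]]; s <- state[[3]]
  Ca <- if (is.null(ca_const)) calcium_transient(t, p, c) else ca_const
  dA <- c$k_on * Ca * (1 - A) - c$k_off * A
  Abar <- permissive_ratio(max(A, 0), p$n_A, p$A_50)
  fG <- c$k_f * Abar^c$n_G
  gG <- c$k_g * (1 + c$c_s * s^2)
  dG <- fG * (1 - G) - gG * G
  phi <- max(0, 1 + s)
  phip <- as.numeric(1 + s > 0)
  Ta <- c$S_a * G * phi
  if (identical(mode, "fixed")) {
    lam <- lam_fixed
    ds <- -s / c$tau_s
  } else {
    lam <- 1 - log1p(Ta / p$passive_alpha) / c$passive_beta
    cc <- c$S_a / (c$passive_beta * (p$passive_alpha + Ta))
    denom <- 1 + c$kappa_s * cc * G * phip
    ds <- (-c$kappa_s * cc * phi * dG - s / c$tau_s) / denom
  }
  list(c(dG, dA, ds), lam = lam, Ca = Ca, Ta = Ta)
}
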