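#' Per-cell sarcomere model parameters
#'
#' Bundles the parameters that vary from cell to cell and are targets of
#' inference: the calcium-transient shape (`Ca_amp`, `Ca_diast`, `tau2`), the
#' thin-filament activation Hill relation (`n_A`, `A_50`), the passive
#' stiffness scale (`passive_alpha`) and the slack sarcomere length
#' (`SL_slack`, measured directly from data rather than inferred).
#'
#' @param Ca_amp peak calcium concentration of the transient (uM).
#' @param Ca_diast diastolic calcium concentration (uM). May be 0 for
#'   counterfactual simulations; otherwise must be below `Ca_amp`.
#' @param tau2 exponential decay time constant of the transient (ms).
#' @param n_A Hill coefficient of the permissive-ratio relation (dimensionless).
#' @param A_50 half-activation point of the permissive-ratio relation
#'   (fraction of calcium-bound TnC, dimensionless).
#' @param passive_alpha passive tension scale (relative tension units).
#' @param SL_slack slack sarcomere length (um).
#' @return An object of class `"sarcomere_params"` (a named list).
#' @seealso [model_constants()] for quantities fixed across cells.
#' @examples
#' p <- sarcomere_params()
#' p$n_A
#' @export
sarcomere_params <- function(Ca_amp = 1.0, Ca_diast = 0.2, tau2 = 60,
                             n_A = 12, A_50 = 0.45, passive_alpha = 1,
                             SL_slack = 1.9) {
  p <- list(Ca_amp = Ca_amp, Ca_diast = Ca_diast, tau2 = tau2,
            n_A = n_A, A_50 = A_50, passive_alpha = passive_alpha,
            SL_slack = SL_slack)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    stop("all sarcomere parameters must be finite scalars; offending: ",
         paste(names(p)[!num], collapse = ", "))
  if (Ca_diast < 0) stop("Ca_diast must be >= 0")
  pos <- c("Ca_amp", "tau2", "n_A", "A_50", "passive_alpha", "SL_slack")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "))
  if (Ca_amp < Ca_diast) stop("Ca_amp must be >= Ca_diast")
  structure(p, class = "sarcomere_params")
}

#' @export
print.sarcomere_params <- function(x, ...) {
  cat("Sarcomere cell parameters:\n")
  cat(sprintf("  Ca_amp  = %.4g uM   Ca_diast = %.4g uM   tau2 = %.4g ms\n",
              x$Ca_amp, x$Ca_diast, x$tau2))
  cat(sprintf("  n_A     = %.4g      A_50     = %.4g      passive_alpha = %.4g\n",
              x$n_A, x$A_50, x$passive_alpha))
  cat(sprintf("  SL_slack = %.4g um\n", x$SL_slack))
  invisible(x)
}

#' Model constants shared across cells
#'
#' Quantities of the mechanistic model that are fixed for all cells: the
#' passive-tension exponent, the active tension scale, the calcium-transient
#' rise constant and stimulus onset, the reference slack length, and the
#' closure constants of the cross-bridge group dynamics (forward/reverse rate
#' laws, mean-strain kinetics and TnC calcium binding).
#'
#' The closure implemented is
#' \deqn{dA/dt = k_{on} Ca (1-A) - k_{off} A}
#' \deqn{f_G(\bar A) = k_f \bar A^{n_G}, \quad g_G(\bar A, s) = k_g (1 + c_s s^2)}
#' \deqn{ds/dt = \kappa_s \, d\lambda/dt - s/\tau_s, \quad
#'       \mathrm{strain\ factor} = \max(0, 1+s)}
#' with defaults calibrated so that a control-range twitch has a time to peak
#' of 100--200 ms, fractional shortening of 5--15% and a force--calcium Hill
#' coefficient in the 4--9 range.
#'
#' @param passive_beta passive tension exponent (dimensionless, fixed at 10).
#' @param S_a active tension scale (per um).
#' @param tau1 calcium-transient rise time constant (ms); must differ from the
#'   per-cell decay constant `tau2`.
#' @param t_start stimulus onset (ms).
#' @param SL_ref reference slack sarcomere length of the unscaled model (um).
#' @param k_f forward rate scale of cross-bridge group formation (1/ms).
#' @param n_G cooperativity exponent of the forward rate (>= 1).
#' @param k_g reverse (collapse) rate scale (1/ms).
#' @param c_s strain sensitivity of the collapse rate (dimensionless).
#' @param tau_s mean-strain relaxation time constant (ms).
#' @param k_on TnC calcium binding rate (1/(uM ms)).
#' @param k_off TnC calcium unbinding rate (1/ms).
#' @param kappa_s coupling of stretch-rate into mean strain (dimensionless).
#' @return An object of class `"model_constants"` (a named list).
#' @examples
#' cst <- model_constants()
#' cst$passive_beta
#' @export
model_constants <- function(passive_beta = 10, S_a = 2.5e5, tau1 = 20,
                            t_start = 10, SL_ref = 1.9,
                            k_f = 0.01, n_G = 1, k_g = 0.011, c_s = 40,
                            tau_s = 25, k_on = 0.016, k_off = 0.04,
                            kappa_s = 45) {
  cst <- list(passive_beta = passive_beta, S_a = S_a, tau1 = tau1,
              t_start = t_start, SL_ref = SL_ref, k_f = k_f, n_G = n_G,
              k_g = k_g, c_s = c_s, tau_s = tau_s, k_on = k_on,
              k_off = k_off, kappa_s = kappa_s)
  num <- vapply(cst, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    stop("all model constants must be finite scalars; offending: ",
         paste(names(cst)[!num], collapse = ", "))
  rates <- c("k_f", "k_g", "k_on", "k_off")
  if (any(unlist(cst[rates]) < 0)) stop("rate constants must be >= 0")
  if (cst$n_G < 1) stop("n_G must be >= 1")
  if (cst$tau1 <= 0 || cst$tau_s <= 0) stop("time constants must be positive")
  structure(cst, class = "model_constants")
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Sarcomere model constants:\n")
  for (nm in names(x)) cat(sprintf("  %-12s = %.6g\n", nm, x[[nm]]))
  invisible(x)
}

# Flatten params + constants into the parameter vector expected by the
# compiled right-hand side. `mode`: 0 unloaded, 1 fixed lambda.
rhs_parms <- function(p, c, mode = 0, lam_fixed = 1,
                      ca_mode = 0, ca_const = 0) {
  if (!inherits(p, "sarcomere_params")) p <- do.call(sarcomere_params, as.list(p))
  if (!inherits(c, "model_constants")) c <- do.call(model_constants, as.list(c))
  if (ca_mode == 0 && isTRUE(all.equal(c$tau1, p$tau2)))
    stop("degenerate calcium-transient normalization: tau1 == tau2")
  c(p$Ca_amp, p$Ca_diast, p$tau2, p$n_A, p$A_50, p$passive_alpha,
    c$passive_beta, c$S_a, c$tau1, c$t_start, c$k_f, c$n_G, c$k_g, c$c_s,
    c$tau_s, c$k_on, c$k_off, c$kappa_s, mode, lam_fixed, ca_mode, ca_const)
}

#' Reference parameter sets for the control and inotrope groups
#'
#' Convenience accessors for the package's reference operating points: the
#' control set is the default [sarcomere_params()]; the drug set differs only
#' in the thin-filament activation parameters (`n_A` decreased from 12 to 7,
#' `A_50` nudged from 0.45 to 0.46), the signature of a myosin-targeting
#' inotrope in this model. All other parameters are identical, reflecting the
#' prior knowledge that the drug does not alter calcium handling or cell
#' stiffness.
#'
#' @param group `"control"` or `"drug"`.
#' @return A [sarcomere_params()] object.
#' @examples
#' om_reference_params("drug")$n_A
#' @export
om_reference_params <- function(group = c("control", "drug")) {
  group <- match.arg(group)
  if (group == "control") sarcomere_params()
  else sarcomere_params(n_A = 7, A_50 = 0.46)
}
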