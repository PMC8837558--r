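# Protocol runners: unloaded shortening, isometric twitch at fixed stretch,
# and the steady-state force-calcium (isosarcometric) sweep. All integrate the
# compiled model right-hand side with deSolve (adaptive lsoda, rtol 1e-6 /
# atol 1e-9); sarcomere_rhs() is the readable reference implementation.

ODE_RTOL <- 1e-6
ODE_ATOL <- 1e-9

# Resting state at constant calcium: A at binding equilibrium, s = 0,
# G at the fixed point of the group dynamics.
initial_state <- function(p, c, ca = p$Ca_diast) {
  A0 <- c$k_on * ca / (c$k_on * ca + c$k_off)
  Abar0 <- permissive_ratio(A0, p$n_A, p$A_50)
  f0 <- c$k_f * Abar0^c$n_G
  G0 <- f0 / (f0 + c$k_g)
  c(G_XB = G0, A = A0, s = 0)
}

integrate_model <- function(y0, times, parms) {
  out <- deSolve::lsoda(y = y0, times = times, func = "sarco_derivs",
                        parms = parms, dllname = "sarcopop",
                        initfunc = "sarco_initmod",
                        nout = 4, outnames = c("lam", "Ca", "Ta", "Tp"),
                        rtol = ODE_RTOL, atol = ODE_ATOL)
  istate <- attr(out, "istate")[1]
  if (is.null(istate) || istate < 0 || nrow(out) < length(times))
    stop(sprintf("force-balance integration failed near t = %.6g ms (istate %d)",
                 out[nrow(out), "time"], istate))
  out
}

#' Simulate unloaded sarcomere shortening
#'
#' Integrates the model with the stretch ratio determined at every instant by
#' the quasi-static balance between active tension and the passive restoring
#' tension of the cell (the cell contracts against its own stiffness). The
#' balance has the closed form
#' \eqn{\lambda = 1 - \log(1 + T_a/passive_\alpha)/passive_\beta}, so
#' \eqn{\lambda \le 1} throughout and \eqn{\lambda = 1} when activation
#' vanishes. The returned sarcomere length is
#' \eqn{SL(t) = \lambda(t) \cdot SL_{ref} \cdot SL_{slack} / 1.9}, i.e. the
#' model's native length rescaled so the slack length equals `SL_slack`.
#'
#' @param p a [sarcomere_params()] object.
#' @param c a [model_constants()] object.
#' @param t_grid output time grid (ms), ascending; default 0--800 ms at 1 ms.
#' @return A [trace()] of kind `"SL"`, with the full state/diagnostic matrix
#'   attached as attribute `"ode"`.
#' @examples
#' tr <- simulate_unloaded(sarcomere_params(), model_constants())
#' min(tr$v)  # peak shortening
#' @export
simulate_unloaded <- function(p = sarcomere_params(), c = model_constants(),
                              t_grid = seq(0, 800, by = 1)) {
  stopifnot(length(t_grid) > 1, all(diff(t_grid) > 0))
  parms <- rhs_parms(p, c, mode = 0)
  out <- integrate_model(initial_state(p, c), t_grid, parms)
  sl <- out[, "lam"] * c$SL_ref * (p$SL_slack / 1.9)
  tr <- trace(out[, "time"], sl, "SL")
  attr(tr, "ode") <- out
  tr
}

#' Simulate an isometric twitch at fixed stretch
#'
#' Holds the stretch ratio fixed (default 10% above slack), drives the model
#' with the calcium transient, and returns the total tension trace (active
#' plus the constant passive tension at that stretch) together with twitch
#' metrics: peak tension, time from stimulus to peak (`TTP_force`), and time
#' from peak to 50% relaxation (`RT50`).
#'
#' @param p a [sarcomere_params()] object.
#' @param c a [model_constants()] object.
#' @param stretch fixed stretch ratio (default 1.10).
#' @param t_grid output time grid (ms).
#' @return List of class `"isometric_sim"`: `trace` (kind `"force"`) and
#'   `metrics` (list `peak`, `TTP_force`, `RT50`; `RT50` is `NA` when there is
#'   no decaying twitch, e.g. at zero calcium).
#' @examples
#' sim <- simulate_isometric(sarcomere_params(), model_constants())
#' sim$metrics$RT50
#' @export
simulate_isometric <- function(p = sarcomere_params(), c = model_constants(),
                               stretch = 1.10, t_grid = seq(0, 800, by = 1)) {
  stopifnot(stretch > 0, length(t_grid) > 1, all(diff(t_grid) > 0))
  parms <- rhs_parms(p, c, mode = 1, lam_fixed = stretch)
  out <- integrate_model(initial_state(p, c), t_grid, parms)
  force <- out[, "Ta"] + out[, "Tp"]
  tr <- trace(out[, "time"], force, "force")
  attr(tr, "ode") <- out
  structure(list(trace = tr, metrics = twitch_metrics(tr, t_start = c$t_start)),
            class = "isometric_sim")
}

#' @export
print.isometric_sim <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Isometric twitch: peak %.6g, TTP_force %.4g ms, RT50 %s ms\n",
              m$peak, m$TTP_force,
              if (is.na(m$RT50)) "NA" else sprintf("%.4g", m$RT50)))
  invisible(x)
}

#' Twitch metrics of a force trace
#'
#' Extracts the peak value, the time from stimulus onset to the peak
#' (`TTP_force`), and the time from the peak to 50% relaxation toward the
#' pre-stimulus baseline (`RT50`, linearly interpolated). `RT50` is `NA` when
#' the trace has no appreciable twitch (relative amplitude below `min_amp`) or
#' never relaxes halfway within the trace.
#'
#' @param tr a [trace()] of kind `"force"` (any trace is accepted).
#' @param t_start stimulus onset (ms), subtracted from the peak time.
#' @param min_amp minimum twitch amplitude relative to the baseline magnitude
#'   (default 1e-3) below which metrics other than `peak` are `NA`.
#' @return List with `peak`, `TTP_force`, `RT50`.
#' @export
twitch_metrics <- function(tr, t_start = 0, min_amp = 1e-3) {
  t <- tr$t; v <- tr$v
  base <- v[which.min(abs(t - t_start))]
  ipk <- which.max(v)
  peak <- v[ipk]
  amp <- peak - base
  if (amp <= min_amp * max(abs(base), 1e-12) || ipk == length(v))
    return(list(peak = peak, TTP_force = NA_real_, RT50 = NA_real_))
  ttp <- t[ipk] - t_start
  half <- base + 0.5 * amp
  rest <- v[ipk:length(v)]
  trest <- t[ipk:length(t)]
  below <- which(rest <= half)
  rt50 <- NA_real_
  if (length(below)) {
    i <- below[1]
    if (i == 1) {
      rt50 <- 0
    } else {
      # linear interpolation across the crossing
      tcross <- trest[i - 1] + (half - rest[i - 1]) *
        (trest[i] - trest[i - 1]) / (rest[i] - rest[i - 1])
      rt50 <- tcross - t[ipk]
    }
  }
  list(peak = peak, TTP_force = ttp, RT50 = rt50)
}

#' Steady-state force-calcium (isosarcometric) curve
#'
#' For each calcium level the intracellular calcium is clamped, the sarcomere
#' is held at a fixed stretch, and the model is integrated until the state is
#' stationary (all derivatives below `steady_tol`). Steady active tensions are
#' normalized to their maximum and the Hill relation is fitted with
#' [fit_hill()], yielding the Hill coefficient `h` and calcium sensitivity
#' `Ca_50`.
#'
#' @param p a [sarcomere_params()] object.
#' @param c a [model_constants()] object.
#' @param ca_grid calcium concentrations to sweep (uM); should span sub- to
#'   supra-saturating levels. Default: 24 log-spaced points in 0.05--30 uM.
#' @param stretch fixed stretch ratio (default 1: held at slack length).
#' @param steady_tol stationarity threshold on the state derivatives
#'   (default 1e-8).
#' @param monotone_tol warn if the steady forces decrease by more than this
#'   (relative to the maximum) anywhere along the sweep.
#' @return List of class `"fca_curve"`: `ca`, `force` (steady active tension),
#'   `f_norm` (normalized), and `fit` (a `"hill_fit"`).
#' @examples
#' \donttest{
#' fca <- simulate_fca(sarcomere_params(), model_constants())
#' coef(fca$fit)
#' }
#' @export
simulate_fca <- function(p = sarcomere_params(), c = model_constants(),
                         ca_grid = 10^seq(log10(0.05), log10(30),
                                          length.out = 24),
                         stretch = 1, steady_tol = 1e-8,
                         monotone_tol = 1e-3) {
  stopifnot(all(ca_grid > 0), length(ca_grid) >= 4)
  ca_grid <- sort(ca_grid)
  force <- vapply(ca_grid, function(ca) {
    parms <- rhs_parms(p, c, mode = 1, lam_fixed = stretch,
                       ca_mode = 1, ca_const = ca)
    y <- initial_state(p, c, ca = ca)
    t_end <- 0
    repeat {
      out <- integrate_model(y, c(t_end, t_end + 2000), parms)
      y <- out[nrow(out), c("G_XB", "A", "s")]
      t_end <- t_end + 2000
      d <- sarcomere_rhs(t_end, y, p, c, mode = "fixed",
                         lam_fixed = stretch, ca_const = ca)[[1]]
      if (max(abs(d)) < steady_tol) break
      if (t_end > 40000)
        stop("no steady state reached within 40 s at Ca = ", ca, " uM")
    }
    active_tension(list(G_XB = y[["G_XB"]], s = y[["s"]]), p, c)
  }, numeric(1))
  fmax <- max(force)
  if (fmax <= 0) stop("steady forces are all zero; check parameters")
  drops <- -diff(force) / fmax
  if (any(drops > monotone_tol))
    warning("steady force-calcium curve is non-monotone beyond tolerance; ",
            "model closure may be misconfigured")
  f_norm <- force / fmax
  fit <- fit_hill(ca_grid, f_norm)
  structure(list(ca = ca_grid, force = force, f_norm = f_norm, fit = fit,
                 stretch = stretch),
            class = "fca_curve")
}

#' @export
print.fca_curve <- function(x, ...) {
  cat(sprintf("Force-calcium curve (%d levels, stretch %.3g): ",
              length(x$ca), x$stretch))
  print(x$fit)
  invisible(x)
}

#' @export
plot.fca_curve <- function(x, ...) {
  pca <- -log10(x$ca)
  graphics::plot(pca, x$f_norm, xlim = rev(range(pca)),
                 xlab = "pCa (-log10 uM)", ylab = "Normalized force", ...)
  ca_fine <- 10^seq(log10(min(x$ca)), log10(max(x$ca)), length.out = 200)
  graphics::lines(-log10(ca_fine), predict(x$fit, ca_fine))
  invisible(x)
}
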