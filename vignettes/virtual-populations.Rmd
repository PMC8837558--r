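---
title: "Calibrating two-group virtual populations of a sarcomere model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating two-group virtual populations of a sarcomere model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Isolated cardiomyocytes show large cell-to-cell variability. When the same
preparation is measured in two conditions — a control group and a group
exposed to a myosin-targeting inotrope such as omecamtiv mecarbil — the
question is not "which single parameter set explains the data" but "which
*distribution* of mechanistic model parameters, pushed through the model,
reproduces the observed distribution of readouts in each group". sarcopop
solves this stochastic inverse problem for a phenomenological mean-field
model of sarcomere contraction, under one decisive piece of prior biology:
the drug acts on the contractile machinery only, so the parameters governing
calcium handling and passive stiffness must share a single distribution
across the two groups, while only the thin-filament activation parameters
(`n_A`, `A_50`) may differ.

Treating the two groups independently cannot honour that constraint. Here it
holds *exactly, by construction*: one generator network produces the shared
parameter block from a common noise source that feeds both groups'
drug-target generators.

## The mechanistic model

States are the formed cross-bridge (XB) group fraction `G_XB`, the fraction
`A` of troponin C with bound calcium, and a mean XB strain `s`. The core
equation is

$$\frac{dG_{XB}}{dt} = f_G(\bar A)\,(1 - G_{XB}) - g_G(\bar A, s)\,G_{XB},$$

with the permissive-ratio Hill relation
$\bar A = A^{n_A} / (A^{n_A} + A_{50}^{n_A})$. Active tension is
$T_a = S_a\, G_{XB} \max(0, 1+s)$; passive tension is the piecewise
exponential of the stretch ratio $\lambda$ with fixed exponent
$passive_\beta = 10$ and per-cell scale $passive_\alpha$. The calcium drive
is the biexponential transient with per-cell amplitude, diastolic level and
decay constant $\tau_2$; its normalizer is the exact extremum of
$e^{-u/\tau_1} - e^{-u/\tau_2}$, so the transient peaks at `Ca_amp` to
machine precision for any $\tau_1 \ne \tau_2$ (the test suite checks 1e-6
across a grid of time-constant pairs).

### Closure

The published core equations leave the rate laws $f_G$, $g_G$, the strain
factor and the TnC kinetics open; sarcopop ships one documented closure
behind a constants interface (`model_constants()`):

* $dA/dt = k_{on}\,Ca\,(1-A) - k_{off}\,A$ — first-order TnC binding
  (defaults $k_{on} = 0.016\,\mathrm{\mu M^{-1} ms^{-1}}$,
  $k_{off} = 0.04\,\mathrm{ms^{-1}}$, i.e. a 2.5 uM dissociation constant,
  which keeps $A$ in its informative range over the 0.05–2 uM calcium span
  of the prior);
* $f_G(\bar A) = k_f\,\bar A^{n_G}$ with $n_G = 1$ and
  $k_f = 0.01\,\mathrm{ms^{-1}}$;
* $g_G(\bar A, s) = k_g (1 + c_s s^2)$ with $k_g = 0.011\,\mathrm{ms^{-1}}$,
  $c_s = 40$ — detachment accelerates sharply while the filament slides;
* $ds/dt = \kappa_s\, d\lambda/dt - s/\tau_s$ with $\kappa_s = 45$,
  $\tau_s = 25$ ms; strain factor $\max(0, 1+s)$.

The constants were calibrated once so that a control-range cell produces a
twitch with 5–15% fractional shortening, time-to-peak in the 100–200 ms
band, and a force–calcium Hill coefficient between 4 and 9 (the defaults
give 7.4%, 137 ms, $h = 6.8$, $Ca_{50} = 1.87$ uM). The strain feedback
($\kappa_s \tau_s \approx 10^3$ ms) is what bounds the shortening velocity:
once activation is strong enough, velocity saturates near
$1/(\kappa_s\tau_s)$ per ms, so control and drug parameter sets shorten at
nearly the same peak velocity — the model-level counterpart of the
experimental observation that this inotrope leaves shortening velocity
unchanged. The closure is deliberately minimal; it preserves every
structural statement of the core equations and is swappable through
`model_constants()`.

### Unloaded shortening as a quasi-static balance

An unloaded myocyte contracts against its own stiffness, $|T_p| = T_a$.
Below slack length the passive law gives the closed form

$$\lambda = 1 - \log(1 + T_a/passive_\alpha)/passive_\beta,$$

so $\lambda$ is not a state variable: it is slaved to $(G_{XB}, s)$, and
$d\lambda/dt$ is eliminated by the chain rule, which makes the strain
equation linear in $ds/dt$ and the whole right-hand side explicit. (The
sign convention matters: below slack the passive tension of the model is
negative — a restoring force — so the balance is between the active tension
and the passive *magnitude*; as printed, an equation with both terms
positive has no solution during shortening.) Reported sarcomere length is
$\lambda \cdot SL_{ref} \cdot SL_{slack}/1.9$: the model's native
slack length is 1.9 um and measured slack lengths enter only as an output
scale, which is why `SL_slack` never needs to be inferred.

Integration uses an adaptive, stiffness-capable solver (lsoda) at
rtol 1e-6 / atol 1e-9 on a compiled right-hand side;
`sarcomere_rhs()` is the exported, readable reference implementation and
the test suite checks the two against each other along a twitch. Steady
state in the force–calcium protocol is declared when every state derivative
falls below 1e-8.

At extreme corners of the prior box (very low `A_50` and `passive_alpha`
with high diastolic calcium) the balance can push $\lambda$ to
non-physiological values; such cells produce extreme features, are far from
any realistic target density, and are simply part of the map the surrogate
learns.

## Features and targets

Each shortening trace is summarized by three features obtained by nonlinear
least squares of

$$SL(t) = (dSL - sSL)\left(1 - e^{-\log^2(t/TTP)}\right) + sSL,$$

giving the diastolic length, the systolic (peak-shortening) length and the
time to peak. The fit uses the full trace (the curve form is symmetric in
$\log t$ and cannot represent asymmetric relaxation; a fitting window is
available as an option but the default follows the full-trace convention).
Per group, a multivariate Gaussian over $(dSL, sSL, TTP)$ is the explicit
target density.

One consequence of the symmetric-in-log-time form is worth knowing: its
fitted `TTP` tracks the temporal midpoint of the twitch, not the argmin of
the trace. A drug-like $(n_A, A_{50})$ shift both advances the onset of
shortening and prolongs relaxation, and the two nearly cancel in the fitted
`TTP`: across any shift magnitude the synthetic drug group's mean feature
`TTP` rises by roughly 20–25 ms even when the trace-level time of peak
shortening moves by 100 ms. The synthetic-data defaults
(`drug_shift = c(n_A = -5, A_50 = +0.01)`) therefore reproduce the reported
*length* contrasts (about $-0.1$ to $-0.26$ um in `dSL`/`sSL`) and the
correct direction, at about half the reported magnitude, of the `TTP`
contrast.

## Surrogate

The parameter-to-feature map is emulated by a fully connected network
(three tanh layers of 128 units; inputs min–max scaled to $[-1,1]$, outputs
standardized) trained on simulator runs at prior samples with `SL_slack`
fixed at 1.9 um; the $SL_{slack}/1.9$ scaling of the two length features is
applied downstream when populations are composed with measured slack
lengths. At 8000 prior samples and 600 epochs the held-out R² per feature
is ≥ 0.999 and the fresh-sample RMSE is ~0.005 um for the lengths and
~0.7 ms for `TTP`, well under the 10% of prior-induced spread that the
package treats as the fidelity bar. Surrogate accuracy matters directly for
inference quality: with target feature standard deviations of order 0.03 um
and 10 ms, a sloppier surrogate visibly blurs the generated feature
distributions (in practice it puts a floor of ~0.1 on the achievable KS
distances).

## The adversarial fit

`fit_vpop()` trains three generators — `G1` for the shared block, `G2`/`G3`
for the per-group `(n_A, A_50)` — and four discriminators: two comparing
generated parameter vectors against uniform-prior draws (a soft constraint
keeping the populations inside and spread over the box, weighted by
`lambda_p`), and two comparing surrogate-predicted features of the
generated parameters against draws from the per-group target Gaussians
(whitened by the target covariance so all three features contribute
comparably). Losses are nonsaturating cross-entropy; all networks are
updated by Adam with a step-decayed learning rate, which settles the
adversarial game near its equilibrium instead of orbiting it.

Choices made where the design was genuinely open:

* `lambda_p = 0.3` by default. With an accurate surrogate, a unit weight on
  the prior discriminators measurably degrades the feature match (the
  generator is pulled toward filling the box uniformly); 0.3 keeps samples
  inside and spread over the box while letting the feature terms dominate.
* Discriminators are 2×128 networks; narrower ones were prone to late
  oscillation.
* Noise dimensions (4, 2, 2) match the dimensions of the blocks they drive.
* "Real" feature batches are drawn from the fitted Gaussians, matching the
  explicit density the study compares against; raw feature rows can be used
  instead (`raw_features`).
* Convergence is tracked every 100 iterations by per-feature
  Kolmogorov–Smirnov distances of generated features against the target
  marginals plus a kernel MMD; the returned model is the checkpoint with the
  best *worst-feature* KS, so no marginal is sacrificed to the average.
  Training aborts with an error only after a long streak of clearly
  worsened distances; transient oscillation is normal. A variance-ratio
  heuristic warns about mode collapse.

All randomness flows from `gan_config(seed=)`; fitting is deterministic
given the seed and the numerical backend.

## What the synthetic data does and does not emulate

`make_ground_truth()` draws truncated-Gaussian parameter populations inside
the prior box — literally one distribution object for the shared block of
both groups, shifted `(n_A, A_50)` for the drug group — simulates every
cell, adds i.i.d. Gaussian length noise (0.005 um by default; an AR(1)
option exists), extracts features and fits the target densities. Group
sizes default to 24 and 17 cells, with larger-n variants for testing. It
emulates the *design* of the experiment (two groups, shared physiology,
drug-shifted activation, feature-level contrasts) — it does not emulate
optical measurement artifacts, pacing irregularities, within-cell
non-stationarity, or non-Gaussian feature tails. Passing the recovery tests
therefore shows the inference machinery works when the data-generating
process matches the model family; it does not certify performance on real
recordings.

## Validation protocols

`validate_om_report()` compares group-mean parameter vectors through three
protocols: the isosarcometric force–calcium sweep (calcium clamped,
length fixed, steady forces Hill-fitted), unloaded shortening (including
the counterfactual with diastolic calcium set to zero), and an isometric
twitch at 10% stretch. At the package's reference parameter sets (control:
$n_A = 12$, $A_{50} = 0.45$; drug: $n_A = 7$, $A_{50} = 0.46$) the drug
set shows the full qualitative signature expected of this inotrope class: a
shallower force–calcium relation ($h$ 6.8 → 4.0) with higher calcium
sensitivity ($Ca_{50}$ 1.87 → 1.83 uM), a shorter diastolic length that
vanishes exactly when diastolic calcium is removed (diastolic calcium is
what generates the residual force), an unchanged (±5%) peak shortening
velocity, and a longer RT50. These are direction checks by design: the
study's printed Hill numbers depend on unpublished inferred means and are
not desk-reproducible.

## Sensitivity analysis

`mda()` implements permutation importance: a regressor (random forest by
default, linear optionally) is fitted once from parameters to a
model-derived metric, frozen, and re-scored on a held-out split after
shuffling one parameter column at a time; the score is the drop in R²,
averaged over repeats that share one permutation across columns (making
scores exactly invariant to column order). The permuted R² is clamped at
the no-skill level 0 — a frozen regressor fed shuffled inputs can be
arbitrarily *anti*-correlated with the target, and counting that below
no-skill would inflate an importance past the share of variance the
parameter explains. Held-out scoring avoids the optimistic bias of
training-set R².

## Numerical choices and problem sizes

Units are fixed as ms, um, uM throughout. Default problem sizes — 8000
prior samples and 600 epochs for the surrogate, 6000 adversarial iterations
at batch 128 with 2000-sample evaluations, 150 cells per synthetic group
for stable target densities, 10 seeded refits for the sign-recovery check —
were chosen as the smallest sizes at which the respective diagnostics
plateau; all are arguments, and each stage scales linearly in them.

## Known limitations

* The closure is a stand-in honoring the structure of the published core
  equations, not the (unpublished here) supplemental rate laws; quantities
  that depend on closure details (absolute Hill coefficients, RT50 values)
  are meaningful as contrasts, not as absolute predictions.
* The fitted-`TTP` compression described above caps the achievable
  synthetic `TTP` contrast near +22 ms.
* Feature targets are Gaussian by construction; heavy-tailed or skewed real
  feature distributions would make the Gaussian target itself the limiting
  approximation.
* Adversarial training is a saddle-point problem: convergence is monitored,
  not guaranteed. The divergence error and mode-collapse warning are
  heuristics; inspect `$history` when in doubt.
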