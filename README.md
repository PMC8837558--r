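# sarcopop

Virtual populations of a mechanistic sarcomere contraction model,
calibrated to two-group (control vs. myosin-targeting inotrope) recordings
of unloaded myocyte shortening by a factorized generative adversarial
network.

## The problem

Isolated cardiomyocytes are highly variable. Given shortening traces from a
control group and a drug-treated group, the goal is a *distribution* over
mechanistic parameter vectors for each group whose simulated outputs
reproduce the observed variability — a stochastic inverse problem

$$x \sim q_X(x) \;\Rightarrow\; y = M(x) \;\Rightarrow\; y \sim q_Y(y),$$

with one structural constraint from prior pharmacology: the drug acts only
on thin-filament activation, so the calcium-handling and stiffness
parameters $x_1 = (Ca_{amp}, Ca_{diast}, \tau_2, passive_\alpha)$ must share
one distribution across groups, while only $x_2 = (n_A, A_{50})$ — the Hill
coefficient and half-activation of the permissive-ratio relation
$\bar A = A^{n_A}/(A^{n_A}+A_{50}^{n_A})$ — may differ:

$$x_1 \sim q_{X_1},\qquad
  x_{2,c} \sim q(x_{2,c} \mid x_1),\qquad
  x_{2,d} \sim q(x_{2,d} \mid x_1).$$

sarcopop enforces the constraint *exactly by construction*: one generator
network emits $x_1$ from a noise source that is shared, realization for
realization, by the two groups' drug-target generators. Four discriminators
drive training — two against the uniform parameter prior, two against the
per-group Gaussian densities of the twitch features $(dSL, sSL, TTP)$ —
with model outputs supplied by a differentiable feed-forward surrogate of
the ODE model.

The package contains the full pipeline: the mechanistic model (calcium
transient, XB-group dynamics, passive tension) with unloaded, isometric and
force–calcium protocols; feature extraction; surrogate training; the
adversarial fit; permutation-importance (mean decrease accuracy)
sensitivity analysis; and a synthetic-data generator that emulates the
two-group experiment so everything is testable end to end.

## Worked example

```r
library(sarcopop)

# mechanistic model at the control reference point
tr  <- simulate_unloaded(sarcomere_params(), model_constants())
fca <- simulate_fca(sarcomere_params(), model_constants())
print(fca)
#> Force-calcium curve (24 levels, stretch 1): Hill fit: h = 6.828, Ca_50 = 1.868 uM (residual norm 0.0208)

# synthetic two-group experiment (24 control / 17 drug cells by default;
# larger groups here for stable target densities)
gt <- make_ground_truth(synth_config(n_c = 150, n_d = 150), seed = 1)
print(gt)
#> Synthetic ground truth (seed 1): 150 control + 150 drug cells (1 regenerated)
#>   drug - control feature means: dSL -0.065 um, sSL -0.234 um, TTP +21.1 ms

# surrogate of the parameter-to-feature map
ts  <- build_training_set(prior_box(), 8000, seed = 2)
sur <- train_surrogate(ts$X, ts$Y, epochs = 600, seed = 3)
print(sur)
#> Feed-forward surrogate (6 -> 128-128-128 -> 3), 6875 training rows
#>   validation R-squared: dSL 0.9998, sSL 0.9999, TTP 0.9995

# adversarial two-group fit and generated populations
slack <- list(mean = mean(gt$params_c$SL_slack), sd = sd(gt$params_c$SL_slack))
vp   <- suppressWarnings(fit_vpop(gt$density_c, gt$density_d, sur, prior = prior_box(),
                 slack = slack, config = gan_config(iters = 6000, seed = 4)))
pops <- simulate(vp, nsim = 2000, seed = 5)
mean(pops$drug$n_A) - mean(pops$control$n_A)   # generating shift was -5
#> [1] -4.188
print(population_report(pops, list(c = gt$density_c, d = gt$density_d), sur))
#> Population report
#>   control: feature KS (dSL, sSL, TTP) = 0.049, 0.028, 0.068
#>   drug: feature KS (dSL, sSL, TTP) = 0.071, 0.071, 0.038
#>   n_A~A_50 correlation: control -0.595, drug -0.448 (coupling flagged)

# counterfactual validation protocols at the reference group means
print(validate_om_report(
  as.data.frame(t(unlist(om_reference_params("control")))),
  as.data.frame(t(unlist(om_reference_params("drug"))))))
#> Validation protocols at group-mean parameters
#>                               control         drug
#>   Hill h                        6.828        4.016
#>   Ca_50 (uM)                    1.868        1.831
#>   diastolic SL (um)               1.9        1.806
#>     ... at Ca_diast=0             1.9          1.9
#>   peak velocity (um/ms)      0.003763     0.003813
#>   RT50 (ms)                      77.2         85.5
#>   velocity ratio drug/control: 1.013
```

Reading the numbers: the drug-direction parameter change flattens the
force–calcium curve (lower Hill coefficient) while *increasing* calcium
sensitivity (lower $Ca_{50}$), shortens the diastolic length — an effect
that disappears entirely when diastolic calcium is zeroed, identifying
residual diastolic activation as its cause — leaves the peak shortening
velocity essentially unchanged, and slows relaxation (larger RT50). That is
the qualitative signature reported for this inotrope class. The per-feature
Kolmogorov–Smirnov distances (< 0.1 at n = 2000) say the generated
populations reproduce the target feature distributions of both groups, and
the recovered mean $n_A$ shift matches the synthetic ground truth.

A thin command-line wrapper over the same functions is installed at
`inst/cli/sarcopop.R` (`simulate-twitch`, `extract-features`,
`train-surrogate`, `train-gan`, `sample-population`, `sensitivity`,
`validate-om`, `run-all`, ...).

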