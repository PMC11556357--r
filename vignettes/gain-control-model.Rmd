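---
title: "The two-stage binocular gain control model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-stage binocular gain control model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`binocgain` implements the two-stage model of binocular contrast gain
control. Each eye's signal first passes through a monocular gain-control
stage in which the other eye's contrast acts divisively:

$$\mathrm{Stage1}_L = \frac{C_L^m}{S + C_L + \omega C_R}, \qquad
  \mathrm{Stage1}_R = \frac{C_R^m}{S + C_R + \omega C_L}.$$

The two monocular outputs are summed ($b = \mathrm{Stage1}_L +
\mathrm{Stage1}_R$) and passed through a second nonlinearity:

$$\mathrm{Stage2} = \frac{b^p}{Z + b^q}.$$

Discrimination of a target increment on a pedestal is limited by
additive internal noise: a threshold is the smallest target contrast at
which the Stage-2 response difference between the target and null
intervals of a 2IFC trial equals the criterion $k$. Equivalently,
sensitivity is

$$d' = \frac{\mathrm{Stage2}_{target+pedestal} -
             \mathrm{Stage2}_{pedestal}}{k/\tau},$$

with $\tau = \Phi^{-1}(0.75)\sqrt{2} \approx 0.954$ fixed, so that a
response difference of $k$ lands exactly on the 75%-correct point of the
psychometric function. $\tau$ is a derived constant, never a free
parameter.

All model computation happens in monocular-threshold-normalized linear
contrast units; decibels ($20\log_{10} C$) are used only for reporting,
staircase stepping, and regressions. Contrasts of exactly zero are
handled analytically (zero response), with no epsilon padding, which
keeps parameter sets with $Z = 0$ well defined.

Two structural consequences matter for the tests the package ships
with. With $\omega \approx 1$, interocular suppression almost exactly
compensates binocular summation at high contrasts, so monocular and
binocular dipper handles converge (ocularity invariance), while the
binocular summation ratio at detection threshold approaches $2^{1/m}$
in the low-contrast limit — for $m = 1$ and $\omega = 1$ the
monocular:binocular ratio is exactly 2 at any $k$, an algebraic
identity of the stage-1 form. And under dichoptic masking, a weak
target suppresses the mask-driven response more than it adds
excitation, producing negative $d'$ at small target contrasts — the
"swan function" region where predicted performance falls below chance.

## Threshold solving

Thresholds solve $\mathrm{Stage2}_{t+p} - \mathrm{Stage2}_p = k$ for
the smallest positive target. Because the dichoptic response difference
is non-monotonic (the swan region), the solver scans a 64-point
log-spaced grid over $[10^{-4}, 10^4]$ normalized units for the *first*
upward crossing, then bisects in log contrast; bisection depth adapts
to the requested tolerance (default: the returned target satisfies the
criterion to a relative error of $10^{-6}$). The scan and bisection are
vectorized across pedestals, which keeps multi-start refits affordable.
A bracket containing no crossing raises an error rather than returning
a clamped value. The test suite compares this solver against an
independent dense-grid + `uniroot` oracle on random parameter draws,
requiring agreement to 0.1 dB.

## The cross-pathway extension

Three mechanisms tuned to the achromatic (AC), L-M (RG) and S-(L+M)
(BY) pathways run in parallel. Interocular suppression generalizes to a
$3\times3$ weight matrix $W$: the stage-1 denominator for mechanism $i$
in one eye accumulates $\sum_j W_{ij} C_{j}$ over all three pathways'
contrasts *in the other eye*. Diagonal entries are the within-pathway
$\omega$ values; there is no monocular (same-eye) cross-pathway
suppression term, mirroring the model as specified. Stage 2 applies per
mechanism with its own $p, q, Z$. The observer reads out the mechanism
tuned to the target's pathway — the experiment displays the target
identity throughout, so no max-over-mechanisms rule is needed.

The d′-to-accuracy link is the standard 2AFC signal-detection form
$P = \lambda/2 + (1-\lambda)\Phi(d'/\sqrt{2})$ with lapse rate
$\lambda = 0.01$ by default. This choice is forced to be consistent
with $\tau$: at $d' = \tau$ and $\lambda = 0$ accuracy is exactly 75%.
Negative d′ then yields below-chance performance naturally.

Each pathway's contrasts are normalized by that pathway's own monocular
detection threshold. The default generating thresholds are 1% Michelson
contrast (AC), 0.004 cone contrast (RG) and 0.035 cone contrast (BY) —
one sixteenth of the classic mask contrasts (16% Michelson, 6.4% and
56% cone contrast), so the standard masks sit at 16 threshold units in
every pathway.

The default cross weights in `default_crosspath_model()` encode the
fitted qualitative pattern: strongest suppression of the L-M mechanism
by S-(L+M) masks (1.11, the one cross weight reported numerically),
weakest coupling between AC and BY (0.30), intermediate elsewhere
(0.50–0.80). Only the 1.11 value is anchored to a published estimate;
the others were chosen once to reproduce the reported ordering and are
not revisited.

## The synthetic observer

`observer_sim` regenerates the three experimental designs as trial
tables:

* **Dipper experiments** (`generate_experiment1()`,
  `generate_experiment3()`): per participant, pathway, pedestal and
  repetition, a block of eight interleaved 3-down-1-up staircases (four
  ocular arrangements crossed with two target-eye assignments), moving
  in 3 dB steps. Pedestal grids are the printed stimulus values
  (achromatic 0–32% Michelson; chromatic 0–64% of maximum cone
  contrast), three repetitions per pedestal. Trials per staircase
  default to 50 (the source experiments report total trial counts but
  not staircase length; 50 gives blocks of 400 trials, matching a
  ~12-minute block at typical pacing) and staircases start 10 dB above
  the generating threshold. Both are configurable and neither is a
  published value.
* **Cross-pathway masking** (`generate_experiment2()`): method of
  constant stimuli over 12 conditions (3 baselines + 9 target×mask
  pairings), 10 target levels × 200 trials/block × 10 blocks per
  participant, masks fixed at 16 threshold units. With three
  participants this is exactly 72,000 trials, 600 per level per
  condition pooled. Target levels are spaced 3 dB apart, centred on the
  group model's predicted 75% point per condition — fixed in advance
  and shared across participants, as a constant-stimuli design
  requires.
* **Participant heterogeneity**: each simulated participant draws
  $m, \omega, k$ as log-normal jitter (SD 0.1 in log units) around the
  group values, with $p, q, S, Z$ shared. This is exactly the structure
  the hierarchical fit assumes, which is what makes the
  parameter-recovery suites a clean test of the fitting machinery
  rather than of model misspecification.

What the generator deliberately does *not* emulate: reaction times,
interval-order and feedback effects, eye dominance beyond the
`target_eye` label, staircase-sampling bias, stimulus rendering, and
any drift or learning across blocks. Passing recovery tests therefore
show that the estimation machinery is correct and calibrated under the
model's own assumptions; they do not show that real observers satisfy
those assumptions.

`generate_mocs_dipper()` is a compact constant-stimuli dipper generator
used by the recovery suites; it avoids staircase path dependence so
that binomial cells have controlled trial counts.

## Psychometric estimation

`fit_psychometric()` estimates a cumulative Gaussian on the dB axis
with guess rate fixed at 0.5, by grid-based Bayesian numerical
integration over (location, slope $\sigma$, lapse): uniform prior on
location across the tested range extended by half its span, log-uniform
on $\sigma \in [0.3, 30]$ dB, and a Beta(1,4)-shaped prior on lapse
over $[0, 0.06]$. Point estimates are posterior means; intervals are
central 95% credible intervals obtained from the weighted grid. The
default grid is $81 \times 41 \times 7$. Threshold is defined at 75%
*absolute* correct on the lapse-corrected function, and the equivalent
Weibull slope uses $\beta = 10.3/\sigma$ (so $\beta\sigma = 10.3$
identically). This mirrors the cited class of Bayesian-integration
psychometric fitting without cloning any specific package's defaults.
All-correct or all-at-chance data are flagged non-identifiable and
return prior-dominated wide intervals instead of failing. Because the
location grid is anchored to the tested levels, fits are exactly
shift-equivariant on the dB axis.

## Model fitting

**Simplex.** `simplex_fit()` minimizes the dB RMSE between model and
data thresholds with Nelder–Mead restarted from 100 random starting
vectors (the published procedure), drawn log-uniformly within fixed
per-parameter ranges; free parameters are optimized on the log scale,
which enforces positivity, and equal-RMSE ties go to the lowest start
index. Each candidate evaluation re-solves the full threshold set, so
the vectorized solver is the performance-critical path.

**Hierarchical Bayesian.** `bayes_fit()` uses a binomial likelihood at
each (participant, arrangement, pedestal, target) cell, with the cell
probability given by the model d′ through the 2IFC link (lapse fixed at
the generator's 0.01). Priors are Gaussian on $p, q, m, \omega$
(centred on the classic published row: 7.99, 6.59, 1.28, 1.00; SDs 2,
2, 0.3, 0.3) and uniform on $S, Z, k$ — weakly informative around
published values and wide enough to cover the spread of reported fits.
Participant-level $m, \omega, k$ are partially pooled log-normally
around group means (hyper-SDs uniform on [0.01, 0.5]); $p, q, S, Z$
are shared, which keeps the seven-parameter model identifiable at desk
scale while still fitting all participants simultaneously. Sampling is
MCMC through JAGS (Gibbs/slice sampling; the original analysis used a
gradient-based sampler, but the model is low-dimensional and mixes
adequately without gradients), with chains seeded deterministically
from R's RNG. A configurable retention fraction (default 10%, the
published retention used for plotting) thins the stored draws.
Convergence is flagged via split-chain PSRF < 1.05 when more than one
chain is run; unconverged fits are flagged, never silently dropped.

`bayes_fit_crosspath()` fixes the within-pathway parameters (including
the diagonal weights) and estimates the nine free parameters of the
extension — three $Z$ values and six cross weights — with uniform
priors ($Z \in [10^{-4}, 1]$, weights $\in [0, 3]$), pooling data over
participants. How the original analysis shared these nine parameters
across participants is not stated; pooling is this package's choice and
is the simplest structure consistent with "fit to the pooled data".

**Problem sizes.** The shipped test suites run reduced-scale versions
chosen once as realistic desk-scale study conditions: recovery
replicates use 3 participants, 4 pedestals, 4 arrangements, 6 levels ×
40 trials per cell, with single chains of 1,500 iterations after 600
warm-up; the psychometric calibration uses 200 replicate fits of 10
levels × 60 trials. The full printed designs (e.g. the 72,000-trial
constant-stimuli experiment) are generated and checked for their exact
trial arithmetic, and the full 100-start simplex refit is exercised by
`scripts/acceptance.R`.

## Numerical and degenerate-input choices

* First-crossing bracketing with adaptive-depth bisection (above);
  solver failures are errors, never clamps.
* Zero contrast and zero binocular sum short-circuit to zero response.
* `rmse_dB` refuses non-positive thresholds and mismatched lengths.
* Staircase levels live on an exact dB lattice (start + multiples of
  3 dB), so aggregation by level is exact.
* CSV round-trips preserve doubles to R's full `write.csv` precision
  (~15 significant digits).

## Known limitations

* The Bayesian fits pool the cross-pathway parameters over
  participants; participant-level cross weights would need richer data.
* The psychometric grid integrator trades a small grid-resolution bias
  for speed and determinism; intervals at extreme slopes touch the
  prior bounds.
* The staircase engine models neither finger errors beyond the lapse
  rate nor sequential dependencies, so it slightly understates the
  variance of real adaptive thresholds.
* Real-data ingestion is out of scope; the CSV schema is compatible
  with tidy trial exports but no mapping scripts are provided.
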