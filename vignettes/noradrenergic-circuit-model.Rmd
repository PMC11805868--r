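---
title: "A mean-field model of cocaine-induced noradrenaline release: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mean-field model of cocaine-induced noradrenaline release: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necsim)
```

## The model and its assumptions

`necsim` simulates four interacting brain regions as mean-field units: the
locus coeruleus (LC) and the nucleus of the tractus solitarius (NTS), the
two main noradrenergic sources; and the medial prefrontal cortex (mPFC)
and nucleus accumbens shell (NAcc), two principal targets in the reward
circuit. Each region is one firing-rate variable (Hz); two additional
variables track extracellular noradrenaline (NE) concentration (pg) in
mPFC and NAcc. All couplings are excitatory: the mPFC drives LC and NTS,
the LC releases NE in the mPFC, and LC and NTS together release NE in the
NAcc; NE in turn excites its host region, closing a positive
mPFC -> LC -> NE_mPFC -> mPFC loop. Direct mPFC -> NAcc projections are
deliberately not modelled; the point of the circuit is to isolate the
*indirect* prefrontal influence on accumbal NE through LC and NTS.

The dynamics are linear: `dy/dt = A(t) y + b` on the state
`y = [LC, NE_mPFC, mPFC, NTS, NE_NAcc, NAcc]`, with negative damping on
the diagonal of `A` and the external drives in `b` (zero on the two NE
coordinates: NE pools have no external source). Mean-field linearity is a
strong assumption — no saturation, no spiking, no other transmitter
systems — accepted here because the regime of interest stays near a
stable operating point.

Two switches modulate `A`:

* **Depletion** `l in {0, 1}`: scales both terms of the mPFC NE equation.
  `l = 0` freezes prefrontal NE exactly at its starting value — an
  idealization of lesion-induced depletion that removes the feedback loop
  while leaving baselines untouched.
* **The cocaine kernel** `k(t) in (0, 1]`: a unitless multiplier on both
  NE clearance rates, `k = 1` before the injection at `t_c` and
  `1 - a(e^{-(t-t_c)^2/b} - e^{-(t-t_c)^2/c})` after. With widths
  `b > c > 0` (minutes squared) the kernel dips below 1 — the
  reuptake-blockade analogue — and returns to 1, so the drug effect is
  transient by construction. The kernel's global minimum has the closed
  form implemented in `kernel_minimum()`; parameter sets whose minimum
  would touch zero are rejected, since `k <= 0` would turn clearance into
  production.

## Parameters, units, defaults

The 17 free circuit coefficients (`circuit_parameter_names()`) are decay
constants `tau_*`, coupling gains, and constant drives. All rates are
treated as per-minute: the experiment's natural timebase is minutes, and a
1-min integration step only makes dimensional sense with per-minute decay
(nominal "Hz" labels for such constants are treated as nomenclature, not
units). Defaults that matter:

| quantity | default | why |
|---|---|---|
| horizon | 180 min | length of the microdialysis session |
| `dt` | 1 min | the model's native discretization; one step = one minute |
| `t_c` | 60 min | injection after three baseline samples |
| sampling interval | 20 min | standard microdialysis cadence |
| cohort size | 10 per condition | the study's animal count |
| `noise_sd` | 0.05 | drive noise, 5% of each external drive |
| divergence ceiling | 1e6 | any state beyond this aborts with the offending time |

## Numerical choices

**Integration.** The native scheme is explicit Euler at `dt = 1` min.
Because the system is linear, the Euler map is `y -> (I + dt A) y + dt b`:
it converges to the *exact* equilibrium (`A y + b = 0` is unchanged by
`dt`) iff the spectral radius of `I + dt A` is below 1. Continuous-time
stability does not imply this — a decay constant above 2/min already
leaves the Euler stability region — so the fitting stage certifies the
discrete map too, for both the sham matrix and the reduced depleted matrix
(under `l = 0` the mPFC row decouples and its eigenvalue becomes exactly
`-tau_mPFC`). An optional `method = "rk4"` with sub-stepping exists for
accuracy checks; the test suite verifies it against an adaptive solver
(deSolve::lsoda) to 1e-6 and the Euler endpoint against the closed-form
equilibrium to 1e-6 on 2000-min noiseless runs.

**Noise.** The equations have no intrinsic noise term; variability across
virtual mice comes from (i) distinct GA optima and (ii) zero-mean Gaussian
perturbations of the four external drives, s.d. `noise_sd * alpha_*_ext`,
redrawn every 1-min step from a private seeded RNG stream (the caller's
RNG state is never touched). Perturbing the drives rather than the states
keeps the linear analysis intact in expectation and leaves the two NE
pools noise-free except through coupling — which is why depleted
prefrontal NE is *exactly* flat, not flat up to noise.

**Equilibria.** Always a linear solve, never an explicit inverse; the sham
fixed point solves `A y + b = 0`. The depleted matrix is singular (zero
row), so `equilibrium_state()` refuses it unless the frozen NE level is
supplied, then solves the reduced 5-variable system. Eigenvalue real parts
within 1e-9 of zero count as zero; the depleted system is reported
`marginally_stable` with exactly one structural zero eigenvalue — a
deliberate refinement of calling it "the same stability" as sham, since a
zero row mathematically forces a zero eigenvalue.

## The genetic algorithm

Each virtual mouse is an independent GA run over 20 genes (17 coefficients
plus kernel `a`, `b`, `c`; `t_c` is the protocol's, not fitted). Bounds:
decay constants (0.01, 10] per minute, gains and drives [0, 10], `a`
[0, 0.999], `b` [200, 20000] min², `c` [5, 5000] min². Fitness (lower is
better) sums:

1. the mean squared relative deviation of the noiseless sham equilibrium
   from the six steady-state targets (weight 5);
2. a 1e6 penalty for any candidate that is continuous- or discrete-time
   unstable (sham or depleted map) or whose kernel leaves (0, 1];
3. a response-shape term (weight 0.5): every mouse is pulled toward the
   same accumbal NE percent-of-baseline curve
   ([+50, +100, +80, +55, +40, +30]% at the six post-injection samples —
   a 200%-of-baseline peak at 40 min with a gradual return, the shape of
   published acute-cocaine microdialysis curves), at least +15%
   post-injection firing in all four regions (the loop, not just the NE
   pools, must engage), and at least a 15-point percent-of-baseline drop
   in accumbal NE at every sample when the same candidate is rerun
   depleted (the depletion experiment is the phenomenon the circuit
   exists to explain; candidates whose response is pure direct
   damping-reduction with a dead loop are not faithful fits, and a
   smaller drop would drown in single-sample dialysate noise).

The GA itself: tournament selection (size 3), blend crossover (rate 0.7),
per-gene Gaussian mutation (rate 0.15) whose scale anneals geometrically
from 10% to 0.3% of each gene's bound width — a fixed coarse scale cannot
polish into the 5% acceptance gate, an always-fine scale cannot explore —
elitism of 2, population 64, up to 300 generations with early stop when
the best fitness reaches `convergence_tolerance` (2e-4). Half the initial
population (and a few immigrants per generation) is drawn
construction-first: random decay constants and gains with drives solved
toward the targets. These individuals are still random; they keep the
steady-state basin represented in the gene pool, without which tournament
selection was observed to converge prematurely onto shape-feasible but
steady-state-degenerate regions.

A fit is **accepted** when every steady-state coordinate is within 5% of
its target and the sham system is certified asymptotically stable. The
17-parameter-to-6-steady-state map is many-to-one, so only the steady
state (not the parameters) is recoverable — the test suite's synthetic
recovery experiment checks exactly that. Distinct seeds land on distinct
accepted optima; a default cohort of 10 therefore carries 170 distinct
coefficients, and this parameter dispersion is the package's model of
between-animal variability.

## The virtual experiment

180 simulated minutes per mouse; samples at 20-min marks; the mean of the
three pre-injection samples (20, 40, 60 min — the injection instant still
has `k = 1`) is the baseline; six post-injection samples at 20–120 min
after injection are expressed as percent of baseline. Sampling indices are
exact multiples of the step — no interpolation. Every run starts at the
mouse's sham equilibrium; the depleted arm freezes prefrontal NE at that
same value, matching the equal baselines reported between groups. Firing
summaries are pre-injection vs post-injection window means per mouse
(windows partition the run at `t_c`). Per-mouse, per-condition simulation
seeds derive deterministically from the mouse seed plus a fixed offset for
the depleted arm.

## Statistics

The selection policy mirrors the published analysis logic: Shapiro–Wilk
*and* D'Agostino–Pearson screen each group at alpha 0.05 (the omnibus K²
test is implemented from the standard skewness/kurtosis z-transforms and
verified against an independent reference implementation); any failure —
or a constant group, or a group too small to screen — routes to the
Mann–Whitney test; otherwise Student's t, with Welch's correction when an
F-ratio test rejects equal variances at 0.05. Tests are two-sided. The
Mann–Whitney branch is exact whenever there are no ties and groups are at
most 50: the normal approximation floors the attainable two-sided p at
about 1.8e-4 for two groups of 10, which would contradict the sub-1e-4
rank-test results this design is meant to support. Timecourse comparisons
run per post-injection timepoint with Sidak adjustment
(`1 - (1 - p)^m`, `m` = number of timepoints); when every
condition-by-timepoint cell passes the normality screens a two-way
mixed-design ANOVA (condition between, time within mouse) is added —
sphericity is not tested, a deliberate simplification. Degenerate
comparisons (both groups constant) are flagged, not raised.

The type-I calibration test simulates both null cohorts from a *single*
parameter set so that the 20 per-timepoint values are i.i.d. (mice
differing only by noise seed); with per-mouse parameter heterogeneity
shared across both groups the unpaired test would be conservative and the
calibration would measure the wrong thing.

## What the generator does and does not emulate

The synthetic cohorts emulate: steady states on literature values,
transient NE responses of realistic amplitude and timing, depletion as a
clean loop knockout, and seed-driven individual variability. They do not
emulate: receptor saturation or nonlinearity, other transmitter systems
(dopamine, serotonin, glutamate kinetics), gradual rather than
instantaneous depletion, pharmacokinetic dose dependence (dose enters only
through the fitted kernel), or measurement noise in the dialysate itself.
Passing tests therefore show internal consistency of the circuit
hypothesis and pipeline, not validation against animals.

## Problem sizes

Defaults were chosen at desk scale: one GA fit is 64 x <=300 evaluations,
each a 6x6 eigensolve plus two 180-step simulations (about a minute per
mouse); the full 10-mouse pipeline with both conditions, statistics and
serialization completes in minutes on one core; the calibration test uses
200 replicate null experiments.

## Known limitations

* Euler at `dt = 1` is first-order; endpoint error vs an adaptive solver
  is at the percent level during fast transients. The scheme is kept
  because it *is* the model's published discretization; the RK4 mode
  exists for verification.
* The acceptance gate constrains steady states, not transients; two
  accepted mice can differ visibly in response width.
* With `l = 0` the full system matrix is singular; equilibrium questions
  are only meaningful for the reduced system with a frozen NE level.
* The reported degrees of freedom follow from the two-sample designs on
  10 + 10 window means; published df conventions for such designs vary.
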