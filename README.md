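# necsim

Simulation of cocaine-induced noradrenaline (NE) release in a four-region
mean-field brain circuit: the locus coeruleus (LC), the medial prefrontal
cortex (mPFC), the nucleus of the tractus solitarius (NTS), and the nucleus
accumbens shell (NAcc). The package is aimed at computational
neuropharmacology work on the noradrenergic reward circuit — in particular
at the question of how prefrontal NE depletion reshapes the accumbal NE
response to an acute psychostimulant challenge — and at anyone who wants a
small, fully reproducible in-silico microdialysis testbed.

## The model

Six state variables — four population firing rates (Hz) and two
extracellular NE concentrations (pg) — evolve by a linear ODE system

```
dLC/dt       = −τ_LC · LC + α_LC^mPFC · mPFC + α_LC^ext
dNE_mPFC/dt  = −l · k(t) · τ_mPFC^NE · NE_mPFC + l · α_mPFC^LC · LC
dmPFC/dt     = −τ_mPFC · mPFC + α_mPFC^NE · NE_mPFC + α_mPFC^ext
dNTS/dt      = −τ_NTS · NTS + α_NTS^mPFC · mPFC + α_NTS^ext
dNE_NAcc/dt  = −k(t) · τ_NAcc^NE · NE_NAcc + α_NAcc^LC · LC + α_NAcc^NTS · NTS
dNAcc/dt     = −τ_NAcc · NAcc + α_NAcc^NE · NE_NAcc + α_NAcc^ext
```

with 17 free coefficients. Cocaine (an NE-transporter blocker) enters as a
unitless pharmacodynamic kernel `k(t) ∈ (0, 1]` multiplying the NE
clearance terms: `k(t) = 1` for `t ≤ t_c` and
`k(t) = 1 − a(e^{−(t−t_c)²/b} − e^{−(t−t_c)²/c})` afterwards, so the
kernel dips below 1 after the injection (reduced reuptake, hence NE
accumulation) and returns to 1 as the drug effect wears off. Prefrontal NE
depletion is the switch `l`: 1 in sham animals, 0 in depleted animals,
which freezes the mPFC NE pool exactly.

In compact form `dy/dt = A(t) y + b`, so equilibria come from a linear
solve of `A y + b = 0` and stability from the spectrum of `A`
(asymptotically stable iff every eigenvalue has negative real part). The
depleted matrix has a structurally zero row and is marginally stable
through exactly one zero eigenvalue.

The 17 coefficients and the kernel's `(a, b, c)` are fitted per virtual
mouse by a genetic algorithm against literature steady states (LC 2.3 Hz,
NE_mPFC 0.4 pg, mPFC 2.05 Hz, NTS 1.85 Hz, NE_NAcc 0.4 pg, NAcc 1.55 Hz)
plus qualitative response-shape constraints; distinct seeds give distinct
optima, which is the package's model of between-animal variability. The
virtual experiment mirrors in-vivo microdialysis: 180 min at 1-min Euler
steps, injection at 60 min, 20-min sampling, three pre-injection samples
averaged into the baseline, percent-of-baseline readouts, and a
statistics pipeline (Shapiro–Wilk + D'Agostino–Pearson screening,
Student/Welch/Mann–Whitney selection, repeated-measures ANOVA with Sidak
correction).

## Worked example

```r
library(necsim)

m <- fit_mouse(seed = 1)                       # GA fit of one virtual mouse
print(m)
#> <fitted_mouse> mouse_01 seed 1: fitness 0.0231 after 300 generations (accepted)
#> steady state: 2.356 0.403 2.067 1.852 0.404 1.564

rep <- stability_report(build_linear_system(m$parameters))
print(rep)
#> <stability_report> asymptotically_stable (max Re lambda = -0.3404, 0 on axis)
```

The fitted steady state sits on the literature targets (2.3, 0.4, 2.05,
1.85, 0.4, 1.55) within the 5% acceptance gate, and the fitted system is
certified asymptotically stable. Running the two-condition experiment over
a fitted cohort:

```r
cohort <- fit_cohort(n_mice = 10, base_seed = 1)   # ~1 min per mouse
proto  <- dialysis_protocol()                      # 180 min, t_c = 60, 5% drive noise
report <- compare_experiment(run_condition(cohort, "sham", proto),
                             run_condition(cohort, "depleted", proto))
print(report)
#> <experiment_report>
#>   NE_mPFC: 6/6 post-injection timepoints significant; baseline p = 0.631
#>   NE_NAcc: 6/6 post-injection timepoints significant; baseline p = 0.529
#>   firing sham.LC: mann_whitney p = 1.08e-05 *
#>   firing sham.mPFC: welch_t p = 6.29e-09 *
#>   firing sham.NTS: welch_t p = 7.15e-10 *
#>   firing sham.NAcc: welch_t p = 1.5e-07 *
#>   firing depleted.LC: mann_whitney p = 0.529
#>   firing depleted.mPFC: student_t p = 0.916
#>   firing depleted.NTS: mann_whitney p = 0.796
#>   firing depleted.NAcc: welch_t p = 1.38e-07 *
```

Read: cocaine raises firing in all four regions of sham mice; after
prefrontal NE depletion only the NAcc increase survives (carried by the
kernel acting directly on accumbal NE clearance), and sham NE
percent-of-baseline exceeds depleted at every post-injection timepoint in
both regions, with no baseline difference — the circuit-level prediction
the package exists to exercise.

A command-line wrapper is available as `exec/necsim`
(`necsim fit | simulate | stability | analyze | reproduce`), each
subcommand a thin layer over the functions above, writing CSV/JSON plus a
checksummed run manifest that `necsim reproduce` re-verifies bit for bit.

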