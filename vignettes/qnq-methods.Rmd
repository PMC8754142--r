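---
title: "Modelling quiescent and nonquiescent yeast through starvation and regrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling quiescent and nonquiescent yeast through starvation and regrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qnq)
```

## The biological problem

Glucose-starved budding yeast populations split into two phenotypes:
quiescent (Q) cells, which actively exit the cell cycle into a dense,
stress-resistant, non-dividing state, and nonquiescent (NQ) cells, which do
not. Q cells survive starvation far better — after four weeks roughly 87% of
Q cells but only 3% of NQ cells remain viable — and they tolerate additional
stresses such as freezing (40% vs 10% survival). NQ cells, however, can
resume division sooner after a *short* starvation, and they can keep
dividing during starvation if residual nutrients are available. Whether a
population dominated by Q cells, by NQ cells, or by the naturally occurring
3:1 mixture regrows best therefore depends on the ecological scenario: how
long starvation lasts, how long regrowth lasts, and whether the starvation
environment permits nutrient recycling. `qnq` implements a deterministic
population model of these dynamics together with the plate-reader analytics
used to study them, and a synthetic-data generator that emulates the
corresponding microplate experiments.

## State variables and units

The state is `(Q, NQ, R, U)`: viable quiescent biomass, viable nonquiescent
biomass, the limiting fresh-medium resource, and a recyclable nutrient pool
fed by dead cells or left over in spent medium. All four share one currency —
cells per 200 µl well-equivalent — by expressing nutrients in
*cell-equivalents*, the number of new cells they can yield, and fixing the
yield coefficient at 1. With this choice `Q + NQ + R + U` is an exact
bookkeeping total: it is conserved whenever recycling is perfect
(`epsilon = 1`) and declines otherwise. Time is in hours; rates quoted per
day are converted by dividing by 24.

## The three dynamical phases

**Growth and differentiation.** On fresh medium, NQ (dividing) cells grow at
the Monod rate $\mu(R) = v_{\max} R/(K_m + R)$ and consume resource.
Differentiation into quiescence is resource-gated,
$\sigma(R) = \sigma_{\max} K_d/(K_d + R)$: negligible while nutrients are
plentiful, approaching $\sigma_{\max}$ as they run out — quiescence entry
starts near depletion and is not instantaneous. No cells die in this phase.

**Starvation.** Q cells neither divide nor feed; they die at rate $d_Q$ and
convert to NQ at rate $\tau$, so over long starvation most Q cells
eventually leave the quiescent pool. NQ cells die at rate $d_{NQ} > d_Q$
and, in the *complex* environment only, divide on the recyclable pool with
the same Monod kinetics; a fraction $\varepsilon$ of all dead biomass flows
back into that pool. In the *simple* environment (sterile water) the
recyclable pool is fully inert — neither fed by dead cells nor consumed —
because a medium lacking everything but what corpses release cannot support
growth. This gating is deliberate: killed biomass from the freezing stress
is booked into the recyclable pool, and if sterile-water cultures could feed
on it, NQ monocultures would regrow during starvation in plain water, which
is not observed.

**Regrowth.** After transfer to fresh medium each subpopulation stays
dormant until its starvation-dependent lag has passed, then joins a common
actively dividing pool at a wake rate $w$ (default 2/h, i.e. most cells
start dividing within half an hour of the end of their lag); active cells
follow Monod kinetics. The integration state therefore separates dormant Q,
dormant NQ, and active cells, and trajectories report
`nq = dormant NQ + active`. We chose this three-pool form over a two-pool
one in which woken Q cells would inherit the NQ gate: under long starvation
the NQ lag reaches 9.4 h while Q monocultures measurably start growing
after about 1.6 h, so each pool must be gated by *its own* lag. There is no
death during the 24 h regrowth window.

Lags follow a linear schedule in starvation weeks,
`lag = lag0 + slope * weeks` (clamped at 0), anchored so that Q runs from
1.5 h (week 0) to 1.6 h (week 6) and NQ from 2.2 h to 9.4 h — the reported
monoculture lags at those ages. The gate is a hard indicator by default; a
logistic gate of width 0.1 h is available (`lag_gate = "smooth"`) for
integrator-friendliness, and the hard gate is handled exactly by splitting
the integration at the lag times.

### Short-starvation lags and detection delay

After a 4-day starvation the *measured* lags are 2 h (Q) and 1 h (NQ) by
the threshold rule below. A threshold estimator on a half-hour grid reports
the first *sample* at which OD has risen by 0.01, which overshoots the true
growth onset by up to one sampling interval plus the time needed to grow
0.01 of OD. The packaged onset gates are therefore set half a sampling
interval below the reported values — `lag_q_short = 1.5`,
`lag_nq_short = 0.5` — so that the simulated assay, analysed exactly as the
laboratory assay is analysed, reproduces the reported 2 h and 1 h. For the
long-starvation schedule the printed lag values are adopted directly as
onset times: the half-interval detection bias is immaterial against
week-scale trends of several hours.

## Protocols

`run_long_starvation()` composes the weekly assay: initialise at OD 0.8
(converted to cells), apply freezing survival (40% Q, 10% NQ; killed
biomass enters the recyclable pool), integrate starvation continuously, and
each week draw a sample, discard the starvation supernatant (and with it
the recyclable pool), resuspend in fresh medium and plate. With the
275 µl → 550 µl → 200 µl geometry the plated well holds the cells of 0.1 ml
of culture — half of the per-well-equivalent biomass. Weekly sampling is
modelled as non-destructive: 275 µl of a 5 ml culture is about 5.5% per
week, it affects all cultures equally, and ignoring it keeps the starved
state continuous. `run_short_starvation()` starts directly in fresh medium
at OD 0.4 with the short-starvation lags and no freezing.

The fresh medium supplies `3.2e7` cell-equivalents per well, chosen so the
regrowth plateau reproduces the observed stationary biomass
(~3.2 × 10⁷ cells/well). The complex environment starts with a residual
recyclable seed of 2% of that value — spent medium retains some usable
compounds — exposed as `residual_seed_frac`.

## Growth-curve analytics

OD600 is converted to cells per well with the empirical cubic
$-2{\times}10^6\,\mathrm{OD}^3 + 3{\times}10^7\,\mathrm{OD}^2 +
3{\times}10^6\,\mathrm{OD} + 2.203{\times}10^5$, strictly increasing on
OD ∈ [0, 2]; the inverse is obtained by bracketed root-finding to better
than one cell. Biomass below the calibration intercept (~2.2 × 10⁵ cells)
is below the reader's sensitivity and is emitted as OD 0 by the generator.

Two lag estimators are provided. The threshold rule returns the first
sampled time at which OD has risen 0.01 above its starting value; a curve
that never crosses yields a typed `NA` sentinel which downstream statistics
drop and count, never a silent maximum. The maximum-growth-rate rule
differentiates biomass with centred finite differences on the raw grid (no
smoothing by default; an optional 3-point running-median prefilter is
available for noisy data) and reports the time of the maximal first
derivative, ties broken earliest. The phrase "time to reach the maximum
growth rate" is sometimes equated with the maximal *second* derivative of
biomass; these differ, so the first-derivative reading is the default and
the second-derivative variant is available via `method =
"second_derivative"`.

Two relative-biomass normalisations mirror the study's analyses: ratio to
the per-time mean of mixed-culture replicates (mixed replicates then
average exactly 1 at every time point, by construction), and the per-type
ratio of complex- to simple-environment means on matched time grids, with
grid mismatches raised as errors rather than silently interpolated. All
analyses use the first 24 h of regrowth at 0.5 h resolution.

## Statistics

Biomass at chosen regrowth times (defaults 2 h, 10 h, 24 h — early
regrowth, the catch-up point, and the plateau) is compared across culture
types by one-way ANOVA with Tukey HSD post hoc tests; lag lengths by a
two-sided t test, Welch by default (the pooled-variance form is a flag)
since equal variances across culture types is exactly what the data
contradict. No multiplicity correction is applied across time points, and
the output metadata says so. Degenerate inputs (all observations equal)
return p = 1 rather than NaN.

## Parameter calibration

Death rates come in closed form from viability fractions,
$d = -\ln(s)/t$. Everything else can be fitted with a self-contained
rand/1/bin differential-evolution optimiser (`de_optimize()`): the
objective is the sum of squared residuals between observed and simulated
biomass over every culture, week, replicate and time point, with the
simulation path identical to the scenario runners. Defaults are the common
DE settings `NP = 10 × dim`, `F = 0.8`, `CR = 0.9`, 200 generations with
early stopping after 30 stalled generations; a fixed seed makes fits
reproducible. Residuals are computed on biomass to match the
converted-biomass analyses (OD-space residuals are a flag); simulation
failures inside the objective are penalised with a large finite value. The
free-parameter set is explicit and mandatory — which parameters to fit is
a modelling decision the user must own.

## The synthetic-data generator

`generate_plate_dataset()` emulates the study design: 3 compositions × 2
environments × 5 replicates over 6 weekly assays (8 820 rows at 49 samples
per curve) plus a 16-replicate short-starvation plate. Replicate structure
enters as a per-replicate jitter of the lag baselines (SD 0.25 h), scaled
by each type's death rate so NQ replicates — which keep dividing and
diversifying during starvation — scatter more than Q replicates, as the
late-week data do. Measurement noise is `od·(1 + ε_mult) + ε_add` with
SDs 0.01 and 0.005, truncated at 0 and with truncations counted; the
magnitudes were chosen once to match the order of magnitude of replicate
error bars in this kind of plate assay. An optional dropout flag emulates
occasionally lost replicates. What the generator does *not* emulate: pipetting
biases between wells, plate-position (edge) effects, the 70 h reader run
beyond the 24 h analysis window, drift in the OD calibration, and any
genetic change during starvation. Tests passing on generated data therefore
validate the analysis machinery and the model's internal consistency, not
the biological fidelity of the model to any particular dataset.

## Numerical choices

Integration uses `lsoda` (adaptive, stiff-capable) at `rtol = 1e-8`,
`atol = 1e-2` cells; phase boundaries are external so no event handling is
needed, and hard lag gates are respected by segmenting the integration at
the lag times. Post-step negative undershoots smaller than `atol` are
clipped to zero; anything larger aborts with an integration error naming
the phase. The production solver is checked against an independent
fixed-step RK4 oracle (step 10⁻³ h) to a relative error below 10⁻⁴ on all
three phases, and halving the output step or tightening `rtol` tenfold
changes final biomass by well under 0.1%.

Default parameter values not pinned by the protocol were set once to
field-realistic magnitudes: `v_max = 0.4`/h (a ~1.7 h doubling time,
typical of rich-medium yeast), `k_m = k_diff = 10⁶` cell-equivalents
(≈3% of the fresh-medium supply, so growth is near-saturated until close
to depletion), `tau = 10⁻³`/h (a ~29-day conversion half-life: most Q cells
leave quiescence over a long starvation while week-scale Q survival stays
high), `sigma_max = 0.1`/h, and `epsilon = 0.5` (half of dead biomass
recoverable in spent medium).

## Problem sizes used in the shipped checks

The test-suite simulations are deliberately modest: qualitative-pattern
checks run the six-week protocols once per composition and environment;
oracle comparisons integrate 24–48 h horizons; the parameter-recovery study
fits two parameters (`d_nq`, `lag_nq0`) on 20 independently seeded noisy
datasets of a two-week, five-replicate NQ scenario with a 12-member DE
population and at most 40 generations. These sizes were chosen as the
smallest that exercise every claim they test.

## Known limitations

The model is deterministic: no demographic stochasticity, no agent-based or
CTMC variant, and no evolutionary dynamics (mutation, selection, GASP-like
phenotypes) even though long NQ division during starvation is exactly the
regime where such changes arise. Temperature and toxin stresses are not
modelled; freezing enters only as fixed survival fractions. The initial
Q/NQ composition is an input, not the outcome of a simulated pre-growth.
The supplementary equations of the original study were not available when
this package was written; the right-hand sides here are a reconstruction
in which every term maps to a stated model assumption, isolated behind the
`*_rhs()` functions so an alternative form can be swapped in and judged
against the same invariants and patterns.
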