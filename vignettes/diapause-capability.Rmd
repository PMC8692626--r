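---
title: "Modelling overwinter capability of Calanus finmarchicus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling overwinter capability of Calanus finmarchicus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overwintr)
```

## The scientific question

High-latitude populations of *Calanus finmarchicus* must survive the winter
in diapause at depth, living off wax esters stored in the lipid sac. A
population's prospects therefore depend on (i) how much lipid individuals
carry relative to what their body size can hold, (ii) how fast they burn it
— a function of structural body mass and ambient temperature — and (iii) how
many individuals sit in the deep layer where diapause happens. `overwintr`
chains these three ingredients into a per-individual capability
classification and scales it to depth-integrated abundance.

## The energetic model and its assumptions

The model is carbon-based. Total body carbon $M$ (elemental analysis) is
partitioned into the lipid reserve $w$ and structural mass $m = M - w$; only
$m$ respires. The reserve is estimated from lipid sac area $A$ via the
published image-analysis calibration $WE = 0.167\,A^{1.42}$ and the 79 %
carbon content of wax esters, $w = 0.79\,WE$. Respiration follows
three-quarter-power allometry with Boltzmann–Arrhenius temperature scaling,

$$ r = b\, m^{3/4} \exp\!\left[E\,\frac{T - T_0}{k\,T\,T_0}\right] \times 86\,400
  \quad [\mu g\,C\,day^{-1}], $$

and diapause duration is the time to draw the reserve down to a retained
fraction $f_{ret}$ of its starting mass,
$D = (1 - f_{ret})\,w / r$, with capability declared when
$D \ge 150$ days (closed boundary). The key assumptions: the reserve is
metabolically inert; diapause metabolism is constant through the winter at
the assigned temperature; and the 150-day threshold plus 20 % retained
reserve together represent what a successful overwintering-and-reproduction
requires.

## Parameters, defaults, and the choices behind them

| parameter | default | units | rationale |
|---|---|---|---|
| `b` | 2.5e-7 | µg C^(1/4) s⁻¹ | published diapause scaling constant |
| `E_eV` | 0.65 | eV | standard metabolic-theory activation energy; the source analyses do not print the value they used, so it is an explicit, configurable assumption |
| `T0_K` | 273.15 | K | base temperature; see below |
| `retained_fraction` | 0.2 | — | 20 % of the reserve must remain at emergence |
| `D_threshold_days` | 150 | days | conservative requirement for a full winter |
| `deep_cutoff_m` | 250 | m | boundary of the candidate overwintering layer |

**Base temperature.** Stating the Arrhenius reference as absolute zero makes
the exponent singular ($T_0$ appears in the denominator). We take
$T_0 = 273.15$ K (0 °C), the standard deviation-from-reference form, so the
exponential is exactly 1 at 0 °C — a property the test suite checks
analytically. At realistic overwintering conditions (deep water near
−0.5 °C, $m \approx 100$ µg C) this yields rates near 0.68 µg C day⁻¹ and
durations of 100–220 days for realistic reserves, the magnitude reported for
deep Fram Strait populations. $T_0$ remains configurable.

**Temperature entering the model.** Three modes: `stratum_midpoint`
(default; CTD temperature interpolated at the capture-stratum midpoint),
`deep_mean` (CTD mean below the deep cutoff — an "assumed overwintering
temperature" mode), and `fixed`. The default uses the information actually
measured for each individual and is the least assumptive.

**Maximum-lipid allometry.** The ceiling $w_{max} = c\,L^{e}$ on reserve
carbon given prosome length has no universally printed coefficients. The
package defaults ($c = 10$ µg C mm⁻³, $e = 3$) encode volumetric scaling at
a magnitude plausible for CV (a 2.5 mm animal holds at most ~156 µg C of
lipid); they are deliberately labelled package defaults, not literature
constants, and every test that depends on them states its coefficients
explicitly. Fullness $w / w_{max}$ above 1 is retained and flagged rather
than truncated, so fullness averages are computed on untruncated values
(truncation is an option).

**Infeasible records.** If estimated lipid carbon meets or exceeds measured
total carbon, structural mass would be non-positive and the duration would
diverge. Such records are excluded and counted, never clamped.

## Hydrography and abundance conventions

CTD profiles are piecewise linear in depth (positive downward); layer means
are exact trapezoidal integrals of that function divided by layer thickness,
and depths outside the sampled range clamp to the nearest endpoint with a
warning. Net catches assume uniform concentration within a stratum, so the
depth integral is refinement-invariant; strata straddling the 250 m cutoff
contribute pro rata. Integration starts at the shallowest sampled depth and
never extrapolates to the surface. The capable fraction is pooled across all
deep-caught assessed individuals of a station (a per-stratum weighting could
be layered on top, but with ~10 assessed individuals per stratum the pooled
estimator has far lower variance). Station summaries round abundances and
durations to integers (half away from zero), while per-individual CSVs keep
full precision.

## What the synthetic generator emulates — and what it does not

The generator reproduces the late-summer observation system the pipeline is
designed for, with one pseudo-random stream per artifact (CTD, population,
catch) derived from a single seed so artifacts regenerate independently:

- **Hydrography**: a linear warm surface layer over 0–125 m whose mean
  equals the station archetype's surface mean (defaults 2.362, 3.643,
  4.319 °C west to east), a thermocline to 400 m, and −0.5 °C deep water,
  plus small-scale noise.
- **Vertical distribution**: CV mixtures concentrated above 250 m at the two
  western archetypes and with a pronounced 375–625 m deep mode at the
  eastern one; deep fractions ≈ 0.19, 0.26, 0.78 of CV totals 2 592, 12 098
  and 15 710 ind m⁻².
- **Biometrics**: stage-specific Gaussian prosome lengths (CV mean 2.5 mm,
  SD 0.15), lipid fullness from a Beta(2, 2) law (the minimal bounded family
  on [0, 1]; no field distribution is published), structural carbon from a
  lognormal-noise allometry $m = 6\,L^3$, and a lipid sac area obtained by
  inverting the wax-ester calibration so the biometric pipeline recovers the
  latent masses exactly. These defaults were chosen a priori, on the model's
  own closed form, to place deep CV in the regime the tools are intended
  for: a required fullness around three quarters of the allometric ceiling,
  so that only the well-provisioned tail of the Beta(2, 2) fullness law
  clears the 150-day threshold.
- **Catches**: Poisson counts with expectation = abundance × vertical-mass ×
  net area (1 m², eight 5–1000 m strata), negative binomial optionally.

Ground truth includes the analytically computed capable fraction: given each
individual's length, structural mass and assigned temperature, capability is
equivalent to fullness exceeding a required-fullness threshold, whose
probability under the Beta law is a closed-form tail. Parameter-recovery
tests compare pipeline estimates against this truth.

The generator does **not** emulate advection, seasonal succession,
multi-species mixtures, measurement error in lipid sac area or elemental
analysis, or vertical structure within a stratum. Passing the recovery suite
therefore shows the pipeline is a faithful estimator of its own model's
quantities under realistic sampling noise — not that the model captures
every property of field data.

## Numerical choices and degenerate inputs

- The capability boundary is closed (`D = 150` days is capable).
- Species-length classification intervals are closed on the lower bound,
  open on the upper; lengths in no interval are `ambiguous`; thresholds are
  configuration input with no shipped defaults, because they are
  survey-specific calibrations.
- Duplicate CTD depths are averaged; fewer than two distinct depths is an
  error; an empty assessed set is an error (a capable fraction of 0/0 would
  otherwise silently scale the population to zero).
- An empty lipid sac ($A = 0$) is valid and yields $D = 0$, not capable.
- Required reserve is the exact closed-form inversion of the duration model;
  the tests verify it against independent bisection to 1e-9 relative
  tolerance.

## Problem sizes used by the test suite

The statistical suites run at sizes chosen to make Monte-Carlo error small
relative to the asserted tolerances while keeping the default test run fast:
200 seeds × 500 individuals for capable-fraction coverage against the
central 95 % binomial interval, 200 Poisson replicates for
depth-integration unbiasedness (asserted within 2 %), and 1 000 random draws
for the inversion and chained-oracle checks.

## Known limitations

- The activation energy and base temperature are assumptions; both are
  logged prominently in every pipeline run. Results for absolute durations
  shift with $E$; the capability *ordering* of individuals does not.
- The max-lipid allometry defaults are plausibility-scaled, not fitted;
  studies with access to a fitted relation should supply it.
- The capable fraction is estimated from small assessed subsamples
  (~10 per stratum in field practice); its binomial uncertainty dominates
  the uncertainty of capable abundance and is reported as `n_capable` /
  `n_assessed` so users can propagate it.
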