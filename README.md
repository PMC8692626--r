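# overwintr

Diapause-capability analysis for *Calanus finmarchicus*: from individual
biometrics and depth-stratified net catches to the abundance of copepods able
to survive the Arctic winter at depth.

## The problem

*Calanus finmarchicus* overwinters in a dormant state (diapause) at depth,
fuelled entirely by wax esters stored in its lipid sac. Whether a population
that has been advected into high-latitude waters can establish itself there
hinges on a simple energetic question: do enough individuals carry enough
lipid to respire through the winter and still retain reserves for the moult
and spring reproduction? `overwintr` implements that assessment as a tested,
reusable pipeline for anyone working with copepod body-condition data,
multinet (MOCNESS-type) catches and CTD profiles.

## The model

For each individual with lipid sac area *A* (mm²), prosome length *L* (mm)
and total body carbon *M* (µg C, from elemental analysis):

- wax-ester mass: `WE = 0.167 · A^1.42` (µg)
- lipid-reserve carbon: `w = 0.79 · WE` (µg C)
- structural (metabolically active) carbon: `m = M − w`
- diapause respiration (µg C day⁻¹), with *T* in Kelvin:

  `r = b · m^(3/4) · exp[E (T − T0) / (k T T0)] · 86 400`

  with `b = 2.5e-7 µg C^(1/4) s⁻¹`, activation energy `E = 0.65 eV`
  (configurable), Boltzmann constant `k`, and base temperature
  `T0 = 273.15 K`, so the Arrhenius factor is exactly 1 at 0 °C
- diapause duration, the time to respire the reserve down to 20 % of its
  pre-diapause mass: `D = (w − 0.2 w) / r` (days)
- an individual is **overwinter-capable** if `D ≥ 150` days.

Capability is scaled to the population through the catch data: per-stratum
counts and filtered volumes give depth-integrated abundance (ind m⁻²), the
stock below 250 m is the candidate overwintering population, and its
abundance times the capable fraction of the assessed deep subsample is the
abundance capable of successful overwintering.

A seeded synthetic-data generator emulates the whole observation system —
two-water-mass CTD profiles, stage-structured vertical distributions,
Beta-distributed lipid fullness, Poisson net catches — with analytic ground
truth, so every stage of the pipeline is testable without field data.

## Worked example

```r
library(overwintr)

cfg    <- generator_config()                      # default station archetypes
bundle <- generate_station(cfg, "S3", seed = 42)  # CTD + individuals + catch
res    <- run_pipeline(run_config(bundle$records, bundle$catch, bundle$ctd))
res$summary
#>   station deep_abundance_ind_m2 D_max_days D_min_days D_mean_days
#> 1      S3                 12288        219          6         105
#>   capable_fraction n_capable n_assessed capable_abundance_ind_m2
#> 1        0.1724138         5         29                     2119
```

Reading the output: the net catches integrate to ~12 300 CV ind m⁻² below
the 250 m cutoff; the assessed deep subsample (29 individuals) spans diapause
durations from 6 to 219 days with a mean of 105; 5 of 29 (17 %) clear the
150-day threshold, which scales to ~2 100 deep CV ind m⁻² capable of
successful overwintering. Per-individual energetics are in `res$profiles`;
rejected/infeasible records (e.g. lipid carbon exceeding measured total
carbon) are listed in `res$rejected` and never silently clamped.

A thin command-line wrapper with `generate`, `assess` and `params`
subcommands is installed at `cli/overwintr.R` inside the package directory.

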