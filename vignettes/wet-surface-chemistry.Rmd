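---
title: "Linking microbial biomass to the volatile and soluble chemistry of wet household surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking microbial biomass to the volatile and soluble chemistry of wet household surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfvoc)
```

## The problem

Periodically wet household surfaces — the inside of a kitchen sink, the
walls of a shower stall — host dense microbial communities whose
metabolism leaves a chemical footprint: volatile organic compounds (VOCs)
emitted into indoor air, and soluble compounds deposited on the surface
itself. `surfvoc` implements the quantitative chain that connects these
observations:

1. **Chamber emissions.** Small removable samplers (stainless-steel
   coupons, 0.0025 m²; ceramic tiles, 0.0023 m²) are enclosed in a 0.5-L
   jar flushed with VOC-free air at 0.25 L/min while a PTR-TOF-MS records
   per-ion concentrations at 1 Hz. After rejecting the first 5 minutes of
   transient, the steady-state mean concentration, minus the matching
   blank, times the flow rate gives each ion's emission rate; dividing by
   the sampler area gives a flux in µg/m²/h.
2. **Biomass.** qPCR gene-copy densities (16S for bacteria, ITS for
   fungi, gene copies/cm²) quantify how much microbial biomass each
   sampler carried, with explicit handling of negative-control
   subtraction and below-detection values.
3. **Yield regression.** Averaging both measurements over location-period
   groups and regressing summed VOC flux on total gene copies/m² yields a
   per-gene-copy VOC production rate (slope, reported in fg/gene copy/h)
   and a non-microbial background flux (intercept, µg/m²/h).
4. **Box model.** A single-compartment mass balance,
   $dC_{in}/dt = E/V + aC_{out} - aC_{in}$, projects fixture-scaled
   emissions to whole-house indoor concentrations; at steady state the
   source contribution is $C = E/(aV)$.
5. **Molecular networking.** MS/MS spectra of soluble extracts from
   surface samples and from cultured surface communities are clustered
   into compound nodes, linked by modified-cosine similarity, stripped of
   blank-derived nodes, and partitioned by source (culture-only,
   material-only, shared).

Every stage consumes and returns plain tibbles so the pieces compose with
the usual tidyverse verbs, and every stage can run on seeded synthetic
data, which is how the package tests itself end to end.

## Tunable parameters and their defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| steady-state rejection window | 300 | s | the chamber's nominal turnover (0.5 L at 0.25 L/min) means ~5 min to approach steady state |
| abundance filter | 1 | ppt | rejects ions at or below the detection limit |
| per-ion relative uncertainty | 30 | % | average proton-transfer rate-constant convention |
| summed-VOC relative uncertainty | 15 | % | per-ion rate-constant errors partially cancel in sums |
| molar volume | 24.45 | L/mol | 25 °C, 1 atm reference state for ppb ↔ µg/m³ |
| ∑VOC ion count | 19 | — | the most abundant ions carry ≥95% of the observed total |
| air exchange rate | 1.13 (summer), 0.61 (winter) | 1/h | median values for single-family houses |
| house volume | 160 | m³ | median single-family volume |
| sink adjustment factor | 548.8 (displays 550) | — | wetted sink area 1.372 m² / coupon area |
| shower adjustment factor | 2218.7 (displays 2200) | — | wetted stall area 5.103 m² / tile area |
| network thresholds | 0.75 cosine, 6 matched | — | standard molecular-networking edge gates |
| library thresholds | 0.70 cosine, 6 peaks | — | standard identification gates |

The "19 most abundant ions" are selected by mean flux, with ties broken
lexicographically by ion label — the selection statistic is a package
choice, made deterministic on purpose.

### Fixture geometry

The wetted-area compositions are a genuinely open design point: which
faces of a sink or stall are actually wetted is not observable from the
fixture's outer dimensions. The package uses the composition that is both
physically sensible and reproduces the familiar rounded factors: the
double-bowl sink counts bottom + two long walls + two end walls + both
faces of the central divider (1.372 m², f = 548.8 → 550 at 2 s.f.); the
shower stall counts three walls + floor, excluding the door side
(5.103 m², f = 2218.7 → 2200). Both are plain named face lists in
`fixture_geometry()`, so any other composition is one argument away.

### Below-detection policy

A qPCR value below the assay limit is carried as an explicit flag, never
as a zero or a missing value, and the policy is applied only at
aggregation time: in group averages it contributes zero while counting in
the denominator (`bd_policy = "zero"`, the convention that reproduces the
printed bathroom fungal average in the bundled table); in per-sample
bacteria:fungi ratios the pair is excluded, because a zero denominator is
undefined. The ×25 headline ratio uses the mean of per-sample ratios;
`"ratio_of_means"` is retained as an alternative because the two
statistics differ whenever fungal densities vary across samples.

### Modified cosine

Peak intensities are square-root transformed and L2-normalised (the
common networking convention; raw-intensity cosines over-weight base
peaks). Candidate fragment pairs match either directly or shifted by the
precursor mass difference; among candidates the package selects the
one-to-one assignment maximising the summed intensity product *exactly*,
by maximum-weight bipartite matching, rather than greedily. Exact
assignment costs little at these spectrum sizes, is deterministic, and
lets the tests verify the score against an exhaustive enumeration oracle;
the greedy variant is kept as `method = "greedy"` for parity with other
tools. No edge-count or component-size pruning is applied to the network:
those are tool-specific post-processing choices, omitted rather than
guessed. Consensus clustering reuses the edge cosine threshold, as no
separate clustering threshold is part of the method definition.

## What the synthetic generators emulate

`synthetic_scenario()` fixes the study conditions; the three generators
derive everything from it under a single seed.

* **Chamber series** rise from zero with a first-order time constant of
  `ramp_duration_s / 3` (a flushed 0.5-L jar at 0.25 L/min has a ~2-min
  nominal turnover) and sit exactly at the steady level implied by the
  sample's true flux once the ramp ends, plus Gaussian noise (sd = 5% of
  the steady level by default) truncated at zero, plus a constant
  background offset shared with the blanks. Holding the post-ramp mean
  exactly at the steady level is what makes the noise-free recovery
  invariant exact (≤1e-6 relative error) with the default 300-s rejection
  window. Within-run drift is deliberately absent: no drift model is part
  of the method definition, so none is invented.
* **Biomass tables** draw lognormal replicates around per-sampler truth
  values whose magnitude structure mirrors the bundled household table:
  kitchen ≫ bathroom, bacteria ≈ 25× fungi, one fungal value below
  detection. A sample's true total VOC flux is
  `voc_yield_slope × copies/m² + voc_background` (defaults 8.4e-8
  µg/copy/h and 1300 µg/m²/h, the first-period study scale), so the
  regression stage has a known truth to recover.
* **Spectrum libraries** assign each synthetic compound to culture-only,
  material-only, or shared (fractions are scenario parameters); shared
  compounds are emitted into both sources with a small intensity jitter
  chosen to keep self-similarity above the edge threshold. A fraction
  summing below one yields blank-only compounds, and a configurable slice
  of material compounds is additionally planted in blanks — both exist so
  the blank-removal rule is exercised, including the case of a compound
  seen in a real source *and* a blank (removed: presence in a blank marks
  background).

What the generators do **not** emulate — and hence what green tests do
not certify about real data: instrument drift and calibration error,
per-ion proton-transfer rate constants, retention-time structure and
adduct chemistry in LC-MS, chimeric consensus spectra, and any
correlation between a sampler's biomass and which compounds it deposits.
The generators validate the estimation chain, not the instruments.

## Numerical choices

* Negative net concentrations (sample below blank) are floored to zero
  for emission reporting — a surface is not treated as a sink — but the
  raw difference and a flag are kept for QC.
* Rounding (3 significant figures for biomass aggregates, 2 for
  adjustment factors, 1 for the fg yield range, 1 decimal for partition
  percentages) is presentation-only; all downstream computation uses full
  precision.
* The dynamic box model has a closed form; the numerical integrator
  (`deSolve`, tolerances 1e-10/1e-12) is kept as an independent route and
  agrees to well under 1e-6 µg/m³.
* OLS is unweighted (no weighting scheme is part of the method), fitted
  per period, never pooled.
* Clustering ties and edge emission are made deterministic by ordering:
  nodes by parent mass, top-ion selections by flux then label, library
  ties by matched count then name.

## Problem sizes

The default test and demo configuration uses the 17-sampler layout with
20 ions at 900 one-hertz scans per run, 60–80 soluble compounds, and 200
replicates for the slope-recovery simulation — sizes chosen so a full
pipeline run completes in a few seconds while every stage still has
non-trivial structure (blanks on both materials, a below-detection value,
shared and blank-contaminated compounds).

## Known limitations

* Ion identities are putative; isomers share a formula, so mass flux is
  insensitive to structural ambiguity, but compound-level claims are not
  supported.
* The box model is single-compartment with ventilation as the only sink:
  no sorption, deposition, multi-zone transport, or time-varying air
  exchange.
* Emission rates are treated as constant in time, temperature, and
  humidity; whole-fixture scaling assumes the sampler flux is uniform
  over the wetted area. Both make the indoor contributions lower-bound
  estimates with fixture-geometry uncertainty attached.
* The ×25 ratio and the yield regression inherit the 16S/ITS copy-number
  ambiguity of qPCR biomass proxies; no copy-number correction is
  applied.

## A worked chain

```{r example, eval = FALSE}
library(surfvoc)

res <- run_pipeline(pipeline_config(seed = 1))
res$biomass_aggregates
res$ratio
res$fits[["S1"]]
res$contribution_totals
res$partition

# or stage by stage on synthetic data
sc <- synthetic_scenario(seed = 1)
run <- gen_chamber_series(sc, "KC.1")
est <- steady_state_mean(run) |>
  abundance_filter() |>
  blank_subtract(steady_state_mean(gen_chamber_series(sc, "BLC.1.S1"))) |>
  emission_rate(run, ion_panel = sc$ion_panel)
sum_voc(est)
```
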