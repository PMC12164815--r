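---
title: "Methods: probabilistic dose and risk from arsenic in settled dust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic dose and risk from arsenic in settled dust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustrisk)
```

## The exposure model

`dustrisk` implements the USEPA residential exposure framework for a
single contaminant (arsenic) in settled dust, for a population stratified
into four biological age groups. For each group, three pathway-specific
average daily doses (mg/kg/day) are computed:

* **Ingestion**: $ADD_{ig} = \dfrac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT} \cdot CF$
* **Inhalation**: $ADD_{ih} = \dfrac{C \cdot InhR \cdot EF \cdot ED}{PEF \cdot BW \cdot AT}$
* **Dermal**: $ADD_{d} = \dfrac{C \cdot AF \cdot ABS \cdot EV \cdot EF \cdot ED \cdot CF \cdot SA}{BW \cdot AT}$

with $C$ the dust concentration (mg/kg), $IR$ the dust ingestion rate
(mg/day), $EF$ exposure frequency (d/y), $ED$ exposure duration (y), $BW$
body weight (kg), $AT$ the non-carcinogenic averaging time (days), $CF =
10^{-6}$ kg/mg, $InhR$ the inhalation rate (m³/day), $PEF$ the particle
emission factor (m³/kg), $SA$ exposed skin (cm²), $AF$ the dust-to-skin
adherence factor (mg/cm²), $ABS$ the dermal absorption fraction and $EV$
the daily event count. Every formula is linear in $C$ and inversely
proportional to $BW$ and $AT$; the carcinogenic dose is therefore obtained
by rescaling, $cADD = ADD \cdot AT / cAT$, which is exactly equivalent to
substituting the lifetime averaging time $cAT$ into the pathway formula.

Non-carcinogenic hazard is $HQ = ADD/RfD$ per pathway and $HI = \sum HQ$;
values above 1 flag potential risk. Carcinogenic risk uses the slope
factor $SF$; the package supports two conventions (see below) and sums
pathways into $aCR$, compared against the $10^{-5}$ criterion.

## Default study conditions

`default_araro_config()` encodes the conditions of a 40-sample dust survey
of the Araró geothermal community: dust arsenic mean 15.6 mg/kg, SD 5.94,
observed range 5.94–42.53 mg/kg; EF 350 d/y; group-specific ED (3.51,
8.82, 15.88, 42.94 y), AT (1,229; 3,087; 5,558; 15,029 d — each equal to
ED × EF within a day), body weights (means 16.31, 33.8, 60.91, 72.67 kg
with reported ranges), intake rates (100, 100, 30, 30 mg/day), inhalation
rates (9.5, 12, 15.75, 14.67 m³/day), skin areas (760; 1,080; 1,840;
1,935 cm²), AF 0.5, ABS 0.03, PEF 1.36 × 10⁹; oral RfD 3 × 10⁻⁴
mg/kg/day and SF 1.5 (mg/kg/day)⁻¹.

Design choices where the source tables were silent or ambiguous:

* **Concentration mean 15.6 vs 15.21.** The parameter table lists 15.6 as
  the simulated average while the survey's descriptive statistics report
  15.21 ± 5.94 (median 12.33). The default uses 15.6 — the value the
  parameter registry says drove the simulation — with the SD 5.94; either
  is accepted through the configuration file.
* **Lifetime averaging time.** cAT is not tabulated; the default is the
  70-year residential lifetime, 70 × 365 = 25,550 days. This value makes
  the tabulated oral cancer risks follow arithmetically from the tabulated
  oral doses (e.g. (1.05 × 10⁻⁴ × 1,229/25,550)/1.5 = 3.37 × 10⁻⁶ against
  a printed 3.36 × 10⁻⁶).
* **Event frequency.** EV appears in the dermal formula but not the
  parameter table; the standard residential default of 1 event/day is
  used, configurable.
* **Dermal contact factor.** The tabulated DFS = 362.4 mg·y/kg/day is
  carried as inert metadata: no dose formula in the framework consumes it.
* **Cancer-risk convention.** The source's formula table defines
  $CR = cADD/SF$, and its cancer-risk tables numerically confirm the
  division. The package defaults to this `printed` convention so those
  tables reproduce; the conventional USEPA product $cADD \times SF$ is the
  `standard` option. For arsenic's SF of 1.5 the two differ by a factor
  2.25.
* **Reference doses.** Oral and dermal hazard quotients divide by the oral
  RfD 3 × 10⁻⁴ mg/kg/day: the tabulated dermal HQ medians equal the dermal
  dose medians divided by exactly that value, so it is what was computed,
  while the dermal value 1.23 × 10⁻⁴ serves only as the dose screening
  limit. The inhalation hazard quotient divides by the arsenic inhalation
  reference dose 1.5 × 10⁻⁵ mg/kg/day: the four tabulated inhalation HQ
  means (0.0005, 0.0003, 0.0002, 0.0002) equal the inhalation doses
  divided by 1.5 × 10⁻⁵ to printed precision, and are a factor ~20 away
  from division by 3 × 10⁻⁴. Inhalation dose *screening* keeps the
  3 × 10⁻⁴ limit shown in the dose tables. All denominators are
  configurable in `tox_criteria()`.

## Distributions and the Monte Carlo engine

Only the two inputs identified as population-sensitive are random: dust
concentration and body weight. All other factors are constants (a
deliberate mirror of the study design; the sampling layer is a hook for
richer error models later).

* **Concentration**: lognormal by method of moments,
  $\sigma^2 = \ln(1 + (sd/mean)^2)$, $\mu = \ln(mean) - \sigma^2/2$,
  truncated to the observed range [5.94, 42.53] mg/kg.
* **Body weight**: only a mean and a population range are reported, so the
  range is read as the central 99% interval of the untruncated lognormal:
  $\sigma = (\ln hi - \ln lo)/(2 z_{0.995})$, with $\mu$ set to match the
  arithmetic mean; draws are truncated to the range. The 99% coverage
  reading treats the reported extremes as near-extremes of the population;
  it is configurable (`bw_coverage`), and widening the assumed coverage
  tightens $\sigma$.

Truncation uses rejection sampling with redraws (the acceptance rate under
the default conditions exceeds 94%, so a bounded retry loop is safe; a
truncation window with near-zero mass raises an error rather than
looping). Each age group draws `n_iterations` paired (C, BW) scenarios;
the three pathway doses, quotients and risks are evaluated on the same
draws, so HI and aCR are within-scenario sums — required for their
distributions and exceedance fractions to be meaningful. Summaries report
mean, SD, median, min, max, P95 and P97 (linear-interpolation percentiles,
R type 7) plus exceedance fractions against the pathway screening limits,
the HQ limit 1 and the CR limit 10⁻⁵.

Defaults: 10,000 iterations (the study's scenario count; a full four-group
run takes well under a second), seed 20180000 (an arbitrary fixed default;
any seed is accepted and all randomness flows through it). Identical
configuration and seed give bit-identical results.

Expected behaviour of the propagation, verified by the test suite: the
simulated median of each dose factorizes as $k \cdot \mathrm{med}(C) /
\mathrm{med}(BW)$ within Monte Carlo error; the simulated mean exceeds the
dose at the mean inputs (Jensen's inequality applied to $1/BW$); and with
both distributions degenerate the simulation collapses exactly to the
deterministic point estimate.

## Sensitivity attribution

`sensitivity_contributions()` attributes output variance to the varying
inputs via squared Spearman rank correlations normalized to sum to one —
the convention used by commercial risk add-ins. With only concentration
and body weight random, concentration dominates under the default
conditions (larger log-scale spread). The operation is generic over the
configured distributions; no published percentages are asserted because
the study quotes them from prior work.

## Survey design and the synthetic generator

`required_sample_count()` implements the Mexican norm's
$n = 2.26 \cdot A^{0.31}$ with truncation to an integer — the only
rounding consistent with the study's 40 samples from 11,400 ha (the
formula yields 40.90). `summarize_survey()` reports descriptive statistics
and the fraction of samples strictly above a regulatory threshold
(default 22 mg/kg). Below-LOD records are substituted at LOD/2 by default
(`lod` and `drop` policies available); the default is exercised only on
synthetic data, as the source survey reported none.

`generate_dust_survey()` emulates a campaign: truth from a lognormal
field, measured value = truth × recovery × mean-one multiplicative
lognormal noise with the instrument's repeatability CV (defaults: CV
0.75%, recovery 117%, LOD 4 mg/kg — the portable-XRF quality-control
constants). The instrument constants are the only anchor for the error
model, so the simplest multiplicative model consistent with them is used;
whether reported concentrations were recovery-corrected is not stated, so
correction is available behind `correct_recovery`. The generator does not
model spatial autocorrelation, sieving physics, or non-lognormal
contamination hot spots — passing tests therefore show pipeline
correctness under the assumed statistical structure, not fidelity to any
particular real site.

## Problem sizes and numerical tolerances

The test suite runs the full 10,000-iteration simulation for table-level
comparisons, 10⁵–10⁶ draws for distribution-recovery and closed-form
oracle checks (1–2% tolerances), and bootstrap standard errors (200
resamples) for median-factorization checks at 3 SE. Simulated medians are
compared with the published cells at ±20%: the study's seed, truncation
choices and body-weight spread are unpublished, so agreement is expected
only to stochastic tolerance. Under the defaults the simulated oral and
inhalation statistics land within ~5% of the published cells.

## Known limitations

* The published dermal dose values are not reproducible from the stated
  dermal formula and tabulated parameters under any single constant
  factor (the discrepancy ratio varies ~1.5–8 across age groups); the
  package computes the formula faithfully and treats the published dermal
  cells, and any aggregate that depends on them (HI including dermal, the
  preschooler "sum" P97), as non-reproducible rather than calibrating
  hidden factors to match them.
* The published inhalation cancer risks are likewise inconsistent with
  applying the oral slope factor (~8× smaller); the slope factor actually
  used is unstated, so a single configurable SF is applied to all
  pathways.
* The published 13.51% regulatory exceedance is not an integer fraction
  of 40 samples; its denominator is unclear, so it is checked only
  qualitatively against the fitted lognormal tail (~12%).
* One contaminant, one exposure medium, no bioaccessibility adjustment,
  no 2-D variability × uncertainty simulation, no Latin hypercube
  sampling.
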