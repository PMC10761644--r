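---
title: "Methods: compound heatwave-drought exposure, spatial scan clusters, and community determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compound heatwave-drought exposure, spatial scan clusters, and community determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohaz)
```

`cohaz` implements a county-scale epidemiological workflow for studying how
heatwaves, droughts, and their co-occurrence relate to psychiatric emergency
department (ED) visits in young people, and which household or community
characteristics mark the places where that burden clusters. The pipeline has
four statistical stages — exposure construction, Bernoulli spatial scanning,
interaction analysis, and MARS variable ranking — plus a synthetic-data
generator that plants known structure so every stage can be validated without
access to restricted health records.

## Exposure construction

**Heatwaves.** The daily mean temperature climatology is summarised per
county by day-of-year percentile thresholds: for each calendar day the 90th
(and 95th) percentile of all temperatures in a centred 31-day window, pooled
over the climatology years (the May 1 threshold pools Apr 15 - May 15 of
every year). Feb 29 is dropped before indexing so the window is cyclic over
exactly 365 positions, and percentiles interpolate linearly between order
statistics (`quantile` type 7) so thresholds are bit-reproducible. A heatwave
event starts on the first of 3 consecutive days strictly above the 90th
percentile and ends on the last above-threshold day followed by 3 consecutive
days at or below it (or by the series end); days inside the event that dip
below the threshold still count as heatwave days. Exceedance is strict:
a temperature exactly at the threshold does not count. By construction about
10% of climatology days exceed their own `t90`; the test suite re-validates
every detected event with an independent run-length re-scan of the raw
series.

One subtlety is worth recording. With a noise-free seasonal cycle the days at
the very top of the annual cycle are the maxima of their own 31-day windows,
so they exceed the window's 90th percentile and yield one short "heatwave"
per year hugging mid July. This is a property of the day-of-year percentile
definition itself, not of the detector; the tests assert it rather than
pretending a pure sinusoid has no events.

**EHF intensity.** For the high-intensity sensitivity definition, the excess
heat factor on day $i$ is
$\mathrm{EHF}_i = \mathrm{EHI}^{sig}_i \times \max(1, \mathrm{EHI}^{accl}_i)$,
where $\mathrm{EHI}^{sig}_i$ is the forward three-day mean (days
$i, i{+}1, i{+}2$) minus the day-of-year 95th percentile and
$\mathrm{EHI}^{accl}_i$ is the same three-day mean minus the mean of the 30
preceding days (units: degC and degC squared). An event is high intensity
when any of its days reaches the county's severity threshold, the 85th
percentile of positive climatology EHF values; the boundary counts
(`ehf >= threshold`), and a county with no positive climatology EHF keeps all
its events low-intensity.

**Droughts.** Weekly drought-monitor categories (None, D0 to D4) define
episodes: an episode starts the first week at D1 (moderate) or worse and ends
at the last such week followed by 3 consecutive weeks below D1, with every
day of every episode week flagged as a drought day. One- or two-week dips
below D1 stay inside the episode, mirroring the heatwave end rule.

**Compound days** are the cell-wise conjunction: a county-day is compound
when it is both a heatwave day and a drought day. Event-level bookkeeping
pairs each heatwave event with every drought episode it overlaps, so two
heatwaves inside one long drought are two separate compound events.

## Bernoulli spatial scan

Visits are aggregated per county into cases (visits on days carrying the
hazard flag) and controls (all other warm-season visits). The scan maximises
the Bernoulli log-likelihood ratio over a family of elliptical windows: for
every centre county, axis ratio in {1, 1.5, 2, 3, 4, 5} and
{1, 4, 6, 9, 12, 15} orientations respectively, counties are ordered by
elliptic distance and nested windows grown while the window holds at most 25%
of the total observations (a flag switches the cap to total cases, the
literal reading of "up to 25% of the total cases"; capping the population at
risk is the scanning convention and the default). For a window with $c$ of
$n$ observations as cases against totals $C$ of $N$, the one-sided LLR is the
usual two-binomial expression, zero whenever the inside rate does not exceed
the outside rate.

Inference is by Monte Carlo permutation: each of 999 replicates redistributes
the $C$ case labels uniformly over the $N$ fixed observations (a multivariate
hypergeometric draw over counties), and the p-value is
$(1 + \#\{\text{replicate max} \ge \text{observed}\})/(1 + 999)$, so the
smallest attainable p is 0.001. Reported clusters are the ranked
non-overlapping local maxima; member counties whose single-county relative
risk falls below 1 are pruned afterwards, with the cluster's cases, size and
RR recomputed but its LLR and p-value left untouched — pruning trims
non-elevated neighbours, it does not re-test. Cluster RR is
$(c/E)\,/\,((C-c)/(C-E))$ with $E = nC/N$. Ties between equal-LLR windows
break deterministically (smaller window, then centre id).

## Interaction measures

With RR$_{10}$ (heatwave alone), RR$_{01}$ (drought alone) and RR$_{11}$
(compound) taken from the primary clusters of the three scans for one
outcome:

* RERI $=$ RR$_{11}$ $-$ RR$_{10}$ $-$ RR$_{01}$ $+ 1$ (0 under exact
  additivity);
* synergy index $S = (\mathrm{RR}_{11}-1) / ((\mathrm{RR}_{10}-1) +
  (\mathrm{RR}_{01}-1))$ (1 under additivity; undefined and flagged when the
  denominator is zero);
* multiplicative ratio $= \mathrm{RR}_{11}/(\mathrm{RR}_{10}\cdot
  \mathrm{RR}_{01})$ (1 under exact multiplicativity).

When any hazard scan lacks a significant finite primary-cluster RR the
pipeline emits an explicit not-estimable record rather than a silent gap.
Confidence intervals for these measures are out of scope.

## Community covariates and MARS ranking

The covariate table carries county proportions (education, vehicle access,
overcrowding at more than 1.5 occupants per room, ages 65+, English
proficiency, health coverage, broadband, vacancy rates, veterans, Hispanic or
Latino population), housing-unit counts, greenspace per person (green area
divided by population, m2/person), and residential segregation as the Index
of Concentration at the Extremes, $(A - P)/T$ for advantaged/deprived/total
counts, in $[-1, 1]$. The ICE inputs are taken as pre-tabulated counts; which
census variables define the extremes is a data-preparation question outside
the package.

County outcome counts within the high-risk cluster counties are then
modelled with multivariate adaptive regression splines under a Poisson
lack-of-fit. The forward pass greedily adds the reflected hinge pair
$\{\max(0, x_v - t), \max(0, t - x_v)\}$ (knots at observed predictor values,
no interaction terms: the model is additive) that most reduces the Poisson
deviance, up to `max_terms` (default 21) or until the relative improvement
drops below `tol` (default 1e-4). Backward pruning walks the elimination path
and keeps the subset minimising
$\mathrm{GCV} = \mathrm{deviance} / (n (1 - M_{\mathrm{eff}}/n)^2)$ with
$M_{\mathrm{eff}} = M + d\,(M-1)/2$ and penalty $d = 2$ (the usual additive
value; configurable). GCV R-square is $1 - \mathrm{GCV}/\mathrm{GCV}_0$
against the intercept-only model. Variable importance drops all of a
variable's hinges, refits, and rescales the GCV increases so the top variable
scores 100; a `bases` column counts hinges per variable.

Two honest caveats. First, greedy knot selection consumes more effective
degrees of freedom than the per-term GCV charge, so on pure noise the pruned
model is not always the bare intercept: across seeded noise replicates about
half retain a hinge or two, though their GCV R-square stays small (measured
below 0.25, versus above 0.7 for planted signals). A heavier penalty prunes
harder and is available. Second, with 9 or more cluster counties the rows are
partitioned into seeded near-equal thirds (train/test/validation); term
selection uses the training third and the held-out thirds only report
out-of-sample deviance — how the thirds interact with selection is a design
choice, and with very few counties the model fits on all rows and says so.

## The synthetic study region

The generator emulates all five inputs on a planar lattice (default: 20
counties, 30 km spacing, 20 climatology years 2000-2019, analysis years
2016-2019, May-September season):

* **Temperature** is a seasonal sinusoid (annual mean 20 degC, half-range
  8 degC, peak in mid July) plus one *regional* AR(1) anomaly
  ($\rho = 0.7$, innovation sd 2 degC) and Poisson-many regional hot spells
  per season (+6 degC for 5 days), shared by all counties, plus optional
  per-county AR(1) noise (`local_noise_sd_c`, default 0). The regional/local
  split is deliberate: heat events are synoptic in scale, and the Bernoulli
  scan's null hypothesis — that a visit's case status is exchangeable across
  counties — only holds when counties share event days. With independent
  county weather each county has a different fraction of event days, the
  per-visit case probability varies spatially, and null scans reject far too
  often (we measured a 0.32 rejection rate at nominal 0.05 with fully
  independent noise, and 0.28 even at 0.5 degC of local noise, against 0.05
  for the scan machinery itself under an exactly homogeneous null). Users who
  turn `local_noise_sd_c` up should expect anti-conservative null behaviour:
  that is a property of the case/control design under spatially heterogeneous
  exposure, not of the scan implementation.
* **Drought categories** follow a first-order Markov chain per county over
  None, D0..D4 with a documented default kernel whose stationary law puts
  most mass on None/D0 and produces multi-week episodes a few times per
  4-year window.
* **Visits** are Poisson per county-day and outcome at
  `baseline_visit_rate` (default 0.5), multiplied by `planted_rr` (default
  3) on days carrying the planted hazard's flag in the planted counties
  (default: a compact 2x2 lattice block of 4). Binarisation into
  cases/controls happens only at scan aggregation.
* **Covariates** follow truncated-normal marginals at county-realistic
  levels, log-normal housing and greenspace, and an ICE value from simulated
  counts; `covariate_effects` shifts chosen covariate means in planted
  counties (zero shift leaves planted counties exchangeable).

What the generator does not emulate: real geography and population weights,
partially correlated spatial fields, seasonality in visit rates, outcome
miscoding, or county-scale reporting artefacts. Passing tests on this
synthetic region therefore validate the algorithms and their inferential
calibration under clean exchangeability assumptions — they do not establish
that any particular real-data cluster is correct.

## Problem sizes and numerical choices

The validation suite runs the whole machinery at deliberately modest sizes
chosen to exercise every code path: 999-permutation scans over a 20-county
region (about 60 cases for the null-calibration study, 200 replicates;
50 replicates for planted-cluster recovery at RR 3 and baseline 0.5); MARS
recovery with 2 planted and 12 noise covariates at 100 counties over 20
replicates; and exhaustive LLR checks for all count configurations with
window sizes up to 12 of 24 observations. Degenerate inputs are handled
explicitly: gaps in a temperature series count as below-threshold days
(logged), counties with no positive climatology EHF keep events
low-intensity, a hazard with no cases yields an explicit "no cases" scan
record, pruning that empties a cluster drops it with a warning, and constant
predictors are skipped by the forward pass. All randomness flows from
explicit seeds; every generator is a pure function of its configuration.
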