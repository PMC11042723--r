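---
title: "Methods: COTS outbreak surveillance, intervention classification, and comparative inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COTS outbreak surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cotswatch)
```

This vignette is the package's own account of its methods: the data model,
the outbreak and management definitions it operationalises, the statistical
models and their numerical details, what the synthetic reefscape does and
does not emulate, and the design decisions taken where more than one
reasonable reading existed.

## 1. Data model

The observational unit is the two-minute manta tow: an observer towed around
a reef perimeter records, per ~200 m × 10 m swath (~2000 m²), an ordinal
hard-coral cover category (0–5) and a count of COTS. Three survey programs
contribute tows (a long-term monitoring program plus two management-program
sources); culling logs record diver bottom-hours per reef and year; a
registry maps each reef to exactly one latitudinal sector, orders sectors
along the outbreak wave path, and flags sectors whose outbreak inception is
judged against the established rather than the potential threshold.

Validation is deliberately strict: rows with an invalid cover category or a
missing numeric field are rejected (and logged), while unknown reefs and
duplicated tow keys abort the read — the former is a bad record, the latter a
corrupted extract. Missing values are never imputed at the record level;
monitoring data should be explicit.

When several programs survey the same reef in the same year, the
representative density is the **maximum of the per-program means**.
Management-program surveys precede cull operations, so the largest mean is
the estimate least biased by removals; the winning program is recorded.

## 2. Outbreak windows

Thresholds (COTS/tow): potential 0.11, established 0.22, severe 1.0. The
lower two are strict exceedances (`>`); density exactly at a threshold does
not count, matching the operational phrasing of the ladder. The severe
boundary is inclusive, matching its "1 COTS/tow" labelling. The ladder is
configurable via `threshold_config()`.

A sector-wide outbreak requires (i) *inception*: density above the inception
threshold for at least `persistence_years = 2` **consecutive** years — the
source definition says "multiple years (≥2)" without "consecutive"; we chose
the consecutive reading as the stricter, testable one; and (ii) *escalation*:
density above the established threshold at or after inception. The window
start additionally includes one year prior to the potential-threshold
crossing. We key that crossing to the consecutive run of above-potential
years that *contains* the inception year, not to the first crossing anywhere
in the series: an isolated early blip would otherwise anchor the window years
before the outbreak (and possibly before the observed series), contradicting
the intent of capturing "the beginning phase of rapid population growth".

The outbreak ends at the first run of `decline_years = 2` consecutive years
below the potential threshold after escalation. Whether those closing
sub-threshold years sit inside or outside the window is genuinely ambiguous
in the source definitions; we include them by default and expose
`include_decline_years` as a switch. Without a decline the window is flagged
`ongoing` and runs to the last observed year.

Sector series use the unweighted mean of reef means (a tow-weighted mean is
available via `weight_by_tows`, off by default). Interior missing years are
linearly interpolated and flagged `imputed`; leading and trailing gaps are
never extrapolated. The detector is checked against an independent
enumeration oracle (literal year-by-year criterion scans) on 10,000 random
series and obeys a monotonicity property: raising all densities never delays
inception.

## 3. Management actions and effort strata

The action taxonomy mixes timing and outcome language; the package's
operational contract is:

* `NoAction` — zero culling hours (and only then);
* `Proactive` — culling starts before the sector ever crosses the potential
  threshold;
* `Timely` — culling starts at/after the crossing and *suppression* is
  achieved;
* `Reactive` — culling starts before severe densities, suppression fails;
* `Limited` — the rest (start at/after severe densities, or failure with
  marginal effort).

Suppression is two-part: after the culling start, density must sit below the
potential threshold for ≥ 2 consecutive years, **and** sector cover at the
end of the assessment window must be at least `1 - depletion_fraction`
(default 75%) of its start value. The second clause separates management
suppression from prey depletion — an outbreak that ends because the coral is
gone also ends with low densities. The full criterion trace is recorded in a
`rationale` column for audit.

Effort stratification standardises hours by outbreak severity:
`effort_ratio = hours / max density` (h per COTS/tow) over the sector's
outbreak window. Reefs below `reef_outbreak_threshold` are the NoOutbreak
control group. The median ratio is computed over outbreak reefs **with**
effort (including zero-effort reefs would drag the median toward zero and
merge the strata — the source is silent on this; we flag it as an
interpretation). Ties at the median go to AboveMedian, deterministically.
The source uses 0.1 COTS/tow in its effort analysis where the outbreak
ladder uses 0.11; we default the reef-level cut to 0.11 with a config
override. Effort shares are percentages of the summed sector hours, rounded
half-up to one decimal (the seven published hour totals imply 38.0% for the
largest campaign where 37.9% was printed; we reproduce the arithmetic).

## 4. Cover metrics

Categories map to bin midpoints (proportions 0, 0.055, 0.205, 0.405, 0.63,
0.88 for bins {0}, (0,10], (10,30], (30,50], (50,75], (75,100] percent), per
the standard manta-tow protocol; the scheme is configurable. Reef-year cover
is the raw tow-midpoint mean — the source is ambiguous about whether
reef-level change metrics use raw or model-smoothed covers; we default to
raw and reserve the model-based estimate for sector summaries. *Relative
change* is percent of baseline; *annual absolute change* is percentage
points per year — only this pairing makes the published per-wave and
per-year figures mutually consistent. Both are exact arithmetic. Trajectory
alignment anchors each reef at the window start year (nearest prior survey
if missing, else the first in-window survey, with the baseline year
recorded) and follows relative change for up to six years; reefs with fewer
than three in-window surveys are flagged and excluded from smoothing.

## 5. Statistical models

All Bayesian models run 3 chains × 4000 iterations with the first 1000
discarded and the remainder thinned by 5 (1800 retained draws), the protocol
fixed by `model_spec()`. Sampling is via JAGS (rjags) with per-chain seeds
derived from the user seed, so summaries are bit-identical across reruns;
the block-updating `glm` module is loaded for the linear hierarchies.
Priors are weakly informative and declared, not inferred: normal(0, 2.5) on
fixed effects of standardized responses, half-normal(1) on random-effect and
residual SDs, gamma(2, 0.1) on the beta dispersion. Half-normal SD priors
are truncated below at 1e-4 as a numerical guard (degenerate zero-variance
data otherwise collapse the precision). Summaries report the posterior
median, central 66% and 90% quantile intervals, the probability of
direction, and rhat; `strict` mode aborts when a reported estimand has
rhat ≥ 1.01. Convergence gates on the reported estimands plus the residual
SD; random-effect SDs (slow mixers when the grouping factor has few levels)
carry their own rhat in the diagnostics without gating, with a note in each
fit object.

**Sector cover.** Per sector, tow midpoints follow a beta likelihood with a
logit-linear predictor: categorical year effects, a reef random intercept,
and a tow-level (observation) random intercept — tows are replicates, not
re-identified across years. Midpoints are compressed off the closed boundary
by `y' = (y(n-1) + 0.5)/n` (category 0 is otherwise inadmissible). The
variance split between the tow-level SD and the beta dispersion is weakly
identified in this family — both absorb overdispersion — so the reported
estimand is the posterior *fitted year mean* (the average of tow-level
expected covers for the year), which is well identified; convergence gates
on those estimands while the nuisance variance components carry their own
rhat in the diagnostics with this caveat noted.

**Wave comparison.** Per-reef responses (mean outbreak-year density, or
relative cover change over the window) with sector × wave cell means —
equivalent to main effects plus interaction — and reef intercepts shared
across waves (the crossed reading; the source doesn't state whether reef
effects were crossed or nested). Only reefs that ever exceeded the potential
threshold enter, the filter rule the source states (its n = 95 is
data-dependent). The density family is unstated in the source; we default to
Gaussian on log(d + 0.01) with back-transformed summaries, the 0.01 offset
admitting zero densities at a scale an order below the smallest threshold.
Sectors observed in one wave get a cell but no contrast, with a note.

**Effort strata.** Annual cover change (pp/yr) with category cell means and
a sector random intercept, Gaussian response.

**Trajectories.** A Gaussian GAM with a penalized cubic regression spline
("cubic spine" in the source read as the obvious typo), basis dimension
k = 4 (at most 4 knots), fitted per sector or per action via mgcv, evaluated
with 95% bands on the annual grid 0..6 (truncated for shorter windows).
Groups need ≥ 5 points and ≥ 3 distinct years.

## 6. The synthetic reefscape

The simulator generates the statistical structure the analysis assumes, so
every downstream stage is testable without restricted monitoring data. Per
reef and year (annual step — the analysis is annual):

* cover follows `c' = c + r c (1 - c/K) - p d c - m c` with logistic growth
  `r = 0.067`, carrying capacity `K = 0.8` (about +1 percentage point per
  year at moderate cover, matching the observed growth rate on non-outbreak
  reefs), predation coefficient `p = 0.12` per (COTS/tow)·year, and episodic
  disturbance mortality `m` from a schedule;
* density follows a wave: seeded at 0.08 COTS/tow in sector 1 at its onset
  year, multiplied by 2.8 annually up to a cap of 3, propagating to sector
  *s* with a 2-year lag per position, and collapsing (×0.1 per year) once
  cover falls below 0.08 — prey depletion ends outbreaks that management
  does not;
* culling, applied before predation, removes `0.5 × hours/100` density
  (surveys precede culls, so observed densities are pre-cull); linear
  dose–response is the simplest testable contract since the source gives
  none;
* observation: 10 tows per reef-year, Poisson counts with mean
  `detection_scale × density`, cover binned after additive observer noise
  (SD 0.03, truncated to [0, 1]); per-reef lognormal density multipliers
  (log-SD 0.2) give between-reef heterogeneity.

The wave constants were chosen together so that the crossing-year density
(~0.22) sits decisively above the potential threshold relative to Poisson
sampling error at 100 tows per sector-year — threshold crossings are then
detected in the right year with high probability, which is what makes the
scenario presets separable. The four presets encode management signatures
relative to each sector's *simulated* crossings: proactive culls from wave
onset (before any crossing), timely from the crossing year with sufficient
hours (100 h/reef/yr × 4 yr), reactive a year late with insufficient hours
(15 h/reef/yr), limited only from the severe crossing with under 10% of the
timely total (5 h/reef/yr).

What the simulator does **not** emulate: larval connectivity between reefs,
hydrodynamic wave spread, spatially explicit tow paths, observer-specific
biases, genus-level coral composition, or disturbance attribution. Passing
recovery tests therefore show the pipeline correctly inverts its own
generative assumptions at realistic magnitudes — not that those assumptions
hold on any particular reef system. All rate constants are calibration
knobs, not estimates of Great Barrier Reef parameters.

## 7. Verification design and problem sizes

The test suite checks, at sizes chosen to keep a full run in minutes on one
CPU:

* the outbreak detector against an independent enumeration oracle on 10,000
  random series of length ≤ 12, plus monotonicity (500 series) and
  truth-window overlap (Jaccard ≥ 0.6 in ≥ 9/10 seeds on the default
  4-sector × 10-reef × 15-year scenario);
* effort-model recovery of category means (+1.1, +0.54, −1.6, −3.6 pp/yr)
  at 25 reefs per category with within-category SD 1.2 — sized a priori so
  the closest pair of means sits ~1.6 SEs apart, giving high power for the
  rank-order check;
* wave-model recovery of a simulated 7-fold density drop within [5, 9] at
  30 reefs per sector, two sectors;
* sector-cover interval coverage ≥ 80% across 20 seeds of a
  5-reef × 4-year × 6-tow sector. The truth is defined on the protocol
  scale — the expected *bin midpoint* of the beta observation, not the
  latent mean — because categorical recording is part of the estimand the
  model can see; checking the latent mean instead penalises the model for
  the binning bias shared by any midpoint-based analysis;
* scenario-label recovery (modal sector label) in ≥ 9/10 seeds per preset;
* byte-identical reruns of the simulator, the pipeline bundle, and all
  MCMC summaries under a fixed seed.

## 8. Known limitations

Interpolated sector-years feed the window detector with synthetic densities;
they are flagged, but the detector does not discount them. The suppression
test compares cover at two time points and can be fooled by offsetting
disturbance and recovery within the window. The beta model's tow-level
SD / dispersion split should not be interpreted, only the fitted means. The
wave comparison assumes a common residual variance across sectors and waves.
Fold changes are ratios of posterior medians, not medians of ratio draws
(both are reported for contrasts). The CLI is a thin wrapper; the R
functions are the supported interface.
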