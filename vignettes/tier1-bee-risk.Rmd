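---
title: "Methods: screening-level pollinator risk assessment for spray adjuvants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening-level pollinator risk assessment for spray adjuvants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beescreen)
```

## The assessment model

Regulatory screening (tier 1) of a sprayed chemical's risk to honey bees
compares exposure estimates against laboratory toxicity endpoints as risk
quotients (RQs),

$$\mathrm{RQ_{acute}} = \frac{\mathrm{EEC}}{\mathrm{LD_{50}}}, \qquad
  \mathrm{RQ_{chronic}} = \frac{\mathrm{EEC}}{\mathrm{NOED}},$$

screened against levels of concern (LOC) of 0.4 (acute) and 1.0 (chronic).
An RQ below its LOC ends the assessment; nothing above tier 1 is modelled
here. `beescreen` applies this framework to spray adjuvants — specifically
three trisiloxane polyether surfactants — which sit outside routine
pesticide review even though they are co-applied at label rates.

Exposure is resolved by caste, because castes eat different things in
different amounts. A caste's daily dietary dose (µg/bee/day) is

$$D = \sum_{m \in \{\text{nectar, pollen, jelly}\}} \frac{C_m\,[\text{mg/kg}] \times I_m\,[\text{mg/day}]}{1000},$$

and the acute contact dose is the application rate (lb a.i./acre) times a
contact unit dose. Matrix concentrations $C_m$ come from one of two modes:

* **Default residue-unit-dose mode.** $C_{\text{nectar}} = C_{\text{pollen}}
  = \mathrm{RUD} \times \text{rate}$, with the RUD default of 110 mg/kg per
  lb a.i./acre — the upper-bound tall-grass residue of the Kenaga
  nomogram used by the regulatory exposure model.
* **Empirical mode.** Peak measured residues from a field study feed
  $C_m$ directly; the contact route still uses the application rate.

The reported adult RQ is the maximum over in-scope adult worker castes; the
larval RQ uses the 5-day-old worker larva. Under equal nectar and pollen
concentrations the nectar forager (292 mg nectar/day) governs; when the
pollen concentration exceeds the nectar concentration by more than
$(292-140)/(9.6-0.041) \approx 15.9$-fold, the nurse caste (140 mg nectar,
9.6 mg pollen) takes over — exactly what happens when field residues
(pollen-dominated) replace the default equal-concentration assumption. The
queen's jelly-only diet is computed but kept out of the reported maxima:
with jelly pegged at the 110-ppm default it would implausibly dominate,
and measured jelly-surrogate residues are far below nectar and pollen.

### Pinned constants

| Constant | Value | Why |
|---|---|---|
| RUD | 110 mg/kg per lb a.i./acre | tier-1 default for nectar and pollen |
| Contact unit dose | 2.7 µg/bee per lb a.i./acre | tier-1 default; consistent to <1% with back-calculation from three independent published contact RQs |
| Unit conversion | 0.892179 lb/acre per kg/ha | exact mass/area conversion |
| Caste consumptions | forager 292/0.041, nurse 140/9.6, larva 120/3.6 mg/day | public tier-1 model workbook |
| LOCs | 0.4 acute, 1.0 chronic | regulatory guidance |

Internal arithmetic is full precision; presentation rounds dietary RQs to
2 significant figures and contact RQs to 3 (`format_rq_report()`). Because
published input rates are themselves rounded to 3 significant figures,
reproduction of published cells is expected only to within one unit in the
last printed digit, and that is the tolerance the package's acceptance
tests use. Two published cells (one larval chronic cell, and the dietary
cells of one chemical in empirical mode printed as "<0.001") are not
reproducible from the published inputs under any caste choice; the package
reports its computed values rather than forcing agreement.

## Use-report cleaning

Raw registry extracts of monthly adjuvant applications contain entry and
transcription errors. Cleaning proceeds per chemical (crops pooled;
per-crop grouping is available behind `group_by`):

1. harmonize units to kg/ha, dropping and counting unparseable rows;
2. remove rates strictly above the IQR fence $Q_3 + 1.5\,(Q_3-Q_1)$;
3. review the remainder and remove rates strictly greater than 10 times
   the highest commercial label rate ("more than one order of magnitude");
4. select the exposure rate: maximum over neat-product records when any
   exist, else the 90th percentile of all records.

Quantiles use linear interpolation (type 7) — the estimator is a
documented parameter because no single convention is canonical in
use-report practice.

## Residue-study reduction

Replicate concentrations per matrix and sampling day reduce to three
exposure inputs: the pollen-group peak (forager pollen and bee bread), the
nectar-group peak (forager and stored nectar), and the larvae peak as a
royal-jelly surrogate. Peaks are maxima over non-censored values across
all days. A fully censored group takes the matrix limit of quantitation
(LOQ) — the conservative default; `mdl`, `half_loq` and `zero` rules are
provided for sensitivity analysis and are never allowed to exceed the LOQ.
Control-plot samples must be fully censored (a warning flags anything
else) and are excluded, as are matrices invalidated by storage instability
and matrices with no dietary route (wax, whole bees).

## Endpoint statistics

**Trimmed Spearman–Kärber LD50.** Observed mortality proportions are
monotonized by weighted pool-adjacent-violators; the empirical tolerance
distribution on $\log_{10}$ dose, extended one dose-spacing beyond each
end when it does not reach 0 or 1, is optionally trimmed symmetrically,
and the LD50 is the mean log dose over the (re-normalized) distribution.
With two doses spanning 0% and 100% mortality this collapses to the
geometric mean of the doses. The variance is a delta-method estimate — a
numeric gradient of the whole monotonize–trim–average pipeline with
binomial variances $p(1-p)/(n-1)$ at the adjusted proportions — and 95%
limits are back-transformed from the log scale. The trim default is 0,
exposed as a parameter. When no dose reaches 50% mortality the estimate is
reported as unbounded at the highest dose tested and used at face value
downstream — the conservative convention for screening endpoints.

**No-observed-effect doses.** Three procedures, selected by the shape of
the data (`decide_test()`): continuous replicate-level responses with
pooled controls go to Williams' test; monotone quantal data to the
Cochran–Armitage step-down; non-monotone quantal data to one-sided
Fisher's exact tests with Holm adjustment. The monotonicity screen (rank
correlation plus sign consistency of adjacent differences) is an
operational rule, documented as such — guideline reports rarely state
theirs. All tests are one-sided toward adverse response at $\alpha = 0.05$
(configurable), since mortality can only be adverse.

Williams' amalgamated-mean critical values are obtained by seeded
Monte-Carlo simulation of the null for the actual design (10,000 draws by
default, cached per design) rather than transcribed 1971/72 tables —
avoiding transcription risk and extending to unbalanced designs. The
procedure tests from the highest dose downward and stops at the first
non-significant dose.

Solvent and negative controls are compared first (Fisher's exact for
quantal, t-test for continuous); absent a significant difference the
negative control drives treatment comparisons.

Published endpoints (e.g. an adult contact LD50 of 43.67 µg/bee with 95%
limits 37.30–51.13) cannot be recomputed because raw mortality tables are
unpublished; they enter the exposure model as fixture constants, and the
statistical machinery is validated on synthetic data instead.

## What the generators emulate — and what they do not

`gen_use_records()` draws label-compliant rates from a log-normal
truncated at the highest label rate (growers report uses within the
label), then injects two kinds of gross contamination: outliers drawn
uniformly between 2 and 4 times the analytic IQR fence of the clean
distribution, and unit-entry errors that multiply a routine
(upper-three-quartile) rate by 100. Because clean rates sit strictly below
the fence while injected records sit far above it, flag sets recover truth
sets exactly — the property the cleaning tests assert. Real registry data
are messier: errors of ambiguous magnitude, rates legitimately above
label, per-crop heterogeneity. Passing the recovery tests shows the filter
logic is correct, not that real-data cleaning is unambiguous.

`gen_residue_study()` uses first-order decay per matrix with log-normal
replicate noise (CV 0.2, triplicates, sampling days 0–10) and censors
below the minimum detectable limit; it emulates a pollen-dominated,
fast-declining residue profile, not foliar dissipation kinetics, weather,
or between-hive variability. `gen_dose_response()` draws binomial deaths
from a log-logistic curve (defaults LD50 50, slope 4, five doses 12.5–200,
10 bees per dose).

## Numerical choices and problem sizes

* RQ verdicts use strict comparison (`rq < loc` is `below_loc`); flagging
  thresholds in cleaning are strict (`>`), matching "above" / "more than".
* The TSK numeric gradient uses central differences of step 1e-5 with
  proportions clipped to [0, 1]; zero within-group variance in Williams'
  test degenerates to an exact mean comparison.
* Simulation studies in the test suite: LD50 recovery uses 500 seeded
  draws (median relative bias within 5%, CI coverage within [90%, 98%]);
  NOED type-I error uses 2,000 seeded null draws per procedure (bounded at
  7% against the nominal 5%); cleaning recovery uses 50 seeded registries
  of 1,000 records. These sizes give Monte-Carlo error comfortably inside
  the asserted bands while keeping the default test run short.

## Known limitations

* Tier 1 only: no foliar dissipation or degradation kinetics, no colony
  dynamics, no synergy with co-applied insecticides, no sublethal
  endpoints — all conservatism-by-omission inherent to the screen.
* The caste consumption table is a fixed snapshot of the public tier-1
  workbook; alternative diets enter via a custom `castes` table.
* The IQR fence's grouping unit in published registry counts is
  under-specified; this package documents its own (per chemical, crops
  pooled) and exposes the alternative.
* LOQ substitution is conservative by design; heavily censored studies
  will overstate exposure relative to maximum-likelihood censoring models,
  which are out of scope for a screening tool.
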