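---
title: "Digestibility coefficients and feed efficiency in laying hens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digestibility coefficients and feed efficiency in laying hens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layerdig)
```

## The problem

Feed is the dominant cost of egg production, and feed efficiency (egg mass
produced per unit feed consumed) is the trait breeders most want to improve.
Because a hen's excreta mix faeces and urine, per-nutrient digestive
efficiency is hard to observe directly; what can be measured at scale is the
chemistry of pooled manure. `layerdig` implements the complete phenotyping
pipeline from per-bird trial records and manure chemistry to apparent
total-tract digestibility coefficients (DCs), feed-efficiency indicators, and
the statistical comparisons and prediction models used to ask whether DCs
predict feed efficiency.

## Digestibility coefficients

A digestibility coefficient is the percentage of an ingested component that
does not reappear in the manure. With intake and excretion in g DM/day:

* manure dry matter: `manure_dm = ADM/1000 * DMW`, where `ADM` (g/kg) is the
  air-dry recovery of fresh manure and `DMW` (g/day) the fresh manure weight;
* feed dry matter: `feed_dm = DFC * DM_feed/1000`;
* `DC_DM = 100 - manure_dm / feed_dm * 100`;
* for a nutrient with contents in g/kg DM on both sides:
  `DC_nutrient = 100 - (manure_dm * content_manure) /
  (feed_dm * content_feed) * 100`.

Assay values arrive on the air-dried-sample basis and are converted with the
sample's own dry-matter content (`content_dm = content_ad * 1000 / dm_ad`).
Feed contents are given as-fed and converted with the feed's dry-matter
content; a `feed_as_fed = FALSE` switch accepts compositions already on a DM
basis. Organic matter is defined as dry matter minus ash on both sides; no
separate organic-matter assay is needed.

Two conventions deserve emphasis:

* **ADM as the DM conversion factor.** The amount-of-manure formula treats
  the air-dry recovery as the dry-matter content of fresh manure. Air-dried
  material retains some residual moisture, which instead enters through the
  assay basis `dm_ad`; the simulator mirrors exactly this convention so the
  two stages are mutually consistent.
* **Uric-acid nitrogen correction.** Manure nitrogen contains urinary
  nitrogen largely bound in uric acid (C5H4N4O3). The nitrogen coefficient
  uses `N_corrected = N_total - f_UA * UA` with the stoichiometric
  `f_UA = 4*14.007/168.11 ≈ 0.3333`, exposed as an argument should a
  different correction be preferred. Negative corrected values are floored
  at zero with a warning.

Coefficients are never clamped: a negative DC flags a mass-balance violation
(`mass_balance` in the `flags` column) rather than being hidden. Zero manure
weight yields coefficients of 100 with a `zero_manure` data-quality flag.
Reported tables round to one decimal; all stored values are full precision.

## Feed-efficiency indicators

* laying percentage `LP = eggs laid / eggs expected * 100` (the laying
  window spans 8 expected eggs by default, one more than the 7-day feed
  window, because an egg from the day before recording can enter the first
  collection);
* egg mass `EM = mean egg weight * LP/100` (g/day);
* feed conversion ratio `FCR = (sum of daily feed / EM) / period`, which for
  a constant daily feed reduces to `DFC/EM`; a hen that laid no eggs has an
  undefined FCR, reported missing and flagged rather than infinite;
* residual feed consumption `RFC = feed - (b0 + b1*DBW + b2*EM + b3*BWG)`,
  the residual of observed feed on a production-based prediction.

The RFC feed term defaults to total feed over the recording period
(`dfc * period_days`) with a `rfc_basis = "per_day"` switch; the
`b`-coefficients are population-specific and must be supplied — the shipped
default is the null model (all zeros), so out of the box `rfc` equals
observed feed and real coefficients have to be provided consciously.
Body-weight gain defaults to zero: over a one-week window in adult hens it
is negligible.

## The synthetic-trial generator

Real per-bird data of this kind are proprietary, so the package ships a
mass-balance simulator whose latent truth the pipeline can be checked
against. For each bird it draws feed intake, body weight, a Bernoulli
laying pattern, an egg weight, and a latent DC vector; it then *constructs*
the manure by inverting the digestibility arithmetic:

* excreted DM = DM intake × (1 − DC_DM/100), and likewise for fat, faecal
  nitrogen and organic matter (organic intake = DM intake − ash intake);
* manure ash is the residual excreted DM − excreted organic matter, so that
  both DC_DM and DC_Org are exactly recoverable;
* uric acid carries a configurable fraction (default 0.35) of total excreted
  nitrogen, sized stoichiometrically;
* fresh weight = excreted DM / (1 − moisture fraction); the air-dry recovery
  is excreted DM per kg fresh manure, and assay contents are expressed on the
  air-dried basis `dm_ad` (default 900 g/kg — air-drying at 70 °C leaves
  roughly 10 % residual moisture);
* every assay value finally receives multiplicative Gaussian noise with a
  configurable CV (default 0.02, a typical wet-chemistry analytical CV).

With the noise CV at zero the pipeline recovers every latent coefficient to
machine precision — the central oracle of the test suite.

**Correlated latent digestibilities.** Dry matter contains the organic
fraction, so DC_DM and DC_Org cannot vary independently once the mass
balance must close: at the default trait spreads, independent draws would be
infeasible (excreted organic matter exceeding excreted dry matter) for about
a fifth of birds, and rejecting those draws would bias the simulated line
means by about two percentage points. The generator therefore draws the four
coefficients from a correlated normal (defaults: 0.9 between DM and organic
matter, 0.5 between nitrogen and each of those, 0.3 for fat — consistent
with the strong within-line DC correlations reported for such trials, e.g.
0.92–0.95 between DC_DM and DC_Org) truncated to [0, 100], with the rare
residual infeasible draw rejected and redrawn. Independence remains available
via `dc_correlation = diag(4)` for small spreads.

**Default study conditions.** `hen_line_defaults()` encodes two White
Leghorn lines: line A (higher intake 142.0 g/day, body weight 1718 g, lower
laying 82 %, higher digestibility: DC_DM 74.6, DC_Fat 86.0, DC_N 77.5,
DC_Org 77.5 %) and line B (intake 122.8 g/day, laying 92 %, DC_DM 65.5,
DC_Fat 78.8, DC_N 73.5, DC_Org 69.8 %), 50 birds each. Between-bird SDs are
reconstructed from the published standard errors as `SE * sqrt(n)` with
n = 43/44. Manure moisture comes from the published air-dry recoveries
(252.4 and 260.2 g/kg → moisture 0.748/0.740), mean egg weight from egg
mass over laying percentage. Values the summary tables do not determine —
egg-weight SD (4 g), the uric-acid share of excreted nitrogen (0.35, within
the range reported for poultry excreta where urinary nitrogen is roughly
half of total and predominantly uric acid), assay noise CV (0.02) and the
air-dried sample's DM (900 g/kg) — were fixed once at field-realistic
values.

All randomness flows from a single seed through per-line and per-bird
substreams, so enlarging a line leaves existing birds bit-identical.

**What the generator does not emulate:** day-to-day autocorrelation,
aging or any gut physiology, feed wastage (hens that play with feed inflate
measured intake, a recognised caveat when interpreting line contrasts in
DFC), and any genetic structure within a line. Correlations between
performance traits and latent digestibilities default to zero. Passing tests
therefore certify the arithmetic and the statistical machinery, not the
biology of any particular flock.

## Statistical stages

* **Outlier screening** uses boxplot (Tukey) fences `[Q1 − k·IQR, Q3 + k·IQR]`
  with `k = 1.5`, quartiles by the linear-interpolation convention, computed
  once per line on the incoming data and never re-iterated. The whole bird
  record is removed when any screened trait (default: DFC, EM, DMW, DBW, FCR
  and the four DCs) is outside its fences; missing values never flag a
  record. Removed ids are logged so 50 → 43-style attrition is auditable.
* **Between-line tests** are two-sided Welch t-tests by default (the
  unequal-variance form is the safer default when line variances visibly
  differ, as they do here); `var_equal = TRUE` gives the pooled test.
  Constant, equal groups return p = 1 by convention.
* **Correlations** are pairwise-complete Pearson, with t-distribution
  p-values and a mask at α = 0.05; no multiplicity correction is applied
  anywhere, matching standard practice for this exploratory stage.
* **Principal components** standardize by default because the traits mix
  grams, percent and ratios; the unscaled variant is a switch. The variable
  set is the performance traits (DFC, EM, DMW, DBW, LP) plus the four DCs,
  per line; FCR and RFC are excluded as derived traits. Contributions are
  squared loadings scaled to 100 within a dimension.
* **Prediction models** are ordinary least squares per line: a performance
  model of FCR or RFC on EM and DBW (DFC and LP are excluded as definitionally
  confounded with the response), and single-DC models with one of DC_DM,
  DC_N, DC_Org at a time — the DCs are too collinear to enter jointly.
  In-sample R² only; no cross-validation is attempted at n ≈ 44.

## Numerical and degenerate-input choices

Quantile type 7 everywhere; fences collapse to a point for constant traits
(nothing removed). A constant trait yields an `NA`, masked correlation and
an error in standardized PCA rather than a silent drop. Division-by-zero
guards: feed DM intake and feed nutrient contents must be positive; egg
mass of zero gives a missing FCR. The latent-DC rejection sampler caps at
10 000 tries and then reports the parameter combination as infeasible.

## Problem sizes used in validation

The shipped checks run the worked-example arithmetic on the published line
means (instant), exact-recovery simulations at 50 birds/line, a
200-replicate recovery study at the published line sizes (43/44), 2000
null replicates for the Welch type-I error, and a 10 000-bird convergence
check of the generator — a few minutes end to end on one core.

## Known limitations

Mean-of-ratios versus ratio-of-means: published line means of FCR and DC_DM
are means of per-bird ratios, so plugging line-mean inputs into the ratio
formulas reproduces them only when within-line variation is small (it does
for line B, not for line A; the discrepancy is structural, not a bug).
Supplementary material detailing the original nitrogen-correction and
organic-matter formulas was not available; the stoichiometric correction and
the DM-minus-ash definition are documented assumptions, exposed as
parameters. AMEn, ileal digestibility, multi-diet trials and any genetic
analysis are out of scope.
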