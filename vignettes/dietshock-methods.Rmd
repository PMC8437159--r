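---
title: "Scoring dietary diversity and quality under food-price shocks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dietary diversity and quality under food-price shocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietshock)
```

## The problem

During acute emergencies, food prices and household food security can shift
faster than diets can be measured with full quantitative instruments. A
pragmatic design used in multi-country telephone surveys asks one adult per
household to recall, for each of 20 locally adapted food groups, the number
of days (0–7) the household consumed it in the past week — once for the
period before the emergency and once for the current period — together with
perceived price changes for five food categories (staples, pulses, fruits,
vegetables, animal-source foods), three yes/no food-insecurity items adapted
from the HFIAS, own crop production, social assistance, and basic
socio-demographics. `dietshock` implements the full analysis pipeline for
such data: scoring, exposure coding, stratified descriptives, and marginal
regression models, plus a synthetic-survey generator that states the world
those analyses assume.

The reference design is six sites in three countries — Nouna (rural) and
Ouagadougou (urban); Kersa (rural) and Addis Ababa (urban); Ibadan (rural)
and Lagos (urban) — with roughly 300 households per site.

## The scores

**DDS (adapted MDD-W count, range 0–10).** The 20 survey groups aggregate
into the 10 MDD-W food groups (grains/white roots/tubers/plantains; legumes;
nuts and seeds; dairy; meats/poultry/fish; eggs; vitamin A-rich dark green
vegetables; other vitamin A-rich fruits and vegetables; other vegetables;
other fruits). With days-based 7-day recall, "eaten at least once each day"
forces days = 7 for a group to count:

$$\mathrm{DDS} = \sum_{g=1}^{10} \mathbf{1}\{d_g / 7 \ge 1\}$$

This is strict — a group eaten 6 of 7 days contributes nothing — and it is
the main reason published site means are low (1.3–2.3). Because the
strictness is unusual, the threshold is a scoring option
(`scoring_options(dds_days_threshold = 1)` gives the ≥1-day sensitivity
variant in one change); the default stays at 7.

**PDQS (adapted, range 0–40).** The 20 survey groups coincide with the
adapted PDQS groups: 14 healthy (dark green leafy vegetables, other vitamin
A-rich fruits and vegetables, cruciferous vegetables, other vegetables,
citrus fruits, other fruits, fish, eggs, poultry, legumes, nuts/seeds,
dairy, whole grains, liquid vegetable oils) and 6 unhealthy (red meat,
processed meats, refined grains — including maize-flour products — SSBs,
desserts/sweets, roots and tubers). Healthy groups score 0/1/2 points for
0–1, 2–3, ≥4 servings/week; unhealthy groups score 2/1/0 on the same cuts.
Weekly *servings* are proxied by *days consumed*, the only frequency the
recall collects; this is a documented proxy, not an equivalence. Two
consequences follow analytically: a zero-intake week scores 12 (all six
unhealthy groups earn 2), and the maximum 40 needs every healthy group ≥4
days and every unhealthy group ≤1.

**Aggregation.** When several survey groups feed one score group, the
default aggregator takes the maximum of constituent days: a day is counted
once however many constituents were eaten, which avoids double-counting days
of consumption toward a 7-day threshold. A sum-capped-at-7 aggregator is
available by option; the choice matters only for multi-constituent groups
and the instrument is silent on it.

**Site masks.** Two sites collected reduced instruments: Kersa lacks the
other vitamin A-rich fruits and vegetables group; Addis Ababa lacks citrus
fruits and other fruits. Masks are declared at the survey-group level in the
codebook and therefore propagate to *both* scores (an instrument-level
absence cannot selectively affect one score); a masked group contributes 0
and the attainable maximum shrinks — scores are deliberately **not**
rescaled, matching the published presentation. Whether the source analysis
masked the PDQS as well is not documented; we chose the instrument-level
reading as the only internally consistent one.

**Missing recall days.** A period's scores are retained only if the fraction
of unmasked groups observed reaches `completeness_threshold` (default 1: any
missing group disqualifies the period). Incomplete periods get `NA` scores
and are excluded — with a logged count — from score-based analyses.
Outcome missingness is never imputed.

**Reconstruction caveat.** The exact 20-group instrument per country is not
published. The packaged codebook (`inst/extdata/codebook.json`) is a
reconstruction from the two published group lists; group ids are fixed,
labels editable. Three survey groups (liquid vegetable oils, SSBs,
desserts/sweets) have no MDD-W counterpart and carry the explicit
non-scoring target `"none"`.

## Exposures, confounders, and the design matrix

Price-change exposures are binary: increased = 1 against a reference of "no
change or decreased". The three food-insecurity items are yes = 1. Crop
production is a 4-level factor (unchanged [ref], decreased, increased, does
not farm). Reference levels mirror the published tables: employed for
occupation, primary/incomplete secondary for education, 20–29 for age,
urban for locality, female for sex.

Confounder missingness uses the missing-indicator method: categorical terms
get an explicit missing column (dummies 0, indicator 1); continuous terms
(household size) are mean-imputed with a companion 0/1 indicator — the
continuous-variable recipe is our choice, since the method is named in the
source only for the categorical case.

## The GEE

Associations are estimated with linear generalized estimating equations,
exchangeable working correlation, clustered by site (6 clusters in the
combined model, 2 in country models), with cluster-robust sandwich
covariance — implemented in the package because no GEE engine is available
in the supported dependency set. The common correlation is re-estimated each
iteration by the Liang–Zeger moment estimator; the exchangeable inverse is
applied in closed form per cluster. CIs are Wald with the 1.96 normal
quantile and no small-sample correction by default, matching the source
analysis; a config-gated m/(m−1) sandwich inflation is available
(`small_sample_correction = TRUE`), as is a household-level clustering
sensitivity mode (`cluster = "household_id"`), because sandwich standard
errors with 2–6 clusters are unreliable (see below).

Model building follows the published rules exactly: every candidate
confounder is fit alone (univariate GEE, same clustering) and kept when its
joint Wald p across levels is < 0.20; the five price exposures are always
retained; crop production and household size are forced. Country models
re-screen within country — the alternative (reusing the combined screen) is
not supported by the published tables, which retain different covariates per
model. Joint Wald tests use a pseudoinverse with rank-based degrees of
freedom because with m clusters the sandwich has rank at most m, and 2-cluster
country fits would otherwise be singular for multi-level candidates.

Degenerate inputs are handled explicitly: a single cluster is an error
directing the user to the independence/household-cluster fallback;
zero-variance and collinear design columns are errors naming the column
(the pipeline prunes dummies for levels absent in a country subset before
fitting, recording what it dropped).

## The synthetic world

`synthetic_config()` states the world the analyses assume rather than
exposing free dials:

* **Site structure**: 6 × 300 households; exposure prevalences and covariate
  category probabilities are fixed at the magnitudes of the published
  site-stratified descriptive tables (price-increase prevalences 0.60–0.99).
* **Consumption**: days per group are Binomial(7, p) — beta-binomial with
  intra-household correlation `overdispersion = 0.08` by default — with
  logit(p) = baseline + during-period drift + exposure/covariate shifts +
  site effect. Effects are injected at the food-group propensity level, not
  on the scores, because the pipeline consumes raw frequencies; the implied
  score-level effect is obtained by `implied_effect_oracle()`, which
  simulates matched exposed/unexposed pairs and scores them with the
  production scorer (no second scoring implementation exists).
* **Clustering**: a shared per-site N(0, `site_sd`²) logit effect, matching
  the exchangeable-correlation assumption. The source reports no variance
  components, so the default `site_sd = 0.25` is an arbitrary, documented
  choice made once.
* **Baseline propensities** were calibrated once so that before-period DDS
  site means land roughly in 1.3–2.3 and PDQS medians near 17–23; exact
  replication of the published descriptives is explicitly not claimed.
* **Missingness** defaults to ~5% on price items and ≤1% elsewhere,
  consistent with the published denominators; food-frequency outcomes are
  never set missing, because the source adjusts only confounder missingness.
* **Determinism**: one seed; per-site and per-stage sub-streams are derived
  by hashing stream labels, so identical config + seed is byte-identical.

A green test on this world establishes that the pipeline recovers what the
generator injects under its assumptions (binomial counts, additive logit
effects, exchangeable site clustering, missingness completely at random). It
does not establish robustness to real-data features the generator omits:
informative missingness, within-week day-to-day structure, reporting/recall
bias, household correlation between the two recall periods, or
cross-covariate dependence beyond what the site mix induces.

## Interval calibration with six clusters (a known red)

The acceptance suite checks, over 200 simulated surveys with a configured
legume-propensity shift, that the mean multivariate pulse-price estimate
matches the Monte-Carlo oracle (it does, to ~0.01 score units, well inside
the ±0.05 band) and that 95% CIs cover the oracle effect 90–98% of the time.
The coverage check **fails, at roughly 75–85% coverage, and is left red on
purpose**. The diagnosis: the estimating equation forces the six per-cluster
score vectors to sum to zero, deflating the empirical sandwich meat by about
(m−1)/m even for independent data (mean estimated SE ≈ 0.055 against a true
sampling SD ≈ 0.069 in our experiments); the site random effect adds
cluster-level confounding noise that six clusters cannot estimate precisely;
and the multivariate design has more columns (~27) than the meat has rank
(≤ 6). These are properties of the published analysis strategy itself —
1.96-quantile sandwich CIs clustered on six sites — not of this
implementation, which matches an independent reference GEE to seven decimal
places. The config-gated m/(m−1) correction recovers only part of the gap
(~0.85–0.90); honest calibration would need t(m−1) quantiles or bias-reduced
corrections that the source analysis does not use.

## Descriptive conventions

Percentages always use the variable's non-missing denominator within the
stratum — the only rule under which the published percentages recompute from
their own printed counts — and are rounded half-up to one decimal (base R
rounds half to even, which a published table does not). DDS is summarized as
mean ± SD and PDQS as median (IQR, quantile type 2), following the source's
mixed convention. A handful of published overall percentages do not
recompute from any visible denominator; the package documents its rule and
does not chase them.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(synthetic = TRUE, outcomes = "dds",
                       scopes = "combined", out_dir = "demo_out", seed = 42)
res <- run_pipeline(cfg)
results_report(res$models$dds_combined)
```

## Known limitations

* The codebook is a reconstruction; per-country localized food lists would
  slot in as label edits, but constituent-to-group mapping differences would
  change scores.
* PDQS servings ≡ days is a proxy; households eating a group several times a
  day are indistinguishable from once-a-day households.
* The 2-cluster country models have essentially anecdotal standard errors;
  they are faithful to the source, and the household-cluster sensitivity
  mode exists for users who want defensible intervals.
* The generator draws the two recall periods independently given the
  propensities; real before/during recalls from one respondent are
  correlated, so change-summary variances in synthetic data are
  conservative.
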