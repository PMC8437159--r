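# dietshock

Scoring and inference for household food-security surveys that ask one adult
per household how many days (0–7) the household ate each of 20 food groups in
the past week — before and during an emergency — alongside perceived food
price changes, food-insecurity items, crop production, and demographics.

The package is aimed at nutrition epidemiologists analysing multi-site rapid
(telephone) surveys of the kind run across sub-Saharan Africa during the
COVID-19 emergency: six sites (Nouna, Ouagadougou, Kersa, Addis Ababa,
Ibadan, Lagos) in three countries, ~300 households each.

## What it computes

* **DDS** — an adapted Minimum Dietary Diversity for Women count over 10 food
  groups, `DDS = Σ_g 1{d_g/7 ≥ 1}` (a group counts when eaten every day of
  the recall week), range 0–10.
* **PDQS** — an adapted Prime Diet Quality Score over 20 groups (14 healthy,
  6 unhealthy): healthy groups score 0/1/2 points at 0–1, 2–3, ≥4
  servings/week and unhealthy groups the reverse, range 0–40 (an all-zero
  week scores 12 by construction).
* **Exposures** — binary price-increase indicators for staples, pulses,
  fruits, vegetables and animal-source foods (reference: no change or
  decreased), three HFIAS-style yes/no items, 4-level crop production.
* **Descriptives** — site-stratified N (%) tables with non-missing
  denominators, before/during consumption-change summaries per food group,
  and DDS mean ± SD / PDQS median (IQR) per site and period.
* **Models** — linear GEE with exchangeable working correlation clustered by
  site and cluster-robust (sandwich) SEs, built by the published rules:
  univariate screen at P < 0.20, five price exposures always retained, crop
  production and household size forced, missing-indicator confounder
  adjustment; combined and country-specific scopes, both outcomes. The GEE
  engine is implemented in the package (verified against an independent
  reference implementation) since none is available in the dependency set.
* **Synthetic surveys** — a six-site generator with configured exposure
  prevalences, covariate mixes, per-food-group logit propensity effects,
  site random effects and missingness, plus a Monte-Carlo oracle
  (`implied_effect_oracle()`) for the score-level effect any propensity
  shift implies.

## Worked example

```r
library(dietshock)

## score one household's week
days <- setNames(rep(0, 20), default_codebook()$survey_groups$id)
days[c("whole_grains", "legumes", "other_veg")] <- 7
days[c("fish", "eggs")] <- 3
compute_dds(map_to_mddw_groups(days))$dds    # 3
compute_pdqs(map_to_pdqs_groups(days))$pdqs  # 20
```

Three groups eaten daily give DDS 3; the PDQS of 20 combines 2 points each
for the three daily healthy groups and 1 each for fish and eggs (2–3
servings/week) with 12 "free" points from untouched unhealthy groups.

```r
## full pipeline on a synthetic survey
cfg <- pipeline_config(synthetic = TRUE, outcomes = "dds",
                       scopes = "combined", out_dir = "demo_out", seed = 42)
res <- run_pipeline(cfg)
s <- res$descriptives$scores
s[s$stratum == "overall", c("period", "dds_mean", "dds_sd",
                            "pdqs_median", "pdqs_q1", "pdqs_q3")]
#>  period dds_mean dds_sd pdqs_median pdqs_q1 pdqs_q3
#>  before     1.70  0.922          21      20      23
#>  during     1.08  0.812          20      18      21
```

Diversity and quality both drop in the emergency period — the generator's
default world injects a broad during-period consumption decline plus
price-shock effects on the matching food groups. Model results are written
to `demo_out/model_results.csv` and formatted in the published
`estimate (CI)` style by `results_report(res$models$dds_combined)`.

The same run from the shell:

```sh
Rscript inst/exec/dietshock run-all --config inst/extdata/demo_config.json --seed 42
```

(`simulate`, `score`, `describe` and `model` also exist as subcommands; run
with no arguments for usage.)

## Layout

* `R/` — codebook, survey CSV I/O + validation, scoring, exposure coding,
  descriptives, GEE + model building, synthetic generator, pipeline/CLI.
* `inst/extdata/codebook.json` — the (reconstructed, editable) 20-group
  codebook with score mappings and per-site masks.
* `vignettes/dietshock-methods.Rmd` — models, assumptions, numerical
  choices, what the synthetic world does and does not establish.
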