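# neorisk

An R package for building and validating an **epidemiological neonatal
mortality risk score** from routinely collected vital-statistics data: birth
records (Live Birth Certificates linked to Death Certificates) and municipal
health-system indicators, as collected in São Paulo State, Brazil. The
package is aimed at epidemiologists and public-health analysts who want to
stratify newborns by risk of neonatal death (0–27 days) using only data
available at birth — no laboratory values or NICU monitoring.

## What it implements

For birth *i* in municipality *j*, the core model is a two-level
random-intercept logistic regression,

    logit P(death_ij) = β0 + Σk βk · x_ijk + u_j,   u_j ~ N(0, σ²u)

over fourteen binary risk conditions (male sex, birthweight < 2,500 g,
maternal age < 17 or ≥ 40, congenital anomaly severity grades 1–3, term
cesarean, preterm cesarean, preterm vaginal delivery, < 7 prenatal visits,
spring/summer birth, multiple pregnancy, below-mean municipal nurse density
and private-insurance coverage). Adjusted odds ratios are converted into
integer points by rescaling their natural logarithms onto 1–10:

    weight = round(a·ln(OR) + b),  a = 9 / (max ln OR − min ln OR),
                                   b = 1 − a·min ln OR

and a birth's score is the sum of the points of its present conditions.

Around that core the package provides, as tested modules:

* **Cohort and indicator I/O** — schema-validated CSV reading/writing with
  secondary-data cleaning rules (out-of-range values become missing, > 10%
  missing indicators are flagged for exclusion).
* **Anomaly severity grading** — ICD-10 Chapter XVII code parsing and the
  empirical 1–3 grading by observed lethality among single-anomaly births.
* **Ecological screening** — proxy municipal neonatal mortality rates,
  z-scores, Pearson screening (p < 0.20), correlation grouping (|r| ≥ 0.50),
  stepwise OLS with VIF control, and mean-cutoff dichotomization.
* **Model fitting** — univariate logistic screening (p < 0.20) and the
  multilevel fit by adaptive Gauss–Hermite quadrature (`lme4` backend).
* **Score building and application** — scaling constants, integer weights,
  record scoring, four-group risk stratification.
* **Validation** — ROC/AUC with DeLong CIs, per-cutoff performance tables,
  Youden-optimal threshold, risk-group summaries, grouped calibration and
  McFadden pseudo-R².
* **Synthetic cohorts** — a generator reproducing the statistical structure
  the analysis assumes (published marginal prevalences, municipality random
  intercepts with σ² = 0.0560, the published ln(OR)s as outcome truth,
  comma-separated ICD-10 code fields with per-category lethality), so the
  whole pipeline is testable without the access-restricted registry data.

## Worked example

```r
library(neorisk)

# rebuild the published point table from its fourteen adjusted odds ratios
table <- assign_weights(ref_model_or()[, c("condition", "or")])
round(c(a = table$a, b = table$b), 5)
#>       a       b
#> 1.60389 0.93524
table$conditions[table$conditions$condition %in%
                   c("severity_3", "low_bw", "few_prenatal", "spring_summer"), ]
#> # A tibble: 4 × 4
#>   condition          or  ln_or weight
#>   <chr>           <dbl>  <dbl>  <int>
#> 1 low_bw           8.46 2.14        4
#> 2 severity_3     285.   5.65       10
#> 3 few_prenatal     2.74 1.01        3
#> 4 spring_summer    1.04 0.0404      1
```

`a = 1.60389` maps the weakest condition (spring/summer birth, OR 1.0412) to
1 point and the strongest (grade-3 congenital anomaly, OR 284.78) to 10; low
birthweight earns 4 points and poor prenatal care 3. A full synthetic run:

```r
sim <- simulate_cohort(sim_config(n_births = 100000, n_municipalities = 150),
                       seed = 101)
dev <- develop_score(sim$cohort, sim$indicators, nAGQ = 1)
print(dev$score_table)     # fitted ORs and integer points
cc  <- !is.na(dev$scores)
validate_score(dev$scores[cc], dev$predictors$neonatal_death[cc],
               dev$score_table)
#> Validation report (n = ...)
#>   AUC ~0.8-0.9 ...; optimal cutoff; risk-group table with rising death rates
```

The frozen artifacts (`dev$severity_table`, `dev$means`,
`dev$score_table`) can then be applied unchanged to an independent cohort
with `apply_score()` — the external-validation path.

A thin command-line wrapper over these functions is installed at
`inst/cli/neorisk.R` (subcommands `simulate`, `grade`, `screen`, `fit`,
`build-score`, `apply`, `validate`).

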