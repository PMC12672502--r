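---
title: "Building and validating an epidemiological neonatal mortality risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating an epidemiological neonatal mortality risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neorisk)
```

## The problem and the model

Neonatal death (death at 0–27 days of life) is a rare outcome (~0.8% of live
births in the São Paulo State registry this package emulates) whose risk is
shaped both by characteristics recorded on the Live Birth Certificate — sex,
birthweight, gestational age and delivery type, prenatal care, congenital
anomalies — and by the context of the mother's municipality of residence.
`neorisk` implements a complete pipeline that turns such data into a simple
integer risk score usable at the moment of birth, without laboratory tests.

The statistical core is a two-level random-intercept logistic model. For birth
$i$ in municipality $j$,

$$\operatorname{logit} P(Y_{ij} = 1) = \beta_0 + \sum_k \beta_k x_{ijk} + u_j,
\qquad u_j \sim \mathcal{N}(0, \sigma^2_u),$$

where the $x_{ijk}$ are fourteen binary risk conditions from eleven variables
(reference levels: female, $\ge$2,500 g, maternal age 17–39, no anomaly,
vaginal term delivery, $\ge$7 prenatal visits, autumn/winter birth, singleton
pregnancy, at-or-above-mean municipal nurse density and insurance coverage).
The municipality intercept $u_j$ absorbs between-municipality differences not
captured by the measured indicators. The likelihood is maximized by adaptive
Gauss–Hermite quadrature (`nAGQ` points, default 11; `nAGQ = 1` is the
Laplace approximation), via `lme4::glmer` on binomially aggregated covariate
patterns — aggregation leaves the likelihood unchanged and makes
registry-scale fits fast.

Each adjusted odds ratio is converted into an integer point by a linear
rescaling of its natural logarithm,

$$\text{weight} = \operatorname{round}(a \ln \text{OR} + b), \qquad
a = \frac{10 - 1}{\max \ln \text{OR} - \min \ln \text{OR}}, \qquad
b = 1 - a \min \ln \text{OR},$$

so the weakest retained condition maps to 1 point and the strongest to 10
before rounding; reference categories contribute 0 and a record's score is
the sum over its present conditions. Rounding is half-away-from-zero
("commercial" rounding); no half-case arises on the published inputs, so the
choice is cosmetic but fixed. ln(OR)s are always taken from full-precision
ORs, never from printed two-decimal log columns. On the published table of
fourteen adjusted ORs this reproduces $a = 1.6039$ and every printed integer
weight; $b$ computes to 0.93524 where 0.9353 is printed — a discrepancy of
one unit in the fourth decimal attributable to print rounding, with no
effect on any weight.

```{r}
table <- assign_weights(ref_model_or()[, c("condition", "or")])
round(c(a = table$a, b = table$b), 5)
table$conditions
```

## Severity grading of congenital anomalies

Anomalies arrive as a free-text field of comma-separated ICD-10 codes. Only
the first three characters of each token are used (subcategories collapse
onto their Chapter XVII category, `Q00`–`Q99`); invalid tokens are dropped
with a warning count; duplicates collapse. The empirical severity of each
category is estimated on births with *exactly one* recorded category, so the
observed neonatal-death proportion is attributable to that category:

* grade 1 — fewer than 10 unique cases, or death proportion < 20%;
* grade 2 — proportion in [20%, 40%);
* grade 3 — proportion ≥ 40%.

The boundary semantics (0.20 belongs to grade 2, 0.40 to grade 3) keep grade
1 strictly "< 20%". Each birth then receives the *maximum* grade over its
recorded categories; an anomaly flag without any valid category is grade 1;
no anomaly is 0. An optional override map supports the clinical-coherence
review step; no automated clinical logic is attempted. Because the grading
uses the same outcome later being modelled, the severity table is a frozen,
serializable artifact: validation cohorts must reuse the development table
rather than re-derive it.

## The ecological screening stage

Municipal indicators (one row per municipality × year) are screened against
a proxy municipal neonatal mortality rate — deaths among same-calendar-year
births per 1,000, which misses cross-year deaths but is stable when annual
patterns are — in four steps: z-score standardization; Pearson screening at
p < 0.20; single-linkage grouping of indicators with pairwise |r| ≥ 0.50,
retaining per group the indicator best correlated with the rate (ties break
lexicographically); and bidirectional stepwise OLS with entry/removal at
p = 0.05 and post-hoc removal of any variable with VIF > 2, returning the
highest-adjusted-$R^2$ model among the valid models visited. Single linkage
was chosen because the grouping is described only by a pairwise threshold;
with chains (A–B and B–C correlated, A–C not) it joins all three, which is
the more conservative anti-collinearity reading. Indicators entering the
individual-level model are dichotomized at their pooled development mean
(below mean = risk flag); the means are stored and reused verbatim on
validation data.

## The synthetic cohort generator

Because the registry data are access-restricted, the package ships a
generator whose defaults are the published study conditions: the marginal
prevalences of the birth characteristics (male 48.8%, birthweight < 2,500 g
9.2%, extreme maternal age 6.7%, < 7 visits 22.0%, multiple pregnancy 2.4%,
preterm 10.5%, spring/summer 47.8%, anomaly 1.0%, with the delivery-type
split conditional on preterm derived from the published joint table), a
municipality random-intercept variance of 0.0560, the fourteen published
ln(OR)s as the outcome truth, and per-field missingness at the published
rates. The baseline intercept is calibrated at generation time by
root-finding so the expected marginal death rate equals 7.69 per 1,000.
Municipality sizes are unequal (gamma/Dirichlet weights, shape 0.6) because
real cohorts are size-skewed; clean equal-size configurations are available
for unit tests.

Where the study reports only marginals, defaults are explicit synthetic
assumptions, recorded in `truth.json`: positive dependence among multiple
pregnancy, preterm birth and low birthweight is induced by log-odds
cross-terms (defaults `log(8)`, `log(15)`, `log(4)`) with intercepts
re-calibrated to preserve the marginals; the anomaly specification uses 21
plausible `Q` categories with lethalities from 1% to 72% so all three grades
are exercised; seasons default to the Southern-Hemisphere astronomical
window (Sep 23 – Mar 20, configurable), since no boundary is published.

Anomalies can act on the outcome in two modes, and the distinction matters.
In the default `"grade"` mode the severity-grade ln(OR)s enter the linear
predictor, which makes parameter recovery exact in expectation — but then
the *realized* death proportion of a truly lethal category is bounded by
what the grade OR yields at the baseline rate (a grade-3 OR of 284.78 at a
~0.8% baseline gives ~25% observed lethality, not ≥ 40%), so empirical
re-grading of a grade-mode cohort misclassifies severe categories by
construction. The `"lethality"` mode instead makes specified-anomaly births
die with their most lethal category's configured probability, which is what
the binomial-concentration properties of the grading module need. One
outcome model cannot satisfy both at once; tests use the mode that matches
the property under study, and parameter-recovery checks build their design
matrix from the generator's latent truth rather than from re-derived grades
(re-deriving would inject outcome-dependent misclassification — the same
circularity the empirical grading is known for).

What passing tests on synthetic cohorts do **not** show: fidelity to the
true joint covariate distribution of any real population, temporal trends,
cross-year death attribution, or recording quality. They show that the
pipeline's estimators recover the parameters of the model class they assume,
at the scales exercised.

## Validation machinery

Discrimination uses the rank-statistic AUC with DeLong confidence intervals
(via `pROC`; an exhaustive pair-counting oracle cross-checks it in the
tests). The per-cutoff table classifies positive at score ≥ cutoff for every
integer cutoff from 0 to max + 1 and reports sensitivity, specificity, PPV,
NPV (undefined when no record is classified negative), correctly-classified
percentage and the Youden index (sensitivity + specificity − 100), all as
percentages rounded half-away-from-zero to 2 decimals. The operating cutoff
is the Youden argmax, ties to the lowest cutoff. Births are stratified into
four groups (defaults 0–4, 5–9, 10–15, ≥16: Very Low to Very High risk); the
boundaries ship as configurable defaults rather than being re-derived, since
no boundary-selection algorithm is published — they reflect the published
distribution-and-death-pattern choice. Grouped calibration compares the mean
score with the observed death rate per group, and the score's explanatory
power is summarized by McFadden's pseudo-$R^2$ from a univariate logistic
fit (configurable in principle; McFadden is the flavor implemented). The
within-group death proportion (deaths / births in the group) is what the
group tables report; it coincides with the PPV at the top group's lower
cutoff only for the open-ended top group.

## Numerical choices and problem sizes

* Quadrature: `nAGQ = 11` default; tolerance and iteration control are
  `lme4` defaults. Aggregation to covariate patterns precedes every fit.
* The pooled-versus-multilevel likelihood-ratio test halves the
  $\chi^2_1$ tail probability, the boundary-corrected reference for a
  variance component tested at zero.
* Degenerate inputs guarded with errors: a single municipality, one record
  per municipality (non-identifiable $\sigma^2_u$), constant outcomes,
  zero-variance indicators, rank-deficient designs (collinear set named),
  protective (ln OR ≤ 0) conditions in the point scheme, overlapping strata.
* Perfect separation in univariate screens is flagged and the variable
  excluded with a warning rather than reported as an infinite estimate.
* Test problem sizes are chosen to exercise each property at the smallest
  scale where it is informative: registry-scale properties run once at
  200,000 births × 200 municipalities (the published random-intercept
  variance and ln(OR)s), transfer/stability checks at 100,000 births × 150
  municipalities with `nAGQ = 1`, and oracle equivalences at ≤ 500 records.

## Known limitations

* The empirical severity grading is circular by construction (the outcome
  defines the grades that then predict the outcome); the package mitigates
  this the same way the methodology does — single-anomaly subsets, maximum
  grade per birth, frozen tables for validation — but does not remove it.
* Conditions estimated with ln(OR) ≤ 0 cannot receive a weight; near-zero
  true effects can therefore make an otherwise-converged fit unusable for
  score building at moderate event counts. This is a property of the point
  scheme, not of the estimator.
* Municipal flags are contextual approximations assigned to every resident
  birth alike; interpreting them as individual exposures risks ecological
  fallacy.
* No imputation: records missing any final-model variable are excluded from
  modelling and receive missing scores.
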