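---
title: "Methods: intra-household allocation from repeated 24-h recalls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intra-household allocation from repeated 24-h recalls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhequity)
library(dplyr)
```

## The problem

In many South Asian settings food is not shared equally within a
household, and pregnant women — whose requirements are elevated — may
receive the smallest shares. `hhequity` implements a complete analysis
chain for quantifying such intra-household allocation from repeated
24-hour dietary recalls collected on a fixed triad of respondents per
household: the pregnant woman (PW), her mother-in-law (MIL), and the male
household head (HH), sampled within clusters (village development
committee areas).

The chain is:

1. **Nutrient engine** — portion records × food composition table (FCT)
   → per-visit intakes, 3-day mean intakes, food-group gram totals, and
   the Minimum Dietary Diversity for Women (MDD-W) score.
2. **Usual intakes** — Box-Cox transformation, then a linear mixed model
   per nutrient × role with random intercepts for cluster and individual;
   back-transformed best linear unbiased predictors (BLUPs) give each
   person's usual intake.
3. **Adequacy** — the IOM probability approach: each usual intake is
   compared with the requirement distribution to give a probability of
   adequacy (PA); the mean over 11 micronutrients is the MPA.
4. **Allocation ratios** — pairwise food shares (FS), food-share-to-
   energy-shares (FS:ES), relative dietary energy adequacy ratios
   (RDEAR), and MPA ratios, with log transforms.
5. **Inference** — cluster-adjusted tests of the log-ratio intercepts
   against zero (perfect equity), and multivariable mixed-effects models
   for the determinants of allocation, with variance inflation factors.

A synthetic-data generator with known ground truth stands in for field
data, so every stage is testable end to end.

## Models and conventions

### Nutrient totalling and MDD-W

Intakes are linear in grams: a portion of `g` grams of food `f`
contributes `g/100` times the FCT's per-100 g nutrient vector, and
portions are summed within a member-visit. No nutrient retention factors
are applied; composition values are used as entered. Mixed dishes are
resolved upstream to single FCT rows whose composition is the arithmetic
mean of replicate recipe observations (`average_recipes()`).

Mean daily intakes and food-group gram totals average over the recall
period (three visits; a visit with no recorded portions counts as a zero
day). The consumed-any flag per food group covers all three visits. The
MDD-W score counts, on the **first visit only** (the reference period for
which the indicator was validated), how many of the ten defined food
groups were consumed; five or more is "adequate". Alcohol is tracked as
an eleventh reporting group but never enters the score.

### Usual intakes

Single recall days are noisy; the usual intake is the quantity of
interest for adequacy. Daily intakes are first Box-Cox transformed,
`y = (x^λ − 1)/λ` (log at `λ = 0`), with `λ` chosen by maximising the
profile log-likelihood under normality. Zero intakes are handled by a
shift constant added before transforming — zero when all values are
positive, otherwise half the smallest positive value; this keeps the
transform defined without distorting the bulk of the distribution.

On the transformed scale, a linear mixed model is fitted separately per
nutrient and member role, with fixed stratum effects and random
intercepts for cluster and for individual nested in cluster (REML;
boundary fits with a zero variance component are accepted, which
corresponds to dropping that component). Each member's usual intake is
the plain inverse transform of intercept + stratum effect + cluster BLUP
+ individual BLUP. No back-transformation bias correction is applied by
default; a second-order correction is available via
`predict_usual(..., bias_correct = TRUE)` for sensitivity analysis.
When repeated visits are numerically identical (no day-to-day variance),
the model degenerates gracefully: the member mean is fitted at the member
level, the residual variance is reported as zero, and back-transformed
usual intakes equal the observed constant intakes.

### Probability of adequacy

For all nutrients except iron in non-pregnant adults, requirements are
taken as normal with the configured EAR mean and SD, and
`PA = Φ((usual − EAR)/SD)`. The shipped requirement table
(`default_requirements()`) covers the three roles and 11 micronutrients
(vitamin C, vitamin A, thiamin, riboflavin, niacin, vitamin B6, folate,
vitamin B12, iron, zinc, calcium), drawing on WHO/FAO values for the
vitamins, IOM for calcium and iron, and IZiNCG for zinc. Bioavailability
assumptions (iron 23% in pregnancy, 5% otherwise; zinc 25% for women,
18% for men) enter only through the requirement parameters — intakes are
never rescaled.

Iron requirements of non-pregnant adults are right-skewed, so their PA is
read from a table of probabilities per usual-intake interval. The
shipped table is constructed by `build_iron_probability_table()`: a
log-normal absorbed-requirement distribution (women: median 1.46 mg/d,
log-scale SD 0.39; men: median 1.0 mg/d, log-scale SD 0.20, chosen to
match the IOM percentile spread) is rescaled to dietary units at 5%
bioavailability, and each 0.25 mg interval receives the requirement CDF
at its midpoint. The interval width keeps the piecewise-constant table
within 0.02 of the continuous CDF everywhere — a bound verified in the
test suite against Monte-Carlo integration with 10^6 draws. The frozen
CSV in `inst/extdata/` is versioned output of this constructor.

The MPA is the arithmetic mean of exactly the 11 micronutrient PAs;
energy and protein are never included, and `mpa()` errors on any missing
or extra nutrient rather than silently renormalising.

### Energy requirements

Energy EARs multiply a per-kilogram coefficient (by sex and self-reported
activity level; Indian Council of Medical Research reference values, in
an editable table) by body weight, plus a fixed 390 kcal/d increment for
pregnancy. These energy EARs — not micronutrient EARs — feed the RDEAR.

### Allocation ratios

For members `a` and `b` of one household:

* `FS = grams_a / grams_b` per food group, defined only when both
  consumed any of the group over the recall period (the household is
  otherwise dropped for that group — no continuity corrections);
* `FS:ES = (grams_a / kcal_a) / (grams_b / kcal_b)`, identically equal to
  FS divided by the members' kcal ratio;
* `RDEAR = (kcal_a / EAR_a) / (kcal_b / EAR_b)`;
* `MPA ratio = MPA_a / MPA_b`.

Food-group ratios and RDEAR use 3-day mean intakes; MPA ratios use the
BLUP-based MPAs. Dietary diversity is compared as the log ratio of MDD-W
scores, and its energy-adjusted version subtracts the log kcal ratio.
All ratios satisfy `f(a,b) × f(b,a) = 1`; logs are antisymmetric under
pair reversal. Log MPA ratios below −8 are flagged as extreme outliers
and excluded from inference; the exclusion is one-sided (lower tail), as
a symmetric rule was considered and rejected in favour of the simpler
printed rule, with the threshold exposed as an argument.

### Inference

Perfect equity corresponds to a zero log ratio, so `test_equity()` fits
an intercept-only linear mixed model with a cluster random intercept and
tests the intercept against zero — maximum likelihood, with Wald-type
intervals and P values on a t reference with `n_clusters − 1` degrees of
freedom (a plain normal reference is anti-conservative with tens of
clusters: its measured type-I error at the default design is 6.4%
against 4.9% for the t reference), with significance at P < 0.05. When a rare food group leaves
every remaining observation in its own cluster, the cluster variance is
unidentifiable and the model reduces to the intercept-only fit; outcomes
with fewer than three usable observations or fewer than two clusters are
skipped rather than reported with meaningless intervals.

`fit_determinants()` adjusts simultaneously for all hypothesised
determinants — earnings parity between the pregnant woman and her spouse
(reference: earns less), gravidity (reference: no previous pregnancy),
the 0–10 empowerment score, the PCA-based asset score, household mean
energy intake per 1000 kcal, husband working overseas, caste group
(reference: the most disadvantaged group), and season (reference:
pre-monsoon) — with a cluster random intercept. A quadratic asset-score
term probes nonlinear wealth effects behind a flag. VIFs are computed as
`1/(1 − R²)` from regressing each design column on the others. Constant
covariates are dropped with a warning (leaving none, the model
degenerates to the equity test); genuinely collinear sets raise an error
naming the offending columns. Coefficients on log ratios convert to
percent statements via `pct_from_log()`: `100(exp(c) − 1)`% "higher" for
`c ≥ 0`, `100(1 − exp(c))`% "lower" otherwise, displayed half-up at one
decimal and then at integer precision.

## The synthetic-data generator

`sim_config()` defaults define the study conditions the package
emulates: 20 clusters × 8 joint households, each with exactly one
pregnant woman, mother-in-law and male household head; three recall days
per person; log-normal within-person day-to-day variation
(`sd_day = 0.25`); between-cluster and between-individual components of
log energy adequacy (`sd_cluster = 0.1`, `sd_individual = 0.2`); true
crude mean log-RDEARs of −0.20 (PW:HH) and −0.15 (PW:MIL); and an
earnings-parity effect of +0.27 on the pregnant woman's log-RDEARs.
The variance components are not reported by field studies of this
design; the defaults were chosen once as values that reproduce realistic
between-person spread in energy intake (circa 20–35% coefficients of
variation) and are stated in the configuration rather than claimed to
match any particular study.

Two design choices make recovery tests sharp:

* **Top-down intake generation.** Each member-day draws a target energy
  (true usual energy × a log-normal day factor), foods are included by
  per-role Bernoulli draws with log-normal raw portions, and all grams
  are rescaled so the day's summed energy matches the target exactly.
  Downstream totals are therefore controlled, and micronutrient intakes
  follow from the realised basket composition.
* **Truth on the adequacy scale.** True usual log energy is built as
  log(member's energy EAR) + role-level log-adequacy mean + cluster
  effect + individual effect + covariate effects. Because energy EARs
  vary with body weight, anchoring the roles on the adequacy scale (the
  household head's level plus the two configured pair contrasts) is the
  only way to pin each household's true log-RDEAR at the configured
  mean; anchoring on raw energy would let requirement variation leak
  into the ratios. Covariate effects are centred at their **realised
  sample mean**, so the crude mean of the true log-RDEARs equals the
  configured value in every generated dataset — exactly, when all noise
  SDs are zero — while a determinants regression still recovers the
  configured coefficient.

The optional household-calorie knob
(`hh_kcal_effect_on_log_mpa_ratio`) tilts the pregnant woman's odds of
consuming micronutrient-dense food groups with household mean energy;
because MPA is a nonlinear function of intakes, the induced coefficient
on the log MPA ratio is monotone in the knob but not numerically equal
to it, and it defaults to zero.

What the generator does **not** emulate: fasting/feasting spikes,
seasonal food availability, proxy-response error processes, correlated
food preferences within households, and measurement error in portion
sizes. Passing tests therefore demonstrate the correctness of the
estimators under the stated generative model, not robustness to these
real-data features.

A note on the recovery experiments: household mean energy intake is
mechanically a function of the pregnant woman's own intake, which makes
it endogenous to the RDEAR outcome. In recovery runs the determinants
model is therefore fitted with the exogenous covariate set (everything
except household kcal); with household kcal included, the estimand is a
conditional association that differs from the injected coefficient by
construction (about +0.03 at the default configuration). Analyses of
observed data keep the full covariate set, matching the convention of
the field.

## Numerical choices and degenerate inputs

* Box-Cox `λ` is searched on [−2, 2] by golden-section optimisation
  (tolerance 1e−6); `|λ| < 1e−8` is treated as the log limit.
* Back-transformation clamps at zero (intakes are nonnegative).
* `pa_iron_tabulated()` is piecewise constant: below the lowest bound it
  returns the lowest interval's probability, above the highest bound the
  highest.
* Equity tests on a response with zero variance return the observed
  constant with a degenerate interval and P = 1 at zero.
* Percent display uses half-up rounding (applied at one decimal and then
  at integer precision), never banker's rounding.
* All simulation randomness derives from a single integer seed; repeated
  runs are bit-identical, which the pipeline test verifies file by file.

## Problem sizes used in testing

The shipped tests run the full design (20 × 8 households) for recovery
experiments — 200 replicates for estimator means and confidence-interval
coverage, and 500 replicates for the type-I error of the equity test at
a true null — and smaller studies (3–10 clusters) for unit tests of the
pipeline stages. These sizes give Monte-Carlo standard errors a few times
smaller than the effects being recovered while keeping the suite quick to
run.

## Known limitations

* The usual-intake model is the single-part (amount-only) model; no
  two-part episodic-consumption machinery is included, so PA for rarely
  consumed nutrients leans on the Box-Cox normalisation.
* Iron PA for pregnant women treats the requirement as normal (EAR 22,
  SD 2.1 at 23% absorption); a full-probability treatment of pregnant
  iron is out of scope.
* The interval boundaries of any particular published iron PA table are
  not reproduced; the construction recipe (and its Monte-Carlo contract)
  is the specification.
* Ratios involving children or other household members, and
  adult-equivalent scaling, are out of scope.

## A worked example

```{r example, eval = FALSE}
study <- simulate_study(sim_config(seed = 1))
profiles <- intake_profiles(study$portions, study$visits, study$fct)
per_visit <- portions_to_intake(study$portions, study$fct)
usual <- usual_intakes(per_visit, study$members, study$households,
                       nutrients = hh_micronutrients())
adequacy <- compute_adequacy(usual$usual, study$members)
ratios <- allocation_ratios(profiles, study$members, adequacy)
equity_tests(ratios, study$households,
             outcomes = c("log_rdear", "log_mpa_ratio"))
```

The same chain, with per-stage CSV outputs and a run log, is
`run_pipeline(pipeline_config(seed = 1), "out/")`.
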