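---
title: "Methods: whole-grain intake groups, NRF 9.3 scoring and survey-weighted estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-grain intake groups, NRF 9.3 scoring and survey-weighted estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainscore)
```

## What the pipeline estimates

`grainscore` implements a dietary-surveillance analysis of the kind run on
the 2015 Canadian Community Health Survey (CCHS) – Nutrition: participants
report one 24-hr recall; foods are classified into 2007 Canada Food Guide
(CFG) categories and alignment tiers (1–2 aligned, 3 partially, 4 not
aligned); whole-grain (WG) foods are the "Grain products – whole" category,
all tiers 1–4, deliberately excluding WG contained in mixed dishes (which
carry no CFG assignment). The analysis then asks how nutrient intakes, food-
group intakes and overall diet quality vary across four WG exposure groups,
using the survey's sampling weights and bootstrap replicate weights.

The exposure accounting is:

* **WG grams/day** — summed grams of foods flagged whole grain.
* **WG servings/day** — grams divided by each food's serving size from the
  catalog. A consumed WG food with no serving size makes servings undefined
  (NA) for that participant, with a warning; grams are unaffected.
* **Total grain** — whole + refined grains, tiers 1–4.
* **Percent of grain from WG** — `100 × WG / total grain` per participant,
  averaged as the *mean of ratios*, never the ratio of means. A grain-free
  diet contributes 0 % rather than being dropped: the no-WG group includes
  grain-free diets, and group summaries should say 0, not NA. (Published
  descriptions of this quantity are ambiguous about numerator and
  denominator; only WG/total yields percentages bounded by the published
  values, so that direction is implemented.)

## WG intake groups

Participants reporting no WG food form the `no_wg` group. Consumers are cut
at the empirical 1/3 and 2/3 quantiles of WG grams within age stratum
(children 1–18, adults ≥ 19). Three conventions are fixed so the split is
deterministic and order-independent:

* **unweighted** sample tertiles — published group counts are near-equal in
  unweighted n, which is what unweighted cuts produce;
* **type-1 (inverse-CDF) quantiles** — the boundary is always an observed
  value;
* **ties go to the lower group** — with heavily tied data groups can be
  unbalanced (in the degenerate all-tied case everyone is `low_wg`, with a
  warning). With continuous gram amounts the three consumer groups differ
  in size by at most one.

A stratum with fewer than three consumers cannot be cut and raises a
stratification error; the pipeline records it and skips group-based tables.

## The modified NRF 9.3 score

Diet quality is the Nutrient Rich Food Index 9.3 adapted to the whole diet.
For participant *i* with energy $E_i$ (kcal) and daily intake $a_{in}$ of
nutrient $n$ with daily value $DV_n$:

$$
\mathrm{NRF}_i \;=\; \sum_{n \in \text{encourage}}
  \min\!\Big(100\,\tfrac{a_{in}\,(2000/E_i)}{DV_n},\; 100\Big)
\;-\; \sum_{m \in \text{limit}} 100\,\tfrac{a_{im}\,(2000/E_i)}{DV_m}
$$

with nine encourage nutrients (fiber, protein, vitamins D, C and A, iron,
calcium, potassium, magnesium) and three limit nutrients (total sugar,
sodium, saturated fat — total rather than added sugar, since added sugar is
not reported in the survey). Order of operations is energy-adjust → %DV →
cap: this is the only order in which "per 2000 kcal" and the 100 % cap are
both well defined per participant. Encourage contributions are capped so no
single nutrient dominates; limit contributions are uncapped so high intakes
keep lowering the score. The ceiling is therefore exactly 900. Both the cap
and the energy basis are arguments of `nrf93()` (defaults 100 %, 2000 kcal),
so a per-1000-kcal variant — which some descriptions of the index mention in
passing — can be explored without code changes; the package adopts the
2000-kcal basis throughout. Zero-energy diets cannot be energy-adjusted and
are scored NA with a warning. Daily values ship as an editable
Health-Canada-style reference table (`default_dv_table()`, `dv.csv`); the
values are convenience defaults, not a normative source.

## Covariates

Adjusted models use: energy intake as a **categorical** variable (weighted
quantile bins within stratum, default quintiles — categorical because the
energy pattern across WG groups is non-linear, and the bin count is a
parameter), continuous age, gender, overweight/obesity (adults BMI ≥ 25;
children BMI z-score percentile ≥ 75), low income (household income at or
below 19,999 / 39,999 / 59,999 CAD for household sizes 1 / 2–3 / ≥ 4), and
supplement use. Missing covariates are handled by listwise deletion with a
logged count. Extreme energy intakes are retained: the analysis includes
every participant with a recall, and an exclusion would be a separate
sensitivity analysis.

## Survey-weighted estimation

All group estimates are **least-squares means**: fit a weighted linear
regression of the outcome on WG-group indicators plus covariates, then
average the model prediction, with the group forced to *g*, over the
weighted observed covariate distribution. This "population marginal mean"
convention (weighted observed proportions rather than equal weighting of
covariate levels) matches survey-weighted reporting; the reference
distribution is recomputed per replicate so its sampling variability is
propagated.

Variance is design-based via replicate weights: every quantity is
re-estimated under each of the B bootstrap replicate-weight columns, and
$\widehat{\mathrm{Var}} = \tfrac1B \sum_b (\hat\theta_b - \hat\theta)^2$,
the scale appropriate for rescaled-bootstrap weights. Wald tests use
t-references with B − 1 degrees of freedom. Without replicate weights the
functions fall back to classical model-based SEs (useful for oracle
comparisons, not for design-based inference).

* **Trend tests** replace the group factor with ordinal scores 0–3
  (configurable; group medians of WG grams are a documented alternative the
  published methods do not distinguish) and Wald-test the slope.
* **Chi-squared tests** compute the Pearson statistic on the weighted
  contingency table scaled to the sample size — identical to the classical
  statistic under equal weights — then divide by a first-order design
  effect estimated from the replicate variances of the cell proportions
  (Rao–Scott style) before referring to $\chi^2_{(R-1)(C-1)}$.
* **Multiplicity**: Bonferroni within each outcome family — 0.05/22
  nutrients and 0.05/24 food groups (the published family sizes, kept as
  configuration defaults independent of the table row count); the single
  NRF outcome is tested at 0.05.
* **Post-hoc contrasts**: all six pairwise LS-mean differences with
  studentized-range (Tukey–Kramer) adjusted p-values,
  $q = \sqrt{2}\,|\Delta|/\mathrm{SE}(\Delta)$ against the range
  distribution with 4 means and B − 1 df, SE(Δ) from replicate differences.

Food-group tables use 22 stored cells — ten CFG categories × {tiers 1–3,
tier 4} plus discretionary and unclassified grams — with tier-block and
non-CFG totals derived by summation. Top WG sources are ranked within
stratum and consumer group by adjusted LS-mean grams per BNS (Bureau of
Nutritional Sciences) food group, with zero grams imputed for non-eaters of
a source, ties broken lexicographically, and the top-10 subtotal reported
with its share of total WG intake (raw weighted means are available behind
`adjusted = FALSE`).

## The synthetic-data generator

Real CCHS microdata cannot ship with the package, so `generate_catalog()` /
`generate_survey()` produce data with the same structure and *known* ground
truth. Defaults encode the study conditions: about 50 % of children and 54 %
of adults consume no WG food; WG grams among consumers are log-normal
(heavy right tail, matching tertile means that spread roughly 19→163 g/d in
children and 29→220 g/d in adults); energy is positively associated with WG
grams in children (≈1.2 kcal per WG gram) and not in adults; sampling
weights are log-normal with CV 0.5; B = 100 replicate weights come from a
Rao–Wu-style rescaled bootstrap over 50 simulated first-stage units per
stratum, each replicate calibrated to the stratum weight total. Default
sample sizes are 2000 per stratum — the scale at which the recovery
experiments below are run.

The key design choice is how nutrient gradients enter. Mechanically
realistic routes (putting fiber into the WG bread) make the true slope of
per-2000-kcal intake on WG grams depend on the energy distribution, so
"configured slope 0.041" would only be approximate. Instead the generator
separates roles:

* grain-category foods carry **mass only** (zero energy and nutrient
  density) — they drive exposure, stratification and the food-group tables;
* a pool of composite **baseline dishes** (the `unclassified` category,
  mirroring the mixed dishes that dominate unassigned food codes in real
  data) carries randomized density patterns scaled so expected per-2000-kcal
  intake matches realistic baselines; per-dish log-normal gram noise creates
  between-person variation;
* two **gradient dishes** have densities equal to the configured positive
  (and reflected negative) slopes and grams proportional to
  `wg × energy/2000`, so per-2000-kcal intake is *exactly*
  `baseline + slope × WG grams` in expectation — a configured null slope is
  exactly null. Negative gradients (folic acid tracking fortified refined
  grains, fats) pivot on a cap so densities stay non-negative;
* all scalable grams are renormalized so recall-derived energy equals the
  drawn energy exactly.

Default gradients are sized from the published adult no-WG→high-WG
differences divided by the WG-gram span (e.g. fiber +0.041 g, magnesium
+0.41 mg, folic acid −0.20 µg per WG gram per 2000 kcal). WG grams are
split across BNS sources by a Dirichlet draw around configurable expected
shares, dominated by the breakfast-cereal and bread sources as in the
published top-source tables.

What the generator does *not* emulate: multi-stage clustered sampling with
informative design (PSUs are assigned at random, so design effects are
mild), correlated covariates and confounding beyond the child energy–WG
link, food-level realism of nutrient co-occurrence (nutrients ride on
composite dishes), misreporting, or day-to-day intake variation (one recall
per person, no usual-intake modelling). Passing recovery tests therefore
demonstrates that the estimators are correct under the stated design, not
that the pipeline is robust to violations real surveys can exhibit.

## Verification at desk scale

Because the restricted microdata are unavailable, verification combines:

1. **Arithmetic identities** against published tables shipped as reference
   CSVs: top-10 source sums (52.9, 156.9, 216.2 g/d), the >680 % adult
   high-vs-low contrast, percent reductions in folic acid (21 % children,
   36 % adults) and discretionary foods (48 % adults), and the Bonferroni
   cutoffs 0.00227 and 0.00208.
2. **Property suites**: NRF ceiling of exactly 900, scale invariance and
   cap saturation on 1000 randomized profiles; mean-of-ratios convention;
   additivity of intake profiles; tertile monotonicity.
3. **Oracle equivalences**: with equal weights and no covariates LS-means
   equal group means to 1e-8; weighted fits match an independent
   normal-equations solver on 50 random designs; the chi-squared statistic
   matches the classical Pearson value; Tukey–Kramer p-values match the
   classical balanced-design test.
4. **Parameter recovery** on synthetic surveys at n = 2000 per stratum,
   B = 100, 50 seeds: trend tests on nutrients with a true-null gradient
   reject at the nominal 5 % level (observed rate required to lie in
   [0.02, 0.09]), and LS-mean contrasts against the no-WG group cover the
   exact generator truth within 2 replicate-SEs in ≥ 93 % of cases. The
   contrast (rather than the absolute level) is checked because the
   generator's baseline level involves a dish-composition expectation with
   no closed form, while the contrast truth is exactly
   `slope × weighted mean WG grams`.

These problem sizes keep the full suite under a minute of estimation time
while leaving binomial error on the recovery rates well inside the asserted
bands.

## Known limitations

* Tie and quantile conventions can move a few boundary participants
  relative to other software; published group counts are reproducible only
  up to the (unpublished) convention.
* Adjusted LS-means of non-negative outcomes can be slightly negative for
  sparse sources; the top-10 share can touch 100 % when a catalog has ten
  or fewer WG sources.
* The design-effect correction for chi-squared is first-order only; no
  Taylor-linearization variance or finite-population corrections are
  provided.
* Serving sizes are catalog fields; where the real survey supplies
  servings as a derived variable, catalog values must be prepared to match.
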