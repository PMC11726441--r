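---
title: "Cross-cohort diet-pattern microbiome analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort diet-pattern microbiome analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`microdiet` implements a complete multi-cohort pipeline linking habitual
diet patterns (omnivore, vegetarian, vegan) to gut-microbiome composition:
hPDI diet scoring from food-frequency questionnaires (FFQs), alpha/beta
diversity with PERMANOVA, cross-cohort differential-abundance and
correlation meta-analysis, random-forest validation, and food-to-gut
species overlap. Because the observational data such analyses are run on
are typically access-restricted, the package ships a synthetic multi-cohort
generator with planted, calibrated effects; every statistical claim the
test suite makes is checked against that generator's ground truth or
against closed-form and independent-package oracles.

# The core statistic: pooled adjusted standardized mean differences

For one diet pair (reference, comparison) and each species-level feature
(SGB), within every cohort we fit the ordinary least-squares model

$$\arcsin\sqrt{p_{ij}/100} = \beta_0 + \beta_g\,g_i + \beta_1\,\text{sex}_i
  + \beta_2\,\text{age}_i + \beta_3\,\text{BMI}_i + \varepsilon_{ij},$$

where $p_{ij}$ is the percent relative abundance of feature $j$ in sample
$i$ and $g_i$ indicates the comparison diet. The arcsine-square-root
transform stabilizes the variance of proportions; the adjusted Cohen's $d$
is $\hat\beta_g/\hat\sigma_\varepsilon$, with the usual sampling-variance
approximation $\mathrm{var}(d) = (n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))$.
Positive $d$ means enrichment in the comparison diet. Per-cohort Wald
p-values use the $t$ reference with residual degrees of freedom (the
normal reference differs negligibly at the cohort sizes involved; the $t$
is exact under the model and is what a linear-model summary reports).

Per-cohort effects are pooled by DerSimonian–Laird random-effects
meta-analysis: moment estimator for the between-cohort variance $\tau^2$,
inverse-variance weights $1/(v_i+\tau^2)$, normal-approximation 95% CIs,
Cochran's $Q$ and $I^2$. A single-cohort feature degenerates to that
cohort's effect with $\tau^2 = 0$ and $I^2$ reported as 0. Features whose
diet groups fall below the minimum per-cohort size (default 3) or whose
residual variance is zero are skipped in that cohort rather than imputed;
the pooled `k` records how many cohorts contributed. Benjamini–Hochberg
adjustment is applied in two separate families — per-cohort Wald p-values
within each cohort, and meta-analysis p-values across features — with
significance at $q < 0.1$. The implementation is unit-tested against
hand-evaluated DL arithmetic and against `metafor::rma(method = "DL")` on
random inputs to $10^{-9}$.

`run_diffabund_meta()` evaluates all features of a cohort through a single
QR decomposition of the shared design matrix; the test suite asserts exact
agreement with the per-feature `adjusted_cohens_d()` path.

# Correlation meta-analysis

Partial Spearman correlations adjust feature abundance versus exposure
(food-group intake or hPDI) for sex, age and BMI. All variables, the
numeric covariates included, are rank-transformed before residualization —
this is the convention under which a variable that is an exact monotone
function of a covariate is fully explained away, which a raw-scale
residualization does not achieve. Per-cohort correlations move to the
Fisher $z$ scale, are pooled with the same DL machinery and back-transform
by $\tanh$. The $z$-scale variance uses $1/(n-3-k)$ with $k$ adjustment
covariates; `fisher_df = "classic"` reproduces the plain $1/(n-3)$
convention of generic meta-analysis tooling. Consumer-population rules
restrict who enters each correlation: meat groups use omnivores only,
dairy/eggs/animal-fat use omnivores and vegetarians, produce groups use
everyone, and hPDI correlations run within a single diet pattern.

Because Spearman correlation is rank-invariant, the arcsine-square-root
transform applied for consistency with the SMD stage does not change the
correlations; it is kept so both stages consume the same matrix.

# hPDI scoring

Eighteen FFQ food groups each contribute a quintile score of 1–5: healthy
plant groups score positively (above the top quintile cutpoint of the
scored population scores 5), less-healthy plant and animal groups score in
reverse. The total therefore spans 18–90. Quintile boundaries are computed
from the scored population per cohort by default (`stratify_by_cohort`),
since cohort FFQ instruments differ; a pooled mode exists. Ties at a
boundary fall into the lower bin — the source convention is unstated, and
this choice is fixed and documented so scores are reproducible. Interior
bins score 2–4 in bin order, the natural completion given that only the
extremes are pinned by the definition. The item-to-group mapping, with its
positive/reverse flags, is user-supplied data: the canonical 18-group
composition is instrument-specific and proprietary.

# Diversity

Observed richness is the count of strictly positive features. The richness
outlier rule removes samples outside the central 95% percentile interval
(2.5th–97.5th); an interval of a *mean* would remove nearly every sample
in large cohorts, so the percentile reading is the only self-consistent
one. The filter is pooled by default and applied per cohort by calling it
per stratum. Groupwise comparisons use Kruskal–Wallis with tie correction,
followed by Dunn's rank-mean $z$ contrasts with tie-corrected variance and
BH adjustment within the pairwise family.

Beta diversity offers Bray–Curtis (via `vegan`), Aitchison (CLR on
proportions after multiplicative pseudocount replacement of zeros, default
half the smallest nonzero proportion of the table — the upstream tooling's
default is undocumented, so the choice is explicit and configurable), and
unweighted/weighted UniFrac from a user-supplied newick tree. Unweighted
UniFrac is branch length unique to one of the two feature sets over the
branch length of their union; the implementation enumerates edge-tip
incidence directly and is verified against hand-enumerated toy trees and
against `picante::unifrac`. The weighted variant is the normalized form.
PERMANOVA delegates to `vegan::adonis2` with terms assessed sequentially
in the fixed order sex, scaled age, scaled BMI, diet — diet last, so its
$R^2$ is the variance explained after the covariates — with 999 free
permutations by default.

# Machine-learning validation

Probability random forests (via `ranger`) with the study configuration:
1,000 trees, minimum 10 samples per leaf, no depth limit, Gini impurity,
`mtry` = 10% of the feature count. Three schemes: per-cohort stratified
repeated k-fold CV; leave-one-dataset-out (train on all other cohorts,
test on the held-out one); and cross-LODO, the hybrid in which every CV
training fold of the target cohort is augmented with all pair-labelled
samples of the other cohorts while test folds remain strictly
target-cohort. Support samples are restricted to the two diet labels under
comparison, since the models are pairwise and a third label would break
the binary AUC. Class imbalance (~92% omnivores) is handled by
stratification only — no class weights — matching the defaults of the
standard metagenomic ML tooling. Per-test AUCs are computed per fold;
curve averaging linearly interpolates each test's ROC onto a common FPR
grid, anchors the averaged curve at (0,0) and (1,1), and builds a 95% band
from the bootstrap standard error of the mean under a $t$ reference.

The full profile (1,000 trees, 10×10 folds) is expensive at ~20k samples;
the packaged experiments and tests use the first-class `scaled` profile
(200 trees, 5×5 folds), which preserves every structural property being
validated. The label-permutation negative control permutes diet labels
within each cohort before splitting; at the scaled problem size
(3 cohorts × 400 samples, ~12 vegans per cohort) a single permutation's
mean AUC scatters around 0.5 with a standard deviation near 0.03, so the
acceptance test estimates the null mean over three permutations rather
than one draw.

Per-feature presence prediction from FFQs models features whose
within-cohort prevalence lies in [10%, 90%], runs the repeated CV per
cohort, summarizes the cohort AUC with standard error
$\mathrm{sd}/\sqrt{\text{tests}}$, and pools cohorts with the same DL
estimator.

# Food-to-gut overlap

A feature is a *food SGB* when detected at ≥0.1% relative abundance in ≥4
food samples of a food-metagenome catalog; a called food SGB is a
*signature* of meat, dairy or fruits/vegetables when its prevalence in
that category strictly exceeds 0.1%. The inclusive/strict threshold pair
is encoded exactly as defined. Per-sample statistics are the count of
distinct food SGBs present and their cumulative relative abundance; zeros
are retained. Prevalence differences across diets use the Pearson
chi-squared statistic with a fixed-margins Monte-Carlo p-value (99,999
replicates via `stats::chisq.test`), group contrasts reuse the Dunn
machinery, and health-rank comparisons of two signature sets use the
equal-variance two-sample t-test preceded by Levene's check (via `car`).
Zero-inflated mixed models for the same contrasts are out of scope here;
the Dunn path covers the group comparisons.

# The synthetic generator

`simulate_cohorts()` emulates the study design: by default five cohorts of
strongly unequal size (1062, 12353, 7931, 118, 97), diet proportions
0.92/0.05/0.03, 200 sparse compositional features closing to 100 per
sample, sex ~ Bernoulli(0.5), age ~ N(45, 12²) truncated at 18, BMI ~
N(25, 4²) truncated at 15. Feature log-means spread with sd 1.5,
within-cohort log-abundance sd 1.0, and a per-cohort-by-feature random
shift with sd 0.3 supplies between-cohort heterogeneity. Per-feature
detection prevalence is drawn Uniform(0.2, 0.95) unless configured;
signature and food features are fixed at 0.9 so abundance effects stay
identifiable. These values are choices of realism, not estimates: they
produce abundance distributions, sparsity and cohort imbalance of the
right general shape, while making no attempt at phylogeny, strain
structure or read-level noise — so passing tests demonstrate correctness
of the statistical machinery, not biological fidelity of any particular
effect-size landscape.

Planted effects are specified in SMD units *on the analysis scale*: a
generator-side Monte-Carlo calibration (common random numbers, 10,000
draws) finds the log-scale multiplier whose expected adjusted Cohen's d on
arcsine-square-root proportions equals the target. Two details matter.
First, the standardizing residual SD of the downstream OLS is the
group-size-weighted pooled SD, so the calibration weights the group
variances by the configured diet proportions — with a 50/50 weighting the
planted effects overshoot by tens of percent under 92/3 imbalance. Second,
compositional closure couples the signature features (each elevated
feature deflates the others' proportions in the comparison group), so the
calibration iterates three passes, recalibrating each feature against
totals that include the others' current multipliers. After both
corrections, recovery is unbiased within Monte-Carlo error across
$d \in \{0.2, 0.5, 1.0\}$ and pooled 95% CIs cover the target in ≈95% of
replicates. Calibrated multipliers are exposed in the truth record.
Zero-inflation is applied after effect planting so prevalence and
abundance effects are controlled independently.

FFQ intakes are log-normal per item with diet-dependent group means:
diet-excluded groups (all animal groups for vegans; meat and fish for
vegetarians) are zero, and healthy-plant group intakes rise by a
configurable log-scale step (default 0.6) along omnivore → vegetarian →
vegan, which makes hPDI separate the diet patterns as expected.
Designated food features (default 12, split across dairy, meat and
fruits/vegetables) have detection odds that follow the standardized intake
of their matching FFQ group on the logistic scale (default slope 2), so
food-SGB counts drop in vegans and FFQ-based presence prediction has
planted signal. Note the food features are therefore genuinely
diet-associated — null-calibration experiments set `n_food_features = 0`.

One master seed fans out through a fixed splitting rule
(`seed + 1000003·k`), so adding a cohort never perturbs earlier cohorts
and identical seeds give byte-identical output.

# Problem sizes and determinism

The packaged experiments run at desk scale by choice: 3 cohorts of
400–500 samples and 200 features for the classification and recovery
experiments, the `scaled` RF profile throughout, 99–999 permutations for
permutation tests. All randomness funnels through explicit seeds; split
lists, forests, permutation p-values and Monte-Carlo p-values reproduce
bit-for-bit for a fixed seed. Degenerate inputs fail loudly: zero-sum
samples for distances, rank-deficient designs, infeasible simulation
configurations (a cohort drawing zero members of a planted contrast),
zero-margin contingency tables.

# Known limitations

* The generator's closure step means even "null" features are weakly
  negatively coupled to planted ones; at the default effect counts this is
  far below detectability, and the FDR-control tests confirm it.
* DL is the only heterogeneity estimator (no REML, no Hartung–Knapp), as
  the pipeline's conventions dictate.
* The weighted UniFrac variant is provided but optional; headline analyses
  use the unweighted form.
* The per-cohort linear mixed model for richness and zero-inflated mixed
  models for food-SGB counts are intentionally out of scope; Kruskal–Dunn
  covers those contrasts.
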