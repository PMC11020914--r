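---
title: "Multimorbidity subgrouping of heart-failure cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity subgrouping of heart-failure cohorts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Most heart-failure (HF) patients carry several chronic conditions at once,
and the combinations matter clinically: an anaemic, renally impaired
octogenarian and an obese hypertensive with atrial fibrillation are both
"HF with multimorbidity" yet follow very different trajectories. `hfpheno`
implements an end-to-end, unsupervised workflow for finding such subgroups
in EHR-derived tabular data and characterizing them: mixed-type clustering,
phenotypic disease networks, per-cluster profile tables with hypothesis
tests, and survival stratification by unplanned hospital admissions.
Because real hospital EHR extracts of this kind are access-restricted, the
package ships a synthetic cohort generator with planted subgroup structure,
so every stage of the workflow runs, and is tested, without external data.

This vignette records the models, the tunable parameters, and the design
decisions taken where more than one reasonable choice existed. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Cohort identification

Patients enter the cohort if any diagnosis record matches an HF ICD-9-CM
code prefix or a free-text keyword. Codes are normalized by stripping dots
before prefix matching, so `"428.0"` and `"4280"` are equivalent; the
default prefixes are the 428 family, the hypertensive heart/kidney disease
codes with HF, and the 425.4–425.9 cardiomyopathies (`hf_icd9_codes()`).
Keyword matching (`hf_keywords()`) is case- and diacritic-insensitive
substring containment, so `"Insuficiência cardíaca"` also matches
unaccented spellings. No further text processing is attempted: free-text
handling is deliberately limited to literal containment.

## Preprocessing

The preprocessing rules are fixed and order-deterministic:

1. **Aggregation** (`aggregate_patient_features()`): labs and BMI are the
   mean over all of a patient's observations — a single recent anomalous
   value should not define a patient — while age is taken at the last
   observation and comorbidity flags are ever-present. The default
   synthetic cohort is already one-row-per-patient, so this step matters
   only for longitudinal inputs.
2. **Prevalence filter**: binary features with cohort prevalence strictly
   below 2% are dropped.
3. **Missingness filter**: features with strictly more than 40% missing
   cells are dropped. Both inequalities are strict, so a feature exactly at
   a threshold is kept; every dropped column is recorded in an audit table.
4. **Imputation** (`impute_chained()`): chained-equation imputation with a
   linear ridge regressor per incomplete column, initialized at column
   means, iterated (default 10 sweeps) until the largest change of any
   imputed cell falls below 1e-3. The ridge penalty is a tiny multiple of
   the predictor scale and exists only for numerical stability under
   collinearity; with an exact linear relation in the data the imputed
   values reproduce it to ~1e-6. Observed cells are never modified — the
   suite asserts this cell by cell.
5. **Scaling** (`scale_features()`): continuous features are z-scored with
   the population (1/n) standard deviation; binary features map
   {0,1} → {−0.5,+0.5}. Scaling is idempotent, and zero-variance continuous
   columns raise an error (they indicate a degenerate simulation spec
   rather than something to silently drop).

The Gower pathway consumes the *unscaled* matrix: the range normalization
inside the Gower formula makes prior z-scoring redundant. The scaled matrix
feeds the FAMD pathways and the coordinate-based validity indices.

## Patient clustering

Three pathways are evaluated, reflecting common practice for mixed-type
EHR data:

* **Gower + Ward.** The Gower dissimilarity between patients $x$ and $y$
  over $m$ features is
  $$d_G(x, y) = \frac{\sum_{j=1}^m w_j\, f_j(x_j, y_j)}{\sum_{j=1}^m w_j},
  \qquad
  f_j = \begin{cases}
    |x_j - y_j| / r_j & \text{interval feature, range } r_j\\
    \mathbf{1}[x_j \neq y_j] & \text{categorical feature,}
  \end{cases}$$
  with unit weights throughout. Binary comorbidity flags are treated as
  categorical (match/mismatch). A dissimilarity must vanish for identical
  records, so the mismatch indicator form is used. Ward linkage is applied
  to this matrix via the Lance–Williams recursion
  (`stats::hclust(method = "ward.D2")`). Ward's variance objective is exact
  only for Euclidean input, so Ward-on-Gower is a heuristic — a documented
  caveat, retained because this pairing is precisely the practice the
  package implements and evaluates.
* **FAMD + Ward** and **FAMD + K-means.** Factor analysis of mixed data:
  continuous columns are z-scored; each level of a categorical column
  becomes an indicator divided by $\sqrt{p_\text{level}}$ and centred; the
  combined matrix is factored by truncated SVD, acting as PCA on the
  quantitative block and MCA on the qualitative block. The embedding keeps
  the smallest number of components explaining ≥ 80% of inertia
  (overridable); component signs follow the largest-loading-positive
  convention so results are platform-stable. Ward or K-means
  (`stats::kmeans`, 10 random restarts, best inertia, seeded) then runs in
  embedding space. K-means++ seeding is not used — determinism plus
  multiple restarts serves the same robustness end with the tools R
  provides.

Cluster ids are relabelled 1..k by decreasing cluster size in every
pathway, which makes labels comparable across methods and runs.

## Model selection

Every (method, k) configuration for k in 2..12 is scored with three
internal validity indices:

* mean silhouette width — on the Gower matrix for the Gower pathway and on
  Euclidean embedding distances for the FAMD pathways, with singleton
  clusters contributing 0;
* Calinski–Harabasz, $[\mathrm{tr}(B)/(k-1)]\,/\,[\mathrm{tr}(W)/(n-k)]$;
* Davies–Bouldin, the mean worst-case $(s_i + s_j)/d_{ij}$ over cluster
  pairs.

Calinski–Harabasz and Davies–Bouldin need coordinates, which a bare Gower
matrix does not provide; for the Gower pathway they are computed on the
scaled feature matrix. This is a genuine design gap in the underlying
procedure and the choice is surfaced here deliberately.

A configuration is *admissible* only if its smallest cluster strictly
exceeds the size floor, `max(375, 10% of n)` by default — a stability
floor that discards solutions with clinically unusable slivers. Each index
nominates its best admissible configuration and the configuration taking
at least two of three nominations wins (`majority_vote()`). A three-way
split is an error carrying the full tally: the tie the floor cannot break
is, in the original procedure, resolved by clinical interpretability,
which no formal rule captures honestly; callers may pass `prefer_k` to
encode that judgement explicitly.

## Phenotypic disease networks

For any patient subset, the PDN has a node per disease with nonzero subset
prevalence and an edge between two diseases whose co-occurrence prevalence
(fraction of the subset carrying both) is at least 2% — pairs strictly
below the threshold are discarded, and the denominator is always the
subset's own size, so per-cluster networks and the whole-cohort network
use the same rule. Reported metrics are the average degree $2|E|/|V|$ and
the mean unweighted local clustering coefficient (nodes with fewer than
two neighbours contribute 0). Weights affect export and visual thickness
only; topology-level metrics are deliberately unweighted so that a
complete graph scores exactly 1. Networks export to GraphML (for
visualization tools) plus node/edge CSVs that round-trip losslessly
through `read_network()`.

## Cluster profiles

`summarize_clusters()` reports median (IQR) per cluster for continuous
characteristics with a Kruskal–Wallis test across clusters, and
percentages with a Pearson chi-square test (no continuity correction) for
binary ones, flagging significance at p < 0.05 per row. Choices the
underlying procedure leaves open: quantiles are type-7 (linear
interpolation); no multiple-testing correction is applied by default,
mirroring the per-row 0.05 rule (a Benjamini–Hochberg adjustment can be
applied downstream from the returned p-values). Prescription summaries
count a patient once per pharmacological group (at-least-one-prescription
prevalence) and average per-patient prescriptions per year over the
follow-up window; admission summaries report median (IQR) events per
patient-year — person-time runs from diagnosis to the censor date — and
the percentage of patients with an event within one year and within the
observation period.

## Survival stratification

All patients are aligned at $t_0$ = HF diagnosis. For each outcome
(hospitalisation, emergency admission), duration is time to the first
qualifying event, with administrative censoring at the configured date or
horizon; events dated at or before diagnosis are excluded with a warning.
Kaplan–Meier curves per cluster use the product-limit estimator with
Greenwood bands; groups are compared with the K-group log-rank test. Three
Cox proportional-hazards specifications are fitted with Efron tie
handling: Model 1, cluster dummies only; Model 2, + age and gender; Model
3, + NT-proBNP. Hazard ratios are reported against the reference cluster,
chosen per outcome as the one with the lowest observed event percentage;
when outcomes disagree about the lowest-risk cluster each outcome keeps
its own reference. Gender is coded female = 1. Constant covariates are
dropped from a model rather than failing the fit; rows with missing
NT-proBNP are dropped by the partial likelihood in Model 3.

## The synthetic cohort generator

`cohort_spec()` fixes every generator parameter: mixing proportions,
per-cluster disease prevalences, a Gaussian-copula correlation for
comorbidity co-occurrence (latent multivariate normal thresholded at each
disease's marginal quantile — the simplest mechanism that gives exact
marginals with controllable pairwise co-occurrence), per-cluster lab means
and sds with MCAR missingness (an optional MAR switch makes missingness
logistic in age), and per-cluster admission hazards. Event times follow a
homogeneous Poisson process, so first-event times are exponential and
proportional hazards holds exactly — which is what makes hazard-ratio
recovery a meaningful end-to-end check. Identical spec and seed reproduce
byte-identical CSVs.

**What the defaults represent.** `default_cohort_spec()` plants four
subgroups (n = 2000; mixing 0.22/0.23/0.32/0.23) whose *qualitative*
pattern follows subgroup structures reported for real HF cohorts: a
male-predominant high-burden cluster (ischemic cardiomyopathy, diabetes,
AF, CKD, near-universal anaemia, highest NT-proBNP and urea/creatinine);
a hypertension/AF/obesity cluster with the highest BMI; a large
anaemia-dominant cluster with otherwise low burden and normal renal labs;
and a young, female-predominant low-burden cluster. Every number is a
synthetic stand-in chosen by us, not an estimate of any real population.

**Why the defaults are as sharp as they are.** The generator's defaults
are the package's reference *study conditions*: planted structure must be
recoverable (Gower+Ward at k = 4 reaches ARI ≥ 0.8) and the majority vote
must select k = 4 reliably across seeds. Two geometric facts drove the
calibration. First, internal validity indices reward coarse 2-splits
whenever one cluster is much farther from the rest than the others are
from each other, or when many features align on a single axis; the four
subgroup signatures are therefore balanced to comparable magnitude
(near-equidistant geometry), e.g. the anaemia-dominant cluster gets normal
renal labs so it does not simply shadow the high-burden cluster. Second,
within-cluster spread must be small relative to between-cluster contrasts:
signature prevalences sit at ≥ 0.85 rather than mid-range (a Bernoulli
feature at p = 0.5 contributes maximal mismatch noise), and lab sds are
tight — defensible because the lab features emulate per-patient *means*
over repeated observations, which are considerably less dispersed than
single measurements. Prevalence contrasts of at least ~0.6 on
distinguishing diseases and lab shifts of ≥ 2 within-cluster sds are the
conditions under which recovery is asserted; weaker separation degrades
ARI and pushes the vote toward k = 2, which is expected behaviour, not a
defect.

**What the generator does not emulate.** Longitudinal lab trajectories,
visit calendars, disease-onset ordering, informative (outcome-dependent)
missingness, free-text notes, competing mortality risk, and non-constant
hazards. Passing tests on this generator therefore demonstrate that the
pipeline's machinery is correct and that planted structure of the stated
strength is recovered; they do not demonstrate that any particular real
EHR cohort contains four subgroups, nor calibrate the indices' behaviour
under time-varying hazards or informative censoring.

## Numerical choices and degenerate inputs

* Seeds: one global seed deterministically derives per-stage seeds
  (`derive_seed()`), so stages rerun independently yet reproducibly; all
  derived seeds stay below $2^{31}$.
* Gower with a zero-range interval feature, all-zero weights, FAMD
  components beyond the matrix rank, k > n (Ward) or k > distinct rows
  (K-means), indices at k = 1 or k = n, duplicate Davies–Bouldin
  centroids, zero-margin contingency tables, all-tied Kruskal–Wallis
  input, empty PDN subsets, and censor dates preceding diagnosis are all
  explicit errors rather than silent degradation.
* Ties in cluster-size relabelling break by first appearance, making
  label assignment deterministic.
* The problem sizes used by the suite — n = 2000 for recovery and
  hazard-ratio checks, n = 5000 for calibration bounds, 200 replicates for
  log-rank type-I error, 20 replicates for vote stability — were chosen
  as the smallest sizes at which the corresponding statistical tolerances
  (binomial bounds, ±15% HR error) are comfortably non-vacuous.

## Known limitations

Ward-on-Gower lacks Ward's variance-objective guarantee; the
coordinate-based indices for the Gower pathway are computed on a different
representation than the distances that produced the labels; silhouette
values are compared across non-commensurable representations in the joint
vote (as in the underlying procedure); the chained imputer is linear and
will under-impute strongly nonlinear lab relationships; and the
majority-vote error on three-way splits means fully automated runs on
weakly structured data must either widen `k_range`, set `prefer_k`, or
accept failure as the honest outcome.
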