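---
title: "Onset-stratified analysis of adolescent binge drinking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Onset-stratified analysis of adolescent binge drinking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistics: the model behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design choices made where more than one
defensible option existed.

## The analysis problem

Three-wave adolescent cohorts (assessments at ages 14, 16, 19) allow
drinkers to be stratified by the *onset* of binge drinking, operationalized
as the first wave at which the ESPAD-banded count of lifetime drunken
episodes reaches a threshold (default: band ≥ 2, i.e. three or more
episodes). Five groups result: long-term (onset by 14), medium-term (onset
at 16), short-term (onset at 19) drinkers, and two control groups with zero
lifetime drunkenness. Long- and short-term drinkers plus Control I form the
training sample; medium-term drinkers plus Control II are a genuinely
held-out test sample, because under the working hypothesis — earlier and
heavier exposure leaves larger feature alterations — medium-term drinkers
should show *intermediate* deviations the model never saw during training.

Three feature domains enter: a per-subject resting-state functional
connectivity (rsFC) vector (upper triangle of a region-by-region
correlation matrix; 19,900 links for 200 regions), binary SNP mutation
indicators, and personality scores (SURPS, NEO-PI-R) with covariates sex
and acquisition site.

## Stage 1 — candidate features and stability selection

Within each training stratum (long-term vs Control I; short-term vs
Control I):

1. Connectivity is residualized on sex and site (indicator coding plus
   intercept, least squares). The adjustment is estimated once per stratum:
   it is a ~10-parameter nuisance fit whose dependence on any single
   subject is O(1/n), and the held-out test sample is never involved.
2. A lasso-regularized logistic regression of drinker status on all links
   selects candidate links. The penalty is chosen once per stratum by
   10-fold cross-validated deviance (`lambda_rule = "1se"`, the sparsest
   penalty within one standard error of the deviance minimum) and then held
   fixed while the model is refit on every leave-one-out subsample.
   Re-running the penalty search inside each fold changes the selected
   penalty negligibly (folds differ by one subject) at roughly 100× the
   cost.
3. SNPs are screened per fold by 2×2 chi-squared tests (no continuity
   correction) of carrier frequency at `chi2_alpha = 0.001`. The level is a
   package default — small enough that the candidate set stays compatible
   with stability selection over ~600 loci; it is a config knob.
4. Features selected in strictly more than `retention_threshold = 0.9` of
   the n leave-one-out refits are retained; the direction (increased /
   decreased link, risk / protective SNP) is the majority sign, and a
   feature whose sign ties across folds is dropped, because an inconsistent
   direction contradicts the signed summary scores.

Retained features collapse to four per-subject scores: iFC and dFC sum the
(residualized) connectivity over increased and decreased links; rSNP and
pSNP count carried mutations over risk and protective SNPs. Raw sums are
used rather than z-scored sums or supra-threshold counts; the alternative
readings remain available by transforming the inputs.

The final link set comes from the long-term stratum and the final SNP set
is the intersection of both strata's retained sets (with consistent roles),
mirroring the empirical pattern that connectivity discriminates strongest
where exposure is longest while genetic predisposition discriminates in
both strata.

The per-stratum classifier (covariate indicators + the four scores, linear
SVM) is evaluated by leave-one-out, with selection and scoring redone
inside every fold, so its accuracy and AUC are honest for the stratum.
Domain contributions use the continuous net reclassification improvement:
NRI = (P(up|case) − P(down|case)) + (P(down|control) − P(up|control)),
z = NRI/√(4/n₁ + 4/n₀). No risk categories exist here, so the category-free
variant is the only coherent choice; and because margins of different
feature sets are not on a common risk scale, each model's LOO decision
values are standardized before the movement comparison.

## Stage 2 — the hypothesis-of-trend filter

Candidate summary and personality scores are residualized on sex and site
and tested with the Jonckheere–Terpstra statistic across the five groups in
the fixed order Control I < Control II < short < medium < long (the two
control groups' relative position is a recorded convention; they carry no
exposure ordering). JT sums pairwise "lower group value < higher group
value" counts with ½ credit for ties. Features expected to *decrease* in
drinkers (dFC, pSNP) are negated so one code path serves both directions;
the direction is otherwise inferred from the pooled drinkers-minus-controls
mean. One-sided p < `alpha = 0.05` retains a feature. Tiered significance
stars are a display matter; 0.05 is the package's selection default and a
config knob.

`jt_test()` provides three null modes: the tie-corrected normal
approximation (default at n > 40); an exact null for tie-free data via
convolution of Mann–Whitney distributions, using the decomposition of JT
into independent rank statistics of each group against the pool of its
predecessors; and exhaustive enumeration of group assignments for small
tied samples. Fully tied data return z = 0, p = 0.5 by convention. The
exact modes agree with brute-force enumeration (tested on all 90 tie-free
3×2 rank patterns), and the asymptotic p stays within 0.02 of exact for
4×4 designs.

## Stage 3 — the hierarchical classifier

The two-layer stack: SVM1 (covariates), SVM2 (trend-surviving summary
scores, default candidates iFC/rSNP/pSNP — dFC is computed and reported but
not fed forward), SVM3 (trend-surviving personality scores). Each in-layer
model is evaluated by leave-one-out on the training sample, and SVM4 is
trained on the three LOO decision values — so no subject's out-layer input
came from a model that saw that subject. At test time the in-layer models
refit on all training subjects feed SVM4.

All four classifiers are linear by default: after reduction the inputs are
3–5 dimensional, where a nonlinear kernel is unjustifiable (RBF remains a
config option). Cost is fixed at C = 1; class weights are inverse
prevalence, since the training sample has 95 drinkers vs 44 controls and an
unweighted fit degenerates toward majority prediction. Decision signs are
normalized so a larger value always means "more likely a drinker". Features
are standardized with training-estimated constants (constant columns get
unit scale). Linear fits are stored in primal form (weights + intercept),
so models serialize to JSON (17 significant digits) and reload with
bit-identical predictions.

If no feature survives the trend filter for a domain, the classifier falls
back to that domain's full candidate set and flags it in the report. This
keeps the pipeline well-defined on null cohorts, where nothing should and
nothing does survive filtering.

Held-out evaluation reports overall accuracy, accuracy stratified by
lifetime-occasion band within controls and lifetime-binge band within
drinkers, and each input's contribution as |Pearson r| with the SVM4
output, with seeded percentile-bootstrap confidence intervals (default
5,000 resamples) for the difference between each score's contribution and
the covariate layer's. At the generator's default effect sizes the held-out
accuracy sits near ceiling, which compresses the within-drinker severity
gradient of stratified accuracies; the gradient is informative at weaker
planted effects.

## Stage 4 — longitudinal trajectories

Only short-term drinkers have a clean pre-onset period (14→16) and
post-onset period (16→19), so the developmental analysis contrasts them
with the pooled controls. Difference scores are within-subject changes per
period. Two covariate-handling rules, each with a reason:

* For the repeated-measures ANOVA, per-wave sex/site adjustments are
  estimated **on controls only** and applied to everyone. Fitting them on
  the pooled subsample would absorb a large part of the drinkers' own
  post-onset dynamics into the adjustment (drinkers are 41 of 106 subjects
  there).
* The paired sign-flip permutation test uses **raw** within-subject
  differences: subject-constant covariate effects cancel exactly in a
  difference, whereas any estimated adjustment adds one shared random
  offset to every drinker — which breaks the sign-flip exchangeability and
  inflates the test's size (measured: ~16 % instead of 5 % on a scale with
  no planted attenuation).

The permutation test flips the sign of each pair's difference
independently (the only reading of a "permutation of the paired" values
consistent with the pairing), uses the median as its statistic (the mean is
a config option), applies the add-one convention p = (1 + #{|stat*| ≥
|stat|})/(1 + n_perm) to avoid p = 0, and switches to exhaustive
enumeration of all 2ⁿ sign patterns for n ≤ 12. Sign patterns are
exchangeable, so differences are sorted first, making the Monte-Carlo
p-value invariant to pair order.

The time-by-group interaction uses the classical mixed-design ANOVA with
the subject-within-group error term, reported with both the uncorrected and
the Greenhouse–Geisser-corrected p (epsilon from the pooled within-group
covariance of the repeated measures). The same machinery runs on the two
difference scores as a two-level within factor.

## The synthetic cohort: what it emulates, and what it does not

The generator reproduces the structure the analysis assumes — group sizes
54/52/41/44/21, banded non-decreasing ESPAD trajectories consistent with
each group's onset wave, sex proportions per group, site effects on all
continuous measures (so covariate adjustment is non-trivial), Fisher-z-like
connectivity (mean 0.2, SD 0.15 per link; link values are generated
directly because the analysis consumes nothing else from the fMRI),
independent binary SNPs (carrier probability 0.25; no linkage structure),
and three-wave personality trajectories with a subject-level intercept
(SD 1.7) and occasion noise (SD 0.6 for impulsivity).

Planted effects encode the working hypothesis. Connectivity: 8 increased
and 4 decreased links at 0.30 connectivity units, scaled per drinker group
by the gradient (1, 0.6, 0.3). SNPs: 12 risk and 12 protective loci at
log-odds 1.5 — *not* gradient-scaled by default (`snp_trend = TRUE`
restores scaling), because a genetic predisposition is constant over time
and the empirical pattern shows genetic contributions in both the longest-
and shortest-exposure strata. Impulsivity declines 1.0 scale units per
period in controls; after onset the decline is attenuated by 0.85, where a
period counts as post-onset when it ends at or after the onset wave (so
short-term drinkers alone have one clean pre- and one post-onset period).
Drinkers also carry a gradient-scaled baseline elevation (+0.8), making
impulsivity both a predisposition marker and a trajectory outcome.
Sensation seeking gets the elevation but no attenuation — the designed
negative control.

Effect magnitudes are calibration choices, not empirical values; no public
data exist to estimate them. Two calibration facts are worth recording.
First, the link effects must be large (d ≈ 2 in the long-term group):
detectability among 19,900 candidates at n ≈ 100 requires per-link effects
far above anything plausible in real rsFC, so passing recovery tests shows
the machinery is correct, not that real effects of realistic size would be
found. Second, the planted-link count interacts with lasso-logistic
saturation: once the selected links perfectly separate the classes in a
stratum, the deviance gradient vanishes and remaining true links can never
enter at any penalty. With 24 strong planted links only ~60–80 % were ever
recoverable; the defaults settled on 12 links, at which the selection
recovers the planted support (median ≥ 80 %, ≤ 5 false positives over
seeded replicates) — the operating point the pipeline's recovery checks
assert.

Cannabis and smoking bands are generated, but cannabis use is assigned
independently of the drinking groups (its own latent user flag, own eight
planted links disjoint from the binge links). Real cohorts show correlated
substance use; independence is deliberate so that "the binge classifier is
at chance on cannabis labels" is a well-posed specificity probe. The
"null cohort" used by calibration checks sets every planted effect to zero
*and* equalizes the sex proportions across groups, since group-graded sex
composition is itself a real group signal through the covariate layer.

Not emulated: fMRI time series and atlas construction, linkage
disequilibrium and genotyping QC, missing waves and dropout, raw occasion
counts behind the ESPAD bands, and correlated substance use. Tests passing
on these cohorts therefore validate the statistical machinery and its
leakage discipline — not effect sizes, preprocessing robustness, or
missing-data behaviour on real data.

## Determinism, problem sizes, and interfaces

Every stochastic step is seeded; `run_full()` derives per-stage child seeds
from the single global seed by a fixed affine map, so identical
configuration and seed give byte-identical cohorts and reports. Cohort
files round-trip losslessly (doubles written as shortest exact decimals).

The test suite exercises the full-size cohort (212 × 19,900) where sample
bookkeeping and recovery are asserted, and a reduced 30-region / 60-SNP
cohort (same 212 subjects) elsewhere; calibration checks use 1,000 null
simulations per test, recovery and longitudinal mirrors 25 seeded
replicates, and generator property checks 40–60 replicates. These sizes are
the package's choices for routine verification; all are parameters of the
corresponding helpers.

The package's interface is its functions plus `scripts/acceptance.R`;
stage functions (`generate_cohort()`/`write_cohort()`, `assign_groups()`,
`svm_stratum_analysis()`, `trend_select()`, `fit_hierarchical()`,
`evaluate_heldout()`, `longitudinal_analysis()`) compose the same way
`run_full()` does, and all intermediate artifacts are plain TSV/JSON, so
any stage can be re-run from the persisted files of the previous one.

## Known limitations

* The stability rule under leave-one-out resampling barely perturbs the
  selector (folds share n − 2 subjects), so selection frequencies
  concentrate near 0 or 1; the > 90 % rule mainly removes borderline
  features rather than simulating subsampling-based stability selection.
* In a weak-signal stratum the per-fold lasso may select noise links whose
  in-fold summary scores look discriminative; the stratum SVM can lean on
  them and its LOO accuracy then varies widely across seeds. This is a
  property of the construction, visible here because ground truth is known.
* The continuous NRI variance (4/n₁ + 4/n₀) is the standard asymptotic and
  anti-conservative in small samples; NRI results are reported with their
  evaluation n.
* Group assignment assumes complete three-wave ESPAD records; subjects with
  sub-threshold non-zero drinking are excluded and reported, not modeled.
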