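# bingetrace

Onset-stratified classification and developmental-trajectory analysis of
adolescent binge drinking, for three-wave cohort data (assessments at ages
14, 16 and 19).

Longitudinal adolescent cohorts let drinkers be stratified by *when* binge
drinking began, not just whether it occurred. If alcohol disrupts brain and
personality development, features it alters should deviate from controls
most in drinkers with the longest exposure, at an intermediate level with
medium exposure, and least with the shortest exposure — a *hypothesis of
trend* that can be used as a feature filter. `bingetrace` implements that
full analysis as reusable, tested R functions:

* **ESPAD stratification** — lifetime drunkenness counts banded to the
  ESPAD 0–6 ordinal scale (`espad_band()`); five onset groups (long-,
  medium-, short-term drinkers, Control I/II) from the wave at which the
  banded score first reaches the drinker threshold (`assign_groups()`);
  training sample = long + short + Control I, held-out test sample =
  medium + Control II (`split_train_test()`).
* **Stability-selected features** — candidate resting-state connectivity
  links by lasso-regularized logistic regression, candidate SNPs by 2×2
  chi-squared screens, hardened by leave-one-out stability selection: only
  features selected in strictly more than 90 % of LOO refits are retained
  (`svm_stratum_analysis()`, `loo_stability()`). Retained features collapse
  into four per-subject summary scores: iFC and dFC (sums of connectivity
  over increased / decreased links) and rSNP and pSNP (counts of carried
  risk / protective mutations) (`summary_scores()`).
* **Trend filter** — the Jonckheere–Terpstra test across the ordered groups
  (long > medium > short > Control II > Control I), with ½-credit for ties,
  a tie-corrected normal approximation, and an exact small-sample null via
  convolution of Mann–Whitney distributions (`jt_test()`, `trend_select()`).
* **Hierarchical classifier** — a two-layer stack: in-layer margin
  classifiers (linear SVMs) on covariates (SVM1), trend-surviving summary
  scores (SVM2) and personality (SVM3); the out-layer SVM4 consumes only
  their three decision values, each produced leakage-free by LOO
  (`fit_hierarchical()`). Domain contributions by continuous net
  reclassification improvement, NRI = (P(up|case) − P(down|case)) +
  (P(down|control) − P(up|control)), z = NRI / √(4/n₁ + 4/n₀)
  (`nri_domain_contribution()`), and on the held-out sample by |Pearson r|
  between each input and the SVM4 output with bootstrap confidence
  intervals (`evaluate_heldout()`).
* **Longitudinal trajectories** — per-period difference scores
  (16−14, 19−16), a sign-flip permutation test of the paired median, and
  mixed-design repeated-measures ANOVA for the time-by-group interaction
  with Greenhouse–Geisser correction (`longitudinal_analysis()`).
* **Synthetic cohort generator** — raw data of this kind are
  access-restricted, so `generate_cohort()` produces seeded cohorts with
  the full measurement battery (ESPAD bands, SURPS/NEO/Kirby/Cantab scores,
  a 19,900-link connectivity vector, binary genotypes) and *planted*,
  onset-graded effects plus a post-onset attenuation of the impulsivity
  decline, so every stage is testable against known ground truth.

## Worked example

```r
library(bingetrace)
report <- run_full(list(seed = 42))
```

The run simulates the default 212-subject cohort (54/52/41 long/medium/short
drinkers, 44 + 21 controls; training n = 139, test n = 73) and executes
every stage. Selected results from this exact run:

```
SVM-long  LOO accuracy 100.0%, AUC 1.000 (links retained: 12, SNPs: 7)
SVM-short LOO accuracy 77.6%, AUC 0.861
NRI (SVM-long): rsFC z = 1.24 (p = 0.215), SNP z = 0.39 (p = 0.700)

                     feature direction    jt      z        p retained
1                        iFC increased 16154 14.578 1.93e-48     TRUE
2                        dFC decreased 15651 13.579 2.66e-42     TRUE
3                       rSNP increased 12006  6.339 1.15e-10     TRUE
4                       pSNP decreased 11000  4.347 6.91e-06     TRUE
5       surps_impulsivity_19 increased 12800  7.915 1.24e-15     TRUE
6 surps_sensation_seeking_19 increased  9066  0.496 3.10e-01    FALSE
7           surps_anxiety_19 decreased  9230  0.822 2.06e-01    FALSE
8 surps_negative_thinking_19 decreased  8611 -0.408 6.58e-01    FALSE

held-out accuracy 98.6% (n = 73)
contributions: iFC 0.92, rSNP 0.64, pSNP 0.19, impulsivity 0.56, covariates 0.09

impulsivity:        permutation p = 0.001; interaction F(2,208) = 25.87, p < 1e-4
sensation seeking:  permutation p = 0.609; interaction p = 0.746
```

Reading this: the trend filter retains the brain/gene summary scores and
impulsivity (their deviation from controls is ordered by onset), but not
sensation seeking, anxiety or negative thinking — so SVM2/SVM3 are built
from iFC, rSNP, pSNP and impulsivity. The stacked model classifies the
held-out medium-term drinkers vs Control II at 98.6 % (the synthetic
planted effects are deliberately strong; see the methods vignette), with
iFC contributing most and the covariate layer least. Longitudinally, the
decline in impulsivity slows after binge-drinking onset in short-term
drinkers (permutation p = 0.001, significant time-by-group interaction),
while sensation seeking — generated without post-onset attenuation — shows
neither effect.

`run_full(list(seed = 42, out_dir = "out"))` additionally writes the cohort
files (`phenotypes.tsv`, `connectivity.tsv`, `edges.tsv`, `genotypes.tsv`,
`truth.json`), `groups.tsv`, `scores.tsv`, `trend.tsv`, a reloadable
`model.json` and a `report.json` with every number above.

## Documentation

The methods vignette (`vignettes/binge-drinking-pipeline.Rmd`) describes
the statistical model, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical and design choices.
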