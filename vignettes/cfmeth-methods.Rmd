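---
title: "Co-methylated read analysis of cell-free DNA: models and methods"
author: "cfmeth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-methylated read analysis of cell-free DNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmeth)
```

# The problem

Colorectal cancer (CRC) is highly curable when caught at stage I or as an
advanced adenoma (AA), but the non-invasive screening options in wide use
(fecal occult blood, fecal immunochemical tests) have poor sensitivity for
exactly those early lesions. Tumors shed DNA into the bloodstream, and the
methylation state of this circulating tumor DNA (ctDNA) mirrors the tumor
of origin, so targeted bisulfite sequencing of plasma cell-free DNA
(cfDNA) is a natural substrate for an early-detection test. The catch is
dilution: in early disease the tumor-derived fraction of cfDNA is on the
order of a few percent, so single-CpG methylation averages drown in
background from hematopoietic DNA.

`cfmeth` implements a read-centric alternative. Individual sequencing
reads are single molecules; a read whose CpGs are coordinately methylated
almost certainly came from a fully methylated epiallele, no matter how
rare that epiallele is in the pool. The package implements the full
analysis around this statistic: computing it from epiread-level input,
discovering CRC-specific markers in a tissue cohort, refining them in
plasma, fitting a penalised logistic risk score, and evaluating the
result the way a diagnostic study would report it.

# The PCM statistic

For one region and one sample, with reads restricted to the CpGs falling
inside the region,

$$\mathrm{PCM} = \frac{\#\,\text{co-methylated reads}}
{\#\,\text{mapped reads with} \ge 3\ \text{CpGs in the region}},$$

where a read is *co-methylated* when some window of 5 consecutive CpG
calls contains at least 3 methylated calls. Model features are
$\log_2(\mathrm{PCM} + c)$ with pseudocount $c = 10^{-3}$.

Three edge cases are under-determined by that verbal definition, and the
package resolves them as follows (all three are configurable):

* **Reads with 3 or 4 CpGs.** The denominator admits reads with at least
  3 CpGs while the window rule speaks of 5. We treat a short read as a
  single window of its own length requiring ≥ 3 methylated calls, which
  keeps the numerator and denominator consistent; the alternative — short
  reads never co-methylated — is available via
  `is_comethylated(short_read = "exclude")`.
* **No-calls.** `N` never counts as methylated, and a read with fewer
  than 3 non-`N` calls in the region is ineligible. This is conservative
  against false co-methylation.
* **Zero PCM.** The log2 transform uses a pseudocount (default `1e-3`,
  placing empty regions at about −10) because a zero fraction otherwise
  has no finite logarithm. The window is slid over the read's own
  in-region CpG calls, not over reference CpGs.

`comethylation_prob(k, p_m)` gives the exact probability that a read of
`k` i.i.d. calls satisfies the rule, by enumeration of all $2^k$ call
configurations; it is the closed-form reference used throughout the test
suite and the simulator.

# The synthetic cohort generator

The study design this package targets deposits no sequence data, so the
generator is a first-class module: it emulates the *statistical
structure* of the design and carries ground truth for recovery testing.

The generative model is deliberately the simplest one under which PCM is
a consistent estimator of biology. Each region $r$ has a
methylated-epiallele fraction per state: $\theta^N_r$ (normal),
$\theta^{AA}_r$ (adenoma), $\theta^T_r$ (tumor). A sample mixes states:

* tissue CRC: $p_r = (1-\pi)\theta^N_r + \pi \theta^T_r$ with tumor
  purity $\pi \sim U(0.3, 0.9)$;
* tissue AA: $p_r = \theta^{AA}_r$ (an excised lesion is taken as pure);
* plasma: $p_r = (1-f)\theta^N_r + f\theta^{lesion}_r$ with ctDNA
  fraction $f$ drawn from a group/stage-specific range — zero for
  controls, 0.5–2% for non-advanced adenoma, up to 10–25% for stage IV.

Gaussian sample-level noise (SD 0.02) is added and the result clamped to
$[0.01, 0.99]$. Reads then follow a two-epiallele model: a read draws an
epiallele Bernoulli($p_r$) and emits each CpG call with symmetric error
$\varepsilon = 0.02$. Planted CRC markers have background
$\theta^N \sim U(0.05, 0.2)$, effect
$\delta = \theta^T - \theta^N \sim U(0.25, 0.6)$, and a concordant AA
effect attenuated by $U(0.6, 1.0)$; a second, smaller set of regions is
hypermethylated in adenoma only (exercising the AA-vs-CRC augmentation);
all remaining regions share one $\theta \sim U(0.05, 0.95)$ across
states.

Default cohort sizes mirror the post-QC composition of the motivating
study design: tissue 91 Normal / 26 AA / 70 CRC; plasma 133 Normal / 40
NAA / 68 AA / 248 CRC (stages 66/86/62/34). Plasma cfDNA yields are
lognormal with group means 3.94 (Normal), 6.08 (AA) and 6.43 (CRC) ng/mL
— the published group means — and CV 0.5; the NAA mean (4.20) is not
published and was set once near the Normal value, since those groups did
not differ. Serum CEA and CA19-9 analogs are lognormal with arbitrary
offsets targeting moderate discrimination (AUC ≈ 0.75 and ≈ 0.6 vs
controls), included only so the scalar-comparison machinery has realistic
input.

**Exact count-level sampling.** At study scale the cohort implies on the
order of $10^9$ individual reads, which no desktop analysis should
materialise. Because reads are i.i.d. given $p_r$, the co-methylated
count among $n \sim \mathrm{Poisson}(\text{depth})$ eligible reads is
*exactly* $\mathrm{Binomial}\!\left(n,\; p_r \bar q_M + (1-p_r) \bar
q_U\right)$, where $\bar q_M, \bar q_U$ average the enumerated window
probabilities over the read-length distribution (3–10 CpGs, uniform).
`generate_cohort()` samples from this law directly;
`simulate_epireads()` materialises reads for small configurations, and
the test suite verifies that both paths agree with the enumeration
closed form. This is a refactoring of the same generative model, not an
approximation.

What the generator does *not* emulate: fragment-length and GC biases,
bisulfite conversion failure, partially methylated haplotypes, batch
effects, and correlated regions. Passing recovery tests therefore shows
that the analysis machinery is correct and well calibrated under the
stated model — not that the pipeline would achieve comparable AUCs on
real plasma.

# Marker discovery

Tissue-stage selection (`select_tissue_markers()`) computes, per region,
two-sided rank-sum tests for CRC vs Normal, AA vs Normal and AA vs CRC,
Benjamini–Hochberg q-values per contrast family, the CRC-vs-Normal
AUROC, and group-mean PCM differences. A region enters the core set when
both disease contrasts are BH-significant (q < 0.05) with
|Δ PCM| > 0.2 and the CRC and AA changes share a sign; regions with a
BH-significant AA-vs-CRC contrast form an augmentation set.

Two choices deserve justification. The motivating study describes its test as
Wilcoxon signed-rank, but the compared groups are unpaired with unequal
sizes (91/26/70), for which signed-rank is undefined; the unpaired
rank-sum (Mann–Whitney) form is used, with a paired mode available for
matched tumor/adjacent-normal designs. Effect sizes are computed on the
raw PCM scale (a methylation-fraction difference is what "absolute
change > 0.2" naturally means), with the group mean as the summary; the
median is available by argument. The AA-vs-CRC augmentation threshold is
not specified there; BH-adjusted rank-sum at 0.05 is used,
consistent with the other contrasts.

# The risk model

Plasma modeling (`train_risk_model()`) proceeds in the published order:

1. **Refinement**: keep tissue markers with unadjusted rank-sum p < 0.05
   between plasma CRC and Normal. Unadjusted is deliberate — this is a
   pre-screen feeding a penalised model, and the study states a plain
   p-threshold here in contrast to the BH-adjusted tissue stage.
2. **Split**: plasma Normal and CRC samples are assigned 1:1 to training
   and validation arms within strata of sex × age decade × (Normal |
   stage). Within each stratum samples are shuffled and dealt
   alternately, the starting arm being whichever is currently smaller,
   so arm sizes differ by at most one per stratum *and* overall. NAA/AA
   samples are never assigned; the model is a CRC-vs-Normal classifier
   and adenomas are scored only at evaluation. The split ratio is
   configurable (arm sizes are not published; 1:1 is the
   default).
3. **Selection**: L1-penalised logistic regression on the training arm's
   log2-PCM features over a descending log-spaced lambda path, lambda
   chosen to minimise 10-fold cross-validated binomial deviance with
   label-stratified folds; features with nonzero coefficients at
   `lambda.min` survive. Missing cells are median-imputed from the
   training arm, and the imputation values ride along in the model for
   reuse at scoring time.
4. **Fit and threshold**: an unpenalised logistic fit on the selected
   markers (standardised to training mean/SD; a 1e-6 ridge stabiliser
   handles separation, with a warning). The risk score is the logistic
   probability — a value in (0, 1), which is the scale on which a
   threshold like 0.58 is interpretable — and the operating threshold
   maximises Youden's J over midpoints of consecutive training scores,
   ties breaking toward the smaller threshold (favouring sensitivity).

`check_age_independence()` reports the Spearman correlation of each
selected marker with age among plasma controls (|rho| ≥ 0.3 flagged,
nothing auto-removed): plasma controls skew younger than patients in
this design, so an age-tracking marker would inflate apparent
performance.

# Evaluation

`auc_with_ci()` computes the AUC by concordant-pair counting with
half-credit ties (via midranks) and a DeLong placement-value standard
error; the 95% normal CI is truncated to [0, 1]. The CI method is not
named in the study; DeLong is the field default and its coverage is
verified by simulation in the test suite (93–97% at true AUC 0.8,
n=50/50). `subgroup_report()` scores every plasma sample and evaluates
each subgroup (NAA, AA, adenoma, stages I–IV, all CRC, CRC∪AA) against
the *pooled* plasma controls — matching the published panel layout,
e.g. stage I vs all 133 controls — plus arm-specific training and
validation rows. `group_mean_test()` is Welch's unpaired t-test: the
source labels its group comparisons "paired Student's t-test", but the
compared groups are independent with different sizes, so this is read
as a labeling slip. Printed percentages round half-up to 2 decimals, the
convention of clinical tables.

# Problem sizes and reproducibility

The package chooses test and acceptance problem sizes that keep the full
suite in the minutes range while leaving Monte-Carlo error well inside
the asserted tolerances: 10,000 replicates for type-I-error calibration,
2,000 panels for FDR control, 2,000 replicates for CI coverage, 500–1,000
instances for the oracle equivalences, and five seeded study-scale
pipeline runs for the end-to-end properties. All randomness flows from
explicit seeds; `run_pipeline()` records seeds, thresholds, a config
hash and stage timings in `run_manifest.json`, and identical
configurations reproduce identical numeric outputs.

# Known limitations

* The two-epiallele read model has no partially methylated haplotypes;
  PCM's behaviour under haplotype mixtures is untested here.
* The stage → ctDNA-fraction mapping is an assumption (no fraction
  measurements exist for the motivating design); absolute subgroup AUCs
  from the generator are properties of that assumption, only the
  *ordering* is treated as a meaningful target.
* `lambda.min` tends to over-select in p ≫ n regimes; the final model
  typically carries more markers than a minimal signature. This is
  inherent to the published selection rule, not a defect of the
  implementation; `glmnet`'s `lambda.1se` would yield sparser models but
  a different rule.
* Tissue effect sizes are attenuated by tumor purity, so markers planted
  with small effects are undetectable by design at the |Δ| > 0.2
  threshold; recovery rates must be interpreted against the *detectable*
  planted set.
* Real-data ingestion stops at epiread-level calls: alignment,
  methylation calling and conversion QC are out of scope.
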