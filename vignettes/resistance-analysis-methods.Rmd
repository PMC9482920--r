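---
title: "Methods: selection calling, mutant-like signatures and outcome association"
author: "resistsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection calling, mutant-like signatures and outcome association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistsig)
```

# What the package models

`resistsig` implements three linked analyses from treatment-resistance
genomics, plus the seeded synthetic cohorts needed to exercise them without
restricted patient data.

## 1. Treatment-selected mutations in longitudinal cfDNA

Plasma cfDNA mixes tumor and normal DNA, and the tumor fraction moves with
treatment — typically dipping on therapy and rebounding at progression. A
variant's raw mutant allele frequency (MAF) therefore tracks tumor fraction
as much as clonal composition. The package works on the **relative MAF**:

$$\mathrm{rMAF}(v) = 100 \times \frac{\mathrm{MAF}(v)}{\max_{w \in \text{sample}} \mathrm{MAF}(w)}$$

Because tumor fraction multiplies every variant in a sample by a common
factor, it cancels in this ratio; the sample's top variant always scores
exactly 100. The normalizer uses *all* reported variants in the sample
regardless of effect class — eligibility filtering applies only to the call
itself.

A variant is called **selected** when its rMAF increases by *strictly more
than* 25 percentage points between the baseline (PRE) and end-of-study (EOT)
draws and its effect class is eligible (non-synonymous SNVs and indels by
default; indels are included because frameshift loss-of-function alleles are
a typical mode of tumor-suppressor inactivation, while rearrangements are
excluded by default). The strict inequality means a delta of exactly 25.0 is
not called; both the threshold and the class set are arguments. Intermediate
(OTH) draws feed the per-patient evolution maps but never the calls, which
are defined on the PRE/EOT pair only. Selected variants unreported at
baseline are classified *acquired*, those already detectable *pre-existing*;
"unreported" means absent from the table, with an optional rMAF-at-baseline
cutoff for callers that report trace frequencies.

Per gene, patients (counted at most once per gene, however many selected
variants they carry) are cross-tabulated against treatment arm and tested
with a two-tailed Fisher exact test; genes with fewer than 2 selected
patients in both arms are screened out before testing, and
Benjamini–Hochberg adjustment runs across the tested genes only, with
significance declared at FDR < 0.2. The odds ratio is the conditional
maximum-likelihood estimate with the exact 95% interval, oriented with arm A
as the reference column (a cross-product "sample" mode is available).

## 2. The mutant-like transcriptional signature

A mutation's phenotype can arise without the mutation (promoter methylation,
mutations in complex partners), so a transcriptional surrogate is derived:

1. **Differential expression with confounder control.** Per gene, ordinary
   least squares of log2-CPM on
   `mutation + confounder (+ MSI) + mutation:confounder` under treatment
   coding. The tested coefficient is the mutation *main effect*, i.e. the
   shift within the confounder-wild-type stratum. This matters because the
   mutation label is enriched among carriers of a second driver (eRAS/BRAF):
   without the covariate and interaction, genes that respond only to the
   confounder leak into the signature. The fit and the (default-on)
   empirical-Bayes variance moderation are delegated to `limma`; switching
   moderation off reproduces the classical per-gene OLS t-test exactly,
   which is how the tests cross-check the machinery against `lm()`. A joint
   moderated F-test of main effect plus interaction is available behind
   `coef_mode = "joint"`. MSI is included by default and removable by flag.
2. **Gene selection.** Genes at FDR < 0.05 are split by effect sign into up-
   and down-regulated sets (the default simulated truth plants 8 up and 56
   down, the size of the signature this workflow is designed to produce).
3. **Scoring.** Signature genes are z-scored across samples and the score is
   the first principal component of the z-matrix. Raw PC signs are
   arbitrary, so instead of a literal "reverse the sign" convention the
   package orients the score to correlate *positively* with (mean z of
   up-genes − mean z of down-genes); this is deterministic, reproduces the
   reverse-sign convention whenever the down-set dominates PC1, and falls
   back to the mutant-group-mean rule only if that correlation is exactly
   zero. Scoring runs in `refit_per_cohort` mode by default (z statistics
   and PC1 re-estimated per scoring cohort, matching a per-cohort PCA
   reading of the workflow) with `frozen_projection` (stored means, SDs,
   loadings, sign) for deployment-style use; on the fitting cohort the two
   agree in rank order.
4. **Stratification.** Quartile cutoffs use the linear-interpolation
   quantile definition (R type 7) with strict `>` comparisons; Q4 is the
   mutant-like group, ties at the Q3 cutoff fall on the wild-type side. Both
   conventions are deliberate, documented choices since neither is forced by
   the definition of a quartile.

## 3. Outcome association

Survival uses the standard toolkit, exposed behind stable function surfaces
and delegated to the `survival` package: Kaplan–Meier product-limit curves,
the log-rank test, and a biomarker×arm interaction Cox model with Efron tie
handling, optional adjustment covariates and stratified baseline hazards.
Wald tests and intervals are reported per term; rank-deficient designs and
non-convergence are errors naming the offending terms, never silent
results. Response analysis maps CR/PR to "responder", compares group ORRs by
Fisher exact test, and classifies xenograft response from percent tumor
volume change at 3 weeks with conventional thresholds (PR ≤ −50%, PD ≥ +35%,
boundary on the PD side; these are documented conventions, not assay-derived
values) — with a flag reproducing the "(PR, SD-PR)" responder grouping.
Wilcoxon rank-sum comparisons enumerate exactly when both groups have ≤ 10
untied observations and otherwise use the tie-corrected normal
approximation.

# The synthetic cohort generators

The generators reproduce the statistical structure the analyses assume; they
are first-class, tested code, and their defaults are the study conditions.

**cfDNA cohorts** (`simulate_cfdna_cohort()`): 333 patients split between a
control arm A and an anti-EGFR arm B; a truncal clone plus Poisson(3)
subclones per patient with log-normal baseline %MAF; a joint per-sample
tumor-fraction multiplier of (1, 0.3, 1.5) across PRE/OTH/EOT encoding the
on-treatment dip and progression rebound; multiplicative log-normal
measurement noise (SD 0.15, chosen so the null distribution of rMAF changes
concentrates within ±25 points); and a 0.1 %MAF limit of detection
(configurable — panel assays do not publish a single LOD). Resistance
subclones are planted per gene with arm-specific probabilities sized to the
reported selected-patient counts (KRAS 0.06 and ARID1A 0.036 in arm B versus
0.006 in arm A), seeded at a Uniform(0.3, 0.4) fraction of the patient's
maximum baseline MAF — pre-existing with probability 0.4, otherwise first
detectable on treatment — and expanded 8-fold at EOT.

The seeding and expansion ranges are not arbitrary: with seed fraction
$f \in [0.3, 0.4]$ and expansion $E = 8$, an expanded clone always overtakes
the baseline maximum, so its rMAF delta is at least $100 (f_i/f_{\max}) -
100 f_i \ge 35$ points even when several clones are planted in one patient,
while unplanted clones — rescaled jointly by tumor fraction — can never gain
rMAF. In the noise-free, LOD-0 limit the selection caller therefore recovers
the generator's hidden truth channel *exactly*, which is what makes the
caller testable with zero tolerance. Each patient's baseline clone set is
jointly rescaled so that unexpanded MAFs stay below the 100% cap at every
timepoint; joint rescaling is invisible to rMAF, so the cap cannot create
spurious calls.

**Expression cohorts** (`simulate_expression_cohort()`): negative-binomial
counts (size 10) for 2000 genes × 337 samples with library sizes uniform in
0.8–1.6 million; 8 up / 56 down signature genes shifted ±1.0 log2 in mutant
samples; mutation prevalence 0.1, eRAS/BRAF prevalence 0.45, MSI 0.19, and
an odds multiplier of 4 linking the mutation to eRAS/BRAF (the conditional
prevalences are solved numerically from the marginal and the odds ratio).
Optional confounder genes shift only in eRAS/BRAF mutants — the instrument
for demonstrating that the interaction model excludes them while a naive
one-covariate model lets them leak.

**Outcomes** (`simulate_outcomes()`): exponential event times with hazard
$\lambda_0 \cdot \mathrm{HR_b}^{[\mathrm{bio}]} \cdot \mathrm{HR_a}^{[\mathrm{armB}]}
\cdot \mathrm{HR_{int}}^{[\mathrm{bio \times armB}]}$ and independent
exponential censoring. Defaults: baseline 1/30 per month, interaction HR 3.3
(the reported multivariable OS interaction effect), censoring 1/90.
Best-response categories are drawn per (arm, group) from probability vectors
whose defaults reproduce the reported ORRs (44% vs 89% under anti-EGFR
therapy, 50% vs 63% under control). **Xenografts**
(`simulate_pdx_cohort()`): one normal percent-volume-change draw per model;
the default group means/SDs (85 ± 40 mutant-like, 52 ± 45 WT-like) are set so
the expected responder fractions under the default thresholds match the
reported 11% vs 36%.

What the generators deliberately do **not** emulate: read-level sequencing
error, clonal phylogenies and subclone nesting, copy-number and
rearrangement events, batch and GC effects in expression, non-proportional
hazards, and informative censoring. Passing tests therefore demonstrate that
the *statistical machinery* behaves as specified under the assumed
structure, not that the biological findings would replicate on real
restricted-access cohorts.

# Numerical and design choices

- **Strict thresholds everywhere they are stated as "exceeding"**: the
  25-point selection rule and the Q4 cutoff both use `>`, so boundary values
  fall on the conservative side; both are configurable.
- **Fisher machinery**: `stats::fisher.test` supplies the two-tailed p,
  conditional-MLE OR and exact CI; the test suite verifies it against an
  exhaustive hypergeometric enumeration oracle (all tables with cells ≤ 6
  plus seeded random tables with margins up to 30). The MLE agrees with the
  enumeration oracle to about 1% relative at extreme ORs, the precision of
  the underlying root-finder.
- **BH adjustment** is `stats::p.adjust(method = "BH")` behind a validated
  front, oracle-checked against a hand-written step-up implementation.
- **DE engine**: `limma` rather than a hand-rolled OLS/method-of-moments
  stack — it is exactly per-gene OLS with empirical-Bayes moderation, and
  the moderation-off path is verified coefficient-for-coefficient against
  `lm()`. Precision weighting by a fitted mean–variance trend (voom-style)
  is not implemented; at the simulated depth and dispersion the constant
  weight approximation is adequate, and this is a documented simplification.
- **Cox details**: Efron ties (the common default; nothing in the workflow
  depends on the choice at the simulated tie rate), Wald tests and CIs,
  convergence tolerance 1e-9 with 25 iterations, stratified baselines via
  `strata()`. Proportional-hazards diagnostics (Schoenfeld residuals) are
  out of scope and intentionally not claimed.
- **Degenerate inputs** are contracts, not afterthoughts: all-zero samples
  raise an undefined-normalization error and are excluded with a warning at
  table level; zero-variance genes carry NA statistics and leave the FDR
  ranking; a score vector with no spread refuses to stratify; an exactly
  null orientation correlation falls back to labels or errors.
- **Determinism**: every generator takes an integer seed and is
  bit-reproducible; derived seeds stay below 2^31. The pipeline writes a
  manifest with config hash and per-file checksums; repeated runs with the
  same seed are byte-identical (the manifest's timestamp aside).

# Problem sizes used by the test suite

The package's deeper simulation tests run at the sizes the analyses are
designed for while staying desk-scale: 1000 null cfDNA cohorts of 300
patients for false-discovery control of the arm-enrichment screen; 20
replicates of the 330-sample, 2000-gene signature recovery and of the paired
confounder-leak comparison; 200 replicates of interaction-HR recovery at
5000 subjects per arm×group cell with coverage checking; 1000 null log-rank
replicates for type-I error. The full suite completes in a few minutes on
one CPU.

# Known limitations

- The per-gene screen treats genes independently; a patient with selected
  mutations in several genes contributes to each (the dual-mutation case is
  counted once *per gene*, not once overall).
- `refit_per_cohort` scoring re-estimates the PC on each cohort, so scores
  are comparable within, not across, cohorts; use `frozen_projection` when
  absolute comparability matters.
- The signature derivation assumes the confounder interaction model is
  identifiable — a cohort in which mutation status is constant within the
  confounder-wild-type stratum errors by design.
- PDX response thresholds are field conventions, not derived from any assay;
  conclusions sensitive to them should be checked across thresholds.
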