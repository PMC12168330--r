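---
title: "Methods: plasma proteome networks, differential abundance and biomarker panels"
author: "plasmanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma proteome networks, differential abundance and biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices made where the design was genuinely open.

## The data and its quality-control model

The central object is a samples × proteins matrix of relative log2
abundances from a multiplex proximity-extension assay (NPX-like units).
Three artifacts dominate the QC model:

* **Censoring at the limit of detection.** Each assay has a background
  distribution from buffer wells; the LOD is the median log2 buffer
  signal plus three buffer standard deviations. `apply_lod_mask()` codes
  cells strictly below the LOD as missing; a value exactly equal to the
  LOD is retained. With `buffer_sd = 0` the LOD degenerates to the
  buffer median and the strict inequality still applies.
* **Redundant and unreliable assays.** `filter_proteins()` first drops
  assays carrying a QC warning, then keeps exactly one assay per
  UniProt accession, then drops proteins whose missing fraction is
  strictly above 0.5 (exactly 50% missing is retained). The
  duplicate-assay tie-break is: lowest missingness, then highest
  variance, then lexicographically smallest assay id. The source
  protocol specifies only that repeated measurements are removed; the
  tie-break is this package's choice, ordered to retain the most
  informative assay and to be fully deterministic.
* **Aberrant samples.** A technically compromised sample decorrelates
  from every other sample. `sample_connectivity()` scores each sample by
  the sum of its biweight midcorrelations with all other samples
  (pairwise-complete proteins) and standardizes the sums to Z scores;
  `remove_outlier_samples()` removes samples with Z < −3 in a single
  pass. The rule is one-sided by design: decorrelation can only lower
  connectivity, so a high-connectivity "outlier" is not a failure mode
  of this statistic. A single pass (no iteration) is used because the
  removal of a few decorrelated samples barely moves the connectivity
  distribution of the rest. If all connectivities are equal the Z score
  is undefined; the function returns all-zero Z with a warning rather
  than dividing by zero.

### Covariate adjustment with case protection

Age and sex influence many plasma proteins. Removing their effects by
per-protein regression risks removing disease effects too whenever the
groups differ demographically. The adjustment therefore models
`protein ~ age + sex + group` — the group indicators absorb case-related
mean differences so the age and sex coefficients are estimated from
within-group variation — but only the age and sex terms are subtracted.
Coefficients are medians over `n_boot = 1000` bootstrap replicates;
resampling is stratified by group so every replicate retains all group
levels and the design stays full rank. Replicates that are nonetheless
singular (for example, a resample holding one sex only) are redrawn up
to a retry cap. The median over replicates is robust to occasional
ill-conditioned fits; with `n_boot = 1` and resampling disabled the
procedure reduces exactly to ordinary least squares, which the tests
use as an oracle.

The raw (uncentered) covariates are multiplied by the median
coefficients at subtraction. This shifts every protein's mean by a
constant (β·mean(age)); all downstream inference is
location-invariant, so the constant is harmless and the convention
matches standard practice for this pipeline.

## The signed weighted co-expression network

The network model assumes modules of proteins driven by shared latent
processes, observed in few samples (~10²) relative to proteins
(~10³), with occasional outlying values — hence a robust correlation
and a soft-thresholded, signed similarity.

* **Biweight midcorrelation** (`bicor`). Each vector is centred on its
  median and observations are weighted by `(1 − u²)²` for |u| < 1 where
  `u = (x − med)/(9·MAD)` with the *unscaled* median absolute
  deviation. A vector with MAD = 0 (majority-tied) falls back to mean
  centring (Pearson weighting) for that vector alone. On complete data
  the matrix routine equals the pairwise definition exactly; with
  missing data, per-column weights are combined over pairwise-complete
  observations — the standard fast approximation, exact again whenever
  a column has no missing cells.
* **Signed adjacency.** `a_ij = ((1 + c_ij)/2)^β` with β = 7.5. The
  signed map sends anti-correlated proteins to ~0 adjacency so they
  cannot share a module. β is taken as an analysis constant (it was a
  published choice, not fitted here), and non-integer powers are
  accepted as-is; scale-freeness is therefore not asserted or tested.
* **Topological overlap.** `TOM_ij = (ℓ_ij + a_ij)/(D_ij + 1 − a_ij)`
  with `ℓ_ij = Σ_u a_iu a_uj` over u ∉ {i, j} and `D_ij` the mean of
  the two node connectivities (`tom_denom = "mean"`; `"min"` is
  available). TOM rewards shared neighbourhoods and stabilizes
  clustering when individual correlations are noisy. The implementation
  is a matrix product; the test suite proves it equal to the O(n³)
  brute-force triple loop on exhaustive small instances.

### Dynamic hybrid module detection

Modules are cut from the average-linkage dendrogram of `1 − TOM` with
an adaptive, variable-height procedure implemented in this package:

1. A static cut at `ref + 0.99·(max(h) − ref)`, where `ref` is the 5th
   percentile of joining heights, defines the top branches.
2. Each branch is recursively examined. A node is accepted as a cluster
   when its **core scatter** (mean of the lowest `min_module_size − 1`
   internal joining heights) is below a threshold and its **gap** to
   the parent join is above one. An accepted cluster is split further
   only when both children independently satisfy size, scatter and gap
   criteria; otherwise it is emitted whole. Branches smaller than
   `min_module_size = 10` dissolve to "unassigned".
3. Thresholds scale with `deep_split` ∈ 0..4 through the canonical
   sensitivity grid: maximum core scatter {0.64, 0.73, 0.82, 0.91,
   0.95} of the normalized height range and minimum gap
   `(1 − maxCoreScatter)·3/4`. The default `deep_split = 4` is the most
   sensitive setting.
4. A **PAM stage** assigns unassigned proteins to the module with the
   smallest average dissimilarity, provided that distance does not
   exceed the static cut height, and (with `pam_respects_dendro`,
   default) only to modules within the protein's own static-cut
   branch.

The PAM stage is deliberately permissive — on pure-noise input it will
attach most proteins to whatever weak cluster exists. The guarantee
that noise ends up unassigned is provided by the **kME-consistency
stage** below, which dissolves modules whose members do not actually
track their eigenprotein. This division of labour (permissive
geometric rescue, then correlation-based pruning) mirrors how the
field's reference pipeline splits responsibilities between its tree
cut and its module-quality gates, and the package's null simulations
(samples of pure Gaussian noise) verify that the full build leaves the
large majority of noise proteins unassigned.

### Eigenproteins, merging, kME

A module eigenprotein is the first principal component of the
column-standardized member submatrix, computed by SVD, standardized to
unit variance, and sign-flipped so its mean correlation with members is
positive. Missing cells are median-imputed *for this computation only*;
the imputation never propagates back into the data. Zero-variance
members are dropped with a warning. Modules whose eigenproteins are
closer than `merge_cut_height = 0.07` in correlation dissimilarity are
merged iteratively (closest pair first, eigenproteins recomputed after
every merge) until no pair qualifies.

`kme[p, m] = bicor(protein p, eigenprotein m)` measures membership
strength. `enforce_kme_consistency()` iterates to a fixed point (cap 30
iterations, warning on non-convergence): a protein whose maximal kME
belongs to another module is reassigned there; a protein whose
own-module kME falls below `min_kme = 0.30` becomes unassigned; an
unassigned protein whose best kME clears the threshold rejoins; modules
falling below the minimum size dissolve. The 0.30 threshold is exposed
as a parameter — the upstream protocol's exact constant is not printed
anywhere, and 0.30 is the conventional membership floor in this
literature. Final modules are renumbered by decreasing size (M1
largest).

## Differential abundance

Per protein, a fixed-effects one-way ANOVA on non-missing cells, then
Tukey–Kramer HSD p-values from the studentized-range distribution with
`SE = sqrt(MSE/2·(1/n_a + 1/n_b))` — the Kramer form, because the
groups are unbalanced (44/22/39 in the emulated design). Log2 fold
changes are differences of group means. Proteins lacking two groups
with ≥ 2 values are flagged `tested = FALSE` rather than dropped.
Degenerate inputs are resolved exactly: all-equal data give F = 0 and
p = 1; zero within-group variance with nonzero between-group variance
gives F = ∞ and p = 0. The Tukey machinery is cross-checked in the
tests against `stats::TukeyHSD` on `aov` fits (an independent code
path). Differential abundance is declared at unadjusted Tukey p < 0.05
for the per-pair tables (matching the upstream usage); BH-FDR is
available where family-wise control is wanted.

Two-group eigenprotein contrasts (for example an autopsy-confirmed
CTE+ vs CTE− split) use a two-sided Welch t test.

The abundance-tier analysis bins proteins by absolute plasma
concentration — high > 9.5, intermediate [6.0, 9.5] (closed interval),
low < 6.0 log10 pg/L — and runs a one-way ANOVA of *signed* per-protein
log2 fold changes across tiers plus a chi-square test of independence
(no continuity correction) on the tier × upregulated table. Signed
fold changes are used because the question is whether elevation (not
absolute perturbation) concentrates in low-abundance proteins.

## Enrichment statistics

Gene-set enrichment is a one-tailed hypergeometric (Fisher) test,
reported with `z = Φ⁻¹(1 − p)` for overlaps above expectation and
`z = −Φ⁻¹(1 − p_depletion)` below it; p is clamped to
[1e−300, 1 − 1e−16] before inversion so z is always finite. Gene
symbols are harmonized by case-insensitive exact match only — alias
expansion belongs to curated resources outside this package's scope.
The background universe defaults to the assayed proteins (parameterized)
rather than the genome: enrichment among measured proteins is the
question the pipeline asks. Module-wise overrepresentation of
trait-correlated proteins takes hits at nominal two-sided p < 0.05 in a
stated direction and applies BH-FDR across modules. Exact conditional
tests are discrete and therefore conservative when expected overlaps
are small; the package's null simulations quantify this.

## Classification panels

RFECV with a linear SVM (`e1071`), following the standard scheme: C is
tuned first by stratified 5-fold CV over a log grid 10⁻³..10³ (ties to
the smallest C, i.e. the most regularized equivalent model) and then
held fixed. Inside each CV fold an elimination path is computed on the
training part only — standardization statistics and median imputation
values come from the training fold, which the tests verify by spiking a
held-out outlier — and scored on the held-out fold at every panel size.
The optimal size maximizes mean CV accuracy with ties to the smaller
panel; the final panel is read off an elimination path on the full
data, and the reported accuracy/AUC come from a fresh stratified k-fold
on the selected panel. AUC is the Mann–Whitney statistic with
half-credit ties; its 95% CI is a percentile bootstrap over 1,000
class-stratified resamples (the percentile form is the simplest
defensible reading of "non-parametric bootstrap CI", and stratification
guarantees both classes in every resample). Feature importance is
|weight| of the linear decision function — the standard criterion for
linear RFE. Candidate features are the differentially abundant proteins
for the contrast, mirroring the intended use.

## Trait association and neuropathology composites

The global cognition composite is the mean of episodic-memory and
executive-function z-scores, falling back to the available domain when
one is missing (the generator emits already-residualized z-scores;
normative-cohort residualization requires external data and is out of
scope). Neuropathology burden is the exact integer sum of 0–3 ordinal
ratings over regions, per proteinopathy, with a medial-temporal-lobe
region of interest (dentate gyrus, CA1/subiculum, CA2, CA3/CA4,
entorhinal cortex, amygdala); subregion contributions are percentages
of the composite. Module–trait correlation uses Spearman's ρ on
midranks or bicor, with two-sided p from the t approximation on n − 2
degrees of freedom; cells with fewer than 5 complete pairs or a
zero-variance trait are marked untested rather than reported. The t
approximation is adequate at the n ≥ 10 typical here; an exact
permutation alternative would only matter below that.

## The synthetic-data generator

`generate_cohort()` draws, per module, a standard-normal latent factor
per sample; member proteins are `loading × factor + noise` with
loadings uniform on [0.5, 1] (giving a realistic within-module kME
spread and well-defined hubs) and residual SD `1/module_snr`. Group
effects are mean shifts of the factors, so a protein's planted shift is
its loading times the factor shift. Age and sex enter through
per-protein coefficients drawn from centred normals; demographics
default to the emulated cohort's (ages 70.6 ± 7.2 / 57.8 ± 12.1 /
67.6 ± 9.8; male fractions 0.64 / 1.00 / 0.44 for CTL / RHI / AD).
LOD censoring uses a deterministic empirical-quantile threshold per
low-abundance protein, and the emitted QC table reproduces exactly that
threshold, so re-masking is a no-op and planted retention counts are
exact. Outlier samples carry no factor structure: independent noise at
`outlier_noise_multiplier` (≥ 3, default 5) times each protein's
marginal SD — an explicit decision to model *decorrelation*, the
phenomenon the connectivity statistic detects, rather than a mean
shift, which it would not detect. Traits are linear in the standardized
realized factors with analytic scaling to the requested correlations;
neuropathology ratings come from a latent Gaussian severity cut at
fixed quantiles, so burden–factor correlation targets are well defined.

Two bookkeeping subtleties:

* The ground truth records both the *nominal* planted shift and the
  *realized* one (loading × the factor group-mean difference actually
  drawn). A module's factor is shared by all members, so its group-mean
  sampling error (~√(2/n)) is common to the whole module and does not
  average out; recovery checks compare against the realized shift so
  they measure the pipeline rather than the generator's draw.
* `orthogonalize_factors = TRUE` residualizes factors on age and sex
  within each group before shifts are applied. Without it, a factor's
  chance correlation with the covariates biases every member protein's
  fitted age/sex coefficient by the same shared amount — a real
  phenomenon of latent-structure data, but the wrong fixture for
  measuring the adjustment machinery itself. Covariate-recovery tests
  use the orthogonalized mode; null-calibration tests use the default,
  because within-group residualization also zeroes factor group means
  and would make null group tests conservative.

What the generator does **not** emulate: plate/bridge batch structure
and Olink's internal normalization, longitudinal sampling, genetic
covariates, realistic protein–protein correlation outside planted
modules (background proteins are independent), non-Gaussian abundance
tails, and informative (non-LOD) missingness. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative model, not robustness to every artifact of real plasma
data.

## Problem sizes and numerics

The validation suites use desk-scale problem sizes chosen once: the
assay-panel accounting fixture at the full 2,944-assay width; module
recovery on 9 planted modules × 60 proteins across 105 samples (five
seeds); covariate recovery at n = 100 per group with 1,000 bootstrap
replicates; null calibration at 500 proteins × 20 seeds (ANOVA) and
×40 seeds (module overrepresentation); RFECV on 10 informative + 90
noise features at n = 100 per group, with pure-noise controls at 60
features. Key numerical conventions: correlations are clipped to
[−1, 1] before downstream use; p-clamping bounds for z transforms are
[1e−300, 1 − 1e−16]; eigenprotein sign is fixed by mean member
correlation; module ids are stable integers ordered by size; all
stochastic stages take explicit integer seeds, and the pipeline derives
deterministic per-stage substreams from one master seed so stages can
be re-run in isolation.

## Known limitations

* The dynamic hybrid cut follows the published algorithm's contract and
  sensitivity grid, but is an independent implementation; on borderline
  branches it can differ from other implementations in which of two
  near-equivalent partitions it returns (the merge and kME stages
  absorb most such differences).
* Bicor's fast matrix path uses per-column weights with
  pairwise-complete accumulation under missingness; fully per-pair
  recomputation (used by the scalar `bicor`) can differ slightly when
  missingness is heavy and asymmetric.
* Fisher-exact calibration is conservative for small expected overlaps;
  interpret per-module enrichment q-values, not raw rejection counts.
* The SVM panel machinery assumes two classes and complete features
  after training-fold median imputation; heavily censored proteins are
  better filtered upstream.
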