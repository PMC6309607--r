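---
title: "Mapping brain omics modules onto MRI microstructure: methods and design"
author: "voxelOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping brain omics modules onto MRI microstructure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelOmics)
```

# The scientific problem

In cohorts where postmortem brain omics (bulk gene expression, DNA
methylation) and *ex-vivo* quantitative MRI are measured in the same
subjects, one can ask where in the brain microstructure covaries with
molecular activity. The MRI measure used here is the voxelwise transverse
relaxation rate R2 = 1/T2, which is sensitive to the local molecular
environment (myelin, cellular density, water content). The molecular
phenotype is not a single gene but a *module*: a set of genes (or CpG loci)
whose levels covary across subjects, summarized by one per-subject average
level. Mapping a module level onto R2 across tens of thousands of voxels is
then formally identical to a standard voxelwise neuroimaging association
study, with the module average playing the role of the phenotype.

voxelOmics implements this pipeline end to end:

1. module detection by consensus clustering of the feature-feature Pearson
   correlation matrix (`consensusCluster()`),
2. per-subject module average levels (`moduleAverages()`),
3. covariate and neuropathology adjustment by per-voxel / per-module OLS
   residualization (`residualizeVolumes()`, `residualizeLevels()`),
4. voxelwise Pearson mapping with Benjamini-Hochberg FDR control and
   cluster-extent filtering (`mapAllModules()`),
5. gray-matter impact scoring of significant white-matter regions through
   streamline connectivity (`impactScores()`),
6. module-trait association grids and incremental variance explained
   (`moduleTraitGrid()`, `incrementalVariance()`), and
7. hypergeometric gene-set over-representation (`hypergeomEnrich()`).

Because the kind of cohort this method targets is access-restricted, the
package ships a synthetic-data generator that plants every effect the
pipeline is supposed to find, with full ground truth.

# Module detection

## Model

Features are z-scored per feature. The working model for a module is a
single shared factor: each member of a module with target within-module
correlation $r$ is generated (and assumed) as

$$x_i = \sqrt{r}\, f + \sqrt{1-r}\,\varepsilon_i,$$

with $f$ the per-subject latent factor. Under this model the expected
pairwise correlation between members is exactly $r = b^2/(b^2+\sigma^2)$
with loading $b=\sqrt r$ and residual variance $\sigma^2 = 1-r$, which is
the structure the clustering stage is designed to recover.

## Procedure and parameters

`consensusCluster()` proceeds in four steps:

* **Graph construction.** Feature pairs with correlation at or above
  `edgeThreshold` (default 0.2) become weighted edges. Negative edges are
  discarded: module levels are unsigned means of z-scores, so anti-correlated
  features inside one module would cancel each other in the average.
* **Stochastic base runs.** Weighted label propagation (igraph) is run
  `nRuns` times (default 50) with distinct derived seeds. Label propagation
  is fast, order-sensitive, and therefore a good source of perturbed
  partitions for consensus.
* **Consensus cut.** Co-assignment frequencies across runs form the
  consensus matrix; average-linkage hierarchical clustering of
  1 − consensus is cut at height 1 − `consensusThreshold` (default 0.5: two
  features belong together if they co-clustered in at least half the runs).
* **Membership pruning.** A member whose correlation with its module's
  average profile — computable from the correlation matrix alone as
  $\bar r_{i\cdot}/\sqrt{\bar r_{\cdot\cdot}}$ over members — falls below
  `minMembership` (default 0.4) is returned to the unassigned pool,
  iterating until stable. This step exists because a background feature
  attached to a module by a single spurious edge adopts the module's label
  in essentially *every* label-propagation run, so neither the consensus
  matrix nor the cut can remove it; the membership statistic separates such
  features (membership ≲ 0.25 under the factor model) cleanly from true
  members (≈ $\sqrt r$, i.e. 0.55 even at $r = 0.3$). The default sits
  between those two regimes.

Modules smaller than `minModuleSize` (default 20, a typical lower bound for
interpretable coexpression sets) are merged into the unassigned pool, id 0.
Surviving modules are renumbered by decreasing size. The procedure is
deterministic given its seed; exact invariance to feature order holds on
separable data, and partitions agree up to label permutation otherwise.

`moduleAverages()` computes each module's per-subject level as the
arithmetic mean of the z-scored member features, so scale-heterogeneous
features contribute equally. Rows are therefore zero-mean with SD at most 1,
reaching 1 only if all members are perfectly correlated.

# Adjustment

Age at death, sex and years of education are removed from both the voxel
data and (optionally) the module levels with ordinary least squares: each
in-mask voxel's across-subject series is replaced by its residual against
the design, intercept included. Neuropathology indicators (global AD
pathology, gross infarcts, microinfarcts, Lewy bodies) form a second,
optional design block, mirroring the with/without-pathology model pair used
to ask how much of an imaging-omics association a common pathology explains.
Both sides (volumes, levels) are adjustable independently, since which side
should be controlled is analysis-dependent. Subjects with missing design
entries are dropped listwise with a logged count. Rank-deficient designs are
rejected naming the collinear columns. Residualization is idempotent and
produces residuals orthogonal to the design to numerical precision; both
properties are tested.

# Voxelwise mapping

For module level $m$ and voxel series $v$ over $n$ subjects, the package
computes the sample Pearson correlation $r$ and its two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. Both signs are
mapped: microstructure may rise or fall with molecular activity.
Zero-variance voxels get undefined $r$ and $p = 1$, keeping them in the
family but never rejected.

**FDR control.** Benjamini-Hochberg at $q = 0.05$ over the in-mask
p-values. The family defaults to per module (`family = "per_module"`); a
pooled family across all module-voxel tests is available, since with many
modules the two conventions genuinely differ and the choice should be
explicit. The BH critical p-value is reported so maps can state the exact
rejection threshold.

**Cluster-extent filter.** Connected components of the rejection mask are
labelled at face connectivity (6-neighborhood) by default — the most
conservative reading of "contiguous" — and components below
`minClusterVoxels` (default 100) are discarded. At the default 1 mm
isotropic voxels, 100 voxels equal 100 mm³, so the voxel and volume
thresholds coincide; for other voxel sizes the threshold can be stated in
mm³ and is converted by rounding up. The filter presumes spatially smooth
noise (isolated false positives are spatially small), which is why the
synthetic generator produces smoothed noise fields. The filter is idempotent
and monotone in its threshold; both are tested.

Per-module summaries also count voxels at an uncorrected p < 0.01, which is
useful for comparing the spatial extent of associations with and without
multiple-comparison control; the uncorrected count can never be smaller than
the FDR-controlled count.

# Impact scores

R2 is most sensitive in white matter, but the biological reading of a
white-matter finding is usually about the gray-matter regions it connects.
Given a streamline table (endpoint gray-region pair plus traversed voxels
per streamline) and a significant ROI, `impactScores()` computes, over the
streamlines that traverse the ROI (at least one traversed voxel inside it —
no minimum overlap is imposed), the percentage connecting each endpoint
pair, and scores each gray region by summing the percentages of all pairs it
participates in. Percentages are relative to ROI-traversing streamlines, not
the whole atlas, so scores are comparable across ROIs of different sizes.
Pair percentages sum to 100; region scores sum to 200 when no streamline
self-connects (each streamline has two endpoints). A self-connecting pair
contributes its percentage once to its region, a convention chosen so no
streamline is double-counted within one region; the alternative (counting
twice) would make self-pairs dominate.

# Traits and variance explained

`moduleTraitGrid()` correlates every module with every trait. Binary traits
are coerced to 0/1, making the statistic the point-biserial correlation —
identical in formula to Pearson — so one statistic family covers the whole
grid and a single BH correction across all defined cells is coherent. Cells
with constant traits or fewer than 4 complete pairs are excluded from the
family rather than polluting it.

`incrementalVariance()` quantifies whether a module carries information
about a trait (e.g. the per-subject cognitive-decline slope, consumed as a
precomputed value; longitudinal slope estimation is out of scope) beyond
what mean R2 over trait-associated voxels already explains: it reports the
R² of trait on module, trait on base, and the gain of the nested full model
over the base model, which is nonnegative by construction.

# The synthetic cohort

Defaults emulate an aged, community-based autopsy cohort with paired omics
and imaging: 200 subjects; four planted 50-feature modules at within-module
correlation 0.6 among 400 features; a 24×24×24 grid of 1 mm voxels with a
brain-like ellipsoid mask (a box mask — all but a 1-voxel border — is
available when analyses need more in-mask voxels, e.g. ≥ 10⁴ for null
calibration); baseline R2 of 20 s⁻¹; residual fields built by convolving
white noise with an isotropic Gaussian kernel (SD 2 voxels) and rescaled to
unit marginal SD. Pathology scores use gamma distributions and Bernoulli
indicators with moments matching such cohorts (global AD pathology
0.75 ± 0.62, amyloid 4.82 ± 4.52, tangles 6.89 ± 8.18; gross infarcts
32.4%, microinfarcts 25.7%, Lewy bodies 20.3%), and covariates match
demographics (age at death 89.75 ± 5.96, 68.9% female, education
15.77 ± 3.59 years). Sex and education are simulated independent of modules
so covariate adjustment is testable both as a no-op and as an active
correction.

Three design choices deserve explanation:

* **Named seed substreams.** All randomness flows from one root seed through
  fixed offsets per stage (pathology, omics, volumes, streamlines, traits,
  clustering), so each stage is bit-reproducible in isolation and adding a
  stage never perturbs another's draws.
* **Exact in-sample trait planting.** The cognitive-decline slope is built
  as $y = \alpha m + \beta b + \sigma\varepsilon$ over the standardized
  module level $m$ and mean-R2 base $b$, with $\alpha, \beta$ solved from
  the requested marginal module R² and incremental R²
  ($\Delta R^2 = \alpha^2(1-\rho^2)$ and $(\alpha+\beta\rho)^2 = R^2_m$,
  $\rho$ the sample correlation of $m$ and $b$), and $\varepsilon$ drawn
  orthogonal in sample to the planted predictors. Without the
  orthogonalization the realized decomposition wanders around the target
  with the sampling error of $n = 200$ (occasionally by enough to make a
  planted effect undetectable), which confounds generator fidelity with
  analysis error; with it, recovery error measures the analysis alone.
* **Confounding is plantable on both sides.** A pathology can be given a
  correlation with a module's latent factor and an effect on R2 in a chosen
  ROI, creating a common-cause association between module and voxels that
  correct adjustment must remove, while directly coupled ROIs must survive.

What the generator does *not* emulate: registration error and other spatial
artifacts, non-Gaussian and spatially non-stationary noise, correlated
module latents, cell-type composition shifts, realistic streamline geometry
(traversals are axis-aligned segments), and any form of omics measurement
bias. Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to the full messiness of
real cohort data.

# Numerical choices and degenerate inputs

* Correlations are clamped to [−1, 1] before the t transform; |r| = 1 maps
  to p = 0.
* The BH critical p-value is 0 (nothing rejected) when no sorted p-value
  falls under its step-up line; the empty family is an error.
* Cluster reporting sorts by decreasing size with ties broken by smallest
  linear voxel index, making outputs deterministic.
* Voxel indices are 1-based linear indices in R array (column-major) order
  everywhere — in memory and in written tables. A mixed 0/1-based convention
  was rejected deliberately: the package's tables are consumed from R, where
  off-by-one translation at every boundary would be the dominant defect
  risk.
* Zero-variance features are filtered (with a logged count) before
  correlation; a zero-variance module level or an empty ROI is an error, not
  a silent NA.
* Ties in module sizes during renumbering resolve by original cluster
  label, so partitions are reproducible.

# Test design and problem sizes

The test suite checks hand-derived values (Pearson on 4-subject vectors, BH
on 4 p-values, hypergeometric tails against brute-force pmf sums, impact
scores by hand counting), cross-checks every nontrivial computation against
an independent oracle (`cor.test`, `p.adjust`, a fixpoint
connected-component labeller, closed-form regression), and runs
simulation-based checks at the package's reference conditions: 200-replicate
global-null calibration of the mapping stage on ≥ 10⁴ in-mask voxels
(achieved FDR well under q = 0.05 — BH is conservative under the positive
dependence that smoothed noise induces), planted-module recovery at
within-correlation 0.6 (ARI ≥ 0.9 over 10 seeds; in practice 1.0),
recovery of a planted 17% marginal / 7% incremental variance decomposition
within ±0.03 averaged over 20 seeds, and a planted common-cause confounding
scenario in which pathology adjustment suppresses the confounded ROI while
the directly coupled ROI persists. Monotone-recovery checks (ARI
non-decreasing in planted correlation over 0.3–0.9) use 3 seeds per level
and allow a 0.02 slack, since ARI at fixed conditions is a random variable
and strict pointwise monotonicity is not a theorem. These sizes were chosen
to estimate each property with useful precision while keeping the whole
suite in the low minutes on a single core.

# Known limitations

* The consensus procedure targets non-overlapping, positively correlated
  modules; overlapping modules and signed (anti-correlated) module structure
  are out of scope.
* FDR is controlled per family of voxelwise tests; no permutation-based
  cluster-mass inference or spatial smoothing of statistic maps is offered.
* Adjustment is linear; no mixed-effects, spatial or nonlinear models.
* The module counts found in real cohorts (tens of modules per omic) are
  data-dependent outcomes, not contracts of the algorithm; the package makes
  no attempt to reproduce a particular count.
* Impact scores inherit every limitation of the upstream tractography that
  produced the streamline table; the package treats that table as given.
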