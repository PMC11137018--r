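---
title: "Linking tumor radiomic phenotypes to somatic gene burdens: methods and design"
author: "radscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking tumor radiomic phenotypes to somatic gene burdens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscan)
```

## The problem

Pancreatic ductal adenocarcinoma is extraordinarily heterogeneous: the
same diagnosis covers tumors with very different mutational landscapes
and very different appearances on contrast CT. Beyond the
near-ubiquitous drivers (KRAS in >80% of patients, TP53 in roughly
two-thirds), most recurrently mutated genes are carried by only a
handful of patients in any cohort. `radscan` implements a radiome-wide
by genome-wide association scan for small oncology cohorts: every gene
with enough mutation carriers is tested against every quantitative
imaging feature of the tumor, so that genes shaping tumor morphology
can be found without pre-selecting either side.

The package covers five stages, each usable on its own:

1. **Radiomic feature extraction** from a 3D image plus a binary
   volume-of-interest (VOI) mask: first-order, shape and texture-matrix
   statistics (GLCM, GLRLM, GLSZM, NGTDM, GLDM) under the original
   image, a Laplacian-of-Gaussian filter and the 8 single-level wavelet
   bands - a canonical catalog of 944 named features.
2. **Gene-burden construction** from somatic variant calls: significance
   and consequence filters, per-variant recurrence, and the gene x
   patient carrier matrix.
3. **Feature heterogeneity and redundancy**: coefficients of variation
   and recursive correlation pruning.
4. **The association scan**: a variance-component (SKAT-type) score test
   per (gene, feature) pair, with mutation-matrix principal components
   as covariates, mixture-of-chi-square p-values and Benjamini-Hochberg
   adjustment.
5. **Survival stratification**: Kaplan-Meier curves and log-rank
   comparison of carriers of a gene set against non-carriers.

A synthetic-cohort generator with known ground truth ties the stages
together so that every claim the package makes about itself is checked
end to end by its test suite.

## Feature extraction conventions

All conventions are parameters of `feature_config()`; the defaults are
the ones used throughout:

* **Resampling**: images and masks are resampled to isotropic 2 mm
  voxels (trilinear for the image, nearest-neighbour for the mask) onto
  a grid covering the mask bounding box plus a one-voxel margin. Shape
  features are computed after resampling.
* **Discretization**: fixed bin width of 25 intensity units, anchored
  at the masked minimum, so gray levels are invariant to a global
  intensity shift. The number of levels `N_g` is data-driven.
* **Texture directions**: all texture matrices aggregate the 13 unique
  3D directions at distance 1 before feature computation (GLCM is
  additionally symmetrized), which makes every texture feature exactly
  invariant to 90-degree rotations of the VOI.
* **Wavelets**: one undecimated level of an orthonormal pair (Coiflet-1
  by default), applied along each axis with circular boundary handling;
  band `XYZ` names the filter applied along array axes 1, 2, 3. With an
  orthonormal pair the 8 bands carry exactly 8x the input energy - the
  test suite asserts this Parseval identity.
* **Laplacian of Gaussian**: sigma is specified in millimetres (default
  3 mm) and converted per axis through the voxel spacing; the discrete
  second-derivative kernels are calibrated to annihilate constants
  exactly and reproduce quadratics exactly.
* **Shape**: volume and surface area come from a marching-tetrahedra
  triangulation of the 0.5 isosurface. The binary mask is pre-smoothed
  with a separable [1,2,1]/4 kernel before meshing: a jagged voxel
  surface overestimates the area of a smooth object by tens of percent
  (a digitized ball would score a sphericity near 0.78), while the
  smoothed mesh brings a radius-20-voxel ball to within 2% of the
  analytic sphere. For masks so small that smoothing removes the
  interior, the raw binary field is used.
* **Degenerate inputs** (single voxel, single gray level, 0/0 ratios)
  yield 0 by a documented per-feature rule, with the natural exceptions
  (Idmn of a constant VOI is 1, GLCM correlation of a constant VOI is
  1), so a feature matrix never contains missing values.

The catalog counts are structural: 14 shape + 18 first-order + 24 GLCM
+ 14 GLDM + 16 GLRLM + 16 GLSZM + 5 NGTDM = 107 original features; the
93 non-shape features repeat under one LoG sigma and under each wavelet
band (93 + 744), for 944 in total. The co-occurrence/dependence split
(24 + 14 = 38) reflects the two distinct matrix types behind the
38-feature dependence-family count used in common radiomics platforms.

## Variant filters and the burden matrix

Records are kept when the adjusted somatic-call P-value is strictly
below 1e-5 and the consequence class is one of the six retained
classes (missense, stop gain, start loss, sequence feature, splice
donor, intron). The two filters commute, and carrier status is
idempotent under record duplication - both are asserted as properties.
Genes are kept when at least 3 of the patients carry at least one
qualifying record. Recurrence is reported both per alternate allele and
pooled per position (the convention under which two hotspot alleles at
one codon pool into a single recurrence count).

## The association scan

For a feature vector `y` across `n` patients, covariates `X`
(intercept plus the top-2 principal components of the column-centred
patient x gene carrier matrix) and a variants x patients genotype
matrix `G` with weights `w`:

* null model: `y = X a + e`, residuals `r`, `s2 = r'r / (n - rank X)`;
* score statistic: `Q = r' G' W^2 G r`;
* null distribution: `sum_i lambda_i chi2_1` with `lambda` the
  eigenvalues of `s2 W G P G' W`, `P = I - X (X'X)^-1 X'`.

With a single variant this reduces exactly to the square of the
classical score test - the suite asserts agreement to 1e-8 - and the
empirical type-I error at alpha 0.05 over 2,000 small-sample null
simulations stays in [0.03, 0.07].

Design choices that were genuinely open:

* **Variant weights** default to 1. The classical Beta(MAF; 1, 25)
  weighting is meaningful for population allele frequencies, not for
  somatic carrier indicators; it remains available via the `weights`
  argument.
* **Burden mode**: whether a gene enters as its variant-level genotype
  matrix or collapsed to a single carrier indicator is ambiguous in
  gene-based burden testing; both are implemented (`mode = "skat"` /
  `"burden"`) and the default is the variant-level kernel.
* **Tail evaluation**: the default evaluates the mixture tail by
  numerical inversion of the characteristic function (Imhof's
  integral; the exact scaled-chi-square closed form is used when all
  eigenvalues coincide). Moment matching (`method = "liu"`) is kept as
  a fast alternative, but it is only reliable in the right tail: when
  one eigenvalue dominates - which is exactly what a recurrent hotspot
  produces - the moment-matched surrogate clips the left tail to 1 and
  visibly distorts the null distribution of the scan. The accurate
  inversion is what lets the suite demand that null scan p-values pass
  a Kolmogorov-Smirnov uniformity test.
* **Trait transform**: radiomic features are routinely far from
  Gaussian - zone-size and cluster statistics are products of squared
  quantities and extremely right-skewed - and the score test's
  Gaussian error model miscalibrates badly on them at cohort sizes of
  26-100 (observed KS distance ~0.12 against uniform under the null).
  Each feature is therefore mapped to rank-based normal scores (Blom)
  before testing by default (`trait_transform = "inverse_normal"`);
  `"none"` recovers the raw-scale test. This is the one place the
  package deliberately goes beyond the minimal scan recipe, because
  without it the scan's p-values are not trustworthy at these sample
  sizes.
* **Significance calling** uses the raw p-value against alpha = 1e-4
  (a conventional stricter-than-nominal genome-wide screen threshold
  for small cohorts); BH-adjusted p-values are always reported
  alongside so either convention can be applied downstream.
* **PCs** are computed on the gene-level carrier matrix, the same
  matrix the burden analysis uses; signs are fixed by the
  largest-magnitude loading so results are reproducible across BLAS
  implementations.

## Feature selection

The coefficient of variation uses the sample SD over the absolute
mean, so a sign convention cannot flip a heterogeneity ranking;
zero-mean features are flagged rather than silently dropped.
"Recursive correlation pruning" is implemented as deterministic greedy
elimination: repeatedly remove the feature with the most remaining
partners above |r| = 0.8 (ties: larger mean |r|, then name), until no
pair exceeds the cutoff. The retained set provably contains no pair
above the cutoff, and every removed feature is assigned to its most
correlated surviving representative. Other published pruning variants
(hierarchical clustering with representatives, iterative deletion in
correlation order) can retain different counts; the retained count is
therefore reported, never asserted against an external value.

## The synthetic cohort

The generator is the package's study design, not a fixture; its
defaults are fixed and the validation studies run against them.

* **Phantoms**: a stationary Gaussian random field - white noise
  convolved with an isotropic Gaussian of width `correlation_length` -
  inside an ellipsoidal mask (default semi-axes 16 x 13 x 11 mm,
  roughly a 3 cm tumor, ~1,200 voxels at 2 mm). Skew is planted with a
  monotone exponential transform, which preserves the spatial
  correlation structure while controlling first-order asymmetry. The
  default correlation length is 3 mm: texture at the scale of the
  acquisition resolution, the regime in which texture statistics are
  actually sensitive (by 6 mm the features have largely saturated).
  Intensities are scaled to SD 50 HU-like units around a mean of 80,
  spanning a few hundred units across a VOI as contrast-enhanced tumor
  ROIs do; with the fixed bin width of 25 this yields on the order of
  10-20 gray levels. Much smaller spreads quantize to ~5 levels and
  alias the texture response.
* **Between-patient variation**: correlation length and intensity SD
  vary log-normally with 25% CV; skew and mean vary additively. The
  large observed heterogeneity of radiomic features across patients
  (CVs above 1 for a third of retained features) is the motivation for
  a generous between-patient spread.
* **Variants**: carrier status per (gene, patient) is Bernoulli with
  per-gene probabilities spanning 0.12-0.85 across a 40-gene pool,
  emulating carrier counts from ~3 to ~22 of 26. Per-patient record
  totals are Poisson with mean 51. Each gene has six fixed hotspot
  sites with Zipf-like recurrence weights; qualifying records are drawn
  from the hotspots, passengers get uniform positions and
  non-qualifying annotations. Hotspots matter: if every somatic variant
  were private to one patient, a variant-level kernel test would have
  no power against a carrier-level mean shift - recurrent sites are
  what make the kernel see the signal, exactly as recurrent codons do
  in real tumors.
* **Planted effects** shift a texture parameter of carriers of a
  designated gene by `delta` between-patient SDs. A correlation-length
  effect is expected to surface in the spatial-arrangement families
  (GLCM, GLRLM, GLSZM, NGTDM, GLDM), an intensity-SD or skew effect in
  first-order statistics; `planted_feature_families()` records this
  mapping.
* **Survival**: exponential event times with non-carrier median 331
  days; carriers of the designated gene set (default CDKN2A, PRKG1,
  BCORL1) have their hazard multiplied by `hazard_ratio` (default 2).
  Censoring is an independent exponential calibrated to the requested
  censored fraction (default 0: rapid-autopsy cohorts observe every
  death).

What the generator does **not** emulate: scanner and reconstruction
effects, contrast phases, anatomy, segmentation uncertainty, linkage
between genes, or any coupling between mutation count and survival
beyond the planted group. Passing validation on these phantoms
demonstrates that the pipeline recovers what it claims from data with
the declared structure - not that a given clinical dataset satisfies
that structure.

## Validation studies and problem sizes

The test suite runs, among others: brute-force enumeration oracles for
every texture family on 200 random 5x5x5 VOIs (exact for counts, 1e-9
for statistics); the single-variant score-test identity; the
mixture-tail evaluator against chi-square closed forms and a
1,000,000-draw Monte-Carlo tail; 10,000 null simulations for type-I
error; a 20-seed planted-recovery study at n = 100 with a +2 SD
carrier shift (called at raw p < 1e-4 in at least 80% of seeds); a
3-seed pooled null scan tested for p-value uniformity; and
hand-tabulated Kaplan-Meier and log-rank instances at 1e-10. The
cohort sizes (26 for study-scale checks, 100 for power studies) are
the package's chosen validation design.

## Known limitations

* Binary-trait outcomes, SKAT-O-style adaptive combinations and
  small-sample moment corrections of the score test are not
  implemented.
* The shape meshing is accurate for blob-like VOIs at the default
  resampling; thin structures a voxel wide mesh poorly (the smoothing
  fallback guards degenerate cases but accuracy degrades).
* The Imhof integral is evaluated to roughly 1e-6-1e-7 absolute
  accuracy; p-values far below 1e-12 are reported as 0.
* The per-feature extraction cost is dominated by the wavelet bands;
  extracting the full 944-feature catalog for a 26-patient cohort
  takes on the order of a minute, and validation studies use the
  compact `default_scan_panel()` instead.
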