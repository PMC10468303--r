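---
title: "Quantifying rough-eye degeneration and mapping its modifiers: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rough-eye degeneration and mapping its modifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`rougheye` measures ommatidial degeneration in compound-eye micrographs and
carries the measurements through the statistics of an inbred-panel modifier
screen. This vignette documents the models, the tunable parameters and the
choices made where the design was genuinely open, so that a user can judge
what a result does and does not show.

# Image pipeline

## Preprocessing and ROI selection

A color image is reduced to luminance (Rec. 709 weights 0.2126, 0.7152,
0.0722) and transformed with a white top-hat: the image minus its
morphological opening with a disk structuring element. The top-hat passes
bright features smaller than the element and removes flat or smoothly
varying background, which makes the bright-pixel threshold insensitive to
illumination gradients. The structuring radius (default 8 px) should be
about 1.5 times the expected ommatidium radius: smaller elements erode the
ommatidia themselves, much larger ones re-admit background structure.

Bright pixels are selected by Otsu's histogram threshold by default; a
fixed-quantile rule is available where exposure varies strongly between
batches. The ROI is then found by pruning and ellipse fitting:

* **Centroid-distance pruning.** The Euclidean distance from every bright
  pixel to the pixel-cloud centroid is computed and pixels beyond the 0.8
  empirical quantile are discarded. Quantiles use linear interpolation
  between order statistics (R's default type 7), and ties at the quantile
  are kept — pixels are discarded only when strictly farther. For any
  distinct-distance input of size n the retained fraction is within 1/n of
  the quantile.
* **Confidence ellipse.** The ROI is the ellipse defined by the sample mean
  and covariance of the retained pixel coordinates, with semi-axes scaled
  by the chi-square(2) quantile at the confidence level (default 0.95).
  Rank-deficient covariances (collinear pixels) are an error rather than a
  degenerate ellipse.

This isolates the in-focus face of the (3-D) eye and removes glare and
background, without any hand-drawn region. Coordinates are 1-based
(row, col) with pixel centers at integer positions, the R raster
convention.

## Segmentation and the 16 metrics

Inside the ROI, Otsu's threshold (computed over ROI pixels only) defines
foreground, and 8-connected components are the ommatidium candidates;
clusters below `min_cluster_size` (default 5 px) are treated as noise.
Ommatidia touching the ROI boundary are retained by default — the array
near the rim is still informative — but `exclude_boundary = TRUE` drops
them for users who prefer the conservative set.

Per cluster we compute: centroid (mean pixel coordinate); area (pixel
count); perimeter (Moore boundary chain, diagonal steps weighted sqrt(2));
radii as distances from centroid to boundary pixels, summarised as
mean/min/max/sample-SD; and eccentricity sqrt(1 - l2/l1) from the
eigenvalues of the second central moments. Each pixel contributes a 1/12
diagonal moment term (treating it as a unit square), which keeps
eccentricity strictly below 1 even for degenerate clusters. Radii use
boundary pixels only, so a pit that notches the rim or punches a hole
lowers `radius_min` immediately.

The image-level traits are the arithmetic mean and sample SD (n - 1) of
eight per-ommatidium measurements — nearest-neighbour distance,
eccentricity, area, perimeter, radius mean, radius SD, radius min, radius
max — giving 16 metrics. At least two ommatidia are required, otherwise
the SDs are undefined and the image is rejected.

Degeneration moves these metrics in predictable directions: fusion merges
blobs (area and perimeter means rise), pitting notches rims (radius-min
mean falls), and spatial disorder inflates the nearest-neighbour SD. These
directions are asserted over seeded replicates in the test suite.

# Synthetic data

The generator exists so every stage can be tested against ground truth; it
emulates the geometry the pipeline exploits, not photorealism.

* **Lattice.** Ommatidia are anti-aliased disks on a hexagonal lattice
  (rows offset half a spacing, row pitch spacing·sqrt(3)/2), so interior
  dots have six equidistant neighbours — the wild-type signature. Defaults
  (11 × 11 dots, spacing 16 px, radius 5 px, background 0.1, dots 0.9)
  give roughly the dot-to-spacing proportions of a mid-magnification eye
  image at a size small enough for fast tests.
* **Degeneration.** Fusion selects adjacent pairs with probability
  `fusion_rate` and draws a bright capsule (half-width 0.6 radius) between
  them; pitting subtracts a dark disk of half the dot radius at a random
  interior offset (0.3–0.7 radius), guaranteed to remove bright area;
  jitter adds isotropic Gaussian noise to centroids, clipping (with a
  recorded flag) when a dot would leave the frame. Acquisition noise of
  real micrographs is not calibrated; an optional additive Gaussian term
  (`noise_sd`, default 0) is provided but no claim is made that it matches
  any camera.
* **Phenotypes.** Replicated line values follow the screen's mixed model
  with chosen variance components; defaults (`var_line = 1`,
  `var_residual = 3`, 100 lines × 10 replicates) put true broad-sense
  heritability at 0.25, in the modestly-heritable range these traits
  occupy.
* **Genotypes.** Homozygous 0/1 panels (inbred lines carry no
  heterozygotes) with minor-allele frequencies uniform on `maf_range`,
  optional missingness, and population structure by a
  Balding–Nichols-style frequency shift between subpopulations — the
  simplest generative model that exercises PC covariate selection. Causal
  variants contribute additively to a trait. The default panel
  (162 lines) mirrors a realistic screen size.
* **Ortholog fixtures.** Pair tables and catalogs are constructed so a
  designated query has an exact planted count of qualifying pairs
  (score ≥ 3, human member in the catalog), with all other pairs built to
  be non-qualifying.

What passing tests show: the pipeline recovers known geometry, counts and
planted effects under these generative assumptions. What they do not show:
robustness to specular highlights, pigment variation, defocus, or other
photographic artifacts absent from the generator.

# Mixed model, BLUPs and heritability

Per trait, `y_ijk = mu + G_i + B_j + L_k + e_ijk` with image group and
batch fixed and line random, fitted by REML (lme4; convergence tolerance
is lme4's default, about 1e-8 on the criterion). Factors with fewer than
two observed levels drop out automatically, which covers the reduced model
without fixed effects. Negative variance estimates are truncated at zero
by the boundary REML fit, the standard behaviour for this model class. On
balanced one-way designs the REML components coincide with the ANOVA
method-of-moments estimator, which the tests assert to 1e-6; the BLUPs
equal the shrunken centred line means with weight
`var_line / (var_line + var_residual / r)`.

Broad-sense heritability is `H2 = var_line / (var_line + var_residual)`:
group and batch are fixed effects and contribute no variance, so the total
is the sum of the two components. The 95% CI is a percentile interval over
parametric-bootstrap refits (data simulated from the fitted model, as in
`bootMer`). The reference run uses 1,000 draws; the test suite and the
acceptance script use 200 draws and 100–200 simulation seeds (coverage
over 40–100 seeds), sizes chosen to keep the recovery study a few minutes
long while leaving Monte-Carlo error well inside the asserted margins
(mean bias 0.03, coverage ≥ 0.90).

Machine scores are validated against blinded human 0–4 scores by Spearman
correlation on matched line BLUPs, average ranks for ties, with the
analytic large-sample two-sided P (the data are far from the small-n
regime where an exact or permutation P would differ materially). Trait
selection keeps traits with `H2 > 0.05` (strict) and correlation
`P < 0.05`, and labels the keepers with the fixed central (5) /
dispersion (9) taxonomy; retained traits outside the taxonomy are flagged
for review, never silently classified.

The transgene analysis is an ordinary two-way fixed-effect interaction
model on 0/1 indicators, so coefficients are effects relative to the
control cell and the interaction term is the non-additive synergy.

# Association scan

Variants are filtered on missing rate (> 0.2 discarded) and minor-allele
frequency (< 0.05 discarded; MAF over non-missing calls). Missing data are
handled differently by stage, and deliberately so: PCA mean-imputes
(structure estimation wants all lines on all axes), while association uses
case-wise deletion per variant (a regression should not be driven by
imputed calls).

PC covariates come from the SVD of the standardised call matrix. The
number of PCs is chosen by a Patterson-style Tracy–Widom test: for each
leading eigenvalue the remaining spectrum estimates the effective marker
count `n' = m(m+2) / (m^2·S2/S1^2 - m)`, the eigenvalue is normalised and
compared with the TW1 critical value (0.9793 at alpha = 0.05; 2.0234 and
3.2724 at 0.01 and 0.001), stopping at the first non-significant PC. This
normalisation was verified against the TW1 null on simulated panels
(about 5% exceedance at the 0.05 critical value; unstructured panels
retain zero PCs ≥ 90% of the time, structured panels retain the true
axes).

The scan itself is OLS of line BLUPs on the 0/1 minor-allele class plus
covariates, one regression per variant, two-sided t test on the allele
coefficient. 0/1 coding is forced by biology: fully inbred lines have no
heterozygotes, so 0/1/2 dosage would be degenerate. Complete variants
share the covariate projection (Frisch–Waugh residualisation), which is
algebraically identical to per-variant OLS and is asserted against a
normal-equations oracle to 1e-10; variants with missing calls take the
explicit per-variant path. Records with too few usable lines
(n ≤ covariates + 2) or no allelic variation are flagged untested rather
than given a meaningless P.

BH correction is applied within trait by default — per-trait scans are
reported per trait — with a flag for pooled adjustment, since the
alternative reading is defensible. Significant hits are `p_adjust < 0.05`,
suggestive hits `p_raw < 1e-5`; the two sets are defined independently on
their own thresholds. Gene mapping assigns every annotated interval
(1-based inclusive, ± a window) overlapping the variant; the primary gene
is the deterministic tie-break (smallest start, then lexicographic id),
because the upstream pipeline's "gene 1" ordering is not reproducible from
the annotation alone.

# Permutation enrichment

The observed count is the number of ortholog pairs whose fly member is in
the query set, score ≥ 3, and human member in the disease catalog. Because
orthology is many-to-many, "count" is ambiguous: counting pairs and
counting distinct human genes are both implemented and the mode is a
required argument — no silent default collapses the distinction.

The null samples query-sized gene sets without replacement from the full
annotated universe (not only genes with orthologs: random draws from the
genome include ortholog-less genes, and so must the null). The default P
estimator is the add-one rule `(1 + #{ho_perm >= ho_obs}) / (1 + n_iter)`,
the standard estimator that cannot return zero; the plain proportion is
available behind `add_one = FALSE` for comparability with analyses that
used it. Under a null query the rejection rate at 0.05 sits at or slightly
below nominal — the count statistic is discrete, so the attained level is
conservative by at most one step of its distribution.

# Numerical and degenerate-input choices

* Flat images: top-hat returns all zeros; detection returns an empty set
  with a warning; quantification fails with a stage-tagged error.
* Empty ROIs or empty filtered scans warn and propagate empty results
  rather than stopping the whole batch/pipeline.
* All randomness flows through one explicit seed per spec or call; no
  generator touches the global RNG state without restoring it. Identical
  seeds give bit-identical images, tables, bootstrap draws and permutation
  counts.
* Perimeter of a single-pixel cluster is 0 by convention; radius SD of a
  single boundary pixel is 0.
* `run_full` writes per-stage TSV/JSON outputs plus a provenance record
  (config hash, seeds, per-stage counts, package version).

# Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use scaled designs chosen to
finish in minutes on one CPU while keeping Monte-Carlo error away from the
asserted thresholds: images at 11 × 11 dots (~200 px frames); heritability
recovery at 100 lines × 10 replicates over 100–200 seeds with 200
bootstrap draws; null scans with 2,000–10,000 variants on 162 lines;
end-to-end recovery on 20 panels of 162 × 5,000; enrichment nulls with
2,000 iterations over 200 seeded runs. The reference analysis these mirror
used larger sizes (e.g. 1,000 bootstrap draws, millions of variants);
nothing in the methodology depends on the scale.

# Known limitations

* The segmentation is threshold-plus-components; watershed splitting of
  genuinely touching ommatidia is out of scope, so heavy fusion is read as
  fewer, larger blobs — which is exactly the signal the metrics use, but
  it means per-ommatidium counts are not reliable under severe
  degeneration.
* The synthetic images do not model pigment loss, specularities or focus
  gradients; conclusions about real-image robustness need real images.
* Tracy–Widom selection assumes approximately independent markers; strong
  LD would inflate the leading eigenvalues and the retained PC count.
* The permutation test conditions on the query-set size only; it does not
  match gene length, ortholog multiplicity or other covariates of the
  query genes.
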