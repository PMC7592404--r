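---
title: "Density and GLCM entropy of apical lung parenchyma: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density and GLCM entropy of apical lung parenchyma: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungtexture)
```

## The problem

Patients considered for radical (curative-intent) lung radiotherapy have
their respiratory reserve assessed with formal lung-function tests: FEV1
(forced expiratory volume in one second) and TLCO (carbon-monoxide transfer
factor), each expressed as a percentage of the value predicted for the
patient's age, height and gender. A common working rule labels a patient
*fit* when both values are at or above 50% predicted and *unfit* when either
falls below. Every such patient also has a planning CT. Emphysematous
destruction of alveolar walls — predominantly apical in the centrilobular
pattern seen in smokers — produces low-density, internally homogeneous air
spaces (bullae) that are visible in that scan. This package quantifies
exactly that: the density and textural disorder of a small, standardised
cylinder of apical lung parenchyma, and asks whether those two numbers
separate fit from unfit cohorts.

## The measurement pipeline

1. **Volume input.** A single 3-D CT volume per patient (NIfTI). When a 4-D
   breathing-phase series is available, `average_phases()` collapses it into
   an average-intensity (AVIP) volume first; the apex moves little with
   respiration, so the mean is a reasonable single-volume summary. Grey
   levels are used exactly as stored (after the format's slope/intercept);
   the method never assumes Hounsfield calibration, so absolute density
   values are convention-dependent and only comparisons within a cohort
   analysed under one convention are meaningful. Arrays are indexed
   `[row, column, slice]` with the slice index increasing inferior to
   superior — the natural order for R's column-major arrays and the NIfTI
   voxel layout — and this convention is fixed, not configurable.

2. **VOI geometry.** A right circular cylinder, 40 mm in diameter, spanning
   10 consecutive slices (25 mm at the nominal 2.5 mm slice thickness),
   placed in the lung apex contralateral to the tumour. A voxel belongs to
   the mask iff its centre lies strictly inside the circle and on an
   included slice: a reproducible, resolution-independent rule. We read the
   geometry as a 4 cm *diameter* circle (an 8 cm circle could not exclude
   chest wall and rib circumferentially in an apex). If a volume's slice
   thickness differs from the expected 2.5 mm, the 10-slices semantics wins:
   the code warns and keeps `n_slices` slices. Placement is supplied
   explicitly (`cylinder_spec`); automatic apex localisation is out of
   scope, matching clinical practice of hand-drawn ROIs.

3. **Reference-fixed quantisation.** Grey levels are quantised into 16
   equal-width bins whose edges span the min–max range of one *reference*
   VOI (`derive_levels()`), then held fixed for every patient
   (`apply_quantisation()`), so level *k* denotes the same density across
   the cohort. Bins are half-open, left-closed, with the top edge mapping to
   level 16. Values outside the reference range — possible for any
   non-reference patient — are clipped to the end levels and the
   out-of-range fraction is reported as a warning. The min–max span of the
   reference VOI is an assumption (a fixed scanner range would also be
   defensible); it guarantees the reference itself uses all 16 levels. A
   synthetic reference scheme derived from a pristine phantom is packaged
   (`default_reference_scheme()`) for phantom work.

4. **Voxel-wise GLCM entropy.** For each in-mask voxel a grey-level
   co-occurrence matrix is accumulated over the 26 surrounding voxels (the
   13 displacement directions and their negatives, at displacement 1 in
   index space). Each centre–neighbour pair increments cell
   $(k_\text{centre}, k_\text{neighbour})$ *and its transpose*; counts are
   normalised and the voxel's score is the Shannon entropy
   $H = -\sum_{p_{ij} > 0} p_{ij} \log_2 p_{ij}$ in bits. Homogeneous
   tissue (bulla interiors) scores near zero; mixed parenchyma scores high.
   Conventions that the literature leaves open, fixed here:

   * **Symmetrisation.** The transpose-increment convention above (the
     standard Haralick symmetrisation, doubling the diagonal). Note a
     subtlety: since all mass lies in one row and one column, the matrix has
     at most 31 distinct non-zero cells, so the attainable per-voxel maximum
     is $\log_2 31 \approx 4.95$ bits, not $\log_2 26 \approx 4.70$; white
     uniform noise over 16 levels can exceed 4.70. Spatially correlated CT
     texture sits far below either bound in practice (the test suite checks
     the 4.70 bound over random phantoms).
   * **Logarithm base 2** (bits). With this construction, tissue-like
     phantom textures score roughly 1.8–3 bits — the scale the original
     study reported.
   * **Boundary rule.** Neighbours outside the grid or outside the VOI mask
     are skipped; the voxel keeps its entropy from the remaining pairs
     (`valid_pairs` records how many). This avoids padding artefacts in a
     thin cylinder. A voxel with *no* valid neighbour is flagged and
     excluded from the map.
   * **Displacement in index space**, not millimetres: one voxel along each
     axis, despite anisotropic spacing. No physical-distance weighting is
     applied and volumes are never resampled.
   * The module is fully deterministic.

5. **Features.** Per patient (`build_feature_record()`): mean, median and
   mode of density (raw grey levels — quantisation only feeds the GLCM) and
   of entropy; a moment analysis (Fisher–Pearson skewness and excess
   kurtosis, biased population estimators — the plain moment definitions);
   and the *low-density low-entropy subregion*: the count and fraction of
   voxels with density below a threshold AND entropy below a threshold,
   where bullae accumulate. The mode of a continuous signal is defined over
   bins (the quantisation edges for density, 16 equal bins over
   $[0, \log_2 26]$ for entropy), ties resolved to the lowest bin midpoint.
   Default subregion thresholds are the scheme's level-4/5 edge and 1 bit;
   both are configuration parameters since no canonical values exist.

6. **Cohort statistics.** Fit/unfit labels from the 50%-predicted rule
   (threshold configurable); a two-sided Mann–Whitney test per feature
   (rank-based, appropriate for the skewed distributions these features
   have); Spearman rank correlations of features against FEV1 and TLCO. The
   Mann–Whitney p-value is exact by full enumeration for pooled samples of
   at most 12 without ties, otherwise a normal approximation with
   tie-corrected variance and continuity correction — the variant is fixed
   and tested against an independent implementation. Raw p-values are the
   primary report (one test per feature); a Holm-adjusted column is emitted
   alongside, clearly labelled, without changing the headline values.

## The phantom generator

No patient data accompany the method, so `generate_phantom()` /
`generate_cohort()` synthesise VOI-scale volumes with the statistical
structure the analysis relies on:

* **Healthy parenchyma**: Gaussian-smoothed white noise (correlation length
  `smooth_mm` = 1.5 mm) rescaled to mean `base_density` = 220 and spread
  `texture_sd` = 60 grey levels, plus bright tubular vessel segments
  (`vessel_density` = 0.2 cm⁻³, +250 grey levels). A smoothed random field is
  the minimal structure that gives healthy tissue non-trivial entropy; it is
  not a physiological airway-tree model.
* **Emphysema**: spheres with radii uniform in 2–6 mm overwrite tissue with
  `bulla_value` = 30 ± 8 grey levels until the bulla volume fraction reaches
  the severity *s* ∈ [0, 1]. Additive acquisition noise (sd 12) is applied
  last. The default scales were chosen once, on the grounds that healthy
  apical parenchyma in the study's offset grey-level convention sits near
  200–250 with bullae near air values, and CT noise is small against
  tissue–air contrast.
* **Severity → lung function**: FEV1 = 95 − 90·s, TLCO = 80 − 90·s, each
  plus independent N(0, 8) noise, clamped to 10–130% predicted. Fit
  severities follow Beta(2, 18) (mean 0.10), unfit Beta(18, 22) (mean 0.45).
  These four numbers were calibrated once against the published group means
  (fit ≈ 85/74, unfit ≈ 53/43 %-predicted) and the requirement that the
  50% rule recover the intended groups for ≥ 90% of patients at the default
  noise.
* **Cohort composition**: 29 fit and 32 unfit patients, matching the study;
  the first fit patient is generated at severity 0 and flagged as the
  quantisation reference (the "fit non-smoker"). One master seed drives
  per-patient seeds, so cohorts are reproducible patient by patient.

One behaviour worth knowing: at *low* bulla burden the median VOI entropy
can tick slightly *up* before it falls. Scattered small bullae contribute
interface voxels (locally very mixed neighbourhoods) while their
homogeneous interiors are still too few to move the median; only from
roughly 20% burden onward does the decline dominate. Mean density, by
contrast, falls monotonically from the first bulla. The property tests
assert exactly this shape, and the cohort-level separation between fit
(s ≈ 0.1) and unfit (s ≈ 0.45) groups is unaffected.

A second behaviour matters for interpretation: the *density* contrast
between simulated fit and unfit groups is robust, but the *entropy*
contrast depends on the texture scale relative to the voxel grid. The GLCM
displacement is one voxel in index space, so at the full 1 mm in-plane
resolution the sampled lag is short against the 1.5 mm parenchymal
correlation length: healthy tissue looks locally smooth, its entropy falls
toward the bulla level, and the group difference shrinks. On top of that,
the cohort's bins span the min–max of a single random reference phantom, so
a bright vessel in the reference stretches the bin width (roughly 37–52
grey levels across seeds) and shifts every patient's entropy jointly —
cohort-level entropy contrasts at full resolution therefore vary from seed
to seed and can reverse. At the coarser 2 mm in-plane scale used for the
replicate studies the texture is under-resolved relative to the lag and the
entropy contrast is strong and stable. Real parenchyma carries sub-voxel
structure that the smoothed-field phantom lacks, which is one more reason
phantom results quantify the computation rather than clinical effect sizes.

What the phantoms do **not** emulate: reconstruction kernels and beam
hardening, breathing motion, the spatial apex-predominance of centrilobular
disease (the whole phantom *is* the apical VOI), true airway/vessel
anatomy, and scanner-to-scanner grey-level conventions. Tests passing on
phantoms therefore demonstrate the correctness and operating
characteristics of the *computation*, not clinical performance on real
scans.

## Problem sizes and numerical choices

* Full-resolution phantoms are 48 × 48 × 14 voxels at 1 × 1 × 2.5 mm
  (≈ 12 500 in-mask voxels — the study geometry); the replicate operating
  characteristic studies in the tests and the acceptance script use
  24 × 24 × 14 voxels at 2 × 2 × 2.5 mm (≈ 3 000 in-mask voxels), which
  preserves the 40 mm × 25 mm cylinder while keeping 200 simulated cohorts
  of 61 patients comfortably inside a coffee break on one CPU.
* An entropy map of the full-resolution VOI computes in well under a second
  (the per-voxel matrices collapse to neighbour-level histograms and are
  vectorised over the mask).
* Uniform edge spacing is enforced to 1 part in 10⁹; the probability-matrix
  normalisation check uses 10⁻⁸; oracle equivalence tests assert 10⁻¹² or
  exact integer equality.
* Degenerate inputs are rejected with specific errors: constant reference
  VOIs (no derivable edges), constant samples in `moments()` (zero
  variance), empty masks, isolated voxels (excluded, flagged), empty
  cohorts or single-class labelings.

## Reproducibility

The pipeline (`run_pipeline()`) is deterministic given its inputs: the
quantisation scheme is derived exactly once per run from the designated
reference and recorded, with the configuration hash, in `manifest.json`;
rerunning the same configuration reproduces `features.csv` and
`comparison.csv` byte for byte. All simulation randomness flows from
explicit seeds.

## Limitations

* Absolute density values depend on the scanner/export convention; only the
  published directionality (unfit below fit) is expected to transfer, never
  the absolute group means.
* The fixed 16-level scheme clips patients whose VOI exceeds the reference
  range; the warning reports the clipped fraction, and a reference chosen
  from pristine lung keeps that fraction small but non-zero in emphysema.
* Entropy is the single texture measure by design (avoiding multi-feature
  overfitting); the package deliberately implements no further Haralick
  features.
* Mann–Whitney p-values at n = 29/32 use the normal approximation; no
  claim of exactness is made at those sizes.
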