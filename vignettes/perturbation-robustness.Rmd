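---
title: "Assessing radiomic feature robustness by image perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing radiomic feature robustness by image perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radiomic models summarise a region of interest (ROI) in a medical image —
here, a gross tumour volume in CT — through hundreds of quantitative
features: shape descriptors, intensity statistics and texture measures.
Features that are sensitive to small differences in patient positioning,
acquisition noise or delineation do not transfer to new images, so
robustness screening is a standard preprocessing step. The reference
procedure is test–retest imaging: acquire the same anatomy twice, compute
features on both images and keep only features that agree. Test–retest data
are rarely available, however.

`radrobust` implements a single-image alternative: the image and its ROI
mask are distorted by chains of five perturbation operators, the feature set
is recomputed on every distorted copy, and each feature's repeatability
across the copies is scored by the intraclass correlation coefficient. A
feature that survives perturbation is treated as a candidate robust feature,
exactly as a feature that survives test–retest imaging would be.

## The perturbation operators

Five operators act on an image $I$ and mask $M$; all parameters are in
physical units (mm, degrees, HU), never raw voxel indices.

* **Rotation (R).** An affine in-plane rotation about the z-axis by
  $\theta$ degrees, by default $\theta \in [-13^\circ, 13^\circ]$. The
  image is resampled trilinearly; the mask becomes a fractional occupancy
  field that is re-thresholded later. The rotation centre defaults to the
  ROI centre of mass so the tumour cannot drift off the grid; the grid
  centre or any explicit point can be configured instead.
* **Noise addition (N).** I.i.d. Gaussian noise with mean zero and a
  standard deviation equal to the noise level *estimated from the image
  itself*. The estimator applies the discrete 1-D Laplacian
  $x_{i-1} - 2x_i + x_{i+1}$ along each axis (it annihilates constant and
  linear structure), rescales by $\sqrt{6}$, and takes the median absolute
  deviation of the pooled residuals, restricted to voxels above a body
  threshold (default $-500$ HU, which drops air in CT). A pure gradient
  therefore estimates $\approx 0$ while a flat noisy field recovers the
  true $\sigma$; both behaviours are tested. The estimate is made once per
  input image, not per perturbed copy.
* **Translation (T).** A sub-voxel shift by fractions
  $\eta \in [0, 0.75]$ of the voxel spacing, realised by trilinear
  resampling. A grid of $m$ fractions is permuted over the three axes,
  giving $m^3$ distinct shifts.
* **Volume adaptation (V).** Grows or shrinks the mask by a signed
  fraction $\tau \in [-0.28, 0.28]$. The implementation computes the
  Euclidean signed distance to the mask boundary (exact distance
  transform, anisotropic spacing respected), ranks voxels by that
  distance, and keeps the $\mathrm{round}((1+\tau)N_0)$ closest. Growth is
  therefore always a superset and shrinkage a subset of the input, the
  count error is bounded by distance ties (broken deterministically in
  array order), and any $\tau$ is reached smoothly. On digital spheres the
  achieved count is within 2% of target.
* **Contour randomisation (C).** The image is over-segmented into 3-D
  SLIC supervoxels (deterministic grid initialisation, combined
  intensity/space metric, default target volume 150 mm³ and compactness
  20 HU). Each supervoxel with fractional overlap $f$ with the mask is
  always kept when $f \ge 0.9$, kept with probability $f$ when
  $0 < f < 0.9$, and never added when $f = 0$: the ROI core survives while
  the rim is resampled. Both thresholds and all SLIC settings are
  configuration, because the appropriate supervoxel scale depends on
  modality and resolution. On a sharply contrasted noise-free phantom SLIC
  snaps exactly to the intensity boundary and the randomisation
  degenerates to the identity — real CT boundaries are fuzzy, which the
  noisy phantoms used in the tests emulate.

Operators compose into 18 labelled chains (R, N, T, V, C, RT, …, NTVC).
Whatever the label order, application follows the fixed processing order
rotation → noise → translation → *isotropic interpolation* → volume
adaptation → contour randomisation, so that the geometric operators act on
the native grid and the mask operators on the interpolated grid. A chain's
parameter grids are fully permuted; the number of perturbed copies is the
product of the grid sizes. The shipped default grids reproduce the
conventional per-chain image counts (27–40 per chain); they are a plain R
structure (`default_chain_registry()`) and each entry can be replaced to
match any published parameter table.

## Image processing

Processing between perturbation and feature computation follows the usual
radiomics standardisation scheme:

* interpolation to isotropic voxel spacings (default 1, 2, 3 and 4 mm) by
  trilinear resampling with prior Gaussian anti-aliasing. The smoothing
  parameter $\beta = 0.93$ is interpreted as the band fraction preserved at
  the target Nyquist frequency: along any axis that is downsampled by a
  ratio $r > 1$ the image is pre-smoothed with $\sigma = \beta r / \pi$
  source voxels; upsampled axes are not smoothed, which keeps trilinear
  interpolation exact on affine intensity fields;
* rounding of interpolated intensities to the nearest integer HU, with
  halves rounded away from zero for bit-reproducibility;
* binarisation of the (fractional) mask at the partial-volume threshold
  0.5;
* re-segmentation of the intensity mask: first the HU window (default
  $[-300, 200]$, the soft-tissue window for lung; $[-150, 180]$ fits neck
  anatomy), then a single $\pm 3\sigma$ outlier pass with $\mu, \sigma$
  computed on the window-filtered ROI. The order matters — gross outliers
  like air pockets would otherwise inflate $\sigma$ — and the pass is not
  iterated;
* discretisation, either to a fixed number of bins
  ($g = \min(N_b, \lfloor N_b (x - x_{\min})/(x_{\max} - x_{\min})\rfloor + 1)$,
  defaults 8, 16, 32, 64) or to fixed bin sizes anchored at the lower edge
  of the re-segmentation range ($g = \lfloor (x - lo)/w \rfloor + 1$,
  defaults 6, 12, 18, 24 HU). Anchoring at the range minimum rather than
  the ROI minimum keeps grey levels comparable across images and is the
  choice that changes feature values most, hence it is called out here.

## The feature set

182 base features span 11 families: morphology (29), local intensity (2),
intensity statistics (18) and intensity–volume histogram (15) need no
discretisation; intensity histogram (23), grey level co-occurrence (25),
run length (16), size zone (16), distance zone (16), neighbourhood grey
tone difference (5) and neighbouring grey level dependence (17) are
computed per discretisation setting. Expanded over 4 spacings and 8
discretisation settings this yields $64 \times 4 + 118 \times 4 \times 8 =
4032$ features per image. The exact family split of the 64 non-discretised
features is documented in `build_manifest()` and validated at run time.

Numerical choices worth knowing:

* the ROI surface is meshed by marching tetrahedra at the 0.5 iso-level of
  the occupancy field smoothed with $\sigma = 0.7$ voxels; vertex placement
  uses linear interpolation and volume follows from the divergence theorem
  over outward-oriented triangles. Meshing the raw binary field instead
  overestimates a sphere's surface by roughly 28% (the voxel staircase),
  which would bias every area-derived descriptor; with smoothing a
  radius-10 mm digital sphere reproduces the analytic volume within 1% and
  sphericity 0.98;
* the oriented bounding box is approximated in the principal-axis frame,
  and the minimum-volume enclosing ellipsoid by Khachiyan's algorithm on
  the convex hull of surface-voxel centres (hull built by an incremental
  beneath–beyond algorithm); ellipsoid surface areas use Thomsen's
  approximation (error < 1.1%);
* Moran's I and Geary's C are $O(n^2)$ in ROI voxels and use a
  deterministic, evenly spaced subsample of at most 600 voxels on larger
  ROIs;
* GLCM and GLRLM are built in 3-D for the 13 unique directions at
  Chebyshev distance 1 and their features averaged after computation; the
  zone, distance-zone, tone-difference and dependence families use one
  matrix per ROI with 26-connectivity, and the dependence coarseness
  parameter is $\alpha = 0$;
* degenerate inputs return defined limits where a natural one exists (a
  one-level ROI has GLCM correlation 1, histogram entropy 0) and a flagged
  `NA` otherwise (Moran's I of a constant ROI, pair-based texture of a
  single-voxel ROI) — never a silent zero.

## Robustness statistics

For each feature, the $n \times k$ panel of subjects × perturbed copies
feeds the one-way random-effects, single-measurement intraclass
correlation:

$$\mathrm{ICC}(1,1) = \frac{\mathrm{MSB} - \mathrm{MSW}}
  {\mathrm{MSB} + (k-1)\,\mathrm{MSW}},$$

with the exact F-based 95% confidence interval
($F_L = F_0 / F_{1-\alpha/2;\,n-1,\,n(k-1)}$,
$F_U = F_0 \cdot F_{1-\alpha/2;\,n(k-1),\,n-1}$, bounds
$(F_x - 1)/(F_x + k - 1)$). Negative estimates are retained rather than
truncated — classification only reads the interval. A panel with zero
within-subject variance has ICC exactly 1 and the degenerate interval
$[1, 1]$; a panel with zero total variance has no defined ICC and is
flagged rather than scored.

Classification against the threshold 0.90 is three-state: *robust* when the
whole interval lies at or above the threshold, *non-robust* when the whole
interval lies below, *indeterminate* when it straddles. With two replicate
images per subject the perturbation ICC and its interval bounds are
averaged element-wise over the two replicates, the test–retest ICC is
computed from the unperturbed features of the two replicates, and each
feature lands in a comparison category with test–retest as reference:
true/false positive/negative, or indeterminate with the sub-state (e.g.
`T0P+`) retained. False positives — robust under perturbation but not under
test–retest — are the quantity a good perturbation chain minimises.

Subjects with a missing value for a feature are dropped listwise for that
feature; interval width shrinks as the number of perturbed copies grows, so
the indeterminate fraction is partly a budget choice.

## The phantom generator

`generate_phantom()` builds ellipsoidal ROIs in a uniform background with
constant, linear-ramp or textured foreground (a smoothed Gaussian random
field quantised to a configurable number of grey levels) plus optional
additive Gaussian noise, all strictly determined by a seed. The phantoms
emulate the *geometry* of a tumour ROI, realistic HU scales, and a
controllable noise floor — enough to exercise every processing stage and to
verify operators against analytic ground truth (sphere volumes, ramp
interpolation, known noise σ). They do not emulate scanner physics:
no reconstruction kernels, no streak or beam-hardening artefacts, no
anatomical context, and their intensity boundaries are sharper than real
tumour margins. Passing tests therefore validate the machinery, not any
clinical claim about which features are robust in patients.

## Reproducibility and problem sizes

Every stochastic step (phantom noise and texture, noise addition,
supervoxel selection) draws from a private RNG stream seeded by a
deterministic hash of the base seed, the chain label, the parameter tuple
and the repetition index. Re-running a sample's recorded provenance
reproduces it bit-exactly, and a whole `run_robustness()` with a fixed base
seed writes byte-identical CSVs.

The test suite runs phantom cohorts at 2–3 mm spacing with grids of
$16^3$–$36^3$ voxels and restricted manifests (one spacing, one or two
discretisation settings), which keeps the full suite under a minute while
still covering every operator, family and statistic; the cohort sizes
($n = 2$–8 subjects, $k = 2$–6 repetitions) are chosen so each statistical
property under test (parameter recovery, CI coverage, classification) has
adequate resolution at that scale.

## Known limitations

* CT only in spirit: no intensity standardisation for MRI and no SUV
  handling for PET, although nothing in the data model forbids other
  scalar volumes.
* DICOM series and RTSTRUCT files are not parsed; NIfTI is the interchange
  format, with RTSTRUCT-style planar polygons accepted as plain coordinate
  lists via `rasterise_contours()`.
* In-plane rotation only; no elastic deformation or scanner simulation.
* The supervoxel scale for contour randomisation is resolution-dependent
  and will need adjustment for non-CT modalities.
* NIfTI stores spacings as 32-bit floats; round-trips are bit-exact only
  for spacings representable at that precision.
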