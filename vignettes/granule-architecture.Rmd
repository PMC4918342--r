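---
title: "Mapping mRNA organization inside germ granules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mRNA organization inside germ granules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulescope)
```

## The problem

Germ granules are membraneless ribonucleoprotein condensates, up to about
500 nm across, in the posterior germ plasm of the early *Drosophila*
embryo. Localized mRNAs (e.g. *cycB*, *nos*, *pgc*, *gcl*) concentrate in
them as homotypic clusters — multi-copy aggregates of a single species that
occupy a defined position within the granule, some central, some at the
granule edge. Resolving that internal organization from two-channel 3D
smFISH / structured-illumination stacks requires a chain of quantitative
steps, each of which this package implements and tests against simulated
ground truth:

1. a **forward model** (scene generator + renderer) that produces stacks
   with known emitter positions, copy numbers and channel shifts;
2. **sub-pixel spot detection** to localize mRNA clusters and granule
   centers to a few nanometres;
3. **fiducial-bead registration** of the two channels;
4. **co-localization statistics** — object overlap, Pearson correlation,
   Costes-thresholded PCC with block-shuffle significance, and
   center-to-center distances;
5. **absolute quantification** — single-mRNA intensity calibration, molar
   concentration, and mask-based localization efficiency;
6. **triangulation** — embedding the average 5-point granule architecture
   from its 10 pairwise distances and classifying the mirror-image
   solution families.

Because the original microscope data are not deposited, every claim the
package makes is validated by parameter recovery on synthetic scenes whose
truth is known exactly.

## The forward model

A scene is a list of point emitters (mRNAs; a homotypic cluster of k
copies is one emitter of k × unit intensity), Gaussian granule blobs, and
beads visible in all channels, in nm coordinates. Rendering integrates a
separable 3D Gaussian over each voxel: the contribution of an emitter at
position $p$ to voxel $i$ along one axis is
$F\,[\Phi((x_{i+1}-p)/\sigma) - \Phi((x_i-p)/\sigma)]$, with $\Phi$ the
normal CDF. Voxel integration (rather than point sampling) makes flux
conservation exact up to the 5-sigma support window, which the tests
verify to < 1%.

Defaults mirror the imaging regime the pipeline targets: voxels of
56 × 56 × 200 nm; granules drawn from a truncated normal (mean 350 nm,
capped at 500 nm); cluster radial offsets staged at 54 nm (central),
198 nm (peripheral) or 408 nm (chance-level); PSF widths
$\sigma_{xy} = 80$ nm, $\sigma_z = 250$ nm. The lateral/axial PSF widths
are a modeling choice — super-resolution reconstructions do not come with
a published Gaussian width — and are exposed in every relevant function.
Granule blobs render with the blob radius (diameter/4) added to the PSF in
quadrature.

Noise is Poisson shot noise on signal + background followed by additive
Gaussian read noise, with a recorded seed; identical configuration and
seed reproduce stacks bit for bit.

**What the simulator does not emulate:** structured-illumination
reconstruction artifacts (honeycombing, negative ringing), depth-dependent
aberrations, autofluorescence texture, probe-labeling stochasticity, and
granule shape irregularity (blobs are isotropic Gaussians). Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to every real-data pathology.

## Spot detection and fitting

Candidates are local maxima (26-neighborhood) above a threshold —
`"auto"` uses median + 5 × MAD of the whole stack, robust statistics that
ignore the sparse bright spots — followed by non-maximum suppression
within one fit window (default 7 × 7 × 5 voxels).

Each candidate is fitted with a fixed-width voxel-integrated 3D Gaussian
on an affine local background $a_0 + a_x x + a_y y + a_z z$. For a trial
center, all five linear parameters (four plane coefficients and the flux)
are profiled out by linear least squares; only the three center
coordinates are optimized (L-BFGS-B within the window). Profiling the
background jointly, rather than pre-estimating it from the window border,
avoids the bias the PSF tails would impose on a border-only estimate and
makes the noiseless fit exact — the tests recover staged sub-voxel centers
to well under 1 nm and cluster intensities on a steep intensity ramp to
1%. Integrated intensity is the fitted flux (amplitude × Gaussian volume),
reported in ADU. Fixed PSF widths are the default because the kernel
should represent the average point-spread function, not adapt to each
spot; the widths are arguments where a different optical configuration
needs them.

The single-mRNA unit intensity is the median (robust to the bright tail
of unresolved doublets; mean available) of ≥ 50 fitted singles, and
cluster copy number is cluster intensity / unit, reported as both a real
and a rounded count.

## Channel registration

The shift model is a pure 3D translation, estimated as the mean
displacement of mutual-nearest-neighbor bead pairs; alignment precision is
the RMS residual displacement after correction. Spots are always corrected
in coordinate space (exact); stack resampling (trilinear, zero-padded)
exists only for visual overlays. No rotation, scaling or field-dependent
correction is modeled — the staged misalignment is a camera-registration
pixel shift, not chromatic aberration.

## Co-localization statistics

Segmentation is intensity-only (fixed threshold or Otsu; no shape
filtering), 8-connected in 2D and 26-connected in 3D. Overlap between two
particle sets uses the ≥ 1 shared pixel criterion; reported are the per
cent of query particles overlapping a reference particle, the
particle-count ratio, and per-reference-particle area coverage.

PCC is the Pearson correlation of voxel intensities over the ROI. The
Costes thresholds are found on the orthogonal (total least squares)
regression line between the channels, walking down from the maximum of
channel A in 1% quantile steps until the PCC of sub-threshold voxels is
≤ 0 (the walk schedule is a convention; published descriptions leave it
open, and we take ≤ 0 rather than = 0 as the stopping target). If no
threshold achieves it — e.g. for identical images — minimum-intensity
thresholds are returned with a flag, so PCC(Costes) of a channel with
itself is 1.

Randomization significance shuffles pixel blocks of one channel (block
edge = PSF FWHM in voxels, rounded up, configurable), recomputes the
thresholded correlation against the untouched channel n = 200 times, and
reports 100 × the fraction of null values below the observed PCC(Costes).
Two implementation decisions matter here: the ROI is cropped to a whole
number of blocks (a partial, unshuffled remainder would retain true
correlation and bias the null), and the thresholds are estimated once on
the observed pair and held fixed during the shuffles (threshold
re-estimation is undefined whenever a shuffled pair is not positively
correlated, which is the typical null case).

Center-to-center distances are measured between fitted sub-pixel spot
centers of overlapping particle pairs, in nm with anisotropic calibration.
Localization precision from repeated acquisitions of the same field
tracks neighboring spot pairs across repeats and reports the mean absolute
deviation of each pair's distance from its first-acquisition value
(s.e.m. alongside; RMS also available — whether the canonical statistic is
mean-absolute or RMS is ambiguous, so both are exposed).

## Absolute quantification

Concentration is exact arithmetic:
$c\,[\mathrm{nM}] = N / (N_A \cdot V[\mathrm{L}]) \times 10^9$. ROI counts
extrapolate to the embryo by the volume ratio; the embryo volume is a user
input (the field volume in synthetic work).

Localization efficiency applies the 3D granule mask (connected components
of the protein channel above a threshold) to the mRNA channel: localized
mRNA-equivalents are the background-subtracted fluorescence inside the
mask divided by the unit intensity (background = modal intensity outside
the mask), and the raw percentage of the embryo total is divided by the
mask's **capture fraction** — the fraction of true cluster signal the mask
actually covers. Peripheral clusters straddle the mask boundary, so their
capture fraction is well below 1 and the correction is substantial; the
tests verify that central placements are captured better than peripheral
ones and that inside + outside equivalents reconstruct the staged total
within 2%.

## Triangulation and chirality

The average granule architecture — one protein center plus four cluster
centers — is embedded from its 10 mean pairwise distances by minimizing
$\sum_{i<j}(\lVert x_i - x_j\rVert - d_{ij})^2$ (unweighted by default;
$1/\sigma^2$ weighting available). Optimization is quasi-Newton (BFGS with
an analytic gradient) from 5 random starts, keeping the best, followed by
a Levenberg–Marquardt polish in a gauge-fixed parameterization (point 1 at
the origin, point 2 on +x, point 3 in the xy-plane; 3n − 6 parameters
against n(n−1)/2 residuals, so the least-squares system is well posed).
On exact distances the solution reproduces the classical MDS embedding to
below 1e−6 nm and the mean absolute deviation between implied and measured
distances is numerically zero.

Distances cannot distinguish a structure from its mirror image. The
bootstrap therefore draws 1,000 distance sets from normals centered on the
means (s.d. = the 16.8 nm measurement uncertainty; negative draws are
redrawn rather than truncated, keeping the noise symmetric), solves each,
and registers every solution onto the noise-free reference using **proper
rotations only** (Kabsch with det = +1, robustified by consensus over
3-point minimal subsets with a 2 × median-residual inlier threshold).
Because reflections are excluded, the two mirror families cannot collapse
onto each other; seeded k-means (k = 2, 10 starts) on the flattened
registered coordinates separates them, and each structure's signed volume
(scalar triple product of the cluster-center simplex) provides an
interpretable check that the classes really are chirality classes. For a
non-planar staged geometry the split is binomial around 50/50; planar
geometries are achiral, flagged, and their k-means split is not
chirality-driven. The k-means feature space (flattened coordinates rather
than, say, inter-point distances) is a convention validated by that
signed-volume agreement.

Two numerical caveats the tests make explicit. First, with noise s.d.
comparable to an edge length (16.8 nm against a 54 nm protein–cluster
edge) the embedded edge carries a convexity bias of order
$\sigma^2/d$ — a property of least-squares distance embedding, not of the
implementation — so the parameter-recovery property is asserted on a
staged geometry whose edges are large relative to the noise. Second, the
ensemble as a whole mixes the two mirror families, so per-point cloud
centroids are only meaningful within one chirality class.

## Problem sizes and runtime choices

The test-suite and analysis scripts use fields of 3.5–11 µm a side
(60–200 voxels laterally, 20–30 planes), 10–50 granules, 40–1,300
emitters, bootstrap ensembles of 150–1,000 structures, and 200
randomization shuffles — sizes chosen so each stage exercises realistic
densities while a full run stays in minutes on a single core. The
statistics themselves (binomial class splits, s.e.m.-scaled distance
checks) set their own tolerances at these sizes.

## Known limitations

- The renderer's Gaussian-blob granules have no substructure or shape
  anisotropy; object-based overlap statistics on real SIM data will see
  rougher boundaries.
- The registration model is translation-only; real chromatic offsets can
  have field dependence this package does not correct.
- Costes thresholds assume a positive overall channel correlation;
  anti-correlated channels are reported as errors, and the randomization
  falls back to whole-ROI thresholds under a null.
- TIFF I/O stores intensities as normalized 32-bit floats with a sidecar
  scale file; metadata-rich OME-XML is not written.
- With distance noise approaching the shortest inter-particle distance,
  embedded short edges are biased outward (see above); reported mean
  deviations remain honest measures of fit but centroids of short-edge
  points should be read with that bias in mind.
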