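# granulescope

Quantitative mapping of mRNA organization inside germ granules from
two-channel 3D smFISH / structured-illumination stacks.

Germ granules are membraneless RNA–protein condensates (up to ~500 nm) in
the posterior germ plasm of the early *Drosophila* embryo. Localized
transcripts concentrate in them as homotypic clusters that occupy
reproducible positions — some central, some at the granule edge. This
package implements the full analysis chain needed to resolve that internal
architecture, together with a ground-truth simulator so every stage is
verifiable without the original microscope data:

- **simulate** — scenes of granules, mRNA clusters at configurable radial
  offsets, single mRNAs and fiducial beads; voxel-integrated Gaussian
  rendering (56 × 56 × 200 nm voxels) with Poisson + read noise and
  configurable inter-channel shifts.
- **spots** — sub-pixel 3D Gaussian fitting on an affine local background
  (`a0 + ax·x + ay·y + az·z`), single-mRNA unit-intensity calibration, and
  cluster copy-number counting.
- **register** — mutual-nearest-neighbor bead matching, translation
  estimation, RMS alignment precision.
- **coloc** — intensity segmentation, object overlap statistics, PCC,
  Costes automatic thresholds and PCC(Costes), 200-fold block-shuffle
  randomization significance, center-to-center distances, localization
  precision from repeated acquisitions.
- **quantify** — molar concentration `c = N/(N_A·V)·1e9` nM, ROI-to-embryo
  extrapolation, mask-based localization efficiency with capture-fraction
  correction.
- **triangulate** — least-squares embedding of the 5-point granule
  architecture from its 10 pairwise distances
  (`min Σ (‖x_i−x_j‖ − d_ij)²`, BFGS + Levenberg–Marquardt), 1,000-fold
  noise bootstrap, rotation-only (det = +1) robust registration, and
  k-means separation of the two mirror-image (chirality) classes.

## Worked example

Stage ten granules whose clusters sit 54 nm from the granule center,
render both channels, and measure co-localization and distances:

```r
library(granulescope)

sc <- make_granule_scene(scene_config(
  n_granules = 10, n_single = 30, radial_offset_nm = 54, seed = 101,
  field_nm = c(5000, 5000, 5000), min_separation_nm = 1100,
  edge_margin_nm = 800, cluster_copies = 8))
P <- render_stack(sc, "protein", noise = noise_model(shot = TRUE, background = 10, seed = 1))
M <- render_stack(sc, "mrna1",   noise = noise_model(shot = TRUE, background = 10, seed = 2))

costes_randomization(M, P, n = 200, seed = 5)
#> PCC 0.690; PCC(Costes) 0.773; significance 100.0% (n=200 shuffles)

spP <- detect_spots(P); spM <- detect_spots(M)
rec <- center_distances(spP[spP$status == "ok", ], spM[spM$status == "ok", ],
                        segment(P), segment(M))
c(mean = attr(rec, "mean_nm"), sem = attr(rec, "sem_nm"))
#>      mean       sem
#> 56.644338  2.283669
```

The staged 54 nm offset is recovered as 56.6 ± 2.3 nm, and the thresholded
correlation (PCC(Costes) 0.77) is flagged maximally significant: none of
the 200 block-shuffled nulls reaches the observed value. Repeating with
`radial_offset_nm = 198` (edge of the granule) and `408` (chance level)
drops PCC(Costes) to 0.45 and 0.04 — position inside the granule, not mere
overlap, drives the statistic.

The numbered drivers under `analysis/` run the full workflow
(`01_simulate.R` … `05_triangulation.R`), writing truth tables,
registration, co-localization, quantification and triangulation outputs
to `results/` (bulky rendered stacks go to `scratch/`). For instance
`05_triangulation.R` reconstructs the 5-point architecture, bootstraps
1,000 noisy solutions and reports the chirality split:

```
noise-free solve: mean deviation 6.39e-15 nm
ensemble: 1000 structures, mean deviation 3.6 nm
chirality classes: 457 / 543 (sign agreement 0.96)
```

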