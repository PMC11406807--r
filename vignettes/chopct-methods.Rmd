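---
title: "Methods: hindbrain choroid plexus segmentation and morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hindbrain choroid plexus segmentation and morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The hindbrain choroid plexus (HbChP) is the CSF-producing tissue of the 4th
ventricle. In iodine-contrast micro-CT of mouse embryo heads it appears as a
bright, convoluted body suspended inside the dark, CSF-filled ventricle lumen,
surrounded by mid-intensity neural tissue. `chopct` implements a
semi-automated pipeline that (i) localizes the 4th ventricle, (ii) extracts
the plexus from it, and (iii) reduces the resulting binary masks to a
morphometric criterion panel suitable for comparing developmental stages and
mutant lines. Because real scans of this kind are large and proprietary, the
package ships a synthetic phantom generator that reproduces the intensity and
topology assumptions the pipeline relies on, with exact ground truth.

# Segmentation model

The pipeline exploits three facts about these images:

1. **The ventricular system is dark.** CSF takes up little contrast agent, so
   a low-intensity threshold (Otsu by default, percentile as an override)
   extracts the ventricular system after a 3D median filter
   (`median_window = 3`) and optional cropping.
2. **False connections are thin.** The 4th ventricle is often connected to
   the rest of the ventricular system through narrow, poorly contrasted
   passages. A morphological opening (`separation_radius = 2` voxels) severs
   them before connected components are labelled. Each candidate component is
   converted to a point cloud (one point per voxel centre, mm), rigidly
   registered to a reference 4th-ventricle mask by ICP (centroid
   initialization, nearest-neighbour matching + Kabsch refits, no scaling),
   and scored by the symmetric Hausdorff distance after registration; the
   best-scoring component is the ventricle. Clouds above `max_points = 5000`
   are subsampled with a fixed seed — the Hausdorff score is then an estimate,
   which is all the selection step needs; `exact = TRUE` disables it.
3. **The plexus is a bright island in a dark cavity.** Morphologically
   closing the ventricle mask (`closing_radius = 5`) fills the notch the
   plexus occupies; subtracting the original mask leaves a candidate gap
   region, inside which high-intensity voxels (Otsu restricted to the region)
   and the largest connected component form the *primary mask*.

The ventricle mask is refined before step 3 by a morphological two-phase
(Chan–Vese) active contour run on the complemented image: voxels on the
6-connected interface are reassigned by region competition between the inside
and outside mean intensities, followed by one binary-majority smoothing pass
per sweep. The majority filter acts as a discrete curvature flow. We use the
7-cell (centre + 6 neighbours) majority rather than the full 27-cell one: the
larger kernel visibly rounds away the thin CSF wrap that separates the plexus
from the ventricle wall, which step 3 depends on.

For E13.5 samples the primary mask seeds a fully automatic extension: a local
range image (window 3) is thresholded at the mean range inside the primary
mask; range components touching the primary mask are selected and closed;
low-intensity voxels are removed; an opening (`opening_radius = 2`) sheds
residual tissue shells; the largest component is kept and refined by a final
active contour on the *raw* image (the plexus is bright — a flag
`ac_on_complement` flips this if needed). For E15.5/E17.5 the pipeline stops
at the primary mask, which is exported for manual branch segmentation;
`merge_manual()` unions the returned branches back in.

All structuring elements are digital balls. Erosion treats out-of-grid voxels
as background, so objects touching the image border shrink under
opening/closing — the phantom keeps its structures away from the border, and
real crops should too.

# Morphometric panel

* **Volume** — voxel count × voxel volume.
* **Surface area** — Crofton formula `S = 4 Σ_k (c_k / λ_k) χ_k`, with run
  counts `χ_k` (run-length encoding of foreground along discrete lines) and
  line density `λ_k = d_k / v` (`d_k` the voxel spacing along direction `k`,
  `v` the voxel volume). The default uses the three axis directions with
  `c_k = 1/3`. The optional 13-direction mode adds the 6 face and 4 body
  diagonals with the standard cubic-grid isotropic direction weights,
  normalized to sum to one (0.0916 axis / 0.0740 face / 0.0704 body); on
  digitized balls both modes land within a fraction of a percent of `4πr²`.
* **Outgrowth angle** — the moment (PCA) ellipsoid of foreground voxel
  coordinates: `A` is their covariance matrix; eigenvalues are sorted in
  descending order; the angle between the first eigenvector and a reference
  axis `u` is `acos(|u·v₁|) · 180/π`, folded to `[0, 90]°` because the sign
  of an eigenvector is arbitrary. The defining formula states
  `u = ⟨1, 0, 0⟩`, "the vector of the sagittal plane (X-axis)"; in this
  package's `(z, y, x)` array-order coordinates that axis is the *third*
  component, so the default is `u = c(0, 0, 1)`. The prose alternative
  ("a posteriorly placed frontal plane") is not resolved here — `u` is a
  plain argument.
* **Proportion** — plexus volume over plexus + ventricle volume.
* **Rostrocaudal split** — partition of the mask by a plane (point + normal,
  default: transverse plane through the mask centroid); voxel classification
  by signed distance makes the two volumes sum to the total exactly.
* **Lateral measures** — deterministic analogues of the interactive
  transverse-plane measurements: the centre is the plexus centroid projected
  onto the sagittal midline plane; each branch length is the maximum
  transverse (stack-axis-ignoring) distance from the centre to a voxel on
  that side of the midline; branch angles are measured against the in-plane
  central axis; the central length subtracts, per side, the extent beyond a
  ventricle-body bound. The bound is genuinely ambiguous in the source
  procedure, so it is a config input (`body_bound_mm`), defaulting to 60% of
  the ventricle's lateral half-extent. These are labelled automated
  analogues: they are reproducible, but not identical to hand-placed
  click-measurements.

# Generalized Procrustes analysis

Landmark configurations (ordered points, order = anatomical correspondence;
10 by default) are compared after removing translation, rotation and — by
default — scale. Each configuration is centred and normalized to unit
centroid size; the first configuration seeds the mean; all configurations are
aligned to the mean by orthogonal Procrustes (SVD; reflections are disallowed
because anatomical landmarks must not mirror); the mean is re-estimated,
re-centred and re-normalized; iteration stops when the mean displacement
drops below `tol = 1e-6` (at most `max_iter = 100`). The Procrustes distance
of a sample is the sum of squared landmark-wise differences to the converged
mean. `gpa_against_reference()` skips the iteration and aligns each sample
once to a fixed (e.g. wild-type mean) configuration — the mode used for
scoring mutants — and `subset_landmarks()` restricts the analysis to a subset
of landmarks (1-based indices) when only some remain identifiable.

# The phantom: what it emulates, and what it does not

`phantom_spec()` states the world the tests run in: a 128³ grid at 4 µm
voxels with plexus/tissue/ventricle mean intensities 200/120/40 and additive
Gaussian noise σ = 10 clipped at zero — i.e. a plexus-vs-tissue
contrast-to-noise ratio of 8, at the favourable end of what the method
assumes. The geometry is a topological, not anatomical, model:

* the 4th ventricle is a bent elliptical slab with two cylindrical lateral
  recesses whose length grows with stage (E13.5 < E15.5 < E17.5) and tilts by
  `branch_angle_deg`;
* the plexus is a medial ridge suspended two voxels off the ventral wall,
  attached to it by a thin fin (a stand-in for the tela choroidea root), plus
  two tapered branch tubes running along the recess axes out to
  `branch_length_frac` of the ventricle half-width;
* an optional decoy — a second dark component joined to the cavity by a
  1.4-voxel false connection — exercises the component-separation and
  reference-selection machinery;
* ten deterministic landmarks (centre, ridge ends, junctions, mid-branches,
  tips, wall contact) provide the GPA ground truth.

An early draft placed the ridge directly on the wall as a bump; morphological
closing of the lumen cannot engulf a wall bump, only an enclosed island, so
the geometry was corrected to the suspended/fin form. That is the one
geometry revision made during development, done to restore the stated
topology rather than to reach any acceptance number.

What the phantom does **not** model: beam hardening, reconstruction
artefacts, staining gradients, anisotropic noise, realistic anatomy, or
partial-volume effects beyond the implicit voxelization. A green end-to-end
test therefore establishes that the algorithm chain is implemented correctly
and is robust over the stated noise range — not that it will segment any
particular real scan.

# Numerical choices

* **Thresholds** — Otsu on a 256-bin histogram; the degenerate constant image
  yields an empty mask plus a warning rather than an error.
* **ICP** — convergence on relative RMSE change below `icp_tol = 1e-5`
  (1e-6 sits below the nearest-neighbour jitter floor of subsampled clouds
  and never triggers); non-convergence returns the best transform with a
  warning, as the selection step only consumes the score.
* **Ties** in reference selection go to the first (largest) candidate, with a
  message.
* **Meshes** — iso-surfaces are extracted by marching tetrahedra (six
  tetrahedra per cell sharing the main diagonal, shared-vertex hashing, hence
  watertight meshes for solid components) at level 0.5. The binary indicator
  is anti-aliased by a 3³ box mean first: on raw binary fields any
  marching-style surface inherits the voxel staircase and overestimates area
  (~17% for a digitized ball); after anti-aliasing the mesh area agrees with
  an independent marching-cubes implementation to ~0.3% and with `4πr²` to
  ~2%. Masks too thin to survive the smoothing fall back to the raw field.
* **Degenerate morphometry inputs** — collinear voxel sets are rejected in
  `orientation_angle()`; a near-tie between the two leading eigenvalues is
  flagged as ambiguous. `build_report()` converts per-criterion failures to
  `NaN` plus a log entry instead of aborting the panel.
* **dB convention** — the contrast-to-noise ratio is reported raw and in both
  `20·log10` (default, amplitude convention) and `10·log10`, since the source
  figures do not state theirs.
* **Seeds** — every stochastic step (noise field, cloud subsampling, landmark
  sets) takes an explicit seed and restores the caller's RNG state.

# Known limitations

* The TIFF codec intentionally covers only the dialect the pipeline itself
  writes (uncompressed single-sample grayscale, 8/16-bit unsigned or 32/64-bit
  float, single- or multi-page); compressed, tiled or multi-sample files are
  rejected with a clear message.
* Brute-force nearest-neighbour search bounds ICP/Hausdorff inputs to the
  subsampling cap in practice; exact mode on multi-million-point clouds is
  quadratic.
* The E13.5 extension assumes the plexus is the brightest structure inside
  the range-selected region; heavy staining artefacts would violate this.
* Micro-CT resolution cannot capture microvilli-scale surface, and staining
  shrinks tissue — reported absolute values are specific to this modality and
  preparation, a caveat inherited from the measurement model itself.
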