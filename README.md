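# chopct

Segmentation and morphometry of the embryonic hindbrain choroid plexus
(HbChP) in contrast-enhanced micro-CT.

## Who this is for

Developmental biologists and imaging scientists quantifying 4th-ventricle
choroid plexus outgrowth across embryonic stages (E13.5–E17.5) and mutant
lines from whole-embryo micro-CT stacks. In iodine-stained scans the plexus
is a bright convoluted body inside the dark, CSF-filled 4th ventricle,
surrounded by mid-intensity tissue; `chopct` turns such stacks into binary
plexus/ventricle masks and a reproducible morphometric criterion panel. A
synthetic phantom generator with exact ground truth makes the whole pipeline
testable offline.

## What it computes

**Segmentation** (`run_pipeline()`): 3D median filter and crop → low-intensity
(Otsu) threshold of the CSF-filled ventricular system → morphological opening
and connected components → each candidate registered to a reference
4th-ventricle mask by point-cloud ICP and scored by the Hausdorff distance →
Chan–Vese active-contour refinement → *primary plexus mask* as the bright
content of `close(ventricle) − ventricle`. For E13.5 a local-range analysis
extends the primary mask to the full plexus automatically; for E15.5/E17.5
the primary mask is exported and manually segmented branches are merged back
in with `merge_manual()`.

**Quality gate**: contrast-to-noise ratio
`CNR = |x̄_fg − x̄_bg| / σ_bg`, reported raw and in dB (both 20·log10 and
10·log10 conventions).

**Morphometry** (`build_report()`):

| criterion | definition |
|---|---|
| volume | `N_voxels · voxel_size³` (mm³) |
| surface area | Crofton estimate `S = 4 Σ_k (c_k/λ_k) χ(X ∩ L_k)` (mm²), 3 axis directions with `c_k = 1/3` (13-direction option) |
| outgrowth angle | `cos⁻¹(u·v₁ / ‖u‖‖v₁‖)·180/π`, `v₁` = first eigenvector of the voxel-coordinate covariance, folded to [0°, 90°] |
| proportion | `V_plexus / (V_plexus + V_ventricle)` |
| rostrocaudal split | exact volume partition by a configurable plane |
| lateral measures | branch lengths/angles from the midline-projected centre, central vs total length, ventricle length |

**Shape analysis** (`generalized_procrustes()`): landmark-based GPA removing
translation, scale and rotation; per-sample Procrustes distances (sum of
squared landmark differences to the mean); fixed-reference mode for mutants
and landmark subsetting (`subset_landmarks()`).

## Worked example

```r
library(chopct)

spec <- phantom_spec()                      # E13.5, 128^3, 4 um voxels, noise sd 10
ph   <- generate_embryo_phantom(spec)
ref  <- generate_reference_ventricle(spec, rotation_deg = 5,
                                     translation_vox = c(2, 1, 0))

contrast_to_noise(ph$image, ph$plexus_truth, ph$tissue_truth)
#> <cnr_result> ratio 7.996 (18.06 dB20 / 9.029 dB10); fg 200, bg 120 +/- 10.01

run <- run_pipeline(ph$image, ref, "E13.5")
dice(run$final, ph$plexus_truth)
#> [1] 0.9778386

build_report(run$final, run$ventricle, sample = "phantom_E13.5")
#> <morphometry_report> phantom_E13.5
#>   volume_mm3             0.000230144
#>   surface_area_mm2       0.023168
#>   outgrowth_angle_deg    0
#>   ventricle_volume_mm3   0.00214758
#>   proportion             0.0967916
#>   rostral_volume_mm3     0.000115968
#>   caudal_volume_mm3      0.000114176
#>   left_length_mm         0.0914229
#>   right_length_mm        0.0914229
#>   left_angle_deg         79.8782
#>   right_angle_deg        79.8782
#>   central_length_mm      0.182846
#>   total_length_mm        0.182846
#>   ventricle_length_mm    0.345769
```

Reading the panel: the measured CNR (7.996 ≈ the constructed (200−120)/10 = 8)
confirms the contrast regime; the pipeline recovers the ground-truth plexus
with Dice 0.978; the plexus occupies ~9.7% of the combined plexus+ventricle
volume; its principal axis lies exactly along the lateral (sagittal-normal)
reference axis (outgrowth angle 0°); left/right branch extents are equal, as
they must be for a mirror-symmetric phantom; and the 0.183 mm total lateral
extent sits inside the 0.346 mm ventricle span.

Landmark shape analysis on generated fixtures:

```r
sets <- generate_landmark_sets(8, noise_sigma_mm = 0.02, seed = 1)
g <- generalized_procrustes(sets)
g$distances          # per-sample Procrustes distances to the converged mean
gpa_against_reference(sets, landmark_config(g$mean_config))  # mutant-scoring mode
```

## Command line

An `Rscript` wrapper is installed at `<library>/chopct/exec/chopct`:

```sh
chopct phantom  --out phantom_dir --seed 1
chopct pipeline --phantom --stage E13.5 --out run_dir --seed 7
chopct segment  --stage E15.5_17.5 --image stacks/ --reference ref_mask/ --out out/
chopct cnr      --image stacks/ --fg plexus_mask/ --bg tissue_mask/
chopct gpa      --landmarks fcsv_dir/ --subset 5,6,7,8,10,11 --out distances.csv
```

Subcommands exchange per-slice TIFF stacks (masks as 8-bit 0/255), Slicer
`.fcsv` landmark files, binary STL meshes and CSV reports; every run writes a
`provenance.json` with the configuration and timings. A single JSON config
(see `run_config()`) carries all module parameters; unknown keys are
rejected.

## Scope

Reconstruction, staining protocols, DICOM/NIfTI, nonrigid registration,
interactive editing and group statistics are out of scope. See
`vignettes/chopct-methods.Rmd` for the model, parameter rationale, phantom
design and known limitations.
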