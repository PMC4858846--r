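# noduleseg

Segmentation of pulmonary nodules in CT, aimed at the two categories
that defeat classical methods: **ground-glass opacity (GGO) nodules**
(low contrast, intensity inhomogeneity, fuzzy margins — global
two-phase models leak or truncate them) and **juxta-vascular nodules**
(attached to vessels of near-identical attenuation — appearance-driven
models over-segment into the vessel). The package is aimed at
researchers in medical image analysis who need a tested, scriptable
reference implementation of this family of methods with synthetic
ground truth.

## The method

The nodule contour is the zero level of a signed function φ evolved by
gradient descent on an integrated energy

E = E_edge + E_local + E_global

* **E_edge** — geodesic curvature term μ ∫ δ(φ) g |∇φ|, with a
  contrast-invariant stop function g built from the smoothed gradient.
* **E_local** — for each voxel near the contour, a KNN-adaptive local
  domain Ω_τ is selected (the full disc of radius r when the k nearest
  feature-neighbours are consistent with the rest of the disc, the KNN
  set alone otherwise, with r ≤ 4 mm/spacing and k ≤ πr²/K₀, K₀ = 4).
  The Parzen density of feature norms ‖O‖, O = (x, y, z, I, ASM-level),
  over Ω_τ is compared against the mean inside/outside densities with
  the 1D Wasserstein distance W₁(p, q) = ∫ |F_p − F_q| dτ, gated by a
  fuzzy C-means nodule membership u: the force is
  δ(φ)[−λ₁(1−u)^m W(P_v, P₁) + λ₂ u^m W(P_v, P₂)].
* **E_global** — the Bhattacharyya overlap B = ∫ √(P₋ P₊) dτ between
  the feature-norm densities of the two sides, minimized by its
  variational flow, which drives the two populations apart.

The texture feature is the angular second moment (ASM = Σ P(m,n)² of
the normalized gray-level co-occurrence matrix), quantized to 6 levels.
Vessels are grown by flow-direction-feature region growing on the
structure tensor (flow l_d = √(s₂+s₃)·e₁); the vessel/nodule
attachment collar S_r = S_c1 ∩ S_c2 is then relabelled by K-means on
(x, y, z, I, shape-index), touching nothing outside S_r.

## Worked example

Segment a juxta-vascular phantom (sphere of radius 6 mm overlapping a
3 mm vessel tube, matched intensities, noise) and refine away the
vessel stub:

```r
library(noduleseg)

ph  <- make_phantom(phantom_spec("juxta_vascular", size = c(40, 40, 40),
                                 radius_mm = 6, tube_radius_mm = 3,
                                 noise_sd = 5, seed = 2))
seg <- segment_nodule(ph$volume, init = list(seed = c(28, 20, 20), radius_mm = 4),
                      params = acm_params(max_iter = 60, roi_margin_mm = 6,
                                          seed = 2))
fld <- structure_tensor(ph$volume)
sc1 <- fdf_region_grow(ph$volume, fld,
                       vessel_params(intensity_range = c(32.5, 150),
                                     seeds = list(c(20, 20, 20))))
sr      <- refinement_region(sc1, seg$mask, dilation = 1)
refined <- cluster_refine(sr, seg$mask, ph$volume, k_clusters = 3, seed = 2)

jaccard_error(seg$mask, ph$truth$sphere)   # unrefined, vessel stub included
jaccard_error(refined,  ph$truth$sphere)   # after K-means refinement
```

Output:

```
#> [1] 0.421875
#> [1] 0.2636816
```

The unrefined contour (correctly, by appearance) swallows the attached
vessel stub inside its region of interest, giving a Jaccard error of
0.42 against the true sphere; relabelling the attachment collar
removes most of the stub and drops the error to 0.26 without touching
any voxel outside S_r.

## Command line

```sh
inst/cli/noduleseg phantom --kind juxta_vascular --size 40,40,40 --noise 5 --out jx
inst/cli/noduleseg segment --input jx.nii.gz --seed-point 28,20,20 --radius 4 --out sc2
inst/cli/noduleseg vessels --input jx.nii.gz --seed-point 20,20,20 --lo 32.5 --hi 150 --out sc1
inst/cli/noduleseg refine  --input jx.nii.gz --vessels sc1.nii.gz --nodule sc2.nii.gz --out refined
inst/cli/noduleseg evaluate --pred refined.nii.gz --truth jx_truth_sphere.nii.gz
```

`noduleseg run --config pipeline.yaml` chains the stages from one
declarative YAML file.

## Scope

Inputs are NIfTI volumes, PNG slices, or in-memory arrays with voxel
spacing in mm; DICOM series must be converted to NIfTI first (the HU
rescale affine is available as `apply_hu_rescale()`). The methods
vignette (`vignettes/methods.Rmd`) documents the model, all tunable
parameters, the numerical scheme, and what the synthetic phantoms do
and do not emulate.
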