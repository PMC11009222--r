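# retialign

Registration of steered **wide-field (WF)** fundus images onto a single
**ultra-wide-field (UWF)** reference image, with explicit 3D
distortion correction, and fusion of the registered fields into a
composite. Written for retinal-imaging researchers who need to
co-localize peripheral anatomy across devices whose optics differ too
much for plain 2D warping.

## The method in brief

Both images are reduced to *vessel maps* (per-pixel vessel
probabilities), the common currency across modalities. Keypoints on the
maps are matched by bidirectional (mutual nearest-neighbour) consensus,
cleaned by either seeded RANSAC with consensus-set refinement
(RANSAC-SC) or a fully deterministic IRLS robust reweighting, and a
2×6 second-order polynomial transform

    [u, v]ᵀ = M_poly [m, n, m², n², m·n, 1]ᵀ

is estimated from the weighted pairs by weighted least squares.
Alignment quality is the soft Dice overlap

    Dice(I₁, I₂) = 2 · Σ min(I₁, I₂) / (Σ I₁ + Σ I₂).

Because the UWF periphery carries projection distortion that no 2D
polynomial removes, the package models the eye as a unit sphere with a
stereographic UWF projector (camera at (0,0,−1), image plane z = 1)
and a 5-degree-of-freedom WF pinhole camera (position x, y, z;
rotations θx, θy; focal depth pinned by the z = 1 plane-centre
constraint). Distortion correction searches those five parameters:
each candidate pose reprojects the UWF map into the WF perspective
through the WF-grid → sphere → UWF projection chain, the 2D pipeline
registers the pair, and the Dice score drives a derivative-free search
(grid multi-start + Nelder–Mead + a registration-free coarse-to-fine
polish). The optimized pose plus a final 2D polish places each WF
field — and its Gaussian-feathered mask — in the UWF frame; fields are
fused as `Σ(mask·image)/Σ(mask)`.

A **phantom eye** (seeded vessel tree grown on the unit sphere,
rendered through both camera models with known poses and dense
correspondences) replaces clinical data for validation; see the
methods vignette (`vignettes/registration-model.Rmd`) for the model,
parameter and generator details.

## Worked example

Register one steered phantom field with and without distortion
correction:

```r
library(retialign)

scene <- make_scene(phantom_config(seed = 1))   # 512 px UWF, 9 WF fields
field <- scene$fields[[9]]                      # steered (+0.35, +0.35) rad

# 2D-only registration (deterministic IRLS rejector)
sr  <- nominal_scale_ratio(scene$eye, scene$K, camera_pose(z = -0.2))
r2d <- register_2d(scene$uwf_vm, field$vm, reg_config(scale_ratio = sr))

# distortion correction: 5-DOF pose search + UWF-frame finalization
r3d <- optimize_pose(scene$uwf_vm, field$vm,
                     pose_opt_config(eye = scene$eye, K = scene$K))
fin <- finalize_wf_to_uwf(r3d$pose, r3d$matches, scene$uwf_vm, field$vm,
                          scene$eye, scene$K)

cat(sprintf("2D-only UWF-frame dice: %.3f\n",
            retialign:::dice_2d_in_uwf(scene$uwf_vm, field$vm,
                                       r2d$T_uwf_to_wf)$dice))
cat(sprintf("with DC: dice %.3f at pose theta_x %.3f theta_y %.3f\n",
            fin$dice_final, r3d$pose$theta_x, r3d$pose$theta_y))
```

```
2D-only UWF-frame dice: 0.832
with DC: dice 0.968 at pose theta_x 0.351 theta_y 0.350
```

The 2D registration plateaus near the quadratic model's ceiling
(~0.82–0.84 on this phantom scale); the pose search recovers the true
steering (0.35, 0.35) rad to three decimals and lifts the overlap to
~0.97. `run_pipeline()` does the same for all fields of an eye and
writes the composite, a checkerboard QC image and a per-field summary
CSV; `inst/cli/retialign.R` exposes `register`, `composite`,
`phantom`, `evaluate` and `checkerboard` subcommands for shell use.

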