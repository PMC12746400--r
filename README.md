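# cinemop

Automated ventricular function assessment from 2D+t short-axis cardiac
cine MRI, built as one connected chain: multi-frame image registration,
motion-compensated reconstruction of undersampled k-space, weakly
supervised segmentation, and strain/ejection-fraction analysis. The
package is aimed at methods researchers who want a fully inspectable,
CPU-scale reference implementation of this joint pipeline, with a
synthetic deforming cardiac phantom providing exact ground truth for
every stage.

## What is inside

* **Phantom** (`generate_cine_phantom`): an annular myocardium
  contracting and twisting around an LV blood pool with an adjacent RV
  crescent, rendered over a raised-cosine cardiac cycle. The deformation
  `r' = r (1 - alpha(t) w(r))`, `theta' = theta + beta(t) w(r)` has a
  numerically exact inverse, so dense ground-truth flows between any two
  frames, per-frame volumes, and end-systolic strain are available in
  closed form. Multi-coil k-space, smooth complex coil maps and
  variable-density incoherent ky-t sampling masks complete the
  simulation.
* **MR forward model** (`apply_forward`, `apply_adjoint`,
  `zero_filled_recon`): the Cartesian operation `A = phi F C` with a
  centred orthonormal FFT and exact adjoint.
* **Registration** (`estimate_motion`, `full_cycle_inference`): a
  recurrent optical-flow network over three overlapping tri-frame
  groups with dual correlation volumes, hidden motion states warped
  between triplets each refinement iteration (motion propagation), a
  conv-GRU decoding residual bidirectional flows
  `warped(p) = source(p + u(p))`, and sliding-window inference that
  tiles the cyclic frame sequence and composes adjacent flows into a
  frame-to-reference table.
* **Reconstruction** (`ktslr_reconstruct`): proximal-gradient solve of
  `sum_t ||phi_t F C U_t X_t - y_t||^2 / 2 + lambda_lr ||Casorati(X)||_*
  + lambda_s TV(X)` — the k-t low-rank plus sparsity prior on the
  motion-aligned image series.
* **Segmentation** (`build_unet`, `segment`, `generate_pseudo_labels`):
  a 2D U-Net over four classes (background, LV pool, myocardium, RV
  pool) with soft Dice training and pseudo-labels warped from manual
  end-diastolic/end-systolic masks along the estimated motion.
* **Training** (`run_training_stage`): photometric + smoothness
  registration loss summed over refinement iterations
  (`lambda1 = 0.04`), Dice segmentation loss, and a joint stage with
  reconstruction in the loop and a differentiable warped-Dice term
  (`lambda2 = 0.05`, `lambda3 = 0.04`), optimised with AdamW under
  cosine annealing and gradient clipping.
* **Function analysis** (`analyze_function`): Simpson-style volumes,
  `EF = 100 (EDV - ESV) / EDV`, the Green-Lagrange tensor
  `E = (grad u + grad u' + grad u' grad u)/2` of the end-diastolic
  displacement field, radial/circumferential projections
  `Err = r'Er`, `Ecc = c'Ec` in a contour-derived local frame, and
  AHA 17-segment bull's-eye maps.
* **Metrics** (`dice`, `hausdorff`, `mean_contour_distance`,
  `overlap_score`, `nrmse`, `ssim`,
  `nonpositive_jacobian_fraction`).

The trainable networks run on a small reverse-mode autodiff engine
included in the package (every operator is gradient-checked in the test
suite); no external deep-learning framework is required.

## Worked example

Generate a 3-slice phantom, undersample it at R = 8, reconstruct with
the phantom's exact motion, and read off function parameters:

```r
library(cinemop)

gt <- generate_cine_phantom(phantom_config(grid_size = 48, n_frames = 9,
                                           n_slices = 3, n_coils = 4,
                                           heart_scale = 1.2, seed = 3))
coils <- generate_coil_maps(4, c(48, 48))
mask  <- generate_kt_mask(c(9, 48), R = 8, acs_lines = 4, seed = 4)
ks    <- simulate_kspace(gt$images_clean, coils, mask, noise_sigma = 0.002)

ft  <- phantom_flow_table(gt, frames = 1:9)
rec <- ktslr_reconstruct(ks, ft, moco_config(n_iters = 20))
ref <- zero_filled_recon(ks, use_full = TRUE)
zf  <- zero_filled_recon(ks)
round(c(nrmse_zf = nrmse(zf, ref), nrmse_moco = nrmse(rec$recon, ref)), 4)
#>   nrmse_zf nrmse_moco
#>     0.0971     0.0808

rep <- analyze_function(gt$slice_labels, ft, gt$spacing, gt$slice_thickness)
round(c(lvef = rep$lvef, mGRS = rep$strain$mGRS, mGCS = rep$strain$mGCS), 3)
#>   lvef   mGRS   mGCS
#> 35.270  0.153 -0.130
```

The zero-filled images at R = 8 carry strong aliasing
(NRMSE 0.097 against the fully sampled reference); the
motion-compensated kt-SLR solve with the phantom's exact motion cuts
that error and sharpens the myocardial borders. The LV ejection
fraction of 35.3% recovered from the masks sits within a quarter point
of the phantom's closed-form value (35.0% for this contraction
profile), and the global strains have the clinical signs: positive
radial (wall thickening), negative circumferential (shortening).

A command-line front end with the same stages lives in
`inst/cli/cinemop`:

```sh
Rscript inst/cli/cinemop pipeline --out run1 --R 8 --seed 1 --true-flows
```

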