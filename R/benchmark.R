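# Phantom benchmark: the standard evaluation the package runs in place
# of a clinical dataset. Each WF field of a phantom scene is registered
# to the UWF reference three ways — RANSAC-SC 2D, IRLS 2D, and IRLS with
# 3D distortion correction — and scored by soft Dice in the UWF frame
# over the warped field's footprint, mirroring how composite overlays
# are graded.

#' Benchmark registration methods on a phantom scene
#'
#' For every field: a 2D-only registration with the RANSAC-SC rejector,
#' a 2D-only registration with the deterministic IRLS rejector, and
#' (optionally) the full distortion-correction path (pose optimization
#' initialized on-axis + UWF-frame finalization) on top of IRLS. All
#' scores are UWF-frame soft Dice of the warped WF vessel map against
#' the UWF vessel map over the warped footprint, so the three methods
#' are directly comparable.
#'
#' @param scene a `"phantom_scene"`.
#' @param dc run the distortion-correction path (default TRUE).
#' @param ransac a [ransac_config()] for the baseline.
#' @param irls an [irls_config()] for the deterministic rejector.
#' @param pose_opt overrides merged into the [pose_opt_config()] used
#'   for distortion correction.
#' @param fields which fields to evaluate (default all).
#' @param verbose emit one progress message per field.
#' @return data.frame with one row per field: `field`, `theta_x`,
#'   `theta_y` (true steering), `dice_ransac`, `dice_irls`,
#'   `dice_irls_dc`, `pose_err_rot`, `pose_err_pos` (recovered-pose
#'   errors against the generator's ground truth; NA when `dc = FALSE`).
#' @export
phantom_benchmark <- function(scene, dc = TRUE, ransac = ransac_config(),
                              irls = irls_config(), pose_opt = list(),
                              fields = seq_along(scene$fields),
                              verbose = FALSE) {
  stopifnot(inherits(scene, "phantom_scene"))
  eye <- scene$eye; K <- scene$K
  init <- camera_pose(z = scene$cfg$camera_z)
  sr <- nominal_scale_ratio(eye, K, init)
  rows <- lapply(fields, function(i) {
    fl <- scene$fields[[i]]
    if (verbose) message(sprintf("[benchmark] field %d/%d", i,
                                 length(scene$fields)))
    d2 <- function(rej) {
      r <- register_2d(scene$uwf_vm, fl$vm,
                       reg_config(rejector = rej, scale_ratio = sr))
      dice_2d_in_uwf(scene$uwf_vm, fl$vm, r$T_uwf_to_wf)$dice
    }
    d_ransac <- tryCatch(d2(ransac), error = function(e) NA_real_)
    d_irls <- tryCatch(d2(irls), error = function(e) NA_real_)
    d_dc <- NA_real_; err_rot <- NA_real_; err_pos <- NA_real_
    if (dc) {
      pcfg <- utils::modifyList(
        pose_opt_config(init_pose = init,
                        reg = reg_config(rejector = irls, scale_ratio = 1),
                        eye = eye, K = K),
        pose_opt)
      r3 <- tryCatch(optimize_pose(scene$uwf_vm, fl$vm, pcfg),
                     error = function(e) NULL)
      if (!is.null(r3)) {
        fin <- tryCatch(
          finalize_wf_to_uwf(r3$pose, r3$matches, scene$uwf_vm, fl$vm,
                             eye, K),
          error = function(e) NULL)
        if (!is.null(fin)) d_dc <- fin$dice_final
        tp <- pose_vector(fl$pose); rp <- pose_vector(r3$pose)
        err_rot <- max(abs(rp[4:5] - tp[4:5]))
        err_pos <- sqrt(sum((rp[1:3] - tp[1:3])^2))
      }
    }
    data.frame(field = i, theta_x = unname(fl$offset["theta_x"]),
               theta_y = unname(fl$offset["theta_y"]),
               dice_ransac = d_ransac, dice_irls = d_irls,
               dice_irls_dc = d_dc, pose_err_rot = err_rot,
               pose_err_pos = err_pos)
  })
  do.call(rbind, rows)
}
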