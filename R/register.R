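# Registration orchestration.
#
# Three layers:
#  * register_2d(): the forward feature-based pass — detect/describe on
#    both vessel maps, bidirectional matching, outlier rejection, WLS
#    polynomial fits in both directions, warp, Dice.
#  * optimize_pose(): the iterative 3D distortion-correction loop — at
#    each probed 5-DOF WF camera pose the UWF vessel map is reprojected
#    to the WF perspective (project_wf_grid + resample_with_field), the
#    2D pass registers the reprojected UWF map to the WF map, and the
#    resulting Dice drives a derivative-free pose search.
#  * finalize_wf_to_uwf(): with the optimized pose, WF keypoints are
#    pushed through the 3D chain into the UWF frame and a final 2D
#    polynomial polish is fitted there; the closed-form inverse chain
#    plus the polish places the WF image in the UWF frame.

#' Registration result container
#'
#' @param pose optimized `camera_pose`, or `NULL` in 2D-only mode.
#' @param T_wf_to_uwf,T_uwf_to_wf `poly_transform`s between the two
#'   frames (for a pose-optimized result these are the UWF-frame polish
#'   transforms; the full mapping composes them with the 3D chain at
#'   `pose` — see [warp_wf_to_uwf()]).
#' @param dice_final soft Dice of the registered vessel maps.
#' @param matches the final weighted `match_set`.
#' @param trace data.frame of pose-optimization iterates, or `NULL`.
#' @export
registration_result <- function(pose, T_wf_to_uwf, T_uwf_to_wf, dice_final,
                                matches, trace = NULL) {
  stopifnot(dice_final >= 0, dice_final <= 1)
  if (!is.null(trace)) {
    stopifnot(all(is.finite(trace$dice)))
    stopifnot(isTRUE(all.equal(trace$dice[nrow(trace)], dice_final)))
  }
  structure(list(pose = pose, T_wf_to_uwf = T_wf_to_uwf,
                 T_uwf_to_wf = T_uwf_to_wf, dice_final = dice_final,
                 matches = matches, trace = trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration result: dice %.4f, %d weighted matches%s\n",
              x$dice_final, sum(x$matches$w > 0),
              if (is.null(x$pose)) " (2D-only)" else " (pose-optimized)"))
  if (!is.null(x$pose)) print(x$pose)
  invisible(x)
}

#' 2D registration configuration
#'
#' @param rejector [irls_config()] (default) or [ransac_config()].
#' @param detect keypoint-detection overrides for both maps (see
#'   [detect_keypoints()]).
#' @param scale_ratio expected size of a retinal structure in the first
#'   (UWF-side) map relative to the second (WF-side) map; descriptor and
#'   detection radii on the first map are scaled by it so descriptors
#'   sample corresponding retinal neighbourhoods. 1 when both maps share
#'   a frame (as inside the pose loop); use [nominal_scale_ratio()] for
#'   raw UWF-vs-WF registration.
#' @param dice_scope `"footprint"` (score only pixels whose backward warp
#'   lands inside the source map — the WF field of view overlap) or
#'   `"full"`.
#' @param min_matches minimum surviving (positively weighted) matches.
#' @param guided run a guided re-matching pass ([match_guided()]) under
#'   the first-pass transform and refit (default TRUE).
#' @param guide_gate_px spatial gate of the guided pass, destination px.
#' @param model transform model fitted from the weighted matches:
#'   `"poly2"` (default) or `"affine"`. The pose optimizer restricts its
#'   inner registration to affine so that the residual distortion — which
#'   only the camera pose can explain — remains visible to the Dice
#'   objective.
#' @export
reg_config <- function(rejector = irls_config(), detect = list(),
                       scale_ratio = 1, dice_scope = "footprint",
                       min_matches = 6L, guided = TRUE, guide_gate_px = 4,
                       model = "poly2") {
  stopifnot(scale_ratio > 0, dice_scope %in% c("footprint", "full"))
  model <- match.arg(model, c("poly2", "affine"))
  rejector$model <- model
  list(rejector = rejector, detect = detect, scale_ratio = scale_ratio,
       dice_scope = dice_scope, min_matches = as.integer(min_matches),
       guided = isTRUE(guided), guide_gate_px = guide_gate_px,
       model = model)
}

#' Nominal UWF/WF pixel-scale ratio at the posterior pole
#'
#' Ratio of UWF pixels to WF pixels per radian of retinal arc for an
#' on-axis WF camera: used to scale descriptor radii when registering a
#' raw UWF map to a WF map.
#'
#' @param eye an `eye_model`; `K` a `wf_intrinsics`; `pose` the nominal
#'   WF pose (only the focal depth matters).
#' @param K,pose WF camera intrinsics and nominal pose.
#' @export
nominal_scale_ratio <- function(eye, K, pose = camera_pose()) {
  fp <- wf_focal_depth(pose)
  wf_px_per_rad <- ((K$image_px - 1) / 2) / tan(K$fov_deg * pi / 360) / fp
  uwf_pixel_scale(eye) / wf_px_per_rad
}

# scale the detection config for the UWF-side map
scaled_detect_cfg <- function(detect, ratio) {
  cfg <- utils::modifyList(default_detect_cfg(), detect)
  cfg$desc_radius <- cfg$desc_radius * ratio
  cfg$sigma_d <- max(0.6, cfg$sigma_d * ratio)
  cfg$sigma_i <- max(1, cfg$sigma_i * ratio)
  cfg
}

#' Forward 2D registration of a WF vessel map to a UWF-side vessel map
#'
#' Runs the feature pipeline: keypoint detection/description on both
#' maps, bidirectional-consensus matching, the configured outlier
#' rejector, weighted least-squares polynomial fits in both directions,
#' a backward warp of the UWF-side map into the WF frame, and the soft
#' Dice of the result. Deterministic whenever the rejector is (IRLS
#' always; RANSAC-SC for a fixed seed).
#'
#' @param uwf_vm reference-side vessel map (either the raw UWF map or the
#'   pose-reprojected UWF map inside the distortion-correction loop).
#' @param wf_vm WF vessel map.
#' @param cfg a [reg_config()].
#' @param kp_uwf,kp_wf optional precomputed `"keypoints"` (plug-in point
#'   for learned detectors, and a cache hook for the pose loop).
#' @return a [registration_result()] (pose absent). `T_wf_to_uwf` maps WF
#'   pixels to UWF-side pixels; `dice_final` is scored in the WF frame
#'   over the configured scope. The warped UWF-side map is attached as
#'   attribute `"warped"`.
#' @export
register_2d <- function(uwf_vm, wf_vm, cfg = reg_config(),
                        kp_uwf = NULL, kp_wf = NULL) {
  stopifnot(is.matrix(uwf_vm), is.matrix(wf_vm))
  if (max(uwf_vm) == 0 || max(wf_vm) == 0) {
    stop("insufficient matches: a vessel map is empty")
  }
  if (is.null(kp_uwf)) {
    kp_uwf <- detect_keypoints(uwf_vm, scaled_detect_cfg(cfg$detect,
                                                         cfg$scale_ratio))
  }
  if (is.null(kp_wf)) kp_wf <- detect_keypoints(wf_vm, cfg$detect)
  m <- match_bidirectional(kp_wf, kp_uwf)   # src = WF, dst = UWF-side
  if (length(m$w) < max(6L, cfg$min_matches)) {
    stop(sprintf("insufficient matches: %d consensus pairs", length(m$w)))
  }
  rej <- reject_outliers(m, cfg$rejector)
  mw <- rej$matches
  if (sum(mw$w > 1e-3) < max(6L, cfg$min_matches)) {
    stop(sprintf("insufficient matches: %d survive outlier rejection",
                 sum(mw$w > 1e-3)))
  }
  if (cfg$guided) {
    T0 <- fit_model(mw$src, mw$dst, mw$w, cfg$model)
    m2 <- match_guided(kp_wf, kp_uwf, T0, cfg$guide_gate_px)
    if (length(m2$w) >= max(6L, cfg$min_matches)) {
      rej2 <- tryCatch(reject_outliers(m2, cfg$rejector),
                       error = function(e) NULL)
      if (!is.null(rej2) && sum(rej2$matches$w > 1e-3) >=
            max(6L, cfg$min_matches)) {
        mw <- rej2$matches
      }
    }
  }
  T_wf_to_uwf <- fit_model(mw$src, mw$dst, mw$w, cfg$model)
  T_uwf_to_wf <- fit_model(mw$dst, mw$src, mw$w, cfg$model)
  T_wf_to_uwf$frame <- "wf->uwf"
  T_uwf_to_wf$frame <- "uwf->wf"

  nr <- nrow(wf_vm); nc <- ncol(wf_vm)
  g <- grid_mn(nr, nc)
  q <- poly_apply(T_wf_to_uwf, cbind(g$m, g$n))
  warped <- matrix(bilinear_sample(uwf_vm, q[, 1], q[, 2]), nr, nc)
  mask <- if (cfg$dice_scope == "footprint") {
    matrix(q[, 1] >= 0 & q[, 1] <= ncol(uwf_vm) - 1 &
             q[, 2] >= 0 & q[, 2] <= nrow(uwf_vm) - 1, nr, nc)
  } else NULL
  d <- dice(wf_vm, warped, mask)
  out <- registration_result(NULL, T_wf_to_uwf, T_uwf_to_wf, d, mw)
  attr(out, "warped") <- warped
  out
}

#' Pose-optimization configuration
#'
#' @param init_pose starting `camera_pose` (on-axis default).
#' @param method derivative-free search: `"nelder_mead"` (simplex with
#'   box penalty) or `"coord_search"` (cyclic coordinate descent with
#'   shrinking steps).
#' @param bounds named list of `c(lo, hi)` per parameter
#'   (`x, y, z, theta_x, theta_y`).
#' @param max_outer_iters iteration budget of the main search.
#' @param dice_tol convergence tolerance on the objective.
#' @param grid_steps angular offsets (radians) probed per rotation axis
#'   in the coarse multi-start over `(theta_x, theta_y)`; `NULL`
#'   disables the multi-start.
#' @param polish_sigmas blur levels (WF px) for the coarse-to-fine direct
#'   Dice polish after the main search; `NULL` disables polishing.
#' @param reg a [reg_config()] for the final 2D registration at the best
#'   pose; its rejector must be deterministic (see `allow_ransac`).
#' @param search_model inner transform model during the pose search
#'   (default `"affine"`): a full quadratic inner model absorbs nearly
#'   all pose-induced distortion and flattens the objective, whereas an
#'   affine inner model leaves the curvature residual — which only the
#'   pose can explain — visible to the Dice objective.
#' @param allow_ransac the randomized RANSAC-SC rejector perturbs the
#'   objective between otherwise identical pose evaluations, so the
#'   optimizer refuses it by default; set `TRUE` to override for
#'   experiments.
#' @param eye,K eye model and WF intrinsics.
#' @param seed recorded for provenance (the search itself is
#'   deterministic).
#' @export
pose_opt_config <- function(init_pose = camera_pose(),
                            method = "nelder_mead",
                            bounds = list(x = c(-0.3, 0.3), y = c(-0.3, 0.3),
                                          z = c(-0.6, 0.1),
                                          theta_x = c(-0.8, 0.8),
                                          theta_y = c(-0.8, 0.8)),
                            max_outer_iters = 80L, dice_tol = 1e-4,
                            grid_steps = seq(-0.45, 0.45, by = 0.15),
                            polish_sigmas = c(4, 1.5, 0),
                            reg = reg_config(), allow_ransac = FALSE,
                            search_model = "affine",
                            eye = eye_model(), K = wf_intrinsics(),
                            seed = 1L) {
  stopifnot(method %in% c("nelder_mead", "coord_search"),
            max_outer_iters >= 1)
  list(init_pose = init_pose, method = method, bounds = bounds,
       max_outer_iters = as.integer(max_outer_iters), dice_tol = dice_tol,
       grid_steps = grid_steps, polish_sigmas = polish_sigmas, reg = reg,
       allow_ransac = isTRUE(allow_ransac),
       search_model = match.arg(search_model, c("affine", "poly2")),
       eye = eye, K = K, seed = as.integer(seed))
}

bounds_matrix <- function(bounds) {
  rbind(lo = c(bounds$x[1], bounds$y[1], bounds$z[1],
               bounds$theta_x[1], bounds$theta_y[1]),
        hi = c(bounds$x[2], bounds$y[2], bounds$z[2],
               bounds$theta_x[2], bounds$theta_y[2]))
}

#' Iterative 3D camera-pose optimization (distortion correction)
#'
#' Searches the 5 WF camera extrinsics for the pose whose reprojection of
#' the UWF vessel map best registers to the WF vessel map. Per probed
#' pose: [project_wf_grid()] -> [resample_with_field()] ->
#' [register_2d()] of the reprojected UWF map against the WF map -> soft
#' Dice. The search is a coarse multi-start over the two rotations, the
#' configured derivative-free method over all five parameters, then an
#' optional coarse-to-fine polish that maximizes the direct (registration
#' -free) Dice of the reprojected map — sharply peaked at the true pose —
#' at decreasing blur levels. The best pose is never worse (in registered
#' Dice) than the initial pose, and the entire search is bit-reproducible
#' for fixed configuration.
#'
#' @param uwf_vm UWF vessel map (UWF frame).
#' @param wf_vm WF vessel map.
#' @param cfg a [pose_opt_config()].
#' @return a [registration_result()] with `pose` set, the inner 2D result
#'   at the best pose, and the full evaluation `trace`
#'   (iteration, stage, pose parameters, dice).
#' @export
optimize_pose <- function(uwf_vm, wf_vm, cfg = pose_opt_config()) {
  stopifnot(is.matrix(uwf_vm), is.matrix(wf_vm))
  if (identical(cfg$reg$rejector$type, "ransac_sc") && !cfg$allow_ransac) {
    stop(paste("optimize_pose requires a deterministic rejector;",
               "RANSAC-SC randomness corrupts the pose objective",
               "(set allow_ransac = TRUE to override)"))
  }
  bm <- bounds_matrix(cfg$bounds)
  wf_shape <- dim(wf_vm)
  kp_wf <- detect_keypoints(wf_vm, utils::modifyList(default_detect_cfg(),
                                                     cfg$reg$detect))
  # the search scores poses with the restricted inner model
  scfg <- cfg$reg
  scfg$model <- cfg$search_model
  scfg$rejector$model <- cfg$search_model
  trace <- list()
  n_eval <- 0L

  reproject <- function(v, img = uwf_vm) {
    pose <- pose_from_vector(v)
    field <- project_wf_grid(pose, cfg$K, cfg$eye, wf_shape)
    list(map = resample_with_field(img, field), field = field)
  }
  registered_dice <- function(v, stage, rcfg = scfg) {
    n_eval <<- n_eval + 1L
    d <- tryCatch({
      rp <- reproject(v)
      if (max(rp$map) == 0) 0 else
        register_2d(rp$map, wf_vm, rcfg, kp_wf = kp_wf)$dice_final
    }, error = function(e) 0)
    trace[[length(trace) + 1L]] <<- data.frame(
      iteration = n_eval, stage = stage, x = v[1], y = v[2], z = v[3],
      theta_x = v[4], theta_y = v[5], dice = d)
    d
  }
  in_bounds <- function(v) all(v >= bm["lo", ]) && all(v <= bm["hi", ])

  v0 <- pose_vector(cfg$init_pose)
  if (!in_bounds(v0)) stop("init_pose outside the configured bounds")
  best_v <- v0
  best_d <- registered_dice(v0, "init")

  # coarse multi-start over the steering rotations
  if (!is.null(cfg$grid_steps)) {
    for (dx in cfg$grid_steps) for (dy in cfg$grid_steps) {
      if (dx == 0 && dy == 0) next
      v <- v0 + c(0, 0, 0, dx, dy)
      if (!in_bounds(v)) next
      d <- registered_dice(v, "grid")
      if (d > best_d) { best_d <- d; best_v <- v }
    }
  }

  penalized <- function(v, fn) {
    viol <- sum(pmax(bm["lo", ] - v, 0) + pmax(v - bm["hi", ], 0))
    if (viol > 0) return(1 + viol)       # worse than any -dice
    -fn(v)
  }
  if (cfg$method == "nelder_mead") {
    opt <- stats::optim(best_v, function(v) penalized(v, function(u)
      registered_dice(u, "nelder_mead")),
      method = "Nelder-Mead",
      control = list(maxit = cfg$max_outer_iters,
                     reltol = cfg$dice_tol,
                     parscale = c(0.05, 0.05, 0.05, 0.1, 0.1)))
    if (-opt$value > best_d && in_bounds(opt$par)) {
      best_d <- -opt$value; best_v <- opt$par
    }
  } else {
    steps <- c(0.04, 0.04, 0.04, 0.08, 0.08)
    v <- best_v
    for (outer in seq_len(cfg$max_outer_iters)) {
      improved <- FALSE
      for (j in 1:5) for (sgn in c(1, -1)) {
        cand <- v; cand[j] <- cand[j] + sgn * steps[j]
        if (!in_bounds(cand)) next
        d <- registered_dice(cand, "coord_search")
        if (d > best_d + cfg$dice_tol) {
          best_d <- d; best_v <- cand; v <- cand; improved <- TRUE
        }
      }
      if (!improved) {
        steps <- steps / 2
        if (max(steps) < 1e-3) break
      }
    }
  }

  # coarse-to-fine polish on the direct (registration-free) reprojection
  # Dice: flexible 2D models blur the optimum, but the bare reprojection
  # overlap peaks sharply at the geometrically true pose
  if (!is.null(cfg$polish_sigmas)) {
    sr <- nominal_scale_ratio(cfg$eye, cfg$K, cfg$init_pose)
    for (sg in cfg$polish_sigmas) {
      wf_b <- if (sg > 0) gauss_blur(wf_vm, sg) else wf_vm
      uwf_b <- if (sg > 0) gauss_blur(uwf_vm, sg * sr) else uwf_vm
      direct <- function(v) {
        rp <- tryCatch(reproject(v, uwf_b), error = function(e) NULL)
        if (is.null(rp) || max(rp$map) == 0) return(0)
        mask <- rp$field$valid & wf_b > 0.02
        if (!any(mask)) return(0)
        suppressWarnings(dice(rp$map, wf_b, mask))
      }
      opt <- stats::optim(best_v, function(v) penalized(v, direct),
                          method = "Nelder-Mead",
                          control = list(maxit = 60L, reltol = 1e-6,
                                         parscale = c(0.02, 0.02, 0.02,
                                                      0.04, 0.04)))
      # Nelder-Mead never returns worse than its start, so the polished
      # pose is accepted per blur level (progressively sharper objective)
      if (in_bounds(opt$par)) {
        registered_dice(opt$par, sprintf("polish_s%g", sg))
        best_v <- opt$par
      }
    }
  }

  # report with the full (unrestricted) registration model, and never
  # return a pose that scores below the initial pose
  final_full <- function(v) {
    rp <- reproject(v)
    register_2d(rp$map, wf_vm, cfg$reg, kp_wf = kp_wf)
  }
  final <- tryCatch(final_full(best_v), error = function(e) NULL)
  d_init <- tryCatch(final_full(v0)$dice_final, error = function(e) 0)
  trace[[length(trace) + 1L]] <- data.frame(
    iteration = n_eval + 1L, stage = "init_full", x = v0[1], y = v0[2],
    z = v0[3], theta_x = v0[4], theta_y = v0[5], dice = d_init)
  n_eval <- n_eval + 1L
  if (is.null(final) || final$dice_final < d_init) {
    best_v <- v0
    final <- tryCatch(final_full(v0), error = function(e) NULL)
  }
  if (is.null(final)) {
    e <- simpleError("pose optimization: registration failed at every probed pose")
    e$trace <- do.call(rbind, trace)
    stop(e)
  }
  pose <- pose_from_vector(best_v)
  trace[[length(trace) + 1L]] <- data.frame(
    iteration = n_eval + 1L, stage = "final", x = best_v[1], y = best_v[2],
    z = best_v[3], theta_x = best_v[4], theta_y = best_v[5],
    dice = final$dice_final)
  registration_result(pose, final$T_wf_to_uwf, final$T_uwf_to_wf,
                      final$dice_final, final$matches,
                      do.call(rbind, trace))
}

#' Warp a WF image into the UWF frame at an optimized pose
#'
#' Backward resampling through the closed-form inverse distortion chain:
#' each UWF output pixel is (optionally) moved by the 2D polish
#' transform, back-projected onto the retina and imaged by the WF camera
#' ([uwf_pixel_to_wf_pixel()]), and the WF image is sampled there.
#'
#' @param img WF-frame raster (image, vessel map, or mask).
#' @param pose optimized `camera_pose`.
#' @param polish `poly_transform` mapping UWF pixels to
#'   chain-projected-WF-keypoint coordinates (the `T_uwf_to_wf` of
#'   [finalize_wf_to_uwf()]), or `NULL` for the bare chain.
#' @param out_shape `(rows, cols)` of the UWF output.
#' @param eye,K geometry.
#' @return list with `image` (warped raster) and `mask` (1 where the
#'   backward map lands inside the WF frame).
#' @export
warp_wf_to_uwf <- function(img, pose, polish = NULL,
                           out_shape, eye = eye_model(),
                           K = wf_intrinsics()) {
  nr <- as.integer(out_shape[1]); nc <- as.integer(out_shape[2])
  g <- grid_mn(nr, nc)
  q <- cbind(g$m, g$n)
  if (!is.null(polish)) q <- poly_apply(polish, q)
  bp <- uwf_pixel_to_wf_pixel(q, pose, K, eye)
  mm <- bp$pixel[, 1]; nn <- bp$pixel[, 2]
  vals <- bilinear_sample(img, mm, nn)
  inside <- bp$valid & mm >= 0 & mm <= ncol(img) - 1 &
    nn >= 0 & nn <= nrow(img) - 1
  inside[is.na(inside)] <- FALSE
  vals[!inside] <- 0
  list(image = matrix(vals, nr, nc),
       mask = matrix(as.numeric(inside), nr, nc))
}

#' Finalize: fit the UWF-frame alignment from the optimized pose
#'
#' Pushes the matched keypoints of the pose-optimized inner registration
#' through the 3D chain into the UWF frame: the WF keypoints become
#' "projected WF keypoints" and the reprojected-UWF keypoints recover
#' their true UWF coordinates. A final 2D polynomial polish is fitted
#' between them (both directions); composed with the closed-form inverse
#' chain it places the WF image — and its mask — in the UWF frame.
#'
#' @param pose optimized `camera_pose` from [optimize_pose()].
#' @param matches the `match_set` of the pose-optimized result (`src` =
#'   WF-frame WF keypoints, `dst` = WF-frame reprojected-UWF keypoints).
#' @param uwf_vm,wf_vm vessel maps used to score the final alignment.
#' @param eye,K geometry.
#' @return a [registration_result()]: `T_wf_to_uwf`/`T_uwf_to_wf` are the
#'   UWF-frame polish transforms (near identity), `dice_final` is scored
#'   in the UWF frame over the warped WF footprint. The warped map and
#'   mask are attached as attributes `"warped"` and `"mask"`.
#' @export
finalize_wf_to_uwf <- function(pose, matches, uwf_vm, wf_vm,
                               eye = eye_model(), K = wf_intrinsics()) {
  stopifnot(inherits(pose, "camera_pose"), inherits(matches, "match_set"))
  proj_wf <- wf_pixel_to_uwf_pixel(matches$src, pose, K, eye)
  uwf_pts <- wf_pixel_to_uwf_pixel(matches$dst, pose, K, eye)
  keep <- proj_wf$valid & uwf_pts$valid & matches$w > 0
  if (sum(keep) < 6L) {
    stop("projected keypoints degenerate: fewer than 6 valid pairs")
  }
  pw <- proj_wf$pixel[keep, , drop = FALSE]
  up <- uwf_pts$pixel[keep, , drop = FALSE]
  w <- matches$w[keep]
  polish_fwd <- fit_poly_wls(pw, up, w, frame = "projected-wf->uwf")
  polish_rev <- fit_poly_wls(up, pw, w, frame = "uwf->projected-wf")

  wr <- warp_wf_to_uwf(wf_vm, pose, polish_rev, dim(uwf_vm), eye, K)
  d <- suppressWarnings(dice(uwf_vm, wr$image, wr$mask > 0.5))
  out <- registration_result(pose, polish_fwd, polish_rev, d,
                             match_set(matches$src[keep, , drop = FALSE],
                                       matches$dst[keep, , drop = FALSE], w))
  attr(out, "warped") <- wr$image
  attr(out, "mask") <- wr$mask
  out
}
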