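# Top-level pipeline: configuration, orchestration, artifacts.
#
# One JSON document configures geometry, rejector, pose optimization,
# compositing and I/O. run_pipeline() registers every WF field to the
# UWF image (2D-only or with 3D distortion correction), fuses the
# composite, renders the checkerboard QC and writes a per-field summary
# CSV. All randomness flows from config seeds, so identical config +
# inputs give bit-identical artifacts.

pipeline_schema <- function() {
  list(
    mode = NULL, seed = NULL, log_level = NULL,
    geometry = list(uwf_fov_internal_deg = NULL, uwf_image_px = NULL,
                    wf_fov_deg = NULL, wf_image_px = NULL),
    rejector = list(type = NULL, model = NULL, n_iterations = NULL,
                    inlier_threshold_px = NULL, min_sample = NULL,
                    refine_rounds = NULL, seed = NULL, loss = NULL,
                    scale_px = NULL, max_iters = NULL, tol = NULL),
    pose_opt = list(init_z = NULL, max_outer_iters = NULL,
                    grid_step_rad = NULL, grid_span_rad = NULL,
                    polish_sigmas = NULL, dice_tol = NULL, seed = NULL),
    composite = list(sigma_px = NULL),
    io = list(uwf_image = NULL, wf_images = NULL, uwf_vessel_map = NULL,
              wf_vessel_maps = NULL, out_dir = NULL))
}

check_keys <- function(cfg, schema, path = "") {
  for (key in names(cfg)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(schema)) {
      stop("unknown configuration key: ", here)
    }
    if (is.list(schema[[key]]) && length(schema[[key]]) > 0) {
      if (!is.list(cfg[[key]])) stop("expected an object at: ", here)
      check_keys(cfg[[key]], schema[[key]], here)
    }
  }
  invisible(TRUE)
}

#' Load and validate a pipeline configuration
#'
#' Parses a JSON document (or takes an equivalent list), rejects unknown
#' keys naming the offending path, and fills defaults.
#'
#' @param config path to a JSON file, a JSON string, or a list.
#' @return validated config list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  check_keys(config, pipeline_schema())
  defaults <- list(
    mode = "3d", seed = 1L, log_level = "info",
    geometry = list(uwf_fov_internal_deg = 200, uwf_image_px = 512L,
                    wf_fov_deg = 55, wf_image_px = 256L),
    rejector = list(type = "irls"),
    pose_opt = list(init_z = -0.2, max_outer_iters = 80L,
                    grid_step_rad = 0.15, grid_span_rad = 0.45,
                    polish_sigmas = c(4, 1.5, 0), dice_tol = 1e-4, seed = 1L),
    composite = list(sigma_px = NULL),   # default: 1% of UWF width
    io = list())
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$mode %in% c("2d", "3d")) stop("mode must be '2d' or '3d'")
  class(cfg) <- "pipeline_config"
  cfg
}

build_rejector <- function(rj) {
  args <- rj[setdiff(names(rj), "type")]
  if (identical(rj$type, "irls")) do.call(irls_config, args)
  else if (identical(rj$type, "ransac_sc")) do.call(ransac_config, args)
  else stop("unknown rejector type: ", rj$type)
}

plog <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(...)
}

# UWF-frame dice of a 2D-only registration: backward-warp the WF map
# into the UWF frame with T_uwf_to_wf and score over the footprint
dice_2d_in_uwf <- function(uwf_vm, wf_vm, T_uwf_to_wf) {
  g <- grid_mn(nrow(uwf_vm), ncol(uwf_vm))
  q <- poly_apply(T_uwf_to_wf, cbind(g$m, g$n))
  inside <- q[, 1] >= 0 & q[, 1] <= ncol(wf_vm) - 1 &
    q[, 2] >= 0 & q[, 2] <= nrow(wf_vm) - 1
  warped <- matrix(bilinear_sample(wf_vm, q[, 1], q[, 2]), nrow(uwf_vm))
  mask <- matrix(inside, nrow(uwf_vm))
  list(dice = suppressWarnings(dice(uwf_vm, warped, mask)),
       warped = warped, mask = mask * 1)
}

register_field <- function(uwf_vm, wf_vm, cfg, eye, K) {
  sr <- nominal_scale_ratio(eye, K, camera_pose(z = cfg$pose_opt$init_z))
  rej <- build_rejector(cfg$rejector)
  rcfg2d <- reg_config(rejector = rej, scale_ratio = sr)
  r2d <- register_2d(uwf_vm, wf_vm, rcfg2d)
  w2d <- dice_2d_in_uwf(uwf_vm, wf_vm, r2d$T_uwf_to_wf)
  out <- list(r2d = r2d, dice_before = w2d$dice, warped = w2d$warped,
              mask = w2d$mask, dice_after = NA_real_, pose = NULL)
  if (cfg$mode == "3d") {
    po <- cfg$pose_opt
    pcfg <- pose_opt_config(
      init_pose = camera_pose(z = po$init_z),
      max_outer_iters = po$max_outer_iters,
      grid_steps = if (po$grid_step_rad > 0)
        seq(-po$grid_span_rad, po$grid_span_rad, by = po$grid_step_rad)
      else NULL,
      polish_sigmas = po$polish_sigmas, dice_tol = po$dice_tol,
      reg = reg_config(rejector = if (identical(rej$type, "irls")) rej
                       else irls_config()),
      eye = eye, K = K, seed = po$seed)
    r3d <- optimize_pose(uwf_vm, wf_vm, pcfg)
    fin <- finalize_wf_to_uwf(r3d$pose, r3d$matches, uwf_vm, wf_vm, eye, K)
    out$pose <- r3d$pose
    out$r3d <- r3d
    out$fin <- fin
    out$dice_after <- fin$dice_final
    # distortion correction must not lose to the 2D pass it contains
    if (is.finite(out$dice_after) && out$dice_after >= out$dice_before) {
      out$warped <- attr(fin, "warped")
      out$mask <- attr(fin, "mask")
    }
  }
  out
}

#' Run the full registration + compositing pipeline
#'
#' Per WF field: vessel-map extraction (or precomputed maps from
#' `io$wf_vessel_maps`), forward 2D registration, optionally the 3D
#' distortion-correction pose search and UWF-frame finalization, and a
#' backward warp of the field into the UWF frame. The warped fields are
#' fused with Gaussian-feathered masks into the composite; a
#' checkerboard of composite vs UWF is rendered for QC. Artifacts
#' (per-field registration JSON, warped PNGs, composite, checkerboard,
#' `summary.csv`) land in `io$out_dir`.
#'
#' @param config a [pipeline_config()], or anything it accepts.
#' @return invisibly, a list with `summary` (per-field data.frame:
#'   field, n_matches, dice_2d_wf_frame, dice_before_dc, dice_after_dc)
#'   and `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  io <- cfg$io
  if (is.null(io$uwf_image) || is.null(io$wf_images) || is.null(io$out_dir)) {
    stop("io.uwf_image, io.wf_images and io.out_dir are required")
  }
  dir.create(io$out_dir, recursive = TRUE, showWarnings = FALSE)
  geo <- cfg$geometry
  eye <- eye_model(geo$uwf_fov_internal_deg, geo$uwf_image_px)
  K <- wf_intrinsics(geo$wf_fov_deg, geo$wf_image_px)

  plog(cfg, "[pipeline] reading UWF image: ", io$uwf_image)
  uwf_img <- read_image(io$uwf_image)
  uwf_vm <- if (!is.null(io$uwf_vessel_map)) {
    unclass(read_vessel_map(io$uwf_vessel_map))
  } else extract_vessel_map(uwf_img)

  n_fields <- length(io$wf_images)
  warped <- vector("list", n_fields)
  masks <- vector("list", n_fields)
  rows <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    stage <- sprintf("field %d/%d", i, n_fields)
    plog(cfg, "[pipeline] ", stage, ": registering ", io$wf_images[i])
    wf_img <- read_image(io$wf_images[i])
    wf_vm <- if (!is.null(io$wf_vessel_maps)) {
      unclass(read_vessel_map(io$wf_vessel_maps[i]))
    } else extract_vessel_map(wf_img)
    res <- tryCatch(register_field(uwf_vm, wf_vm, cfg, eye, K),
                    error = function(e) {
                      stop(sprintf("registration failed at %s: %s",
                                   stage, conditionMessage(e)))
                    })
    warped[[i]] <- res$warped
    masks[[i]] <- res$mask
    rows[[i]] <- data.frame(
      field = i, n_matches = sum(res$r2d$matches$w > 0),
      dice_2d_wf_frame = res$r2d$dice_final,
      dice_before_dc = res$dice_before, dice_after_dc = res$dice_after)
    rj <- list(field = i,
               dice_before_dc = res$dice_before,
               dice_after_dc = res$dice_after,
               pose = if (!is.null(res$pose))
                 jsonlite::fromJSON(camera_pose_to_json(res$pose)),
               T_wf_to_uwf = res$r2d$T_wf_to_uwf$M,
               T_uwf_to_wf = res$r2d$T_uwf_to_wf$M)
    writeLines(as.character(jsonlite::toJSON(rj, auto_unbox = TRUE,
                                             digits = NA, null = "null")),
               file.path(io$out_dir, sprintf("registration_%02d.json", i)))
    write_image(file.path(io$out_dir, sprintf("warped_%02d.png", i)),
                res$warped)
  }

  sigma <- cfg$composite$sigma_px
  if (is.null(sigma)) sigma <- 0.01 * ncol(uwf_vm)
  plog(cfg, "[pipeline] fusing composite (mask sigma ", sigma, " px)")
  stack <- field_stack(warped, blur_masks(masks, sigma))
  composite <- fuse_fields(stack)
  write_image(file.path(io$out_dir, "composite.png"), composite)
  uwf_gray <- if (length(dim(uwf_img)) == 3L) uwf_img[, , 2] else uwf_img
  cb <- make_checkerboard(uwf_gray, composite,
                          max(1L, floor(ncol(composite) / 8)))
  write_image(file.path(io$out_dir, "checkerboard.png"), cb)

  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(io$out_dir, "summary.csv"),
                   row.names = FALSE)
  plog(cfg, "[pipeline] done: ", io$out_dir)
  invisible(list(summary = summary, out_dir = io$out_dir))
}
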