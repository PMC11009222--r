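# Phantom eye: a synthetic test bed with known ground truth.
#
# A seeded random vessel tree is grown on the unit-sphere retina and
# rendered twice — through the stereographic UWF projector and through
# the 5-DOF WF pinhole camera at known poses — giving image pairs with
# exact vessel maps, true poses and dense correspondences. The modality
# gap of real devices is emulated by different tone curves, blur and
# background texture in the two renders, so feature matching has to
# bridge appearance, not just geometry.

#' Phantom configuration
#'
#' Defaults mirror the acquisition setup the pipeline targets: one
#' 200-degree-internal-angle UWF image plus nine 55-degree WF fields
#' steered on a 3x3 grid. Raster sizes default to a desk-test scale
#' (512/256 px); set 4000/768 to mimic the devices.
#'
#' @param seed integer; fixes the entire scene (tree, textures, jitter).
#' @param n_fields number of WF fields (1-9; the centre field first,
#'   then the 8 steered neighbours).
#' @param wf_fov_deg,uwf_fov_internal_deg fields of view in degrees.
#' @param uwf_px,wf_px raster sizes in pixels.
#' @param camera_z WF camera axial position (unit-sphere frame).
#' @param steer_rad per-axis steering rotation of the off-centre fields,
#'   radians; 0.35 (about 20 degrees) makes the 9-field mosaic span
#'   roughly 110-120 degrees of retina.
#' @param pose_jitter sd of optional per-field position jitter.
#' @param tree branching parameters: `n_roots`, `branch_prob` (per
#'   step), `step_deg` (great-circle step), `width_deg` (trunk full
#'   width, degrees of arc), `depth` (maximum branching depth; 0 grows
#'   exactly `n_roots` unbranched polylines), `max_steps`, `jitter_deg`
#'   (heading jitter per step), `max_polar_deg` (growth stops past this
#'   polar angle from the posterior pole).
#' @param noise `background` (texture contrast scale) and `sensor`
#'   (additive Gaussian sd on the rendered images; 0 default).
#' @return object of class `"phantom_config"`.
#' @export
phantom_config <- function(seed = 1L, n_fields = 9L, wf_fov_deg = 55,
                           uwf_fov_internal_deg = 200, uwf_px = 512L,
                           wf_px = 256L, camera_z = -0.2,
                           steer_rad = 0.35, pose_jitter = 0,
                           tree = list(), noise = list()) {
  stopifnot(n_fields >= 1, n_fields <= 9)
  tree <- utils::modifyList(
    list(n_roots = 6L, branch_prob = 0.12, step_deg = 3, width_deg = 2.2,
         depth = 3L, max_steps = 28L, jitter_deg = 7, max_polar_deg = 70),
    tree)
  noise <- utils::modifyList(list(background = 1, sensor = 0), noise)
  structure(list(seed = as.integer(seed), n_fields = as.integer(n_fields),
                 wf_fov_deg = wf_fov_deg,
                 uwf_fov_internal_deg = uwf_fov_internal_deg,
                 uwf_px = as.integer(uwf_px), wf_px = as.integer(wf_px),
                 camera_z = camera_z, steer_rad = steer_rad,
                 pose_jitter = pose_jitter, tree = tree, noise = noise),
            class = "phantom_config")
}

# rotate tangent u (perpendicular to unit point p) about p by angle b
rotate_tangent <- function(u, p, b) {
  u * cos(b) + c(p[2] * u[3] - p[3] * u[2],
                 p[3] * u[1] - p[1] * u[3],
                 p[1] * u[2] - p[2] * u[1]) * sin(b)
}

#' Grow a seeded random vessel tree on the unit sphere
#'
#' Branches start near a synthetic optic-disc point and perform
#' great-circle random walks: each step advances `step_deg` along the
#' current tangent with Gaussian heading jitter; side branches spawn
#' with probability `branch_prob` per step (up to `depth` generations)
#' at 30-50 degree branching angles, with width decaying by 0.72 per
#' generation and a gentle taper along each branch. Deterministic for a
#' fixed seed.
#'
#' @param cfg a [phantom_config()].
#' @return list of branches, each `list(vertices = k x 3 unit vectors,
#'   width_rad = k widths in radians of arc)`.
#' @export
grow_vessel_tree <- function(cfg) {
  tc <- cfg$tree
  with_seed(cfg$seed, {
    disc <- c(sin(0.3), 0, cos(0.3))  # optic disc ~17 deg off the pole
    step <- tc$step_deg * pi / 180
    jit <- tc$jitter_deg * pi / 180
    max_polar <- tc$max_polar_deg * pi / 180
    base_w <- tc$width_deg * pi / 180

    # initial states: roots leave the disc in spread directions
    ref <- c(0, 1, 0)
    queue <- lapply(seq_len(tc$n_roots), function(i) {
      ang <- 2 * pi * (i - 0.5) / tc$n_roots + stats::rnorm(1, 0, 0.2)
      t0 <- rotate_tangent(normalize_tangent(ref, disc), disc, ang)
      list(p = disc, t = t0, depth = 0L, width = base_w)
    })
    branches <- list()
    while (length(queue) > 0) {
      st <- queue[[1]]; queue <- queue[-1]
      p <- st$p; tg <- st$t
      verts <- matrix(p, 1L)
      widths <- st$width
      for (k in seq_len(tc$max_steps)) {
        p_new <- cos(step) * p + sin(step) * tg
        tg <- -sin(step) * p + cos(step) * tg
        p <- p_new / sqrt(sum(p_new^2))
        tg <- tg - sum(tg * p) * p
        tg <- tg / sqrt(sum(tg^2))
        tg <- rotate_tangent(tg, p, stats::rnorm(1, 0, jit))
        w_here <- st$width * (1 - 0.2 * k / tc$max_steps)
        verts <- rbind(verts, p)
        widths <- c(widths, w_here)
        if (acos(clamp(p[3], -1, 1)) > max_polar) break
        if (k >= 3 && st$depth < tc$depth &&
            stats::runif(1) < tc$branch_prob) {
          side <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 0.9)
          queue[[length(queue) + 1L]] <- list(
            p = p, t = rotate_tangent(tg, p, side),
            depth = st$depth + 1L, width = w_here * 0.72)
        }
      }
      branches[[length(branches) + 1L]] <- list(vertices = unname(verts),
                                                width_rad = widths)
    }
    branches
  })
}

# component of ref orthogonal to p, normalized
normalize_tangent <- function(ref, p) {
  t0 <- ref - sum(ref * p) * p
  t0 / sqrt(sum(t0^2))
}

# rasterize anti-aliased line segments with per-endpoint widths (px);
# `edge` is the width of the linear intensity ramp at the stroke border
draw_strokes <- function(nr, nc, seg, edge = 1) {
  canvas <- matrix(0, nr, nc)
  if (nrow(seg) == 0) return(canvas)
  for (i in seq_len(nrow(seg))) {
    m0 <- seg$m0[i]; n0 <- seg$n0[i]; m1 <- seg$m1[i]; n1 <- seg$n1[i]
    pad <- max(seg$w0[i], seg$w1[i]) / 2 + edge / 2 + 1
    c_lo <- max(1L, floor(min(m0, m1) - pad) + 1L)
    c_hi <- min(nc, ceiling(max(m0, m1) + pad) + 1L)
    r_lo <- max(1L, floor(min(n0, n1) - pad) + 1L)
    r_hi <- min(nr, ceiling(max(n0, n1) + pad) + 1L)
    if (c_lo > c_hi || r_lo > r_hi) next
    mm <- rep((c_lo:c_hi) - 1, each = r_hi - r_lo + 1L)
    nn <- rep((r_lo:r_hi) - 1, times = c_hi - c_lo + 1L)
    dm <- m1 - m0; dn <- n1 - n0
    len2 <- dm^2 + dn^2
    tt <- if (len2 < 1e-12) rep(0, length(mm)) else
      clamp(((mm - m0) * dm + (nn - n0) * dn) / len2, 0, 1)
    dist <- sqrt((mm - (m0 + tt * dm))^2 + (nn - (n0 + tt * dn))^2)
    w_at <- seg$w0[i] + (seg$w1[i] - seg$w0[i]) * tt
    val <- clamp((w_at / 2 + edge / 2 - dist) / edge, 0, 1)
    blk <- canvas[r_lo:r_hi, c_lo:c_hi]
    canvas[r_lo:r_hi, c_lo:c_hi] <- pmax(blk, matrix(val, r_hi - r_lo + 1L))
  }
  canvas
}

# seeded low-frequency background texture in [0, 1]
background_texture <- function(nr, nc, seed, cutoff = max(nr, nc) / 24) {
  raw <- with_seed(seed, matrix(stats::runif(nr * nc), nr, nc))
  sm <- gauss_blur(raw, cutoff)
  rg <- range(sm)
  if (diff(rg) < 1e-12) return(matrix(0.5, nr, nc))
  (sm - rg[1]) / diff(rg)
}

#' Render the UWF view of a vessel tree
#'
#' Vessel polylines are projected through the stereographic model and
#' drawn as anti-aliased strokes whose widths follow the local
#' (conformal) stereographic magnification `1 + r^2/4`. The ground-truth
#' vessel map is the noise-free stroke raster; the image adds a seeded
#' low-frequency fundus-like background, the UWF tone curve, and is
#' masked to the circular 200-degree rim.
#'
#' @param tree from [grow_vessel_tree()].
#' @param eye an `eye_model`.
#' @param cfg a [phantom_config()].
#' @return list with `image` and `vm` (both `uwf_px` square matrices).
#' @export
render_uwf <- function(tree, eye, cfg) {
  W <- eye$uwf_image_px
  s <- uwf_pixel_scale(eye)
  ctr <- (W - 1) / 2
  segs <- list()
  for (br in tree) {
    prj <- sphere_to_uwf_pixel(br$vertices, eye)
    px <- prj$pixel
    ok <- prj$valid
    r_plane <- sqrt((px[, 1] - ctr)^2 + (px[, 2] - ctr)^2) / s
    w_px <- br$width_rad * (1 + r_plane^2 / 4) * s
    k <- nrow(px)
    if (k < 2) next
    use <- ok[-k] & ok[-1]
    if (!any(use)) next
    segs[[length(segs) + 1L]] <- data.frame(
      m0 = px[-k, 1][use], n0 = px[-k, 2][use],
      m1 = px[-1, 1][use], n1 = px[-1, 2][use],
      w0 = w_px[-k][use], w1 = w_px[-1][use])
  }
  vm <- draw_strokes(W, W, do.call(rbind, segs))
  bg <- background_texture(W, W, cfg$seed + 1L)
  img <- clamp(0.55 + 0.25 * cfg$noise$background * (bg - 0.5) -
                 0.5 * gauss_blur(vm, 0.8), 0, 1)
  if (cfg$noise$sensor > 0) {
    img <- clamp(img + with_seed(cfg$seed + 101L,
      matrix(stats::rnorm(W * W, 0, cfg$noise$sensor), W, W)), 0, 1)
  }
  g <- grid_mn(W, W)
  rim <- matrix(sqrt((g$m - ctr)^2 + (g$n - ctr)^2) / s <=
                  2 * tan(eye$uwf_fov_internal_deg * pi / 720), W, W)
  img[!rim] <- 0
  list(image = img, vm = vm)
}

#' Render a WF field of a vessel tree at a known camera pose
#'
#' Vessel polylines are imaged by the 5-DOF pinhole camera (only retina
#' points on the far side of the eye along the viewing ray are visible);
#' stroke widths follow the pinhole magnification `f_px / depth`. Also
#' computes the dense ground-truth correspondence to the UWF frame via
#' [project_wf_grid()] at the same pose. Bit-reproducible: the
#' background texture is seeded from `cfg$seed` and `noise_stream`.
#'
#' @param tree from [grow_vessel_tree()].
#' @param pose the true `camera_pose` of this field.
#' @param K,eye geometry.
#' @param cfg a [phantom_config()].
#' @param noise_stream integer distinguishing the per-field texture.
#' @return list with `image`, `vm`, `warp` (the ground-truth
#'   `warp_field`) and `pose`. An all-empty field (pose viewing
#'   off-retina) has `empty = TRUE`.
#' @export
render_wf <- function(tree, pose, K, eye, cfg, noise_stream = 0L) {
  W <- K$image_px
  fp <- wf_focal_depth(pose)
  half_px <- (W - 1) / 2
  s <- fp * tan(K$fov_deg * pi / 360) / half_px
  R <- pose_rotation(pose)
  pos <- c(pose$x, pose$y, pose$z)
  f_px <- fp / s
  segs <- list()
  for (br in tree) {
    pc <- sweep(br$vertices, 2, pos) %*% R      # camera frame
    vis <- pc[, 3] > 1e-6
    if (any(vis)) {
      far <- ray_sphere_far_intersection(pos, br$vertices[vis, , drop = FALSE])
      vis[vis] <- rowSums((far - br$vertices[vis, , drop = FALSE])^2) < 1e-9
    }
    m <- f_px * pc[, 1] / pc[, 3] + half_px
    n <- f_px * pc[, 2] / pc[, 3] + half_px
    w_px <- br$width_rad * f_px / pc[, 3]
    k <- nrow(pc)
    if (k < 2) next
    margin <- 60
    infr <- m > -margin & m < W - 1 + margin & n > -margin & n < W - 1 + margin
    use <- vis[-k] & vis[-1] & infr[-k] & infr[-1]
    if (!any(use)) next
    segs[[length(segs) + 1L]] <- data.frame(
      m0 = m[-k][use], n0 = n[-k][use], m1 = m[-1][use], n1 = n[-1][use],
      w0 = w_px[-k][use], w1 = w_px[-1][use])
  }
  # edge ramp matched to the WF/UWF magnification so the ground-truth
  # map has the same boundary softness as the reprojected UWF map
  edge_px <- max(1, (f_px / fp) / uwf_pixel_scale(eye))
  vm <- draw_strokes(W, W, if (length(segs)) do.call(rbind, segs) else
    data.frame(m0 = numeric(), n0 = numeric(), m1 = numeric(),
               n1 = numeric(), w0 = numeric(), w1 = numeric()),
    edge = edge_px)
  empty <- max(vm) == 0
  bg <- background_texture(W, W, cfg$seed + 211L + noise_stream)
  img <- clamp(0.62 + 0.3 * cfg$noise$background * (bg - 0.5) -
                 0.55 * gauss_blur(vm, 0.5), 0, 1)^1.25
  if (cfg$noise$sensor > 0) {
    img <- clamp(img + with_seed(cfg$seed + 307L + noise_stream,
      matrix(stats::rnorm(W * W, 0, cfg$noise$sensor), W, W)), 0, 1)
  }
  list(image = img, vm = vm, warp = project_wf_grid(pose, K, eye, c(W, W)),
       pose = pose, empty = empty)
}

# steering offsets of the 3x3 field layout, centre field first
field_offsets <- function(steer_rad) {
  g <- expand.grid(tx = c(-1, 0, 1) * steer_rad,
                   ty = c(-1, 0, 1) * steer_rad)
  ctr <- which(g$tx == 0 & g$ty == 0)
  g[c(ctr, setdiff(seq_len(nrow(g)), ctr)), ]
}

#' Build a complete phantom scene
#'
#' Grows the vessel tree, renders the UWF view, places `n_fields` WF
#' camera poses on the 3x3 steering grid (centre first, then the 8
#' steered neighbours, overlapping their neighbours), and renders each
#' field with its ground-truth vessel map, pose and dense UWF
#' correspondence. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @return object of class `"phantom_scene"`: list with `cfg`, `eye`,
#'   `K`, `tree`, `uwf_image`, `uwf_vm` and `fields` (each a
#'   [render_wf()] result plus `field_id` and steering `offset`).
#' @export
make_scene <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  eye <- eye_model(cfg$uwf_fov_internal_deg, cfg$uwf_px)
  K <- wf_intrinsics(cfg$wf_fov_deg, cfg$wf_px)
  tree <- grow_vessel_tree(cfg)
  uwf <- render_uwf(tree, eye, cfg)
  offs <- field_offsets(cfg$steer_rad)
  jit <- if (cfg$pose_jitter > 0) {
    with_seed(cfg$seed + 53L,
              matrix(stats::rnorm(2 * cfg$n_fields, 0, cfg$pose_jitter),
                     ncol = 2))
  } else matrix(0, cfg$n_fields, 2)
  fields <- lapply(seq_len(cfg$n_fields), function(i) {
    pose <- camera_pose(jit[i, 1], jit[i, 2], cfg$camera_z,
                        offs$tx[i], offs$ty[i])
    fl <- render_wf(tree, pose, K, eye, cfg, noise_stream = i)
    fl$field_id <- i
    fl$offset <- c(theta_x = offs$tx[i], theta_y = offs$ty[i])
    fl
  })
  structure(list(cfg = cfg, eye = eye, K = K, tree = tree,
                 uwf_image = uwf$image, uwf_vm = uwf$vm, fields = fields),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("phantom scene: %d vessel branches, UWF %dx%d, %d WF fields of %dx%d\n",
              length(x$tree), nrow(x$uwf_vm), ncol(x$uwf_vm),
              length(x$fields), x$K$image_px, x$K$image_px))
  invisible(x)
}

#' Write a phantom scene to a fixture directory
#'
#' Images as 8-bit PNG, vessel maps as 16-bit TIFF, poses as JSON, plus
#' a `manifest.json` tying them together.
#'
#' @param scene a `"phantom_scene"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "phantom_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(file.path(dir, "uwf.png"), scene$uwf_image)
  write_image(file.path(dir, "uwf_vm.tif"), scene$uwf_vm, bits = 16L)
  manifest <- list(seed = scene$cfg$seed,
                   uwf = list(image = "uwf.png", vessel_map = "uwf_vm.tif",
                              fov_internal_deg = scene$cfg$uwf_fov_internal_deg,
                              px = scene$cfg$uwf_px),
                   wf_fov_deg = scene$cfg$wf_fov_deg,
                   wf_px = scene$cfg$wf_px, fields = list())
  for (i in seq_along(scene$fields)) {
    fl <- scene$fields[[i]]
    img <- sprintf("wf_%02d.png", i)
    vmf <- sprintf("wf_%02d_vm.tif", i)
    psf <- sprintf("wf_%02d_pose.json", i)
    write_image(file.path(dir, img), fl$image)
    write_image(file.path(dir, vmf), fl$vm, bits = 16L)
    camera_pose_to_json(fl$pose, file.path(dir, psf))
    manifest$fields[[i]] <- list(image = img, vessel_map = vmf, pose = psf)
  }
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA)),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
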