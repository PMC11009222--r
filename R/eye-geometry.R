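# The spherical-eye 3D model.
#
# The eyeball is a unit sphere. The UWF device is modeled as a
# stereographic projector: its camera sits at the cornea centre
# (0, 0, -1) and images the retina onto the plane z = 1. The WF camera is
# a pinhole inside the eye with five extrinsic degrees of freedom:
# position (x, y, z) and optical-axis rotations (theta_x, theta_y). The
# WF image plane's centre is constrained to lie on z = 1, which pins the
# focal depth f' and keeps exactly five free parameters.
#
# Rotation convention: R = R_x(theta_x) %*% R_y(theta_y), right-handed,
# radians, applied camera->world. theta_y > 0 tilts the optical axis
# toward +x; theta_x > 0 tilts it toward -y.

#' Eye model parameters
#'
#' Fixed geometry of the spherical eye plus the UWF imaging parameters.
#' The sphere radius (1), UWF camera position `(0, 0, -1)` and UWF image
#' plane `z = 1` are structural constants of the model; only the UWF
#' internal field of view and raster size are configurable.
#'
#' @param uwf_fov_internal_deg UWF internal angle in degrees (default 200,
#'   i.e. roughly a 135-degree external field).
#' @param uwf_image_px UWF raster width/height in pixels (default 4000).
#' @return object of class `"eye_model"`.
#' @export
eye_model <- function(uwf_fov_internal_deg = 200, uwf_image_px = 4000) {
  stopifnot(uwf_fov_internal_deg > 0, uwf_fov_internal_deg < 360,
            uwf_image_px >= 16)
  structure(list(sphere_radius = 1,
                 uwf_camera = c(0, 0, -1),
                 uwf_plane_z = 1,
                 uwf_fov_internal_deg = uwf_fov_internal_deg,
                 uwf_image_px = as.integer(uwf_image_px)),
            class = "eye_model")
}

#' WF camera intrinsics
#'
#' @param fov_deg field of view in degrees (default 55).
#' @param image_px WF raster width/height in pixels (default 768).
#' @return object of class `"wf_intrinsics"`. The focal depth f' is not a
#'   free intrinsic: it is derived per pose so the WF image plane's centre
#'   lies on z = 1 (see [wf_focal_depth()]).
#' @export
wf_intrinsics <- function(fov_deg = 55, image_px = 768) {
  stopifnot(fov_deg > 0, fov_deg < 180, image_px >= 16)
  structure(list(fov_deg = fov_deg, image_px = as.integer(image_px)),
            class = "wf_intrinsics")
}

#' WF camera pose (5 degrees of freedom)
#'
#' @param x,y,z camera position inside the unit-sphere eye (`norm < 1`).
#' @param theta_x,theta_y optical-axis rotations about the x and y axes,
#'   radians, each in `(-pi/2, pi/2)`.
#' @return object of class `"camera_pose"`.
#' @export
camera_pose <- function(x = 0, y = 0, z = -0.2, theta_x = 0, theta_y = 0) {
  v <- c(x, y, z, theta_x, theta_y)
  if (!all(is.finite(v))) stop("pose parameters must be finite")
  if (sqrt(x^2 + y^2 + z^2) >= 1) {
    stop("camera position must lie strictly inside the unit sphere")
  }
  if (abs(theta_x) >= pi / 2 || abs(theta_y) >= pi / 2) {
    stop("|theta_x| and |theta_y| must be < pi/2")
  }
  structure(list(x = x, y = y, z = z, theta_x = theta_x, theta_y = theta_y),
            class = "camera_pose")
}

#' @export
print.camera_pose <- function(x, ...) {
  cat(sprintf(
    "WF camera pose: position (%.4f, %.4f, %.4f), theta_x %.4f rad, theta_y %.4f rad\n",
    x$x, x$y, x$z, x$theta_x, x$theta_y))
  invisible(x)
}

pose_vector <- function(pose) c(pose$x, pose$y, pose$z, pose$theta_x, pose$theta_y)
pose_from_vector <- function(v) camera_pose(v[1], v[2], v[3], v[4], v[5])

#' Serialize / deserialize a camera pose as JSON
#' @param pose a `camera_pose`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @rdname camera_pose_json
#' @export
camera_pose_to_json <- function(pose, path = NULL) {
  stopifnot(inherits(pose, "camera_pose"))
  obj <- list(x = pose$x, y = pose$y, z = pose$z,
              theta_x = pose$theta_x, theta_y = pose$theta_y,
              angles = "radians")
  js <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @param json JSON string or file path.
#' @rdname camera_pose_json
#' @export
camera_pose_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  camera_pose(obj$x, obj$y, obj$z, obj$theta_x, obj$theta_y)
}

#' Rotation matrix of a pose
#'
#' `R = R_x(theta_x) %*% R_y(theta_y)`, right-handed, camera-to-world.
#' @param pose a `camera_pose`.
#' @return 3x3 rotation matrix.
#' @export
pose_rotation <- function(pose) {
  cx <- cos(pose$theta_x); sx <- sin(pose$theta_x)
  cy <- cos(pose$theta_y); sy <- sin(pose$theta_y)
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx %*% Ry
}

#' Focal depth f' pinned by the z = 1 plane-centre constraint
#'
#' The WF image plane's centre (camera position + R (0,0,f')) is required
#' to lie on z = 1, giving `f' = (1 - z) / (R e3)_z =
#' (1 - z) / (cos theta_x cos theta_y)`.
#'
#' @param pose a `camera_pose`.
#' @return scalar f' > 0.
#' @export
wf_focal_depth <- function(pose) {
  f <- (1 - pose$z) / (cos(pose$theta_x) * cos(pose$theta_y))
  if (!is.finite(f) || f <= 0) stop("degenerate pose: focal depth not positive")
  f
}

# pixels-per-plane-unit of the UWF stereographic raster: the stereographic
# rim radius 2*tan(FOV_internal/4) maps to the image half-width (outermost
# pixel centre)
uwf_pixel_scale <- function(eye) {
  half_px <- (eye$uwf_image_px - 1) / 2
  half_px / (2 * tan(eye$uwf_fov_internal_deg * pi / 360 / 2))
}

#' Project unit-sphere points to UWF pixel coordinates
#'
#' Stereographic projection: the ray from the UWF camera `(0, 0, -1)`
#' through a retina point P is intersected with the image plane `z = 1`;
#' plane coordinates are converted to pixels by the linear map placing the
#' plane origin at the image centre and the plane half-extent
#' `2 tan(FOV_internal/4)` at the image half-width. A point at internal
#' polar angle phi from `(0,0,1)` lands at plane radius `2 tan(phi/2)`.
#'
#' @param P `k x 3` matrix (or length-3 vector) of points with unit norm.
#' @param eye an `eye_model`.
#' @return list with `pixel` (`k x 2`, 0-based (m, n)), `valid` (logical:
#'   not at the projection pole) and `in_frame` (logical: inside the
#'   raster bounds).
#' @export
sphere_to_uwf_pixel <- function(P, eye = eye_model()) {
  if (is.null(dim(P))) P <- matrix(P, 1L)
  stopifnot(ncol(P) == 3L)
  nrm <- sqrt(rowSums(P^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("points must lie on the unit sphere")
  denom <- 1 + P[, 3]
  valid <- denom > 1e-6          # projection pole (0,0,-1) excluded
  t <- ifelse(valid, 2 / denom, NA_real_)
  plane <- cbind(t * P[, 1], t * P[, 2])
  s <- uwf_pixel_scale(eye)
  ctr <- (eye$uwf_image_px - 1) / 2
  px <- plane * s + ctr
  in_frame <- valid & px[, 1] >= 0 & px[, 1] <= eye$uwf_image_px - 1 &
    px[, 2] >= 0 & px[, 2] <= eye$uwf_image_px - 1
  in_frame[is.na(in_frame)] <- FALSE
  list(pixel = px, valid = valid, in_frame = in_frame)
}

#' Back-project UWF pixels onto the unit sphere
#'
#' Exact inverse of [sphere_to_uwf_pixel()] on its range: the pixel is
#' mapped to plane coordinates and the ray from `(0, 0, -1)` through the
#' plane point is intersected with the unit sphere.
#'
#' @param q `k x 2` matrix (or length-2 vector) of 0-based (m, n) pixels.
#' @param eye an `eye_model`.
#' @return `k x 3` matrix of unit-sphere points.
#' @export
uwf_pixel_to_sphere <- function(q, eye = eye_model()) {
  if (is.null(dim(q))) q <- matrix(q, 1L)
  stopifnot(ncol(q) == 2L)
  s <- uwf_pixel_scale(eye)
  ctr <- (eye$uwf_image_px - 1) / 2
  X <- (q[, 1] - ctr) / s
  Y <- (q[, 2] - ctr) / s
  # pole + t*(X, Y, 2) on the unit sphere: t = 4 / (X^2 + Y^2 + 4)
  t <- 4 / (X^2 + Y^2 + 4)
  cbind(t * X, t * Y, 2 * t - 1)
}

#' Lift WF pixels onto the 3D WF image plane in world coordinates
#'
#' The WF grid (m, n) is placed on the camera's image plane at focal depth
#' f': camera-frame coordinates `((m - c) s, (n - c) s, f')` with
#' `s = f' tan(fov/2) / half_width_px`, then rotated by the pose rotation
#' and translated by the camera position.
#'
#' @param p `k x 2` matrix (or length-2 vector) of 0-based WF pixels.
#' @param pose a `camera_pose`.
#' @param K a `wf_intrinsics`.
#' @return `k x 3` matrix of world points (m', n', on the f' plane).
#' @export
wf_pixel_to_world <- function(p, pose, K = wf_intrinsics()) {
  if (is.null(dim(p))) p <- matrix(p, 1L)
  stopifnot(ncol(p) == 2L, inherits(pose, "camera_pose"))
  fp <- wf_focal_depth(pose)
  half_px <- (K$image_px - 1) / 2
  s <- fp * tan(K$fov_deg * pi / 360) / half_px
  d_cam <- cbind((p[, 1] - half_px) * s, (p[, 2] - half_px) * s, fp)
  R <- pose_rotation(pose)
  sweep(d_cam %*% t(R), 2, c(pose$x, pose$y, pose$z), "+")
}

#' Far intersection of a ray with the unit sphere
#'
#' For a ray from `origin` (strictly inside the sphere) through `through`,
#' returns the intersection with the unit sphere at the larger positive
#' ray parameter — the retina on the far side of the eye.
#'
#' @param origin length-3 vector inside the unit sphere.
#' @param through `k x 3` matrix (or length-3 vector) of points defining
#'   ray directions `through - origin`.
#' @return `k x 3` matrix of unit-sphere points.
#' @export
ray_sphere_far_intersection <- function(origin, through) {
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  if (sum(origin^2) >= 1) stop("ray origin must be strictly inside the sphere")
  if (is.null(dim(through))) through <- matrix(through, 1L)
  D <- sweep(through, 2, origin)
  dn <- sqrt(rowSums(D^2))
  if (any(dn < 1e-12)) stop("degenerate zero-length ray direction")
  D <- D / dn
  b <- as.numeric(D %*% origin)            # o . d
  disc <- b^2 - (sum(origin^2) - 1)        # always > 0 inside the sphere
  t_far <- -b + sqrt(disc)
  sweep(D * t_far, 2, origin, "+")
}

#' Dense WF-grid to UWF displacement field
#'
#' Runs the full distortion-correction projection chain for every WF
#' pixel: lift onto the WF image plane ([wf_pixel_to_world()]), project
#' onto the retina along the camera ray
#' ([ray_sphere_far_intersection()]), then project the retina point into
#' the UWF raster ([sphere_to_uwf_pixel()]). The result is the per-pixel
#' displacement `(m_p, n_p) - (m, n)` used to warp the UWF image to the
#' WF image's distortion level, plus a validity mask (rays hitting the
#' retina away from the projection pole).
#'
#' @param pose a `camera_pose`.
#' @param K a `wf_intrinsics`.
#' @param eye an `eye_model`.
#' @param wf_shape integer `(rows, cols)` of the WF grid; defaults to the
#'   square `K$image_px` raster.
#' @return object of class `"warp_field"`: list with matrices `dm`, `dn`
#'   and logical matrix `valid`.
#' @export
project_wf_grid <- function(pose, K = wf_intrinsics(), eye = eye_model(),
                            wf_shape = c(K$image_px, K$image_px)) {
  nr <- as.integer(wf_shape[1]); nc <- as.integer(wf_shape[2])
  g <- grid_mn(nr, nc)
  Wpts <- wf_pixel_to_world(cbind(g$m, g$n), pose, K)
  Rpts <- ray_sphere_far_intersection(c(pose$x, pose$y, pose$z), Wpts)
  prj <- sphere_to_uwf_pixel(Rpts, eye)
  dm <- prj$pixel[, 1] - g$m
  dn <- prj$pixel[, 2] - g$n
  dm[!prj$valid] <- NA_real_
  dn[!prj$valid] <- NA_real_
  structure(list(dm = matrix(dm, nr, nc),
                 dn = matrix(dn, nr, nc),
                 valid = matrix(prj$valid, nr, nc)),
            class = "warp_field")
}

#' Resample an image through a displacement field (STN-style)
#'
#' `output(p) = bilinear sample of img at p + displacement(p)`; invalid
#' field pixels and samples outside the input are 0. The field's shape
#' defines the output shape.
#'
#' @param img numeric matrix to sample from (e.g. the UWF vessel map).
#' @param field a `"warp_field"` from [project_wf_grid()].
#' @return numeric matrix shaped like the field.
#' @export
resample_with_field <- function(img, field) {
  stopifnot(inherits(field, "warp_field"))
  nr <- nrow(field$dm); nc <- ncol(field$dm)
  g <- grid_mn(nr, nc)
  out <- bilinear_sample(img, g$m + as.numeric(field$dm),
                         g$n + as.numeric(field$dn))
  out[!as.logical(field$valid)] <- 0
  matrix(out, nr, nc)
}

#' Store / load a displacement field as rasters
#'
#' The two displacement channels are linearly rescaled to `[0, 1]` and
#' written as the first two channels of a 16-bit RGB TIFF (the third
#' channel is zero); the validity mask goes to
#' `<path>.valid.tif` and the per-channel affine scaling to
#' `<path>.json`. Quantization error is `range / 65535` (around 0.01 px
#' for typical UWF-scale displacements).
#'
#' @param field a `"warp_field"`.
#' @param path TIFF path for the displacement channels.
#' @rdname warp_field_io
#' @export
write_warp_field <- function(field, path) {
  stopifnot(inherits(field, "warp_field"))
  dm <- field$dm; dn <- field$dn
  dm[!field$valid] <- 0; dn[!field$valid] <- 0
  rng <- function(x) {
    r <- range(x)
    if (diff(r) == 0) r[2] <- r[1] + 1
    r
  }
  rm_ <- rng(dm); rn_ <- rng(dn)
  arr <- array(0, c(dim(dm), 3L))
  arr[, , 1] <- (dm - rm_[1]) / diff(rm_)
  arr[, , 2] <- (dn - rn_[1]) / diff(rn_)
  tiff::writeTIFF(round(arr * 65535) / 65535, path, bits.per.sample = 16L)
  tiff::writeTIFF(field$valid * 1, paste0(path, ".valid.tif"),
                  bits.per.sample = 8L)
  writeLines(as.character(jsonlite::toJSON(
    list(dm_min = rm_[1], dm_max = rm_[2], dn_min = rn_[1],
         dn_max = rn_[2]),
    auto_unbox = TRUE, digits = NA)), paste0(path, ".json"))
  invisible(path)
}

#' @rdname warp_field_io
#' @export
read_warp_field <- function(path) {
  arr <- tiff::readTIFF(path)
  sc <- jsonlite::fromJSON(paste0(path, ".json"))
  valid <- tiff::readTIFF(paste0(path, ".valid.tif")) > 0.5
  dm <- arr[, , 1] * (sc$dm_max - sc$dm_min) + sc$dm_min
  dn <- arr[, , 2] * (sc$dn_max - sc$dn_min) + sc$dn_min
  dm[!valid] <- NA_real_; dn[!valid] <- NA_real_
  structure(list(dm = dm, dn = dn, valid = valid), class = "warp_field")
}

#' Project WF pixels directly to UWF pixel coordinates
#'
#' Point version of [project_wf_grid()] (the forward distortion chain).
#'
#' @inheritParams project_wf_grid
#' @param p `k x 2` matrix of 0-based WF pixels.
#' @return list with `pixel` (`k x 2` UWF coordinates) and `valid`.
#' @export
wf_pixel_to_uwf_pixel <- function(p, pose, K = wf_intrinsics(),
                                  eye = eye_model()) {
  if (is.null(dim(p))) p <- matrix(p, 1L)
  Wpts <- wf_pixel_to_world(p, pose, K)
  Rpts <- ray_sphere_far_intersection(c(pose$x, pose$y, pose$z), Wpts)
  prj <- sphere_to_uwf_pixel(Rpts, eye)
  list(pixel = prj$pixel, valid = prj$valid)
}

#' Project UWF pixels into the WF camera (inverse distortion chain)
#'
#' Back-projects UWF pixels onto the retina and images the retina points
#' with the WF pinhole camera at the given pose. This closed-form inverse
#' of the WF->UWF chain is what finally places WF content in the UWF
#' frame by backward resampling.
#'
#' @inheritParams project_wf_grid
#' @param q `k x 2` matrix of 0-based UWF pixels.
#' @return list with `pixel` (`k x 2` WF coordinates) and `valid`
#'   (retina point in front of the WF camera).
#' @export
uwf_pixel_to_wf_pixel <- function(q, pose, K = wf_intrinsics(),
                                  eye = eye_model()) {
  if (is.null(dim(q))) q <- matrix(q, 1L)
  P <- uwf_pixel_to_sphere(q, eye)
  R <- pose_rotation(pose)
  pc <- sweep(P, 2, c(pose$x, pose$y, pose$z)) %*% R   # R^T (P - c)
  valid <- pc[, 3] > 1e-6
  fp <- wf_focal_depth(pose)
  half_px <- (K$image_px - 1) / 2
  s <- fp * tan(K$fov_deg * pi / 360) / half_px
  m <- fp * pc[, 1] / pc[, 3] / s + half_px
  n <- fp * pc[, 2] / pc[, 3] / s + half_px
  m[!valid] <- NA_real_; n[!valid] <- NA_real_
  list(pixel = cbind(m, n), valid = valid)
}
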