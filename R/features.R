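# Classical feature extraction on vessel maps.
#
# The registration pipeline is feature-based: vessel maps bridge the two
# modalities, and keypoints detected on the maps are matched by
# bidirectional (mutual nearest-neighbour) consensus. The operators here
# are deterministic classical stand-ins with pluggable interfaces: vessel
# segmentation is a multiscale Hessian ridge filter, detection is Harris
# corners on the vessel map, description is a normalized log-polar
# intensity patch. Externally computed vessel maps or keypoints (e.g.
# from learned models) can be supplied wherever these outputs are
# consumed.

# shift a matrix by (dr, dc) with replicate padding
shift_mat <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- clamp(seq_len(nr) - dr, 1, nr)
  ci <- clamp(seq_len(nc) - dc, 1, nc)
  x[ri, ci, drop = FALSE]
}

#' Extract a vessel probability map from a fundus image
#'
#' Multiscale ridge (tubularity) filter: at each scale the image is
#' Gaussian-smoothed and the larger eigenvalue of the local Hessian is
#' scale-normalized (`sigma^2`) and rectified; the response is the
#' maximum over scales, contrast-normalized to `[0, 1]`. With
#' `polarity = "dark"` (default) dark vessels on a bright background
#' respond; `"bright"` flips the sign. Deterministic for fixed inputs and
#' configuration.
#'
#' @param img numeric matrix, or 3-channel array (the green channel is
#'   used, where vessel contrast is strongest).
#' @param cfg list overriding defaults: `scales` (pixel sigmas,
#'   default `c(1, 2, 3)`), `polarity` (`"dark"`/`"bright"`), `quantile`
#'   (normalization quantile of positive responses, default 0.995).
#' @return a matrix in `[0, 1]` (all zero, with a warning, for a constant
#'   image).
#' @export
extract_vessel_map <- function(img, cfg = list()) {
  cfg <- utils::modifyList(list(scales = c(1, 2, 3), polarity = "dark",
                                quantile = 0.995), cfg)
  if (length(dim(img)) == 3L) img <- img[, , 2]
  stopifnot(is.matrix(img))
  if (diff(range(img)) == 0) {
    warning("constant image: returning an all-zero vessel map")
    return(matrix(0, nrow(img), ncol(img)))
  }
  sgn <- if (identical(cfg$polarity, "dark")) 1 else -1
  resp <- matrix(0, nrow(img), ncol(img))
  for (sg in cfg$scales) {
    G <- gauss_blur(img, sg)
    Hxx <- shift_mat(G, 0, 1) - 2 * G + shift_mat(G, 0, -1)
    Hyy <- shift_mat(G, 1, 0) - 2 * G + shift_mat(G, -1, 0)
    Hxy <- (shift_mat(G, 1, 1) + shift_mat(G, -1, -1) -
              shift_mat(G, 1, -1) - shift_mat(G, -1, 1)) / 4
    tr2 <- (Hxx + Hyy) / 2
    disc <- sqrt(((Hxx - Hyy) / 2)^2 + Hxy^2)
    lam1 <- sgn * (tr2 + sgn * disc)   # eigenvalue of the ridge-crossing sign
    resp <- pmax(resp, sg^2 * pmax(lam1, 0))
  }
  pos <- resp[resp > 0]
  if (length(pos) == 0) {
    warning("no ridge response: returning an all-zero vessel map")
    return(resp)
  }
  clamp(resp / stats::quantile(pos, cfg$quantile), 0, 1)
}

default_detect_cfg <- function() {
  list(max_keypoints = 400, sigma_d = 1, sigma_i = 2.5, harris_k = 0.05,
       nms_radius = 3L, rel_threshold = 0.01, desc_radius = 8,
       desc_rings = c(0.3, 0.55, 0.8, 1.0), desc_angles = 8L)
}

#' Detect and describe keypoints on a vessel map
#'
#' Harris corner detection on the vessel map (vessel junctions and bends
#' are the stable landmarks of fundus registration), with 3x3 sub-pixel
#' quadratic refinement, followed by a log-polar intensity descriptor:
#' samples of the smoothed map on concentric rings around the keypoint,
#' mean-subtracted and L2-normalized. Keypoints are returned sorted by
#' response (descending), ties broken by row then column, capped at
#' `max_keypoints`; the whole operator is bit-reproducible.
#'
#' @param vm vessel map matrix.
#' @param cfg list overriding `default_detect_cfg()`: `max_keypoints`,
#'   `sigma_d`/`sigma_i` (derivative / integration sigmas, px),
#'   `harris_k`, `nms_radius`, `rel_threshold` (fraction of the maximum
#'   response), `desc_radius` (outer descriptor ring radius, px),
#'   `desc_rings` (ring radii as fractions of `desc_radius`),
#'   `desc_angles` (samples per ring).
#' @return object of class `"keypoints"`: list with `points`
#'   (data.frame `m`, `n`, `response`; 0-based pixel coordinates) and
#'   `desc` (one row per keypoint, rows L2-normalized).
#' @export
detect_keypoints <- function(vm, cfg = list()) {
  cfg <- utils::modifyList(default_detect_cfg(), cfg)
  stopifnot(is.matrix(vm), nrow(vm) > 4, ncol(vm) > 4)
  empty <- structure(list(points = data.frame(m = numeric(), n = numeric(),
                                              response = numeric()),
                          desc = matrix(numeric(), 0,
                                        length(cfg$desc_rings) * cfg$desc_angles + 1L)),
                     class = "keypoints")
  if (max(vm) <= 0) return(empty)

  G <- gauss_blur(vm, cfg$sigma_d)
  Ix <- (shift_mat(G, 0, 1) - shift_mat(G, 0, -1)) / 2
  Iy <- (shift_mat(G, 1, 0) - shift_mat(G, -1, 0)) / 2
  A <- gauss_blur(Ix * Ix, cfg$sigma_i)
  B <- gauss_blur(Iy * Iy, cfg$sigma_i)
  C <- gauss_blur(Ix * Iy, cfg$sigma_i)
  R <- A * B - C * C - cfg$harris_k * (A + B)^2

  # non-maximum suppression: peak iff equal to the local window maximum
  dil <- R
  for (dr in -cfg$nms_radius:cfg$nms_radius) {
    for (dc in -cfg$nms_radius:cfg$nms_radius) {
      if (dr != 0 || dc != 0) dil <- pmax(dil, shift_mat(R, dr, dc))
    }
  }
  thr <- cfg$rel_threshold * max(R)
  if (thr <= 0) return(empty)
  is_peak <- R >= dil & R > thr
  # keep a 2 px margin so the sub-pixel fit has neighbours
  is_peak[c(1:2, nrow(R) - 1:0), ] <- FALSE
  is_peak[, c(1:2, ncol(R) - 1:0)] <- FALSE
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)

  resp <- R[idx]
  ord <- order(-resp, idx[, 1], idx[, 2])
  ord <- ord[seq_len(min(length(ord), cfg$max_keypoints))]
  idx <- idx[ord, , drop = FALSE]
  resp <- resp[ord]

  # sub-pixel refinement: 1D quadratic fit per axis on the response
  subpix <- function(prev, cur, nxt) {
    den <- prev - 2 * cur + nxt
    d <- ifelse(abs(den) > 1e-12, 0.5 * (prev - nxt) / den, 0)
    clamp(d, -0.5, 0.5)
  }
  r0 <- idx[, 1]; c0 <- idx[, 2]
  dn <- subpix(R[cbind(r0 - 1L, c0)], R[cbind(r0, c0)], R[cbind(r0 + 1L, c0)])
  dm <- subpix(R[cbind(r0, c0 - 1L)], R[cbind(r0, c0)], R[cbind(r0, c0 + 1L)])
  m <- (c0 - 1) + dm
  n <- (r0 - 1) + dn

  # log-polar descriptor sampled from a smoothed map
  Gd <- gauss_blur(vm, cfg$desc_radius / 5)
  ang <- seq(0, 2 * pi, length.out = cfg$desc_angles + 1L)[-(cfg$desc_angles + 1L)]
  offs_m <- as.numeric(outer(cos(ang), cfg$desc_rings * cfg$desc_radius))
  offs_n <- as.numeric(outer(sin(ang), cfg$desc_rings * cfg$desc_radius))
  sm <- outer(m, offs_m, "+"); sn <- outer(n, offs_n, "+")
  desc <- cbind(bilinear_sample(Gd, m, n),
                matrix(bilinear_sample(Gd, as.numeric(sm), as.numeric(sn)),
                       nrow = length(m)))
  desc <- desc - rowMeans(desc)
  nrm <- sqrt(rowSums(desc^2))
  desc[nrm > 0, ] <- desc[nrm > 0, , drop = FALSE] / nrm[nrm > 0]

  structure(list(points = data.frame(m = m, n = n, response = resp),
                 desc = desc),
            class = "keypoints")
}

#' @export
print.keypoints <- function(x, ...) {
  cat(sprintf("%d keypoints (descriptor length %d)\n",
              nrow(x$points), ncol(x$desc)))
  invisible(x)
}

#' Export / import keypoints as JSON lines
#'
#' One JSON object per line: `{"x": m, "y": n, "response": r,
#' "descriptor": [...]}`.
#'
#' @param kp a `"keypoints"` object.
#' @param path destination file.
#' @rdname keypoints_json
#' @export
write_keypoints <- function(kp, path) {
  stopifnot(inherits(kp, "keypoints"))
  lines <- vapply(seq_len(nrow(kp$points)), function(i) {
    as.character(jsonlite::toJSON(
      list(x = kp$points$m[i], y = kp$points$n[i],
           response = kp$points$response[i],
           descriptor = kp$desc[i, ]),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname keypoints_json
#' @export
read_keypoints <- function(path) {
  lines <- readLines(path)
  objs <- lapply(lines, jsonlite::fromJSON)
  desc <- do.call(rbind, lapply(objs, `[[`, "descriptor"))
  structure(list(points = data.frame(
    m = vapply(objs, `[[`, numeric(1), "x"),
    n = vapply(objs, `[[`, numeric(1), "y"),
    response = vapply(objs, `[[`, numeric(1), "response")),
    desc = if (is.null(desc)) matrix(numeric(), 0, 0) else desc),
    class = "keypoints")
}

#' Construct a match set
#'
#' @param src,dst `k x 2` matrices of corresponding 0-based (m, n)
#'   points in the source and destination images.
#' @param w per-pair weights in `[0, 1]` (default 1).
#' @return object of class `"match_set"`.
#' @export
match_set <- function(src, dst, w = 1) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) > 0) stopifnot(ncol(src) == 2L, ncol(dst) == 2L)
  stopifnot(nrow(src) == nrow(dst))
  w <- rep_len(as.numeric(w), nrow(src))
  if (nrow(src) > 0 && (any(!is.finite(w)) || any(w < 0) || any(w > 1))) {
    stop("weights must lie in [0, 1]")
  }
  structure(list(src = unname(src), dst = unname(dst), w = w),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("match set: %d pairs, %d with positive weight\n",
              length(x$w), sum(x$w > 0)))
  invisible(x)
}

#' Match keypoints by bidirectional consensus
#'
#' A pair (i, j) is retained iff keypoint j of `b` is the nearest
#' neighbour (Euclidean distance between L2-normalized descriptors) of
#' keypoint i of `a` AND i is the nearest neighbour of j — mutual
#' nearest-neighbour consensus, which guarantees a one-to-one matching.
#' Ties are broken by the lower index. Initial weights are 1.
#'
#' @param a,b `"keypoints"` objects with equal descriptor length.
#' @return a `"match_set"` with `src` the matched points of `a` and `dst`
#'   the matched points of `b`, plus integer attributes `a_idx`, `b_idx`.
#' @export
match_bidirectional <- function(a, b) {
  stopifnot(inherits(a, "keypoints"), inherits(b, "keypoints"))
  na <- nrow(a$points); nb <- nrow(b$points)
  if (na == 0 || nb == 0) {
    return(match_set(matrix(numeric(), 0, 2), matrix(numeric(), 0, 2)))
  }
  if (ncol(a$desc) != ncol(b$desc)) stop("descriptor lengths differ")
  # squared Euclidean distances
  D <- outer(rowSums(a$desc^2), rowSums(b$desc^2), "+") -
    2 * a$desc %*% t(b$desc)
  best_b <- apply(D, 1, which.min)   # which.min breaks ties by lower index
  best_a <- apply(D, 2, which.min)
  ai <- which(best_a[best_b] == seq_len(na))
  bi <- best_b[ai]
  out <- match_set(as.matrix(a$points[ai, c("m", "n")]),
                   as.matrix(b$points[bi, c("m", "n")]), 1)
  attr(out, "a_idx") <- as.integer(ai)
  attr(out, "b_idx") <- as.integer(bi)
  out
}

#' Guided re-matching under a predicted transform
#'
#' Second-pass matching used after an initial transform estimate: each
#' keypoint of `a` is predicted into `b`'s frame by `transform`, and only
#' `b` keypoints within `gate_px` of the prediction compete (by
#' descriptor distance) for the match. The spatial gate rescues correct
#' pairs that pure descriptor matching loses among repetitive vessel
#' structures.
#'
#' @param a,b `"keypoints"` objects (`a` = source side, `b` = target side).
#' @param transform `poly_transform` mapping `a` coordinates into `b`'s
#'   frame.
#' @param gate_px admissible radius around the predicted position, px.
#' @return a `"match_set"` (src = `a` points, dst = `b` points).
#' @export
match_guided <- function(a, b, transform, gate_px = 4) {
  stopifnot(inherits(a, "keypoints"), inherits(b, "keypoints"), gate_px > 0)
  na <- nrow(a$points); nb <- nrow(b$points)
  if (na == 0 || nb == 0) {
    return(match_set(matrix(numeric(), 0, 2), matrix(numeric(), 0, 2)))
  }
  pred <- poly_apply(transform, as.matrix(a$points[, c("m", "n")]))
  D <- outer(rowSums(a$desc^2), rowSums(b$desc^2), "+") -
    2 * a$desc %*% t(b$desc)
  G <- outer(pred[, 1], b$points$m, "-")^2 +
    outer(pred[, 2], b$points$n, "-")^2
  D[G > gate_px^2] <- Inf
  bi <- apply(D, 1, which.min)
  ok <- is.finite(D[cbind(seq_len(na), bi)])
  match_set(as.matrix(a$points[ok, c("m", "n")]),
            as.matrix(b$points[bi[ok], c("m", "n")]), 1)
}
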