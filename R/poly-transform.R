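# Second-order polynomial point transforms.
#
# A transform is the 2x6 matrix M mapping a lifted point
# [m, n, m^2, n^2, m*n, 1] to (u, v):
#     [u, v]^T = M [m, n, m^2, n^2, m n, 1]^T
# Affine maps are the subcase with zero quadratic columns. The polynomial
# has no closed-form inverse, so the pipeline always fits transforms in
# both directions from the same match set and resamples with the
# output->input (backward) direction.

#' Lift a 2D point into the second-order monomial basis
#'
#' @param p numeric vector of length 2 `(m, n)`, or an `k x 2` matrix of
#'   points (columns m, n).
#' @return a length-6 vector (or `k x 6` matrix): `[m, n, m^2, n^2, m*n, 1]`.
#' @export
poly_lift <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 2L)
    p <- matrix(p, 1L)
    drop_out <- TRUE
  } else drop_out <- FALSE
  if (ncol(p) != 2L) stop("points must have two columns (m, n)")
  if (!all(is.finite(p))) stop("non-finite point coordinates")
  m <- p[, 1]; n <- p[, 2]
  out <- cbind(m, n, m^2, n^2, m * n, 1, deparse.level = 0)
  if (drop_out) out[1, ] else out
}

#' Construct a second-order polynomial transform
#'
#' @param M numeric 2x6 matrix; row 1 produces u, row 2 produces v; columns
#'   multiply `[m, n, m^2, n^2, m*n, 1]`.
#' @param frame optional label such as `"wf->uwf"` recording which frames
#'   the transform maps between (documentation only).
#' @return an object of class `"poly_transform"`.
#' @export
poly_transform <- function(M, frame = NULL) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(2L, 6L))) stop("M must be 2x6")
  if (!all(is.finite(M))) stop("M contains non-finite entries")
  structure(list(M = unname(M), frame = frame), class = "poly_transform")
}

#' Identity polynomial transform
#' @export
poly_identity <- function() {
  poly_transform(rbind(c(1, 0, 0, 0, 0, 0),
                       c(0, 1, 0, 0, 0, 0)), frame = "identity")
}

#' @export
print.poly_transform <- function(x, ...) {
  cat("second-order polynomial transform",
      if (!is.null(x$frame)) sprintf("(%s)", x$frame), "\n")
  M <- x$M
  dimnames(M) <- list(c("u", "v"), c("m", "n", "m2", "n2", "mn", "1"))
  print(M)
  invisible(x)
}

#' Apply a polynomial transform to points
#'
#' @param transform a `poly_transform`.
#' @param points `k x 2` matrix (or length-2 vector) of (m, n) points.
#' @return `k x 2` matrix of transformed (u, v) points.
#' @export
poly_apply <- function(transform, points) {
  stopifnot(inherits(transform, "poly_transform"))
  L <- poly_lift(points)
  if (is.null(dim(L))) L <- matrix(L, 1L)
  L %*% t(transform$M)
}

# lift-basis matrix of the affine normalization p~ = s*(p - c):
# lift(p~) = L %*% lift(p)
.norm_lift_matrix <- function(s, c) {
  cm <- c[1]; cn <- c[2]
  rbind(
    c(s, 0, 0, 0, 0, -s * cm),
    c(0, s, 0, 0, 0, -s * cn),
    c(-2 * s^2 * cm, 0, s^2, 0, 0, s^2 * cm^2),
    c(0, -2 * s^2 * cn, 0, s^2, 0, s^2 * cn^2),
    c(-s^2 * cn, -s^2 * cm, 0, 0, s^2, s^2 * cm * cn),
    c(0, 0, 0, 0, 0, 1))
}

#' Weighted least-squares estimation of a polynomial transform
#'
#' Finds the 2x6 matrix minimizing
#' \eqn{\sum_i w_i \lVert M\,lift(src_i) - dst_i \rVert^2}.
#' Coordinates are mean/scale-normalized before fitting (Hartley-style
#' conditioning of the quadratic monomials) and the estimate is
#' denormalized exactly afterwards, so the returned transform acts on raw
#' pixel coordinates. The normalized weighted design is solved by QR
#' factorization. Zero-weight pairs are discarded before fitting; scaling
#' all weights by a positive constant leaves the estimate unchanged.
#'
#' @param src,dst `k x 2` matrices of corresponding (m, n) points.
#' @param w nonnegative weights (recycled scalar allowed; default 1).
#' @param frame optional frame label stored on the result.
#' @return a `poly_transform` mapping src coordinates to dst coordinates.
#' @export
fit_poly_wls <- function(src, dst, w = 1, frame = NULL) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (ncol(src) != 2L || ncol(dst) != 2L || nrow(src) != nrow(dst)) {
    stop("src and dst must be k x 2 matrices of equal length")
  }
  w <- rep_len(as.numeric(w), nrow(src))
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  keep <- w > 0
  if (sum(keep) < 6L) {
    stop(sprintf("need at least 6 positively weighted pairs, got %d", sum(keep)))
  }
  src <- src[keep, , drop = FALSE]
  dst <- dst[keep, , drop = FALSE]
  w <- w[keep]

  norm_params <- function(p) {
    c0 <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, c0)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    list(c = c0, s = s)
  }
  ns <- norm_params(src); nd <- norm_params(dst)
  src_n <- (src - matrix(ns$c, nrow(src), 2, byrow = TRUE)) * ns$s
  dst_n <- (dst - matrix(nd$c, nrow(dst), 2, byrow = TRUE)) * nd$s

  A <- poly_lift(src_n)
  sw <- sqrt(w)
  Aw <- A * sw
  qrA <- qr(Aw)
  if (qrA$rank < 6L) {
    stop(sprintf(paste0("rank-deficient design (rank %d of 6): source points ",
                        "lie on a degenerate variety of the quadratic basis"),
                 qrA$rank))
  }
  Mn <- t(qr.coef(qrA, dst_n * sw))   # 2 x 6 in normalized frames

  # denormalize: dst = dst_n / s_d + c_d and lift(src_n) = L lift(src)
  L <- .norm_lift_matrix(ns$s, ns$c)
  M <- (Mn %*% L) / nd$s
  M[, 6] <- M[, 6] + nd$c
  poly_transform(M, frame = frame)
}

#' Warp an image by a backward polynomial transform
#'
#' Resamples `img` onto an output grid: each output pixel at 0-based
#' position p is assigned the bilinear sample of `img` at
#' `transform(p)`. `transform` must therefore map output-frame coordinates
#' into input-frame coordinates (backward mapping); samples falling outside
#' the input are 0.
#'
#' @param img numeric matrix (input raster).
#' @param transform `poly_transform` from output frame to input frame.
#' @param out_shape integer vector `(rows, cols)` of the output.
#' @return numeric matrix of shape `out_shape`.
#' @export
warp_image_poly <- function(img, transform, out_shape = dim(img)) {
  stopifnot(length(out_shape) == 2L)
  nr <- as.integer(out_shape[1]); nc <- as.integer(out_shape[2])
  g <- grid_mn(nr, nc)
  q <- poly_apply(transform, cbind(g$m, g$n))
  matrix(bilinear_sample(img, q[, 1], q[, 2]), nr, nc)
}

#' Serialize / deserialize a polynomial transform as JSON
#'
#' The JSON form is
#' `{"M": [[...6...],[...6...]], "basis": "m,n,m2,n2,mn,1", "frame": "..."}`.
#'
#' @param transform a `poly_transform`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @rdname poly_transform_json
#' @export
poly_transform_to_json <- function(transform, path = NULL) {
  stopifnot(inherits(transform, "poly_transform"))
  obj <- list(M = transform$M, basis = "m,n,m2,n2,mn,1",
              frame = if (is.null(transform$frame)) "unspecified" else transform$frame)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @param json JSON string or file path produced by `poly_transform_to_json`.
#' @rdname poly_transform_json
#' @export
poly_transform_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (!identical(obj$basis, "m,n,m2,n2,mn,1")) {
    stop("unsupported basis in serialized transform: ", obj$basis)
  }
  poly_transform(obj$M, frame = obj$frame)
}
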