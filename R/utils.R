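# Internal numerical utilities shared across modules.
#
# Conventions used package-wide:
#  * a raster/vessel map is a numeric matrix `img[row, col]`
#  * a point is (m, n) = (column, row) in 0-based pixel-centre coordinates,
#    so img[r, c] sits at (m = c - 1, n = r - 1)

#' Bilinear sampling of a raster at fractional pixel positions
#'
#' Samples `img` at 0-based (column, row) positions with bilinear
#' interpolation; positions outside the pixel grid contribute zero
#' (zero-padding semantics), so sampling exactly on the integer grid
#' reproduces pixel values bit-for-bit.
#'
#' @param img numeric matrix.
#' @param m,n numeric vectors of equal length: 0-based column / row
#'   coordinates.
#' @return numeric vector of sampled values (0 where outside or non-finite).
#' @keywords internal
bilinear_sample <- function(img, m, n) {
  stopifnot(is.matrix(img), length(m) == length(n))
  nr <- nrow(img); nc <- ncol(img)
  bad <- !is.finite(m) | !is.finite(n)
  m[bad] <- -2; n[bad] <- -2          # lands fully outside -> 0
  x0 <- floor(m); y0 <- floor(n)
  fx <- m - x0; fy <- n - y0
  pick <- function(xi, yi) {
    ok <- xi >= 0 & xi < nc & yi >= 0 & yi < nr
    v <- numeric(length(xi))
    if (any(ok)) v[ok] <- img[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    v
  }
  (1 - fx) * (1 - fy) * pick(x0, y0) +
    fx * (1 - fy) * pick(x0 + 1, y0) +
    (1 - fx) * fy * pick(x0, y0 + 1) +
    fx * fy * pick(x0 + 1, y0 + 1)
}

#' Separable Gaussian blur with reflective boundaries
#'
#' Direct separable convolution with a truncated Gaussian kernel
#' (radius 3 sigma) and mirror padding at the borders. Mirror padding keeps
#' border energy local, which matters for composite mask feathering and for
#' vessel maps whose structures touch the frame edge.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the input
#'   unchanged.
#' @return blurred matrix, same shape.
#' @export
gauss_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), is.finite(sigma))
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  reflect <- function(i, n) {
    # mirror without edge duplication: 0 -> 2, n+1 -> n-1
    i <- ifelse(i < 1L, 2L - i, i)
    i <- ifelse(i > n, 2L * n - i, i)
    pmin(pmax(i, 1L), n)
  }
  blur_rows <- function(x) {
    n <- nrow(x)
    p <- x[reflect(seq.int(1L - r, n + r), n), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) {
      out <- out + k[j] * p[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(img))))
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the prior
#' RNG state afterwards, so seeded components (RANSAC, the phantom
#' generator) never perturb user-level randomness. All package randomness
#' flows through this helper.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# clamp to [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# 0-based pixel-centre coordinate grids for an nr x nc raster, as vectors
# aligned with column-major matrix storage
grid_mn <- function(nr, nc) {
  list(m = rep(seq_len(nc) - 1, each = nr),
       n = rep(seq_len(nr) - 1, times = nc))
}
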