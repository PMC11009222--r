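# Vessel maps and the soft-Dice overlap metric.
#
# A vessel map is the common currency between imaging modalities: a
# per-pixel probability of "this pixel is on a retinal vessel", stored as a
# plain numeric matrix with values in [0, 1].

#' Construct / validate a vessel map
#'
#' @param values numeric matrix with finite values in `[0, 1]`.
#' @return the matrix, classed `"vessel_map"`.
#' @export
vessel_map <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("vessel map must be a numeric matrix")
  }
  if (!all(is.finite(values))) stop("vessel map contains non-finite values")
  if (min(values) < 0 || max(values) > 1) {
    stop("vessel map values must lie in [0, 1]")
  }
  structure(values, class = c("vessel_map", class(values)))
}

#' Soft Dice overlap between two vessel maps
#'
#' The probability-valued (soft) Dice score
#' \deqn{Dice(I_1, I_2) = \frac{2 \sum \min(I_1, I_2)}{\sum I_1 + \sum I_2}}
#' computed pixelwise, optionally restricted to a mask. On binary maps this
#' reduces to the classic set Dice 2|A∩B|/(|A|+|B|). It is both the
#' objective driving camera-pose optimization and the evaluation metric for
#' registered vessel maps.
#'
#' @param a,b numeric matrices of identical shape, values in `[0, 1]`.
#' @param mask optional logical/0-1 matrix of that shape; only pixels where
#'   `mask` is true (or > 0) are scored.
#' @return a scalar in `[0, 1]`. If both maps are identically zero inside
#'   the mask the denominator vanishes; the score is then defined as 0 and a
#'   warning is raised (no vessels means no demonstrated overlap).
#' @export
#' @examples
#' a <- matrix(c(1, 0.5), 1)
#' b <- matrix(c(0.5, 0.5), 1)
#' dice(a, b)  # 2*(0.5+0.5) / (1.5+1.0) = 0.8
dice <- function(a, b, mask = NULL) {
  if (!is.matrix(a) || !is.matrix(b)) stop("dice() expects matrices")
  if (!all(dim(a) == dim(b))) {
    stop(sprintf("shape mismatch: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  }
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(a))) stop("mask shape does not match maps")
    keep <- as.logical(mask > 0)
    av <- a[keep]; bv <- b[keep]
  } else {
    av <- as.numeric(a); bv <- as.numeric(b)
  }
  den <- sum(av) + sum(bv)
  if (den == 0) {
    warning("both vessel maps are zero in the scored region; Dice defined as 0")
    return(0)
  }
  2 * sum(pmin(av, bv)) / den
}
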