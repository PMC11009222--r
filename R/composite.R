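# Composite generation: fuse the registered WF fields (already warped
# into the UWF frame) into one image with smooth seams. Each field
# carries a coverage mask; mask boundaries are feathered by Gaussian
# blurring and the fields are combined as a mask-weighted average:
# sum(mask_i * image_i) / sum(mask_i).

#' A stack of registered fields
#'
#' @param images list of equal-shape rasters in the UWF frame.
#' @param masks list of same-shape weight grids in `[0, 1]`.
#' @return object of class `"field_stack"`.
#' @export
field_stack <- function(images, masks) {
  if (length(images) == 0) stop("empty field stack")
  if (length(images) != length(masks)) stop("images and masks differ in length")
  d <- dim(images[[1]])
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]]) == d) || !all(dim(masks[[i]]) == d)) {
      stop("all images and masks must share one shape")
    }
    if (min(masks[[i]]) < 0 || max(masks[[i]]) > 1) {
      stop("mask values must lie in [0, 1]")
    }
  }
  structure(list(images = images, masks = masks), class = "field_stack")
}

#' Feather field masks by Gaussian blurring
#'
#' @param masks list of mask matrices in `[0, 1]`.
#' @param sigma_px Gaussian sigma in pixels; 0 leaves the masks
#'   unchanged. The pipeline default is 1\% of the UWF width.
#' @return list of blurred masks (values clamped to `[0, 1]`).
#' @export
blur_masks <- function(masks, sigma_px) {
  stopifnot(sigma_px >= 0)
  if (sigma_px == 0) return(masks)
  lapply(masks, function(m) clamp(gauss_blur(m, sigma_px), 0, 1))
}

#' Fuse a field stack into a composite image
#'
#' Pixelwise `sum(mask_i * image_i) / sum(mask_i)`; pixels with total
#' mask weight below 1e-8 (no coverage) are 0.
#'
#' @param stack a [field_stack()].
#' @return composite matrix of the common shape.
#' @export
fuse_fields <- function(stack) {
  stopifnot(inherits(stack, "field_stack"))
  num <- 0; den <- 0
  for (i in seq_along(stack$images)) {
    num <- num + stack$masks[[i]] * stack$images[[i]]
    den <- den + stack$masks[[i]]
  }
  out <- num
  covered <- den >= 1e-8
  out[covered] <- num[covered] / den[covered]
  out[!covered] <- 0
  out
}
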