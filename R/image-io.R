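# Raster I/O and checkerboard QC rendering.
#
# Rasters are numeric matrices (grayscale) or row x col x channel arrays
# (channels in RGB order), values in [0, 1]. Supported lossless formats:
# PNG (8-bit write; 8/16-bit read) and TIFF (8- or 16-bit write/read).
# Writes quantize to the target bit depth, so write -> read round-trips
# are bit-exact.

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop(sprintf("unsupported raster format '.%s' for '%s' (use PNG or TIFF)",
               ext, path))
}

#' Read a lossless raster image
#'
#' @param path PNG or TIFF file.
#' @return numeric matrix (grayscale) or row x col x channel array with
#'   channels in RGB(A) order, values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  fmt <- image_format(path)
  img <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  img
}

#' Write a lossless raster image
#'
#' Values are clamped to `[0, 1]` and quantized to the requested bit
#' depth before writing. 16-bit output requires TIFF (the PNG writer in
#' use is 8-bit); reading 16-bit PNGs works.
#'
#' @param path destination PNG or TIFF path.
#' @param img matrix or row x col x channel array in `[0, 1]`.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(path, img, bits = 8L) {
  fmt <- image_format(path)
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16, got ", bits)
  if (fmt == "png" && bits == 16L) {
    stop(sprintf("16-bit PNG writing is unsupported ('%s'); use TIFF for 16-bit",
                 path))
  }
  q <- 2^bits - 1
  img <- round(clamp(img, 0, 1) * q) / q
  if (fmt == "png") png::writePNG(img, path)
  else tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read / write a vessel map as a 16-bit raster
#'
#' Vessel probabilities in `[0, 1]` are scaled linearly across the
#' 16-bit range; the scaling round-trips exactly for values quantized to
#' that grid.
#'
#' @param path TIFF path (16-bit) or PNG path (read: any depth).
#' @rdname vessel_map_io
#' @export
read_vessel_map <- function(path) {
  img <- read_image(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  vessel_map(img)
}

#' @param vm vessel map matrix.
#' @rdname vessel_map_io
#' @export
write_vessel_map <- function(path, vm) {
  write_image(path, unclass(vm), bits = 16L)
}

#' Checkerboard overlay of two registered images
#'
#' Output pixel (r, c) is taken from `a` when
#' `floor(r/box) + floor(c/box)` is even (0-based), else from `b` — the
#' standard alternating-block QC rendering for judging vessel alignment
#' across box boundaries.
#'
#' @param a,b equal-shape matrices or 3-channel arrays.
#' @param box_px block edge length in pixels (>= 1).
#' @return raster of the common shape.
#' @export
make_checkerboard <- function(a, b, box_px) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch between the two images")
  stopifnot(box_px >= 1)
  nr <- dim(a)[1]; nc <- dim(a)[2]
  parity <- outer(floor((seq_len(nr) - 1) / box_px),
                  floor((seq_len(nc) - 1) / box_px), "+") %% 2
  from_a <- parity == 0
  out <- a
  if (length(dim(a)) == 3L) {
    for (ch in seq_len(dim(a)[3])) {
      pl <- out[, , ch]; pl[!from_a] <- b[, , ch][!from_a]; out[, , ch] <- pl
    }
  } else {
    out[!from_a] <- b[!from_a]
  }
  out
}
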