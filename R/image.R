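#' Calibrated RGB brightfield image
#'
#' Container for an 8-bit-per-channel RGB raster of a PSR-stained section,
#' together with its physical pixel size. All downstream filters, detectors
#' and region rules operate on this object; areas are converted to square
#' micrometres through `px_size_um^2`.
#'
#' @param pixels numeric H x W x 3 array with values in `[0, 255]`
#'   (channel order R, G, B).
#' @param px_size_um physical edge length of one pixel in micrometres (> 0).
#' @param sample_id character identifier carried into all result tables.
#'
#' @return An object of class `psr_image`: a list with elements `pixels`,
#'   `px_size_um` and `sample_id`.
#' @export
psr_image <- function(pixels, px_size_um, sample_id = "sample") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one pixel")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("pixel values must be finite")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255] (8-bit per channel)")
  if (!is.numeric(px_size_um) || length(px_size_um) != 1L || !is.finite(px_size_um) ||
      px_size_um <= 0)
    stop("`px_size_um` must be a single positive number")
  structure(
    list(pixels = pixels, px_size_um = as.numeric(px_size_um),
         sample_id = as.character(sample_id)),
    class = "psr_image"
  )
}

#' @export
print.psr_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("psr_image '%s': %d x %d px, %.4g um/px (%.3g x %.3g mm)\n",
              x$sample_id, d[1], d[2], x$px_size_um,
              d[1] * x$px_size_um / 1000, d[2] * x$px_size_um / 1000))
  invisible(x)
}

#' @export
dim.psr_image <- function(x) dim(x$pixels)[1:2]

is_psr_image <- function(x) inherits(x, "psr_image")

assert_image <- function(img) {
  if (!is_psr_image(img)) stop("expected a `psr_image` object")
  invisible(img)
}

# channel accessors (H x W matrices, dims preserved for 1-px-high images)
channel_of <- function(img, i) {
  m <- img$pixels[, , i, drop = FALSE]
  dim(m) <- dim(img$pixels)[1:2]
  m
}
channel_r <- function(img) channel_of(img, 1L)
channel_g <- function(img) channel_of(img, 2L)
channel_b <- function(img) channel_of(img, 3L)

#' Read an RGB section image from PNG or TIFF
#'
#' The pixel-size calibration is not stored in plain PNG rasters, so it must
#' be supplied by the caller (typically from the run configuration).
#'
#' @param path path to an 8-bit RGB PNG or TIFF file.
#' @param px_size_um pixel edge length in micrometres.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return A [psr_image].
#' @export
read_psr_image <- function(path, px_size_um, sample_id = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (use PNG or TIFF)")
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  psr_image(raw * 255, px_size_um = px_size_um, sample_id = sample_id)
}

#' Write an RGB image, grayscale evidence raster or binary mask to PNG
#'
#' Scalar evidence images are rounded half-up to 8-bit; masks are written as
#' 0/255 grayscale. Used for QC overlays and mask export.
#'
#' @param x a [psr_image], a numeric matrix in `[0, 255]`, or a logical mask.
#' @param path output file path (PNG).
#' @return `path`, invisibly.
#' @export
write_psr_raster <- function(x, path) {
  if (is_psr_image(x)) {
    arr <- x$pixels / 255
  } else if (is.logical(x)) {
    arr <- matrix(as.numeric(x), nrow(x), ncol(x))
  } else if (is.matrix(x)) {
    arr <- floor(pmin(pmax(x, 0), 255) + 0.5) / 255  # round half-up at export
  } else stop("cannot export object of class ", paste(class(x), collapse = "/"))
  png::writePNG(arr, target = path)
  invisible(path)
}

# clip a numeric object into [lo, hi]
clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# matrix <-> EBImage round-trips: EBImage ops are symmetric in x/y so plain
# row/column matrices can be passed straight through; imageData() strips the
# Image class on the way back.
as_ebi <- function(m) EBImage::Image(m)
from_ebi <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2L) m <- m[, , 1L]
  m
}

# odd-sized structuring elements (package-wide: diamond = 4-connectivity)
brush_disc <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
brush_diamond <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "diamond")

# 4-connected labelling of a logical matrix; returns integer matrix (0 = bg)
label_components <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- from_ebi(EBImage::bwlabel(as_ebi(mask)))
  storage.mode(lab) <- "integer"
  lab
}

# drop connected components with fewer than min_px pixels
remove_small_components <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}
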