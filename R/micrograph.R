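#' Calibrated grayscale micrograph
#'
#' A `micrograph` is an 8-bit grayscale image (integer matrix, values 0-255,
#' row-major with the origin at the top-left) together with its microscope
#' calibration in micrometres per pixel and a sample identifier.
#'
#' @param pixels integer or numeric matrix of intensities in \[0, 255\];
#'   at least 32 x 32 pixels.
#' @param microns_per_pixel positive calibration (um/px).
#' @param sample_id character scalar identifying the sample.
#' @return An object of class `micrograph`: a list with elements `pixels`
#'   (integer matrix), `microns_per_pixel` and `sample_id`.
#' @export
micrograph <- function(pixels, microns_per_pixel, sample_id = "sample") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 32L || ncol(pixels) < 32L)
    stop("micrograph must be at least 32x32 pixels, got ",
         nrow(pixels), "x", ncol(pixels))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must be finite and in [0, 255]")
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("`microns_per_pixel` must be a single positive number")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels,
         microns_per_pixel = as.numeric(microns_per_pixel),
         sample_id = as.character(sample_id)),
    class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph '%s': %d x %d px, %.4g um/px>\n",
              x$sample_id, nrow(x$pixels), ncol(x$pixels),
              x$microns_per_pixel))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

# PNG bit depth from the IHDR chunk (byte 25 of the file).
png_bit_depth <- function(path) {
  hdr <- readBin(path, what = "raw", n = 26L)
  if (length(hdr) < 26L) stop("not a valid PNG file: ", path)
  as.integer(hdr[25L])
}

# Collapse an array read by png/tiff to a single grayscale channel in [0, 1].
# RGB is converted by ITU-R BT.601 luminance; an alpha channel is ignored.
to_gray <- function(arr, path) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (nch == 1L) return(arr[, , 1L])
    if (nch == 2L) return(arr[, , 1L])  # gray + alpha
    return(0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L])
  }
  stop("unsupported image layout in ", path)
}

#' Load a micrograph from a PNG or TIFF file
#'
#' Reads a grayscale (or RGB, converted by luminance) image and attaches the
#' microscope calibration. Inputs deeper than 8 bits are rescaled to 8 bits
#' by max-normalization: the brightest pixel maps to 255.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param microns_per_pixel positive calibration (um/px).
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return A [micrograph()].
#' @export
load_micrograph <- function(path, microns_per_pixel,
                            sample_id = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    depth <- png_bit_depth(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(arr, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
  } else {
    stop("unsupported image format '", ext, "' for ", path)
  }
  gray <- to_gray(arr, path)
  if (length(gray) == 0L) stop("zero-size image: ", path)
  if (depth > 8L) {
    raw_vals <- gray * (2^depth - 1)
    mx <- max(raw_vals)
    px <- if (mx > 0) round(raw_vals / mx * 255) else raw_vals
  } else {
    px <- round(gray * 255)
  }
  micrograph(px, microns_per_pixel, sample_id)
}

#' Write a micrograph as an 8-bit grayscale PNG
#'
#' @param m a [micrograph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(m, path) {
  stopifnot(inherits(m, "micrograph"))
  png::writePNG(m$pixels / 255, path)
  invisible(path)
}
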