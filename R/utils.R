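#' @importFrom stats rnorm runif rexp quantile sd median coef predict
#'   wilcox.test pchisq setNames complete.cases
#' @importFrom utils write.csv read.csv
NULL

# Rec. 601 luminance of an rows x cols x 3 array on the 0..255 scale.
luminance <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a per-stage substream seed from one top-level seed so stages can be
# re-run independently. Kept strictly below 2^31.
substream_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %% 2147483629
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Binary matrix helpers -------------------------------------------------

as_mask <- function(m) {
  if (inherits(m, "Image")) m <- EBImage::imageData(m)
  m <- as.matrix(m)
  storage.mode(m) <- "logical"
  m
}

mask_to_ebimage <- function(mask) EBImage::Image(mask * 1)

#' Read an RGB image tile
#'
#' Reads a PNG (or, when the \pkg{tiff} package is available, a TIFF) file
#' into an \code{ImageTile}: an 8-bit rows x cols x 3 array on the 0..255
#' scale plus a microns-per-pixel resolution tag.
#'
#' @param path file path to a PNG or TIFF image.
#' @param mpp microns per pixel of the raster; must be positive.
#' @return An object of class \code{ImageTile}: a list with elements
#'   \code{pixels} (rows x cols x 3 numeric array, 0..255) and \code{mpp}.
#' @export
read_tile <- function(path, mpp) {
  stopifnot_scalar_pos(mpp, "mpp")
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF tiles requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  image_tile(raw * 255, mpp)
}

#' Construct an ImageTile from a pixel array
#'
#' @param pixels rows x cols x 3 numeric array on the 0..255 scale, or a
#'   single-channel matrix (replicated across channels).
#' @param mpp microns per pixel; must be positive.
#' @return An \code{ImageTile} (see \code{\link{read_tile}}).
#' @export
image_tile <- function(pixels, mpp) {
  stopifnot_scalar_pos(mpp, "mpp")
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  structure(list(pixels = pixels, mpp = mpp), class = "ImageTile")
}

#' @export
print.ImageTile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageTile: %d x %d px at %.3g um/px (%.0f x %.0f um)\n",
              d[1], d[2], x$mpp, d[1] * x$mpp, d[2] * x$mpp))
  invisible(x)
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a 0/255 single-channel mask PNG
#'
#' @param path file path; pixels above half intensity are taken as foreground.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  raw > 0.5
}

#' Write an ImageTile as an 8-bit RGB PNG
#'
#' @param tile an \code{ImageTile}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tile <- function(tile, path) {
  png::writePNG(clamp(tile$pixels, 0, 255) / 255, path)
  invisible(path)
}
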