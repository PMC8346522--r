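# Fiber segments: connected dark-line pixels in stroma, each assigned the
# orientation of its equivalent second-moment ellipse.

#' Orientation of a pixel set
#'
#' Returns the angle between the horizontal (column) axis and the major axis
#' of the ellipse with the same second central moments as the pixel set,
#' measured counterclockwise in display convention (rows increase downward)
#' and mapped to \code{[0, 180)} degrees.
#'
#' @param coords two-column matrix of (row, col) pixel coordinates.
#' @return orientation in degrees, or \code{NA} when the pixel set is
#'   isotropic (equal moments) or has fewer than 2 pixels.
#' @export
segment_orientation <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 2)
  if (nrow(coords) < 2) return(NA_real_)
  x <- coords[, 2]
  y <- -coords[, 1]            # display-convention y axis points up
  mxx <- mean(x^2) - mean(x)^2
  myy <- mean(y^2) - mean(y)^2
  mxy <- mean(x * y) - mean(x) * mean(y)
  if ((mxx - myy)^2 + 4 * mxy^2 < 1e-18) return(NA_real_)
  theta <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  theta %% 180
}

#' Extract fiber segments from a BIF label map
#'
#' Intersects the dark-line pixels with the stroma mask, takes 8-connected
#' components, discards components below the minimum area (orientation is
#' ill-posed for tiny sets), and assigns each surviving component its
#' second-moment orientation. Components with an isotropic pixel set are
#' dropped.
#'
#' @param labels a \code{BifLabelMap} (see \code{\link{classify_bif}}).
#' @param stroma logical stroma mask, co-registered with \code{labels}.
#' @param min_segment_px minimum component area in pixels.
#' @param keep_pixels if \code{TRUE}, attach the per-segment pixel
#'   coordinates as the \code{"pixels"} attribute of the result.
#' @return data.frame with one row per fiber segment: \code{id},
#'   \code{centroid_row}, \code{centroid_col}, \code{area_px},
#'   \code{orientation_deg}.
#' @export
extract_fiber_segments <- function(labels, stroma, min_segment_px = 10,
                                   keep_pixels = FALSE) {
  stopifnot(inherits(labels, "BifLabelMap"),
            identical(dim(labels), dim(stroma)))
  dark <- (unclass(labels) == match("dark_line", BIF_CLASSES)) & stroma
  empty <- data.frame(id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0),
                      orientation_deg = numeric(0))
  if (!any(dark)) return(empty)
  comp <- EBImage::imageData(EBImage::bwlabel(mask_to_ebimage(dark)))
  idx <- which(comp > 0)
  lab <- as.integer(comp[idx])
  areas <- tabulate(lab)
  keep_lab <- which(areas >= min_segment_px)
  if (!length(keep_lab)) return(empty)
  rows <- ((idx - 1L) %% nrow(comp)) + 1L
  cols <- ((idx - 1L) %/% nrow(comp)) + 1L
  # second-moment sums per component in one pass (display-convention y up)
  x <- as.numeric(cols)
  y <- -as.numeric(rows)
  sums <- rowsum(cbind(1, x, y, x * x, y * y, x * y), lab)
  labs_present <- as.integer(rownames(sums))
  sel <- labs_present %in% keep_lab
  n_k <- sums[sel, 1]
  mx <- sums[sel, 2] / n_k
  my <- sums[sel, 3] / n_k
  mxx <- sums[sel, 4] / n_k - mx^2
  myy <- sums[sel, 5] / n_k - my^2
  mxy <- sums[sel, 6] / n_k - mx * my
  aniso <- (mxx - myy)^2 + 4 * mxy^2
  ok <- aniso >= 1e-18        # isotropic components: orientation undefined
  if (!any(ok)) return(empty)
  theta <- (0.5 * atan2(2 * mxy[ok], (mxx - myy)[ok]) * 180 / pi) %% 180
  segs <- data.frame(id = seq_len(sum(ok)),
                     centroid_row = -my[ok], centroid_col = mx[ok],
                     area_px = as.integer(n_k[ok]),
                     orientation_deg = theta)
  if (keep_pixels) {
    by_lab <- split(seq_along(lab), lab)
    kept <- labs_present[sel][ok]
    attr(segs, "pixels") <- lapply(by_lab[as.character(kept)],
                                   function(i) cbind(rows[i], cols[i]))
  }
  segs
}

#' Detect fibers in the tumor-associated stroma of a tile
#'
#' Convenience wrapper running the full detector: unit-normalized luminance,
#' Gaussian jet at one scale, BIF classification, and segment extraction
#' restricted to a stroma mask.
#'
#' @param tile an \code{ImageTile}.
#' @param stroma logical stroma mask (use \code{stroma & tumor} for
#'   tumor-associated stroma).
#' @param sigma_px detection scale in pixels.
#' @param epsilon BIF flatness gain.
#' @param min_segment_px minimum segment area.
#' @return data.frame of fiber segments (see
#'   \code{\link{extract_fiber_segments}}).
#' @export
detect_fibers <- function(tile, stroma, sigma_px = 2, epsilon = 0.05,
                          min_segment_px = 10) {
  stopifnot(inherits(tile, "ImageTile"))
  gray <- luminance(tile$pixels) / 255
  jet <- gaussian_jet(gray, sigma_px)
  labels <- classify_bif(jet, epsilon)
  extract_fiber_segments(labels, stroma, min_segment_px)
}
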