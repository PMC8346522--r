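# Tissue masks: epithelium/stroma separation, merged tumor mask, leading-edge
# band and the neighborhood grid.

#' Bundle co-registered tissue masks
#'
#' @param epithelium,stroma,tumor,leading_edge logical matrices of identical
#'   dimensions. Stroma and epithelium must be disjoint and the leading edge
#'   must lie inside the tumor.
#' @return An object of class \code{MaskSet}.
#' @export
mask_set <- function(epithelium, stroma, tumor, leading_edge) {
  dims <- dim(epithelium)
  for (m in list(stroma, tumor, leading_edge)) {
    if (!identical(dim(m), dims)) {
      stop("masks are not co-registered", call. = FALSE)
    }
  }
  if (any(stroma & epithelium)) {
    stop("stroma and epithelium masks overlap", call. = FALSE)
  }
  if (any(leading_edge & !tumor)) {
    stop("leading edge extends outside the tumor mask", call. = FALSE)
  }
  structure(list(epithelium = as_mask(epithelium), stroma = as_mask(stroma),
                 tumor = as_mask(tumor),
                 leading_edge = as_mask(leading_edge)),
            class = "MaskSet")
}

#' @export
print.MaskSet <- function(x, ...) {
  cat(sprintf(
    "MaskSet %d x %d px: epithelium %d, stroma %d, tumor %d, edge %d px\n",
    nrow(x$tumor), ncol(x$tumor), sum(x$epithelium), sum(x$stroma),
    sum(x$tumor), sum(x$leading_edge)))
  invisible(x)
}

#' Separate epithelium and stroma by stain deconvolution
#'
#' A heuristic stand-in for learned segmentation: per-pixel optical densities
#' are unmixed into hematoxylin and eosin contributions with the standard
#' H&E stain matrix; cell-dense, hematoxylin-dominant pixels become
#' epithelium, eosin-dominant fibrous pixels become stroma, and low-density
#' glass is excluded from both. Externally supplied masks bypass the
#' heuristic entirely and are returned unchanged.
#'
#' @param tile an \code{ImageTile}.
#' @param epithelium,stroma optional pre-computed logical masks; when both
#'   are given they are passed through untouched.
#' @param od_background total optical density below which a pixel is glass.
#' @param smooth_px median-filter radius (px) applied to the raw class maps;
#'   0 disables smoothing.
#' @return list with logical \code{epithelium} and \code{stroma} matrices.
#' @export
segment_stroma_epithelium <- function(tile, epithelium = NULL, stroma = NULL,
                                      od_background = 0.04, smooth_px = 2) {
  if (!is.null(epithelium) && !is.null(stroma)) {
    return(list(epithelium = as_mask(epithelium), stroma = as_mask(stroma)))
  }
  stopifnot(inherits(tile, "ImageTile"))
  od <- -log10(pmax(tile$pixels, 1) / 255)
  od_total <- od[, , 1] + od[, , 2] + od[, , 3]
  bg <- od_total < od_background
  if (all(bg)) {
    warning("tile appears to be all background; returning empty masks")
    z <- matrix(FALSE, dim(od)[1], dim(od)[2])
    return(list(epithelium = z, stroma = z))
  }
  resid <- c(STAIN_H[2] * STAIN_E[3] - STAIN_H[3] * STAIN_E[2],
             STAIN_H[3] * STAIN_E[1] - STAIN_H[1] * STAIN_E[3],
             STAIN_H[1] * STAIN_E[2] - STAIN_H[2] * STAIN_E[1])
  unmix <- solve(t(cbind(STAIN_H, STAIN_E, resid)))
  flat <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
                as.vector(od[, , 3]))
  conc <- flat %*% unmix
  d <- dim(bg)
  c_h <- matrix(conc[, 1], d[1], d[2])
  c_e <- matrix(conc[, 2], d[1], d[2])
  epi <- !bg & (c_h > c_e)
  str <- !bg & !epi
  if (smooth_px > 0) {
    epi <- EBImage::medianFilter(mask_to_ebimage(epi), smooth_px) > 0.5
    str <- EBImage::medianFilter(mask_to_ebimage(str), smooth_px) > 0.5
    str <- str & !epi
  }
  list(epithelium = as_mask(epi), stroma = as_mask(str))
}

#' Merge epithelium patches into a tumor mask
#'
#' Dilates the epithelium mask by a physical radius and fills enclosed holes,
#' merging individual epithelial patches into one tumor region. The result
#' always contains the epithelium.
#'
#' @param epithelium logical epithelium mask.
#' @param mpp microns per pixel.
#' @param dilation_um disk dilation radius in microns.
#' @param min_hole_um2 holes smaller than this area are filled;
#'   \code{Inf} (default) fills every enclosed hole.
#' @return logical tumor mask.
#' @export
build_tumor_mask <- function(epithelium, mpp, dilation_um = 50,
                             min_hole_um2 = Inf) {
  stopifnot_scalar_pos(mpp, "mpp")
  if (!any(epithelium)) {
    warning("empty epithelium mask; tumor mask is empty")
    return(as_mask(epithelium))
  }
  r_px <- round(dilation_um / mpp)
  tumor <- epithelium
  if (r_px > 0) {
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    tumor <- EBImage::dilate(mask_to_ebimage(epithelium), brush) > 0.5
  }
  if (is.infinite(min_hole_um2)) {
    tumor <- EBImage::fillHull(mask_to_ebimage(tumor)) > 0.5
  } else if (min_hole_um2 > 0) {
    holes <- EBImage::bwlabel(mask_to_ebimage(!tumor))
    holes <- imageData(holes)
    border_labels <- unique(c(holes[1, ], holes[nrow(holes), ],
                              holes[, 1], holes[, ncol(holes)]))
    tab <- tabulate(holes)
    max_px <- min_hole_um2 / mpp^2
    fill <- which(tab < max_px)
    fill <- setdiff(fill, border_labels)
    tumor[holes %in% fill] <- TRUE
  }
  as_mask(tumor)
}

imageData <- EBImage::imageData

#' Leading-edge band of a tumor mask
#'
#' The set of tumor pixels within a physical distance of the tumor boundary,
#' computed from the Euclidean distance transform of the tumor interior.
#'
#' @param tumor logical tumor mask.
#' @param band_um band width in microns (> 0); default 500.
#' @param mpp microns per pixel.
#' @return logical band mask, a subset of \code{tumor}.
#' @export
leading_edge_band <- function(tumor, band_um = 500, mpp = 0.5) {
  stopifnot_scalar_pos(mpp, "mpp")
  if (band_um <= 0) stop("'band_um' must be positive", call. = FALSE)
  if (!any(tumor)) return(as_mask(tumor))
  d <- EBImage::distmap(mask_to_ebimage(tumor))
  as_mask(tumor & (imageData(d) <= band_um / mpp))
}

#' Partition the tumor into a grid of square neighborhoods
#'
#' Lays a non-overlapping axis-aligned grid of square cells of physical side
#' \code{fov_um}, anchored at the origin of the tumor bounding box. A cell is
#' kept if it intersects the tumor mask (\code{restrict_to = "whole"}) or if
#' its center lies in the leading-edge band (\code{restrict_to = "edge"}).
#' The stroma ratio of a cell is the tumor-associated stromal area over the
#' cell area, both restricted to the image.
#'
#' @param tumor logical tumor mask.
#' @param stroma logical stroma mask (tumor-associated stroma is
#'   \code{stroma & tumor}).
#' @param fov_um cell side length in microns (> 0).
#' @param mpp microns per pixel.
#' @param restrict_to \code{"whole"} or \code{"edge"}.
#' @param leading_edge band mask, required for \code{restrict_to = "edge"}.
#' @param sat_cache optional output of \code{\link{grid_area_tables}} for
#'   these masks, reused across fields of view.
#' @return data.frame with one row per kept cell: \code{cell_id},
#'   \code{row0}, \code{col0} (top-left pixel), \code{side_px},
#'   \code{center_row}, \code{center_col}, \code{stroma_ratio},
#'   \code{is_edge}.
#' @export
tile_grid <- function(tumor, stroma, fov_um, mpp,
                      restrict_to = c("whole", "edge"),
                      leading_edge = NULL, sat_cache = NULL) {
  restrict_to <- match.arg(restrict_to)
  stopifnot_scalar_pos(fov_um, "fov_um")
  stopifnot_scalar_pos(mpp, "mpp")
  empty <- data.frame(cell_id = integer(0), row0 = integer(0),
                      col0 = integer(0), side_px = integer(0),
                      center_row = numeric(0), center_col = numeric(0),
                      stroma_ratio = numeric(0), is_edge = logical(0))
  if (!any(tumor)) return(empty)
  if (restrict_to == "edge" && is.null(leading_edge)) {
    stop("'leading_edge' mask required when restrict_to = \"edge\"",
         call. = FALSE)
  }
  nr <- nrow(tumor); nc <- ncol(tumor)
  side <- round(fov_um / mpp)
  if (side > nr && side > nc) {
    warning("field of view larger than the image; using a single cell")
  }
  rows_t <- range(which(rowSums(tumor) > 0))
  cols_t <- range(which(colSums(tumor) > 0))
  r_starts <- seq(rows_t[1], rows_t[2], by = side)
  c_starts <- seq(cols_t[1], cols_t[2], by = side)

  rect_sum <- function(s, r0, r1, c0, c1) {
    s[cbind(r1 + 1L, c1 + 1L)] - s[cbind(r0, c1 + 1L)] -
      s[cbind(r1 + 1L, c0)] + s[cbind(r0, c0)]
  }
  if (is.null(sat_cache)) sat_cache <- grid_area_tables(tumor, stroma)
  s_tumor <- sat_cache$tumor
  s_tas <- sat_cache$tas

  cells <- expand.grid(row0 = r_starts, col0 = c_starts,
                       KEEP.OUT.ATTRS = FALSE)
  r0 <- cells$row0
  c0 <- cells$col0
  r1 <- pmin(r0 + side - 1L, nr)
  c1 <- pmin(c0 + side - 1L, nc)
  tumor_px <- rect_sum(s_tumor, r0, r1, c0, c1)
  stroma_px <- rect_sum(s_tas, r0, r1, c0, c1)
  ctr_r <- r0 + (side - 1) / 2
  ctr_c <- c0 + (side - 1) / 2
  in_edge <- rep(FALSE, nrow(cells))
  if (!is.null(leading_edge)) {
    ri <- round(ctr_r); ci <- round(ctr_c)
    inb <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    in_edge[inb] <- leading_edge[cbind(ri[inb], ci[inb])]
  }
  keep <- tumor_px > 0
  if (restrict_to == "edge") keep <- keep & in_edge
  if (!any(keep)) return(empty)
  grid <- data.frame(cell_id = seq_len(sum(keep)),
                     row0 = r0[keep], col0 = c0[keep], side_px = side,
                     center_row = ctr_r[keep], center_col = ctr_c[keep],
                     stroma_ratio = stroma_px[keep] /
                       ((r1 - r0 + 1) * (c1 - c0 + 1))[keep],
                     is_edge = in_edge[keep])
  attr(grid, "fov_um") <- fov_um
  attr(grid, "mpp") <- mpp
  grid
}

#' Summed-area tables for the neighborhood grid
#'
#' Precomputes the integral images of the tumor mask and of the
#' tumor-associated stroma, so that \code{\link{tile_grid}} can count cell
#' areas in constant time per cell. Compute once per tile and pass to every
#' field of view.
#'
#' @param tumor,stroma logical masks.
#' @return list with components \code{tumor} and \code{tas} (padded
#'   integral images).
#' @export
grid_area_tables <- function(tumor, stroma) {
  sat <- function(m) {
    cs <- apply(m, 2L, cumsum)             # cumulative down each column
    for (j in 2:ncol(cs)) cs[, j] <- cs[, j] + cs[, j - 1L]
    s <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
    s[-1, -1] <- cs
    s
  }
  list(tumor = sat(tumor), tas = sat(stroma & tumor))
}
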