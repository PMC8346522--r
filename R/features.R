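# CFOD-TS: entropy of the orientation co-occurrence matrix per tumor
# neighborhood, aggregated to the 18-feature patient vector
# (9 fields of view x {leading edge, whole tumor}).

N_BINS <- 18L

#' Discretize an orientation into one of 18 angular bins
#'
#' Bins are half-open 10-degree intervals \code{[10k, 10k+10)} for
#' \code{k = 0..17}; 180 wraps to bin 0. Inputs outside \code{[0, 180)} are
#' normalized modulo 180.
#'
#' @param theta_deg numeric vector of orientations in degrees.
#' @return integer vector of bin indices in \code{0..17}.
#' @export
bin_orientation <- function(theta_deg) {
  as.integer(floor((theta_deg %% 180) / 10) %% N_BINS)
}

#' Orientation co-occurrence matrix of a neighborhood
#'
#' Counts every ordered pair of distinct fibers in the neighborhood: a pair
#' with bins (a, b) increments both \code{C[a, b]} and \code{C[b, a]}
#' (same-bin pairs increment the diagonal twice), so the matrix is symmetric
#' and \code{sum(C) = n (n - 1)} for n fibers. With fewer than 2 fibers the
#' matrix is all zero and flagged degenerate.
#'
#' @param bins integer vector of per-fiber bin indices (0..17).
#' @return An \code{OrientationCoMatrix}: an 18 x 18 count matrix with a
#'   logical \code{"degenerate"} attribute.
#' @export
orientation_cooccurrence <- function(bins) {
  stopifnot(all(bins >= 0 & bins < N_BINS))
  cnt <- tabulate(bins + 1L, nbins = N_BINS)
  C <- outer(cnt, cnt)
  diag(C) <- cnt * (cnt - 1L)
  storage.mode(C) <- "integer"
  dimnames(C) <- list(0:(N_BINS - 1L), 0:(N_BINS - 1L))
  structure(C, degenerate = length(bins) < 2L, class = "OrientationCoMatrix")
}

#' CFOD-TS entropy of a co-occurrence matrix
#'
#' Shannon entropy (base 2, bits) of the normalized co-occurrence matrix
#' \code{P = C / sum(C)}, with \code{0 log 0 := 0}. Degenerate (all-zero)
#' matrices have no defined disorder and return \code{NA}.
#'
#' @param C an \code{OrientationCoMatrix} (or any nonnegative matrix).
#' @return entropy in bits (\code{>= 0}), or \code{NA} for a degenerate
#'   matrix.
#' @export
cfod_entropy <- function(C) {
  total <- sum(C)
  if (total <= 0) return(NA_real_)
  p <- as.numeric(C) / total
  p <- sort(p[p > 0])   # fixed summation order: exact under bin permutation
  -sum(p * log2(p))
}

#' Neighborhood validity filter
#'
#' A neighborhood is kept only when it contains enough fiber-enriched stroma
#' for the disorder measurement to be meaningful: its stroma ratio and its
#' detected fiber count must both reach their thresholds (inclusive).
#'
#' @param stroma_ratio stromal area over neighborhood area, in
#'   \code{[0, 1]}.
#' @param n_fibers number of detected fiber orientations in the
#'   neighborhood.
#' @param min_stroma_ratio,min_fibers thresholds (defaults 0.2 and 10).
#' @return logical.
#' @export
neighborhood_is_valid <- function(stroma_ratio, n_fibers,
                                  min_stroma_ratio = 0.2, min_fibers = 10) {
  stroma_ratio >= min_stroma_ratio & n_fibers >= min_fibers
}

# Assign detected segments to grid cells by centroid; returns the grid with
# per-cell entropy, fiber count and validity.
cells_from_segments <- function(grid, segments, min_stroma_ratio,
                                min_fibers) {
  n <- nrow(grid)
  value <- rep(NA_real_, n)
  nfib <- integer(n)
  if (n == 0) return(cbind(grid, cfod_ts = value, n_fibers = nfib,
                           valid = logical(0)))
  if (nrow(segments) > 0) {
    # grid cells are anchored at the bounding-box origin, so the cell of a
    # centroid follows from integer division by the cell side
    side <- grid$side_px[1]
    r_org <- min(grid$row0)
    c_org <- min(grid$col0)
    gr <- r_org + floor((segments$centroid_row - r_org) / side) * side
    gc <- c_org + floor((segments$centroid_col - c_org) / side) * side
    cell_of <- match(paste(gr, gc), paste(grid$row0, grid$col0))
    th_by <- split(segments$orientation_deg, cell_of)
    for (nm in names(th_by)) {
      i <- as.integer(nm)
      th <- th_by[[nm]]
      nfib[i] <- length(th)
      if (length(th) >= 2) {
        value[i] <- cfod_entropy(orientation_cooccurrence(bin_orientation(th)))
      }
    }
  }
  valid <- neighborhood_is_valid(grid$stroma_ratio, nfib,
                                 min_stroma_ratio, min_fibers) &
    !is.na(value)
  data.frame(grid, cfod_ts = value, n_fibers = nfib, valid = valid)
}

#' Per-neighborhood CFOD-TS feature map at one field of view
#'
#' Runs the fiber detector once over the tile, partitions the tumor into a
#' grid of square neighborhoods at the requested field of view, assigns each
#' detected fiber to the neighborhood containing its centroid, and computes
#' the co-occurrence entropy per valid neighborhood.
#'
#' @param tile an \code{ImageTile}.
#' @param masks a \code{MaskSet}.
#' @param fov_um neighborhood side length in microns.
#' @param params parameter list, see \code{\link{cfod_params}}.
#' @param segments optional pre-computed segment table (from
#'   \code{\link{detect_fibers}} on \code{stroma & tumor}); detection is
#'   re-run when omitted.
#' @param sat_cache optional \code{\link{grid_area_tables}} result for these
#'   masks, reused across fields of view.
#' @return data.frame: the neighborhood grid plus \code{cfod_ts} (bits),
#'   \code{n_fibers} and \code{valid} columns.
#' @export
neighborhood_feature_map <- function(tile, masks, fov_um,
                                     params = cfod_params(),
                                     segments = NULL, sat_cache = NULL) {
  stopifnot(inherits(masks, "MaskSet"))
  if (is.null(segments)) {
    segments <- detect_fibers(tile, masks$stroma & masks$tumor,
                              sigma_px = params$sigma_px,
                              epsilon = params$epsilon,
                              min_segment_px = params$min_segment_px)
  }
  grid <- tile_grid(masks$tumor, masks$stroma, fov_um, tile$mpp,
                    restrict_to = "whole",
                    leading_edge = masks$leading_edge,
                    sat_cache = sat_cache)
  out <- cells_from_segments(grid, segments, params$min_stroma_ratio,
                             params$min_fibers)
  if (nrow(out) == 0 || !any(out$valid)) {
    warning(sprintf("no valid neighborhood at FOV %g um", fov_um))
  }
  out
}

#' Default extraction parameters
#'
#' @param sigma_px detection scale of the Gaussian jet, pixels.
#' @param epsilon BIF flatness gain on unit-normalized luminance.
#' @param min_segment_px minimum fiber-segment area, pixels.
#' @param min_stroma_ratio,min_fibers neighborhood validity thresholds.
#' @param fov_list fields of view in microns.
#' @param band_um leading-edge band width in microns.
#' @return named list of parameters.
#' @export
cfod_params <- function(sigma_px = 2, epsilon = 0.05, min_segment_px = 10,
                        min_stroma_ratio = 0.2, min_fibers = 10,
                        fov_list = seq(50, 250, by = 25), band_um = 500) {
  list(sigma_px = sigma_px, epsilon = epsilon,
       min_segment_px = min_segment_px,
       min_stroma_ratio = min_stroma_ratio, min_fibers = min_fibers,
       fov_list = fov_list, band_um = band_um)
}

#' 18-feature CFOD-TS patient vector
#'
#' For each field of view, the whole-tumor feature is the unweighted mean of
#' CFOD-TS over all valid neighborhoods in the tumor and the leading-edge
#' feature is the mean over the valid neighborhoods whose centers lie in the
#' leading-edge band. Multiple tiles of one patient pool their neighborhoods
#' before averaging. A slot with no valid neighborhood is missing-coded
#' (\code{NA}).
#'
#' @param tiles an \code{ImageTile} or list of tiles for one patient.
#' @param masks a \code{MaskSet} or list of mask sets, one per tile.
#' @param params parameter list, see \code{\link{cfod_params}}.
#' @return An object of class \code{PatientFeatureVector}: named numeric
#'   vector of 18 features with an \code{"n_cells"} attribute giving the
#'   count of contributing neighborhoods per slot.
#' @export
patient_feature_vector <- function(tiles, masks, params = cfod_params()) {
  if (inherits(tiles, "ImageTile")) tiles <- list(tiles)
  if (inherits(masks, "MaskSet")) masks <- list(masks)
  stopifnot(length(tiles) == length(masks))
  fovs <- params$fov_list
  nms <- cfod_feature_names(fovs)
  acc <- setNames(vector("list", length(nms)), nms)

  for (t in seq_along(tiles)) {
    segs <- detect_fibers(tiles[[t]], masks[[t]]$stroma & masks[[t]]$tumor,
                          sigma_px = params$sigma_px,
                          epsilon = params$epsilon,
                          min_segment_px = params$min_segment_px)
    sats <- grid_area_tables(masks[[t]]$tumor, masks[[t]]$stroma)
    for (fov in fovs) {
      cells <- suppressWarnings(
        neighborhood_feature_map(tiles[[t]], masks[[t]], fov, params,
                                 segments = segs, sat_cache = sats))
      v <- cells$cfod_ts[cells$valid]
      e <- cells$cfod_ts[cells$valid & cells$is_edge]
      acc[[paste0("CFOD_whole_", fov)]] <-
        c(acc[[paste0("CFOD_whole_", fov)]], v)
      acc[[paste0("CFOD_edge_", fov)]] <-
        c(acc[[paste0("CFOD_edge_", fov)]], e)
    }
  }
  out <- vapply(acc, function(v) if (length(v)) mean(v) else NA_real_, 0)
  n_cells <- vapply(acc, length, 0L)
  if (any(n_cells == 0)) {
    warning("feature slots with no valid neighborhood are missing-coded: ",
            paste(nms[n_cells == 0], collapse = ", "))
  }
  structure(out, n_cells = n_cells, class = "PatientFeatureVector")
}

#' @export
print.PatientFeatureVector <- function(x, ...) {
  cat("PatientFeatureVector (CFOD-TS, bits):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Render a CFOD-TS feature map as a warm-colormap heatmap PNG
#'
#' @param cells output of \code{\link{neighborhood_feature_map}}.
#' @param dims image dimensions (rows, cols) of the source tile.
#' @param path output PNG path.
#' @return \code{path}, invisibly; a JSON sidecar of the cell values is
#'   written next to it.
#' @export
write_feature_heatmap <- function(cells, dims, path) {
  img <- array(1, c(dims, 3L))
  vals <- cells$cfod_ts
  rng <- range(vals[cells$valid], na.rm = TRUE)
  pal <- grDevices::colorRamp(c("#fff5c0", "#fd9a44", "#b30000"))
  for (i in seq_len(nrow(cells))) {
    if (!cells$valid[i]) next
    f <- if (diff(rng) > 0) (vals[i] - rng[1]) / diff(rng) else 0.5
    rgbv <- pal(f) / 255
    r <- cells$row0[i]:min(cells$row0[i] + cells$side_px[i] - 1, dims[1])
    cc <- cells$col0[i]:min(cells$col0[i] + cells$side_px[i] - 1, dims[2])
    for (ch in 1:3) img[r, cc, ch] <- rgbv[ch]
  }
  png::writePNG(img, path)
  jsonlite::write_json(cells, sub("\\.png$", ".json", path),
                       dataframe = "rows", na = "null")
  invisible(path)
}
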