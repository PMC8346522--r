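# Synthetic fibrous-stroma phantoms with known orientation statistics.
#
# Orientations are axial (period 180 degrees): fibers are undirected, so a
# fiber at 10 degrees is the same structure as one at 190. Sampling therefore
# uses a von Mises distribution on the doubled-angle circle and halves the
# draw, the standard treatment for axial data.

# Ruifrok-Johnston optical-density unit vectors for hematoxylin and eosin.
STAIN_H <- c(0.650, 0.704, 0.286)
STAIN_E <- c(0.072, 0.990, 0.105)

# von Mises sampler (Best & Fisher rejection); mu in radians, kappa >= 0.
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}

#' Sample axial fiber orientations
#'
#' Draws undirected orientations in degrees on \code{[0, 180)} from an axial
#' von Mises model: a von Mises draw on the doubled-angle circle, halved.
#' \code{kappa = 0} gives the uniform axial distribution.
#'
#' @param n number of orientations.
#' @param mean_deg mean orientation in degrees, \code{[0, 180)}.
#' @param kappa von Mises concentration on the doubled-angle circle
#'   (\code{>= 0}); larger values give more aligned fibers.
#' @return numeric vector of orientations in degrees, \code{[0, 180)}.
#' @export
sample_axial_orientations <- function(n, mean_deg, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(rep(mean_deg %% 180, n))
  phi <- rvonmises(n, 2 * mean_deg * pi / 180, kappa)
  (phi * 180 / pi / 2) %% 180
}

#' Specify a fibrous-stroma phantom
#'
#' Collects the physical and photometric parameters of a synthetic stroma
#' tile. Fibers are rendered as anti-aliased dark eosin-stained line segments
#' on a lighter eosin background; optional epithelium blobs are rendered in
#' hematoxylin. Intensities are green-channel targets on the 0..255 scale and
#' the fiber intensity must be darker than the background.
#'
#' @param width_um,height_um physical tile size in microns.
#' @param mpp microns per pixel (> 0).
#' @param n_fibers number of fibers to render.
#' @param mean_orientation_deg mean fiber orientation, degrees \code{[0,180)}.
#' @param kappa axial von Mises concentration (0 = uniform orientations).
#' @param fiber_width_um fiber width in microns.
#' @param fiber_length_um length-2 range; lengths drawn uniformly from it.
#' @param background_intensity,fiber_intensity 0..255 green-channel targets;
#'   fibers must be darker than background.
#' @param epithelium_blobs list of \code{list(center_um = c(row, col),
#'   radius_um = r)} disks rendered as epithelium.
#' @param noise_sd additive Gaussian pixel noise sd on the 0..255 scale.
#' @param seed integer seed; fixing it fixes every output bit-for-bit.
#' @return An object of class \code{FiberPhantomSpec}.
#' @export
fiber_phantom_spec <- function(width_um = 250, height_um = 250, mpp = 0.5,
                               n_fibers = 150, mean_orientation_deg = 45,
                               kappa = 0, fiber_width_um = 1,
                               fiber_length_um = c(10, 30),
                               background_intensity = 220,
                               fiber_intensity = 110,
                               epithelium_blobs = list(),
                               noise_sd = 5, seed = 1L) {
  stopifnot_scalar_pos(width_um, "width_um")
  stopifnot_scalar_pos(height_um, "height_um")
  stopifnot_scalar_pos(mpp, "mpp")
  stopifnot_scalar_pos(fiber_width_um, "fiber_width_um")
  stopifnot(n_fibers >= 0, kappa >= 0,
            mean_orientation_deg >= 0, mean_orientation_deg < 180,
            length(fiber_length_um) == 2L, all(fiber_length_um > 0),
            fiber_intensity < background_intensity,
            background_intensity <= 255, fiber_intensity >= 0,
            noise_sd >= 0)
  structure(list(width_um = width_um, height_um = height_um, mpp = mpp,
                 n_fibers = n_fibers,
                 mean_orientation_deg = mean_orientation_deg, kappa = kappa,
                 fiber_width_um = fiber_width_um,
                 fiber_length_um = sort(fiber_length_um),
                 background_intensity = background_intensity,
                 fiber_intensity = fiber_intensity,
                 epithelium_blobs = epithelium_blobs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "FiberPhantomSpec")
}

# Green-channel intensity target -> stain absorbance coefficient.
intensity_to_absorbance <- function(intensity, stain_g) {
  -log10(pmax(intensity, 1) / 255) / stain_g
}

# Anti-aliased coverage patch of one line segment. Center (r0, c0) px,
# orientation theta degrees (axial, display convention: measured
# counterclockwise from the horizontal axis with rows increasing downward),
# half-length and half-width in px. Returns the bounding-box row/col ranges
# and the local coverage matrix; the caller max-composites it into the full
# coverage raster in place (the raster can be large, so it never crosses a
# function boundary).
segment_patch <- function(dims, r0, c0, theta_deg, half_len, half_w) {
  dx <- cos(theta_deg * pi / 180)
  dy <- -sin(theta_deg * pi / 180)  # row axis points down
  pad <- half_len + half_w + 1
  rr <- max(1L, floor(r0 - pad)):min(dims[1], ceiling(r0 + pad))
  cc <- max(1L, floor(c0 - pad)):min(dims[2], ceiling(c0 + pad))
  dr <- rr - r0
  dc <- cc - c0
  # coordinates along (t) and across (s) the segment for the bbox grid
  t_mat <- outer(dr * dy, dc * dx, "+")
  s_mat <- outer(dr * dx, -dc * dy, "+")
  over <- pmax(abs(t_mat) - half_len, 0)
  d <- sqrt(over^2 + s_mat^2)
  list(rr = rr, cc = cc, cov = clamp(half_w + 0.5 - d, 0, 1))
}

render_disk <- function(mask_dims, center_px, radius_px) {
  dr <- seq_len(mask_dims[1]) - center_px[1]
  dc <- seq_len(mask_dims[2]) - center_px[2]
  outer(dr^2, dc^2, "+") <= radius_px^2
}

# Compose eosin/hematoxylin absorbance maps into an 8-bit RGB array.
stains_to_rgb <- function(a_e, a_h) {
  d <- dim(a_e)
  out <- array(0, c(d, 3L))
  for (ch in 1:3) {
    out[, , ch] <- 255 * 10^(-(a_e * STAIN_E[ch] + a_h * STAIN_H[ch]))
  }
  out
}

#' Render a fibrous-stroma phantom tile
#'
#' Renders the fibers described by a \code{\link{fiber_phantom_spec}} as
#' anti-aliased dark line segments with additive Gaussian noise, and returns
#' both the H&E-style RGB tile and the ground truth (exact sampled
#' orientations, stroma and epithelium masks).
#'
#' @param spec a \code{FiberPhantomSpec}.
#' @return list with elements \code{tile} (an \code{ImageTile}) and
#'   \code{truth} (class \code{PhantomTruth}: \code{orientations_deg},
#'   \code{stroma}, \code{epithelium}, \code{kappa}, fiber centers in px).
#' @export
generate_fiber_tile <- function(spec) {
  stopifnot(inherits(spec, "FiberPhantomSpec"))
  set.seed(substream_seed(spec$seed, 1L))
  nr <- round(spec$height_um / spec$mpp)
  nc <- round(spec$width_um / spec$mpp)
  if (nr < 1 || nc < 1) stop("tile smaller than one pixel", call. = FALSE)

  epi <- matrix(FALSE, nr, nc)
  for (b in spec$epithelium_blobs) {
    epi <- epi | render_disk(c(nr, nc), b$center_um / spec$mpp,
                             b$radius_um / spec$mpp)
  }

  n <- spec$n_fibers
  theta <- sample_axial_orientations(n, spec$mean_orientation_deg, spec$kappa)
  centers <- matrix(NA_real_, n, 2L)
  cov <- matrix(0, nr, nc)
  half_w <- spec$fiber_width_um / 2 / spec$mpp
  if (n > 0) {
    for (i in seq_len(n)) {
      # rejection-sample a center outside epithelium blobs
      repeat {
        r0 <- runif(1, 1, nr); c0 <- runif(1, 1, nc)
        if (!epi[round(r0), round(c0)]) break
      }
      len <- runif(1, spec$fiber_length_um[1], spec$fiber_length_um[2])
      p <- segment_patch(c(nr, nc), r0, c0, theta[i],
                         half_len = len / 2 / spec$mpp, half_w = half_w)
      cov[p$rr, p$cc] <- pmax(cov[p$rr, p$cc], p$cov)
      centers[i, ] <- c(r0, c0)
    }
  }

  a_bg <- intensity_to_absorbance(spec$background_intensity, STAIN_E[2])
  a_fib <- intensity_to_absorbance(spec$fiber_intensity, STAIN_E[2])
  a_e <- a_bg + (a_fib - a_bg) * cov
  a_h <- matrix(0, nr, nc)
  a_h[epi] <- intensity_to_absorbance(120, STAIN_H[2])
  a_e[epi] <- a_e[epi] * 0.15   # epithelium displaces the fibrous matrix

  rgb <- stains_to_rgb(a_e, a_h)
  if (spec$noise_sd > 0) {
    rgb <- rgb + array(rnorm(length(rgb), 0, spec$noise_sd), dim(rgb))
  }
  tile <- image_tile(clamp(rgb, 0, 255), spec$mpp)
  truth <- structure(list(orientations_deg = theta,
                          centers_px = centers,
                          stroma = !epi, epithelium = epi,
                          kappa = spec$kappa),
                     class = "PhantomTruth")
  list(tile = tile, truth = truth)
}

#' Render a whole-tumor phantom with distinct edge and core alignment
#'
#' Builds a disk-shaped tumor with scattered epithelium blobs and fibrous
#' stroma, drawing fiber orientations with concentration \code{edge_kappa}
#' inside the peripheral leading-edge band and \code{core_kappa} elsewhere.
#' Used to emulate the contrast between an aligned invasion front and a
#' disordered tumor core.
#'
#' @param core_kappa,edge_kappa axial von Mises concentrations for fibers in
#'   the tumor core and in the leading-edge band.
#' @param tumor_geometry list with \code{center_um} (row, col) and
#'   \code{radius_um}; must have positive area and fit in the tile.
#' @param seed integer seed.
#' @param tile_um tile side length in microns (square tile).
#' @param mpp microns per pixel.
#' @param band_um leading-edge band width in microns (default 500).
#' @param fiber_density_per_um2 expected fibers per square micron of
#'   tumor-associated stroma.
#' @param mean_orientation_deg shared mean orientation for both regions.
#' @param n_epithelium_blobs number of epithelial disks scattered in the core.
#' @param noise_sd additive Gaussian noise sd (0..255 scale).
#' @return list with \code{tile} (\code{ImageTile}), \code{masks} (class
#'   \code{MaskSet}: epithelium, stroma, tumor, leading_edge) and
#'   \code{truth} (\code{PhantomTruth} with a per-fiber \code{in_edge} flag).
#' @export
generate_wsi_phantom <- function(core_kappa, edge_kappa, tumor_geometry,
                                 seed = 1L, tile_um = NULL, mpp = 0.5,
                                 band_um = 500,
                                 fiber_density_per_um2 = 0.006,
                                 mean_orientation_deg = 45,
                                 n_epithelium_blobs = 6,
                                 noise_sd = 5) {
  stopifnot(core_kappa >= 0, edge_kappa >= 0)
  rad <- tumor_geometry$radius_um
  if (is.null(rad) || rad <= 0) stop("tumor geometry has zero area",
                                     call. = FALSE)
  if (is.null(tile_um)) tile_um <- 2 * rad + 100
  center_um <- tumor_geometry$center_um %||% c(tile_um / 2, tile_um / 2)
  if (any(center_um - rad < 0) || any(center_um + rad > tile_um)) {
    stop("tumor geometry does not fit in the tile", call. = FALSE)
  }
  set.seed(substream_seed(seed, 2L))
  npx <- round(tile_um / mpp)
  tumor <- render_disk(c(npx, npx), center_um / mpp, rad / mpp)

  if (band_um > rad) {
    warning("leading-edge band wider than the tumor; clipped to the tumor")
  }
  band <- leading_edge_band(tumor, band_um = band_um, mpp = mpp)

  # epithelium blobs scattered inside the tumor, clear of its rim
  epi <- matrix(FALSE, npx, npx)
  if (n_epithelium_blobs > 0) {
    for (i in seq_len(n_epithelium_blobs)) {
      ang <- runif(1, 0, 2 * pi)
      rr <- sqrt(runif(1)) * (rad * 0.7)
      ctr <- center_um + rr * c(sin(ang), cos(ang))
      epi <- epi | render_disk(c(npx, npx), ctr / mpp,
                               runif(1, 25, 50) / mpp)
    }
    epi <- epi & tumor
  }
  stroma <- !epi

  tas <- stroma & tumor
  n_fibers <- round(sum(tas) * mpp^2 * fiber_density_per_um2)
  cov <- matrix(0, npx, npx)
  tas_idx <- which(tas)
  half_w <- 1 / 2 / mpp
  pick <- sample(tas_idx, n_fibers, replace = TRUE)
  rows <- ((pick - 1L) %% npx) + 1L
  cols <- ((pick - 1L) %/% npx) + 1L
  in_edge <- band[cbind(rows, cols)]
  theta <- numeric(n_fibers)
  theta[in_edge] <- sample_axial_orientations(sum(in_edge),
                                              mean_orientation_deg,
                                              edge_kappa)
  theta[!in_edge] <- sample_axial_orientations(sum(!in_edge),
                                               mean_orientation_deg,
                                               core_kappa)
  lens <- runif(n_fibers, 10, 30)
  jit <- matrix(runif(2 * n_fibers, -0.5, 0.5), n_fibers, 2L)
  centers <- cbind(rows, cols)
  for (i in seq_len(n_fibers)) {
    p <- segment_patch(c(npx, npx), rows[i] + jit[i, 1], cols[i] + jit[i, 2],
                       theta[i], half_len = lens[i] / 2 / mpp,
                       half_w = half_w)
    cov[p$rr, p$cc] <- pmax(cov[p$rr, p$cc], p$cov)
  }

  a_e <- intensity_to_absorbance(220, STAIN_E[2]) +
    (intensity_to_absorbance(110, STAIN_E[2]) -
       intensity_to_absorbance(220, STAIN_E[2])) * cov
  # glass outside the tumor neighborhood stays near-white
  outside <- !tumor
  a_e[outside & cov == 0] <- 0.01
  a_h <- matrix(0, npx, npx)
  a_h[epi] <- intensity_to_absorbance(120, STAIN_H[2])
  a_e[epi] <- a_e[epi] * 0.15
  rgb <- stains_to_rgb(a_e, a_h)
  if (noise_sd > 0) {
    rgb <- rgb + array(rnorm(length(rgb), 0, noise_sd), dim(rgb))
  }

  masks <- mask_set(epithelium = epi, stroma = stroma, tumor = tumor,
                    leading_edge = band)
  truth <- structure(list(orientations_deg = theta, centers_px = centers,
                          in_edge = in_edge, stroma = stroma,
                          epithelium = epi,
                          kappa = c(core = core_kappa, edge = edge_kappa)),
                     class = "PhantomTruth")
  list(tile = image_tile(clamp(rgb, 0, 255), mpp), masks = masks,
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
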