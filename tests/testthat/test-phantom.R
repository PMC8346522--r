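# Synthetic fibrous-stroma phantoms and their ground truth.

test_that("degenerate concentrations behave as limits", {
  # kappa -> Inf: every orientation equals the mean, circular variance 0
  th <- sample_axial_orientations(50, 30, Inf)
  expect_true(all(th == 30))
  expect_equal(circ_var_axial(th), 0)

  # kappa = 0: uniform over the 18 bins (chi-square goodness of fit)
  set.seed(11)
  th0 <- sample_axial_orientations(10000, 90, 0)
  counts <- tabulate(bin_orientation(th0) + 1L, nbins = 18)
  gof <- suppressWarnings(chisq.test(counts, p = rep(1 / 18, 18)))
  expect_gt(gof$p.value, 0.001)
})

test_that("sampled circular variance decreases in kappa", {
  set.seed(12)
  v <- vapply(c(0, 2, 8, 32),
              function(k) circ_var_axial(
                sample_axial_orientations(5000, 45, k)), 0)
  expect_true(all(diff(v) < 0))
})

test_that("fiber tiles honor their spec and are reproducible", {
  spec <- fiber_phantom_spec(width_um = 100, height_um = 80, n_fibers = 25,
                             kappa = 4, seed = 7)
  ph1 <- generate_fiber_tile(spec)
  ph2 <- generate_fiber_tile(spec)
  expect_identical(ph1$tile$pixels, ph2$tile$pixels)   # bit-for-bit
  expect_identical(ph1$truth$orientations_deg, ph2$truth$orientations_deg)
  expect_length(ph1$truth$orientations_deg, 25)
  expect_identical(dim(ph1$tile$pixels)[1:2], dim(ph1$truth$stroma))
  expect_identical(dim(ph1$tile$pixels)[1:2], c(160L, 200L))

  # fibers darker than background before noise: check a noise-free render
  spec0 <- fiber_phantom_spec(width_um = 100, height_um = 80, n_fibers = 25,
                              kappa = 4, seed = 7, noise_sd = 0)
  ph0 <- generate_fiber_tile(spec0)
  lum <- 0.299 * ph0$tile$pixels[, , 1] + 0.587 * ph0$tile$pixels[, , 2] +
    0.114 * ph0$tile$pixels[, , 3]
  ctr <- round(ph0$truth$centers_px)
  on_fiber <- lum[ctr]
  expect_true(all(on_fiber < max(lum) - 20))
})

test_that("empty and invalid phantom specs are handled", {
  spec <- fiber_phantom_spec(width_um = 50, height_um = 50, n_fibers = 0)
  ph <- generate_fiber_tile(spec)
  expect_length(ph$truth$orientations_deg, 0)
  expect_error(fiber_phantom_spec(width_um = -1), "width_um")
  expect_error(fiber_phantom_spec(mpp = 0), "mpp")
  expect_error(fiber_phantom_spec(fiber_intensity = 240,
                                  background_intensity = 220))
})

test_that("whole-tumor phantoms produce consistent mask sets", {
  ph <- generate_wsi_phantom(core_kappa = 1, edge_kappa = 8,
                             tumor_geometry = list(center_um = c(300, 300),
                                                   radius_um = 250),
                             seed = 3, tile_um = 600, band_um = 100)
  m <- ph$masks
  expect_s3_class(m, "MaskSet")
  expect_true(all(m$epithelium[m$epithelium] & m$tumor[m$epithelium]))
  expect_false(any(m$stroma & m$epithelium))
  expect_true(all(m$tumor[m$leading_edge]))
  # truth labels agree with the band mask at fiber centers
  ctr <- ph$truth$centers_px
  expect_identical(ph$truth$in_edge,
                   m$leading_edge[cbind(ctr[, 1], ctr[, 2])])
})

test_that("degenerate tumor geometries are rejected or clipped", {
  expect_error(generate_wsi_phantom(1, 1, list(radius_um = 0), seed = 1),
               "zero area")
  expect_warning(
    generate_wsi_phantom(1, 1, list(center_um = c(200, 200),
                                    radius_um = 150),
                         seed = 1, tile_um = 400, band_um = 500,
                         fiber_density_per_um2 = 0.001),
    "clipped")
})

test_that("an aligned leading edge lowers edge disorder below whole-tumor", {
  ph <- generate_wsi_phantom(core_kappa = 0.5, edge_kappa = 16,
                             tumor_geometry = list(center_um = c(300, 300),
                                                   radius_um = 250),
                             seed = 9, tile_um = 600, band_um = 100)
  fv <- suppressWarnings(patient_feature_vector(ph$tile, ph$masks))
  edge <- fv[paste0("CFOD_edge_", c(50, 75, 100))]
  whole <- fv[paste0("CFOD_whole_", c(50, 75, 100))]
  expect_true(all(edge < whole))
})

test_that("equal edge and core alignment shows no systematic edge shift", {
  diffs <- vapply(1:8, function(s) {
    ph <- generate_wsi_phantom(core_kappa = 2, edge_kappa = 2,
                               tumor_geometry = list(center_um = c(200, 200),
                                                     radius_um = 170),
                               seed = s, tile_um = 400, band_um = 80)
    fv <- suppressWarnings(patient_feature_vector(ph$tile, ph$masks))
    unname(fv["CFOD_edge_50"] - fv["CFOD_whole_50"])
  }, 0)
  expect_gt(wilcox.test(diffs, exact = FALSE)$p.value, 0.05)
})
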