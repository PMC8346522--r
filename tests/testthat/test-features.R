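# Orientation binning, co-occurrence matrix, entropy, validity filter and
# patient-level aggregation.

test_that("orientations discretize into 18 half-open 10-degree bins", {
  expect_identical(bin_orientation(0), 0L)
  expect_identical(bin_orientation(95), 9L)
  expect_identical(bin_orientation(179.999), 17L)
  expect_identical(bin_orientation(180), 0L)
  expect_identical(bin_orientation(-10), 17L)
  expect_identical(bin_orientation(190), 1L)
  expect_identical(bin_orientation(c(9.999, 10)), c(0L, 1L))
})

test_that("the co-occurrence matrix enumerates ordered pairs", {
  C <- orientation_cooccurrence(c(3L, 3L, 3L))
  expect_identical(C["3", "3"], 6L)
  expect_identical(sum(C), 6L)

  C2 <- orientation_cooccurrence(c(0L, 9L))
  expect_identical(C2["0", "9"], 1L)
  expect_identical(C2["9", "0"], 1L)
  expect_identical(sum(C2), 2L)

  C3 <- orientation_cooccurrence(5L)
  expect_identical(sum(C3), 0L)
  expect_true(attr(C3, "degenerate"))

  # brute-force pair-enumeration oracle on random bin lists
  set.seed(61)
  for (i in 1:20) {
    bins <- sample(0:17, sample(2:20, 1), replace = TRUE)
    C <- orientation_cooccurrence(bins)
    expect_identical(as.vector(unclass(C)),
                     as.vector(cooccurrence_bruteforce(bins)))
    expect_identical(sum(C), length(bins) * (length(bins) - 1L))
    expect_identical(as.vector(unclass(C)), as.vector(t(unclass(C))))
  }
})

test_that("entropy obeys the closed-form axioms", {
  # all mass in one cell
  one <- matrix(0, 18, 18); one[4, 4] <- 12
  expect_identical(cfod_entropy(one), 0)
  # uniform over m cells
  four <- matrix(0, 18, 18); four[1:2, 1:2] <- 3
  expect_identical(cfod_entropy(four), 2)
  # direct-summation oracle
  p <- matrix(0, 18, 18); p[1, 1] <- 0.5; p[1, 2] <- 0.25; p[2, 1] <- 0.25
  expect_identical(cfod_entropy(p), 1.5)
  # degenerate
  expect_true(is.na(cfod_entropy(matrix(0, 18, 18))))
})

test_that("entropy is exactly invariant under 10-degree-multiple rotations", {
  set.seed(62)
  th <- runif(40, 0, 180)
  h0 <- cfod_entropy(orientation_cooccurrence(bin_orientation(th)))
  for (k in c(1, 5, 9, 13, 17)) {
    hk <- cfod_entropy(orientation_cooccurrence(
      bin_orientation((th + 10 * k) %% 180)))
    expect_identical(hk, h0)
  }
})

test_that("entropy respects its scale bound", {
  set.seed(63)
  for (i in 1:20) {
    th <- runif(sample(2:200, 1), 0, 180)
    h <- cfod_entropy(orientation_cooccurrence(bin_orientation(th)))
    expect_gte(h, 0)
    expect_lte(h, 2 * log2(18))
  }
})

test_that("the validity filter applies both thresholds inclusively", {
  expect_true(neighborhood_is_valid(0.5, 20, 0.2, 10))
  expect_false(neighborhood_is_valid(0.1, 20, 0.2, 10))
  expect_false(neighborhood_is_valid(0.5, 5, 0.2, 10))
  expect_true(neighborhood_is_valid(0.2, 10, 0.2, 10))  # boundary inclusive
})

test_that("the feature map equals cell-by-cell recomputation", {
  ph <- phantom_with_masks(kappa = 2, seed = 71, side_um = 200)
  segs <- detect_fibers(ph$tile, ph$masks$stroma & ph$masks$tumor)
  cells <- neighborhood_feature_map(ph$tile, ph$masks, 50, segments = segs)
  expect_gt(sum(cells$valid), 0)
  for (i in which(cells$valid)) {
    inside <- segs$centroid_row >= cells$row0[i] &
      segs$centroid_row < cells$row0[i] + cells$side_px[i] &
      segs$centroid_col >= cells$col0[i] &
      segs$centroid_col < cells$col0[i] + cells$side_px[i]
    th <- segs$orientation_deg[inside]
    expect_identical(cells$n_fibers[i], length(th))
    expect_identical(cells$cfod_ts[i], cfod_entropy(
      orientation_cooccurrence(bin_orientation(th))))
  }
  # a uniform-kappa phantom is spatially more homogeneous than a mixed one
  mixed <- generate_wsi_phantom(core_kappa = 0, edge_kappa = 32,
                                tumor_geometry = list(
                                  center_um = c(150, 150), radius_um = 130),
                                seed = 71, tile_um = 300, band_um = 60,
                                n_epithelium_blobs = 2)
  cells_mixed <- suppressWarnings(
    neighborhood_feature_map(mixed$tile, mixed$masks, 50))
  expect_gt(sum(cells_mixed$valid), 5)
  expect_lte(sd(cells$cfod_ts[cells$valid]),
             sd(cells_mixed$cfod_ts[cells_mixed$valid]))
})

test_that("an all-invalid tile yields no usable neighborhoods", {
  ph <- phantom_with_masks(kappa = 0, seed = 72, side_um = 100, n_fibers = 3)
  expect_warning(cells <- neighborhood_feature_map(ph$tile, ph$masks, 50),
                 "no valid")
  expect_false(any(cells$valid))
})

test_that("patient vectors have 18 slots and respond to alignment", {
  ph <- generate_wsi_phantom(core_kappa = 1, edge_kappa = 1,
                             tumor_geometry = list(center_um = c(250, 250),
                                                   radius_um = 220),
                             seed = 73, tile_um = 500, band_um = 100)
  fv <- suppressWarnings(patient_feature_vector(ph$tile, ph$masks))
  expect_length(fv, 18)
  expect_named(fv, cfod_feature_names(), ignore.order = TRUE)
  # constant kappa: edge and whole agree closely where both are well sampled
  nc <- attr(fv, "n_cells")
  f50 <- abs(fv["CFOD_edge_50"] - fv["CFOD_whole_50"])
  if (nc["CFOD_edge_50"] >= 50) expect_lt(f50, 0.15)

  # disorder direction: uniform orientations out-entropy strong alignment
  m0 <- phantom_mean_entropy(0, seed = 74, side_um = 250)
  m32 <- phantom_mean_entropy(32, seed = 74, side_um = 250)
  expect_gt(m0, m32)
})
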