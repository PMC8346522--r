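# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct counting, and
# closed forms.

# Circular statistics on axial data (period 180 degrees).
circ_mean_axial <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  (atan2(mean(sin(a)), mean(cos(a))) * 90 / pi) %% 180
}
circ_var_axial <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  1 - sqrt(mean(sin(a))^2 + mean(cos(a))^2)
}

# Brute-force orientation co-occurrence: enumerate every ordered pair of
# distinct fibers.
cooccurrence_bruteforce <- function(bins, n_bins = 18L) {
  C <- matrix(0L, n_bins, n_bins)
  n <- length(bins)
  if (n >= 2) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) C[bins[i] + 1L, bins[j] + 1L] <-
            C[bins[i] + 1L, bins[j] + 1L] + 1L
      }
    }
  }
  C
}

# From-scratch Kaplan-Meier product-limit estimate at the distinct event
# times of one group.
km_bruteforce <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (k in seq_along(tt)) {
    at_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = tt, surv = surv)
}

# From-scratch two-group log-rank test by counting risk sets and
# observed/expected events at every distinct event time.
logrank_bruteforce <- function(time, event, group) {
  g <- as.integer(factor(group))
  tt <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (k in seq_along(tt)) {
    at <- time >= tt[k]
    n <- sum(at)
    n1 <- sum(at & g == 1)
    d <- sum(time == tt[k] & event == 1)
    d1 <- sum(time == tt[k] & event == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (o1 - e1)^2 / v
  list(chisq = chisq, p = 1 - pchisq(chisq, 1))
}

# Small single-region phantom wrapped with trivial masks (whole tile =
# tumor) so the feature extractor can run on it.
phantom_with_masks <- function(kappa, seed, side_um = 300, n_fibers = NULL,
                               mean_deg = 45) {
  if (is.null(n_fibers)) n_fibers <- round(side_um^2 * 0.006)
  spec <- fiber_phantom_spec(width_um = side_um, height_um = side_um,
                             n_fibers = n_fibers, kappa = kappa,
                             mean_orientation_deg = mean_deg, seed = seed)
  ph <- generate_fiber_tile(spec)
  d <- dim(ph$truth$stroma)
  tumor <- matrix(TRUE, d[1], d[2])
  masks <- mask_set(ph$truth$epithelium, ph$truth$stroma, tumor,
                    leading_edge_band(tumor, 500, spec$mpp))
  list(tile = ph$tile, truth = ph$truth, masks = masks)
}

# Mean CFOD-TS over valid neighborhoods of a single-kappa phantom at one
# field of view.
phantom_mean_entropy <- function(kappa, seed, fov_um = 50, side_um = 300) {
  ph <- phantom_with_masks(kappa, seed, side_um)
  cells <- suppressWarnings(
    neighborhood_feature_map(ph$tile, ph$masks, fov_um))
  mean(cells$cfod_ts[cells$valid])
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Class-name matrix of a BifLabelMap.
BIF_CLASSES_of <- function(lab) {
  matrix(attr(lab, "levels")[unclass(lab)], nrow(lab), ncol(lab))
}

# Logical disk mask, built independently of the package's renderer.
render_disk_px <- function(dims, center, radius) {
  outer((seq_len(dims[1]) - center[1])^2,
        (seq_len(dims[2]) - center[2])^2, "+") <= radius^2
}
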