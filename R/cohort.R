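# Simulated survival cohorts with CFOD-TS-like feature tables.

#' Names of the 18 patient-level disorder features
#'
#' Nine fields of view (50 to 250 microns in steps of 25) crossed with the
#' two tumor regions (leading edge, whole tumor).
#'
#' @param fov_list fields of view in microns.
#' @return character vector of feature names, edge features first.
#' @export
cfod_feature_names <- function(fov_list = seq(50, 250, by = 25)) {
  c(paste0("CFOD_edge_", fov_list), paste0("CFOD_whole_", fov_list))
}

#' Specify a simulated survival cohort
#'
#' Describes a cohort whose 18 disorder features follow the structure seen in
#' real extractions: the feature mean increases and its spread decreases with
#' the field of view, and the leading-edge and whole-tumor features at a
#' matched field of view are strongly correlated. Event times follow an
#' exponential proportional-hazards model on the standardized features;
#' negative coefficients encode the prognostic direction in which less
#' disordered (more aligned) stroma carries higher hazard.
#'
#' @param n_patients cohort size (>= 2).
#' @param beta length-18 log-hazard coefficient vector over the standardized
#'   features, ordered as \code{\link{cfod_feature_names}}.
#' @param baseline_hazard exponential baseline hazard per day.
#' @param censoring_target desired fraction of censored patients, in
#'   \code{[0, 1)}.
#' @param rho_edge_whole correlation between the leading-edge and whole-tumor
#'   feature at a matched field of view.
#' @param fov_mean_range feature mean (bits) at the smallest and largest
#'   field of view; interpolated linearly in between.
#' @param fov_sd_range feature sd (bits) at the smallest and largest field of
#'   view.
#' @param seed integer seed.
#' @return An object of class \code{CohortSpec}.
#' @export
cohort_spec <- function(n_patients = 300,
                        beta = default_cohort_beta(),
                        baseline_hazard = 1 / 1500,
                        censoring_target = 0.3,
                        rho_edge_whole = 0.8,
                        fov_mean_range = c(3.2, 4.6),
                        fov_sd_range = c(0.55, 0.28),
                        seed = 1L) {
  stopifnot(n_patients >= 2, length(beta) == 18,
            censoring_target >= 0, censoring_target < 1,
            rho_edge_whole >= 0, rho_edge_whole <= 1,
            baseline_hazard > 0)
  structure(list(n_patients = as.integer(n_patients), beta = beta,
                 baseline_hazard = baseline_hazard,
                 censoring_target = censoring_target,
                 rho_edge_whole = rho_edge_whole,
                 fov_mean_range = fov_mean_range,
                 fov_sd_range = fov_sd_range, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Default prognostic coefficient vector
#'
#' Negative log-hazard weights on eight of the 18 features (three edge, five
#' whole-tumor), so that lower disorder implies higher hazard; the remaining
#' features carry no signal.
#'
#' @param strength absolute value of each nonzero coefficient.
#' @return numeric vector of length 18 named by feature.
#' @export
default_cohort_beta <- function(strength = 0.5) {
  beta <- setNames(numeric(18), cfod_feature_names())
  beta[c("CFOD_edge_50", "CFOD_edge_100", "CFOD_edge_250",
         "CFOD_whole_75", "CFOD_whole_125", "CFOD_whole_150",
         "CFOD_whole_200", "CFOD_whole_225")] <- -strength
  beta
}

#' Simulate a feature table and survival table
#'
#' Draws the 18-feature matrix with the field-of-view trend and edge/whole
#' correlation of the spec, then event times from the exponential hazard
#' \code{h0 * exp(beta' z)} on standardized features, with independent uniform
#' censoring calibrated to the target censoring fraction.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list with \code{features} (data.frame: \code{id} + 18 feature
#'   columns) and \code{survival} (data.frame: \code{id}, \code{time_days},
#'   \code{event}).
#' @export
generate_survival_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(substream_seed(spec$seed, 3L))
  n <- spec$n_patients
  fovs <- seq(50, 250, by = 25)
  nf <- length(fovs)
  mu <- seq(spec$fov_mean_range[1], spec$fov_mean_range[2], length.out = nf)
  sdv <- seq(spec$fov_sd_range[1], spec$fov_sd_range[2], length.out = nf)
  rho <- spec$rho_edge_whole

  edge <- matrix(0, n, nf)
  whole <- matrix(0, n, nf)
  for (j in seq_len(nf)) {
    z <- rnorm(n)
    e1 <- rnorm(n); e2 <- rnorm(n)
    edge[, j] <- mu[j] + sdv[j] * (sqrt(rho) * z + sqrt(1 - rho) * e1)
    whole[, j] <- mu[j] + sdv[j] * (sqrt(rho) * z + sqrt(1 - rho) * e2)
  }
  x <- cbind(edge, whole)
  colnames(x) <- cfod_feature_names(fovs)

  z <- scale(x)
  lp <- drop(z %*% spec$beta)
  t_event <- rexp(n, rate = spec$baseline_hazard * exp(lp))

  if (spec$censoring_target == 0) {
    cens <- rep(Inf, n)
  } else {
    # uniform censoring horizon calibrated so E[fraction censored] hits target
    f <- function(cmax) mean(pmin(t_event / cmax, 1)) - spec$censoring_target
    hi <- max(t_event) * 2
    if (f(hi) > 0) {
      warning(sprintf(
        "censoring target %.2f unreachable; achieved about %.2f",
        spec$censoring_target, f(hi) + spec$censoring_target))
      cmax <- hi
    } else {
      cmax <- stats::uniroot(f, c(.Machine$double.eps, hi))$root
    }
    cens <- runif(n, 0, cmax)
  }
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)

  ids <- sprintf("P%04d", seq_len(n))
  list(features = data.frame(id = ids, x, check.names = FALSE),
       survival = data.frame(id = ids, time_days = time, event = event))
}
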