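# End-to-end orchestration: masks -> fibers -> features -> model -> report,
# with reproducibility metadata written next to every output.

# Cheap content fingerprint (byte sum + length) for no-refit assertions and
# input provenance; not cryptographic.
content_hash <- function(x) {
  s <- serialize(x, NULL)
  sprintf("%d-%08x", length(s),
          sum(as.double(as.integer(s)) * seq_along(s)) %% 4294967291)
}

#' Fingerprint of a fitted model's decision state
#'
#' Hashes every component that determines predictions (selected features,
#' coefficients, standardization, imputation means, threshold) so tests can
#' assert that validation never refits.
#'
#' @param model a \code{\link{cfod_cox}} model.
#' @return character fingerprint.
#' @export
model_hash <- function(model) {
  content_hash(model[c("selected", "beta", "center", "scale",
                       "impute_means", "threshold")])
}

write_run_metadata <- function(out_dir, config, seed) {
  meta <- list(
    package = "cfodts",
    version = as.character(utils::packageVersion("cfodts")),
    seed = seed,
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
}

#' Extract the 18-feature table for a batch of patients
#'
#' For each patient: load or reuse the tile and masks, build the tumor mask
#' and leading-edge band when only epithelium/stroma masks are available,
#' and compute the \code{\link{patient_feature_vector}}. Patients whose tile
#' cannot be processed are skipped with a logged error; the run fails only
#' if every patient fails.
#'
#' @param patients named list; each element is a list with either in-memory
#'   \code{tile} (\code{ImageTile}) and \code{masks} (\code{MaskSet}), or
#'   \code{tile_path} (+ optional \code{epithelium_path},
#'   \code{stroma_path}) and \code{mpp}. Lists of tiles/masks per patient
#'   are pooled.
#' @param params extraction parameters, \code{\link{cfod_params}}.
#' @param out_dir optional output directory for the feature CSV and run
#'   metadata.
#' @param seed recorded in the metadata (extraction itself is
#'   deterministic).
#' @return data.frame: one row per patient, \code{id} + 18 feature columns
#'   + per-slot \code{n_cells_*} columns.
#' @export
run_extract <- function(patients, params = cfod_params(), out_dir = NULL,
                        seed = 0L) {
  stopifnot(length(patients) > 0, !is.null(names(patients)))
  rows <- list()
  failures <- character(0)
  for (pid in names(patients)) {
    p <- patients[[pid]]
    res <- tryCatch({
      if (is.null(p[["tile"]]) && !is.null(p[["tile_path"]])) {
        p$tile <- read_tile(p[["tile_path"]], p[["mpp"]])
      }
      if (is.null(p[["masks"]])) {
        epi <- if (!is.null(p[["epithelium_path"]]))
          read_mask(p[["epithelium_path"]])
        str <- if (!is.null(p[["stroma_path"]])) read_mask(p[["stroma_path"]])
        seg <- segment_stroma_epithelium(p[["tile"]], epithelium = epi,
                                         stroma = str)
        tumor <- build_tumor_mask(seg$epithelium, p[["tile"]]$mpp)
        band <- leading_edge_band(tumor, band_um = params$band_um,
                                  mpp = p[["tile"]]$mpp)
        p$masks <- mask_set(seg$epithelium, seg$stroma & !seg$epithelium,
                            tumor, band)
      }
      fv <- patient_feature_vector(p[["tile"]], p[["masks"]], params)
      c(unclass(fv), setNames(attr(fv, "n_cells"),
                              paste0("n_cells_", names(fv))))
    }, error = function(e) {
      message(sprintf("[extract] patient %s failed: %s", pid,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failures <- c(failures, pid) else rows[[pid]] <- res
  }
  if (!length(rows)) stop("feature extraction failed for every patient",
                          call. = FALSE)
  out <- data.frame(id = names(rows), do.call(rbind, rows),
                    check.names = FALSE, row.names = NULL)
  attr(out, "failed") <- failures
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(out_dir, "features.csv"), row.names = FALSE)
    write_run_metadata(out_dir, params, seed)
  }
  out
}

#' Fit and serialize the risk model
#'
#' @param features,survival tables joining on \code{id}; see
#'   \code{\link{cfod_cox}}.
#' @param k_frac feature budget fraction (default 0.10 of the cohort size).
#' @param out_dir optional directory for the model JSON, selected-feature
#'   table and training KM plot.
#' @param seed recorded in metadata.
#' @return the fitted \code{\link{cfod_cox}} model.
#' @export
run_model <- function(features, survival, k_frac = 0.1, out_dir = NULL,
                      seed = 0L) {
  if (nrow(survival) == 0) stop("empty survival table", call. = FALSE)
  unmatched <- setdiff(survival$id, features$id)
  if (length(unmatched)) {
    message("survival ids without features: ",
            paste(utils::head(unmatched, 5), collapse = ", "))
  }
  fit <- cfod_cox(features, survival,
                  k_frac = k_frac,
                  feature_cols = intersect(cfod_feature_names(),
                                           names(features)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_model_json(fit, file.path(out_dir, "model.json"))
    write.csv(data.frame(feature = fit$selected, beta = fit$beta,
                         row.names = NULL),
              file.path(out_dir, "selected_features.csv"),
              row.names = FALSE)
    grDevices::png(file.path(out_dir, "train_km.png"), 700, 500)
    plot(fit, main = "training risk groups")
    grDevices::dev.off()
    write_run_metadata(out_dir, list(k_frac = k_frac), seed)
  }
  fit
}

#' Validate a trained model on a held-out cohort
#'
#' Applies the stored scores and threshold with no refitting (asserted via
#' \code{\link{model_hash}}), producing overall and per-subgroup
#' stratification results.
#'
#' @param model a fitted \code{\link{cfod_cox}}.
#' @param features,survival held-out tables joining on \code{id}.
#' @param subgroups optional named list of logical vectors (aligned with the
#'   joined table rows) selecting patient subsets; subgroups with fewer than
#'   2 patients in either risk arm are skipped with a warning.
#' @param out_dir optional output directory.
#' @return list with \code{overall} (a \code{StratificationResult}),
#'   \code{subgroups} (named list), \code{groups} (per-patient factor) and
#'   the joined table.
#' @export
run_validate <- function(model, features, survival, subgroups = NULL,
                         out_dir = NULL) {
  hash_before <- model_hash(model)
  tab <- merge(features, survival, by = "id")
  grp <- predict(model, tab, type = "group")
  overall <- km_logrank(grp, tab$time_days, tab$event)
  sub_out <- list()
  for (nm in names(subgroups)) {
    sel <- subgroups[[nm]]
    if (min(table(grp[sel])) < 2) {
      warning(sprintf("subgroup '%s' has < 2 patients in an arm; skipped",
                      nm))
      next
    }
    sub_out[[nm]] <- km_logrank(grp[sel], tab$time_days[sel],
                                tab$event[sel])
  }
  stopifnot(identical(model_hash(model), hash_before))  # no-refit contract
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    res <- do.call(rbind, lapply(c(list(overall = overall), sub_out),
                                 function(s) data.frame(
                                   hr = s$hr, ci_lo = s$ci[1],
                                   ci_hi = s$ci[2], p = s$logrank_p,
                                   n_low = s$n[1], n_high = s$n[2])))
    res <- data.frame(group = rownames(res), res, row.names = NULL)
    write.csv(res, file.path(out_dir, "stratification.csv"),
              row.names = FALSE)
  }
  list(overall = overall, subgroups = sub_out, groups = grp, table = tab)
}

#' Simulate a phantom image batch and survival cohort to disk
#'
#' Convenience front end over the synthetic-data generators: writes phantom
#' tiles, truth masks and tables plus a JSON sidecar echoing every
#' generation parameter.
#'
#' @param out_dir output directory.
#' @param n_patients cohort size for the survival simulation.
#' @param n_tiles number of phantom tiles to render.
#' @param seed top-level seed, expanded into per-stage substreams.
#' @param tile_spec a \code{\link{fiber_phantom_spec}} used as template for
#'   the tiles (its seed is replaced per tile).
#' @return invisibly, the list of written paths.
#' @export
run_simulate <- function(out_dir, n_patients = 100, n_tiles = 2, seed = 1L,
                         tile_spec = fiber_phantom_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_len(n_tiles)) {
    sp <- tile_spec
    sp$seed <- as.integer(substream_seed(seed, 10L + i))
    ph <- generate_fiber_tile(sp)
    tp <- file.path(out_dir, sprintf("tile_%02d.png", i))
    write_tile(ph$tile, tp)
    write_mask(ph$truth$stroma, file.path(out_dir,
                                          sprintf("tile_%02d_stroma.png", i)))
    write.csv(data.frame(orientation_deg = ph$truth$orientations_deg),
              file.path(out_dir, sprintf("tile_%02d_truth.csv", i)),
              row.names = FALSE)
    paths <- c(paths, tp)
  }
  cs <- cohort_spec(n_patients = n_patients,
                    seed = as.integer(substream_seed(seed, 20L)))
  coh <- generate_survival_cohort(cs)
  write.csv(coh$features, file.path(out_dir, "features.csv"),
            row.names = FALSE)
  write.csv(coh$survival, file.path(out_dir, "survival.csv"),
            row.names = FALSE)
  write_run_metadata(out_dir, list(n_patients = n_patients,
                                   n_tiles = n_tiles,
                                   tile_spec = unclass(tile_spec)), seed)
  invisible(paths)
}

#' Serialize a fitted model to JSON
#'
#' @param model a \code{\link{cfod_cox}} model.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_model_json <- function(model, path) {
  keep <- model[c("selected", "beta", "k", "k_requested", "lambda",
                  "center", "scale", "impute_means", "feature_cols",
                  "threshold", "train_logrank_p", "threshold_note",
                  "n_train")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a serialized model
#'
#' @param path JSON file written by \code{\link{write_model_json}}.
#' @return a \code{cfod_cox} model usable for prediction (training scores
#'   and survival are not round-tripped).
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("beta", "center", "scale", "impute_means")) {
    m[[f]] <- unlist(m[[f]])
  }
  names(m$beta) <- m$selected
  structure(m, class = "cfod_cox")
}
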