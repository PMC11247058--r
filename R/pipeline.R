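#' Configuration for a full synthetic-study run
#'
#' Collects every tunable of the generate -> extract -> quantify -> regress
#' pipeline in one serialisable object. All stage parameters are echoed
#' into the run log so a run can be reproduced from its log alone.
#'
#' @param seed Integer seed for the whole run.
#' @param truth A [generative_truth()].
#' @param donors Donor panel (list of [donor_blood()]).
#' @param design Recipe design (see [default_design()]).
#' @param mech_source `"trace"` (default): generate a cyclic trace per
#'   clot and use the features re-extracted from it; `"cohort"`: use the
#'   cohort observables directly and skip trace synthesis.
#' @param delta_eps_pct Trace strain sampling step, %.
#' @param baseline_tol Baseline tolerance for [plastic_strain()], kPa.
#' @param ct_voxel_size Phantom voxel size, mm.
#' @param ct_noise_sd Phantom voxel HU noise sd.
#' @param mask_style Histology mask style, `"exact"` or `"blob"`.
#' @param mask_pixels Clot-region pixels per mask.
#' @param sections_per_clot Histology slices averaged per clot (1 or 2).
#' @param flag_prob Probability that a clot is flagged as compromised
#'   during handling (passed to [generate_cohort()]); default 0.
#' @param exclude_flagged Drop clots flagged as compromised (for example
#'   pre-deformed before testing) from the mechanical regressions.
#' @param recovery_replicates If > 0, also run [recover_truth()] with this
#'   many replicate cohorts.
#' @param out_dir Optional output directory for CSV/JSON artefacts.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       truth = generative_truth(),
                       donors = default_donors(),
                       design = default_design(),
                       mech_source = c("trace", "cohort"),
                       delta_eps_pct = 0.1,
                       baseline_tol = 0.01,
                       ct_voxel_size = 0.25,
                       ct_noise_sd = 3,
                       mask_style = c("exact", "blob"),
                       mask_pixels = 10000,
                       sections_per_clot = 2,
                       flag_prob = 0,
                       exclude_flagged = FALSE,
                       recovery_replicates = 0,
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), truth = truth, donors = donors,
                 design = design, mech_source = match.arg(mech_source),
                 delta_eps_pct = delta_eps_pct, baseline_tol = baseline_tol,
                 ct_voxel_size = ct_voxel_size, ct_noise_sd = ct_noise_sd,
                 mask_style = match.arg(mask_style),
                 mask_pixels = mask_pixels,
                 sections_per_clot = sections_per_clot,
                 flag_prob = flag_prob,
                 exclude_flagged = exclude_flagged,
                 recovery_replicates = recovery_replicates,
                 out_dir = out_dir),
            class = "run_config")
}

# Adjust a target feature set into the region the synthetic curve family
# can realise: positive stiffnesses with high >= low, hysteresis inside
# (0, 100), and plastic strain at most the value compatible with the
# unloading exponent q >= 1. Returns the adjusted set and whether any
# component moved.
clip_mech_features <- function(features, peak_strain_pct = 80,
                               stiffness_floor = 0.02,
                               low_window = c(0, 10),
                               high_window = c(75, 80)) {
  low <- max(features[["low_strain_stiffness"]], stiffness_floor)
  high <- max(features[["high_strain_stiffness"]], low)
  hyst <- min(max(features[["hysteresis_loss"]], 0.5), 99.5)
  plas <- min(max(features[["plastic_strain"]], 0),
              peak_strain_pct - 0.5)
  ab <- solve_loading_curve(low, high, low_window, high_window)
  em <- peak_strain_pct / 100
  sigma_max <- ab$A * em + ab$B * em^5
  a_load <- ab$A * em^2 / 2 + ab$B * em^6 / 6
  a_unload <- a_load * (1 - hyst / 100)
  ep_max <- em - 2 * a_unload / sigma_max
  plas <- min(plas, 100 * ep_max - 1e-9)
  plas <- max(plas, 0)
  out <- list(low_strain_stiffness = low, high_strain_stiffness = high,
              hysteresis_loss = hyst, plastic_strain = plas)
  tol <- 1e-9
  clipped <- any(abs(unlist(out) - unlist(features[names(out)])) > tol)
  list(features = out, clipped = clipped)
}

log_entry <- function(log, stage, message) {
  c(log, list(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stage = stage, message = message)))
}

#' Run the full synthetic study pipeline
#'
#' Orchestrates every stage: cohort generation, per-clot cyclic-trace
#' synthesis and mechanical feature extraction, CT phantom synthesis and
#' ROI densitometry, histology mask synthesis and content quantification,
#' and the simple/multiple regressions that relate measured composition to
#' the measured imaging and mechanical characteristics. All randomness
#' derives from `config$seed`, so a repeated run is identical.
#'
#' @param config A [run_config()].
#'
#' @return A list with `cohort` (generated truth-side table), `analysis`
#'   (per-clot measured values), `regressions` (tidy table of simple and
#'   multiple fits), `recovery` (if requested), `config` and `log`.
#'   If `config$out_dir` is set, CSV/JSON artefacts are written there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  log <- log_entry(log, "init", sprintf("seed=%d", config$seed))

  cohort <- generate_cohort(config$truth, config$donors, config$design,
                            seed = config$seed,
                            flag_prob = config$flag_prob)
  n <- nrow(cohort)
  log <- log_entry(log, "cohort", sprintf("%d clots generated", n))

  mech_names <- c("low_strain_stiffness", "high_strain_stiffness",
                  "hysteresis_loss", "plastic_strain")
  analysis <- cohort[c("clot_id", "donor_id", "target_platelet_conc",
                       "rbc_volume_fraction", "diameter_mm", "flagged")]

  for (col in c(mech_names, "ncct_density", "cect_increase", "rbc_content",
                "platelet_content", "normalized_rbc",
                "normalized_platelet")) {
    analysis[[col]] <- NA_real_
  }

  # --- mechanics: synthesise a trace per clot and re-extract features ---
  analysis$mech_clipped <- FALSE
  if (config$mech_source == "trace") {
    for (i in seq_len(n)) {
      targets <- as.list(cohort[i, mech_names])
      cl <- clip_mech_features(targets)
      geom <- section_geometry(
        pi * cohort$diameter_mm[i]^2 / 4,
        feret_diameter = cohort$diameter_mm[i])
      gen <- generate_mech_trace(cl$features, geom,
                                 delta_eps_pct = config$delta_eps_pct,
                                 softening = config$truth$softening)
      feats <- extract_mech_features(gen$trace, geom,
                                     baseline_tol = config$baseline_tol)
      for (f in mech_names) analysis[[f]][i] <- feats[[f]]
      analysis$mech_clipped[i] <- cl$clipped
    }
    log <- log_entry(log, "mech",
                     sprintf("features extracted from %d traces (%d clipped)",
                             n, sum(analysis$mech_clipped)))
  } else {
    for (f in mech_names) analysis[[f]] <- cohort[[f]]
    log <- log_entry(log, "mech", "cohort observables used directly")
  }

  # --- CT: phantom pair per clot, ROI densitometry ---
  for (i in seq_len(n)) {
    ph <- generate_ct_phantom(cohort$ncct_density[i],
                              cohort$cect_increase[i],
                              cohort$diameter_mm[i],
                              voxel_size = config$ct_voxel_size,
                              noise_sd = config$ct_noise_sd,
                              seed = config$seed + 1000L + i)
    dr <- tryCatch(
      density_result(ph$ncct, ph$cect, cohort$diameter_mm[i]),
      error = function(e) stop(sprintf("ctimg stage failed for %s: %s",
                                       cohort$clot_id[i], conditionMessage(e)),
                               call. = FALSE))
    analysis$ncct_density[i] <- dr$ncct_density
    analysis$cect_increase[i] <- dr$cect_increase
  }
  log <- log_entry(log, "ctimg", sprintf("%d phantom pairs measured", n))

  # --- histology: mask pair(s) per clot, content quantification ---
  for (i in seq_len(n)) {
    slices <- lapply(seq_len(config$sections_per_clot), function(s) {
      mk <- generate_label_mask(cohort$rbc_content[i],
                                cohort$platelet_content[i],
                                n_pixels = config$mask_pixels,
                                style = config$mask_style,
                                seed = config$seed + 2000L +
                                  i * 10L + s)
      rbc <- content_percent(mk$msb, "RBC")
      plt <- content_percent(mk$cd42b, "platelet")
      norm <- normalized_composition(
        msb_clot_area = config$mask_pixels,
        rbc_area = rbc / 100 * config$mask_pixels,
        platelet_area = plt / 100 * config$mask_pixels)
      composition_result(rbc, plt, norm)
    })
    comp <- average_slices(slices)
    analysis$rbc_content[i] <- comp$rbc_content
    analysis$platelet_content[i] <- comp$platelet_content
    analysis$normalized_rbc[i] <- comp$normalized[["normalized_rbc"]]
    analysis$normalized_platelet[i] <-
      comp$normalized[["normalized_platelet"]]
  }
  log <- log_entry(log, "histo", sprintf("%d clots quantified", n))

  # --- regression tables ---
  mech_data <- if (config$exclude_flagged) {
    analysis[!analysis$flagged, , drop = FALSE]
  } else analysis
  preds <- c("rbc_content", "platelet_content")
  reg <- rbind(
    regression_table(analysis, c("ncct_density", "cect_increase"), preds),
    regression_table(mech_data, mech_names, preds))
  # size-adjusted contrast model (platelet content + clot diameter)
  size_fit <- tidy_ols(multiple_ols(
    analysis$cect_increase,
    analysis[c("platelet_content", "diameter_mm")]))
  size_fit <- cbind(outcome = "cect_increase", model = "multiple_size",
                    size_fit)
  dia_simple <- tidy_ols(simple_ols(analysis$cect_increase,
                                    analysis$diameter_mm))
  dia_simple$predictor <- "diameter_mm"
  dia_simple <- cbind(outcome = "cect_increase", model = "simple",
                      dia_simple)
  reg <- rbind(reg, dia_simple, size_fit)
  log <- log_entry(log, "regress", sprintf("%d regression rows", nrow(reg)))

  recovery <- NULL
  if (config$recovery_replicates > 0) {
    recovery <- recover_truth(config$truth, config$donors, config$design,
                              n_replicates = config$recovery_replicates,
                              seed = config$seed)
    log <- log_entry(log, "recover",
                     sprintf("%d replicate cohorts", config$recovery_replicates))
  }

  result <- list(cohort = cohort, analysis = analysis, regressions = reg,
                 recovery = recovery, config = config, log = log)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  invisible(result)
}

#' Write pipeline artefacts to the configured output directory
#'
#' Emits `cohort.csv`, `analysis.csv`, `regressions.csv`, a long-format
#' `scatter.csv` (per-clot outcome values against both contents, the
#' scatterplot data), `recovery.csv` when present, and a JSON-lines
#' `run_log.jsonl` echoing the seed and stage messages.
#'
#' @param result The list returned by [run_pipeline()].
#' @return The output directory, invisibly.
#' @export
write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(result$cohort),
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(result$analysis, file.path(dir, "analysis.csv"),
                   row.names = FALSE)
  utils::write.csv(result$regressions, file.path(dir, "regressions.csv"),
                   row.names = FALSE)
  outcomes <- c("ncct_density", "cect_increase", "low_strain_stiffness",
                "high_strain_stiffness", "hysteresis_loss", "plastic_strain")
  scatter <- do.call(rbind, lapply(outcomes, function(o) {
    data.frame(clot_id = result$analysis$clot_id,
               rbc_content = result$analysis$rbc_content,
               platelet_content = result$analysis$platelet_content,
               outcome = o, value = result$analysis[[o]])
  }))
  utils::write.csv(scatter, file.path(dir, "scatter.csv"), row.names = FALSE)
  if (!is.null(result$recovery)) {
    utils::write.csv(result$recovery, file.path(dir, "recovery.csv"),
                     row.names = FALSE)
  }
  con <- file(file.path(dir, "run_log.jsonl"), "w")
  on.exit(close(con))
  writeLines(vapply(result$log, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), character(1)), con)
  invisible(dir)
}

#' Load a run configuration from YAML
#'
#' Reads scalar stage parameters and truth-coefficient overrides from a
#' YAML file; anything not present keeps its [run_config()] default.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  truth_args <- list()
  if (!is.null(y$truth)) truth_args <- y$truth
  truth <- do.call(generative_truth, truth_args)
  args <- y[setdiff(names(y), "truth")]
  args$truth <- truth
  do.call(run_config, args)
}
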