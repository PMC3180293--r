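#' Default pipeline configuration
#'
#' Every analysis parameter defaults to its published value (kernel SDs 15
#' and 4 ms, 100-ms epochs, 150-ms RT floor, 100-ms/20-ms ROC windows, 500
#' permutations, 0.1 classification threshold). Unknown keys passed in `...`
#' are rejected by name.
#'
#' @param ... overrides of default entries.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_trials = 186L,
    n_units_per_type = 3L,
    hemisphere = "left",
    kernel_sigma_ms = 15,
    sensory_sigma_ms = 4,
    min_rt_ms = 150,
    n_perm = 500L,
    type_threshold = 0.1,
    roc_width_ms = 100,
    roc_step_ms = 20
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full synthetic-session analysis pipeline
#'
#' Simulates a session (behavior + typed spike-train population), applies the
#' trial filters, computes per-unit profiles (premovement index, direction
#' preference, RT correlation, type, MSI), the population summary and the
#' behavioral summary, and optionally writes all outputs plus a manifest to
#' `out_dir`. Rerunning with the same config reproduces every numeric output
#' exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; must not already contain a
#'   manifest), or `NULL` to skip writing.
#' @return list: `trials`, `units`, `profiles`, `summary`, `behavior`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  tc <- task_config(n_trials = config$n_trials,
                    seed = derive_seed(config$seed, "behavior_stage"))
  trials <- generate_behavior(tc)
  pop <- typed_population(n_per_type = config$n_units_per_type)
  units <- generate_spike_trains(trials, pop,
                                 seed = derive_seed(config$seed, "spike_stage"),
                                 hemisphere = config$hemisphere)
  profiles <- do.call(rbind, lapply(units, function(u) {
    unit_profile(u, trials, hemisphere = config$hemisphere,
                 n_perm = config$n_perm,
                 seed = derive_seed(config$seed, paste0("profile_", u$unit_id)),
                 threshold = config$type_threshold)
  }))
  summary <- population_summary(profiles)
  behavior <- behavior_summary(trials)

  n_neural <- nrow(filter_trials(trials, "neural"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("spikeroc")),
    config = unclass(config),
    counts = list(
      n_trials = nrow(trials),
      n_catch = sum(trials$modality == "catch"),
      n_neural = n_neural,
      n_units = length(units)
    )
  )

  if (!is.null(out_dir)) {
    if (file.exists(file.path(out_dir, "manifest.json"))) {
      stop("out_dir already contains a run; refusing to overwrite: ", out_dir)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_table(trials, file.path(out_dir, "trials.tsv"))
    write_spike_times(units, file.path(out_dir, "spikes.tsv"))
    utils::write.table(profiles, file.path(out_dir, "profiles.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(behavior, file.path(out_dir, "behavior.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$checksums <- as.list(tools::md5sum(
      list.files(out_dir, full.names = TRUE, pattern = "\\.tsv$")))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(trials = trials, units = units, profiles = profiles,
       summary = summary, behavior = behavior, manifest = manifest)
}

#' Write / read a trial table as TSV
#'
#' Plain tab-separated text with a one-line header; `NA` for missing events.
#'
#' @param trials a `trial_table`.
#' @param path file path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("stimulus_side", "modality", "choice_side", "injection_condition")) {
    d[[col]] <- as.character(d[[col]])
  }
  structure(d, class = c("trial_table", "data.frame"))
}

#' Write / read per-unit spike times as TSV (`unit_id`, `time_ms`)
#'
#' @param units list of `unit_spikes`.
#' @param path file path.
#' @export
write_spike_times <- function(units, path) {
  d <- do.call(rbind, lapply(units, function(u) {
    if (!length(u$spike_times_ms)) return(NULL)
    data.frame(unit_id = u$unit_id, time_ms = u$spike_times_ms)
  }))
  if (is.null(d)) d <- data.frame(unit_id = integer(0), time_ms = numeric(0))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_spike_times
#' @export
read_spike_times <- function(path) {
  d <- utils::read.delim(path)
  lapply(sort(unique(d$unit_id)), function(id) {
    structure(list(unit_id = id,
                   spike_times_ms = sort(d$time_ms[d$unit_id == id]),
                   ground_truth = NULL),
              class = "unit_spikes")
  })
}

#' Plain-text report of a pipeline run
#'
#' Deterministic human-readable summary: trial and unit counts, type
#' fractions per direction, correlation and MSI statistics, behavioral means.
#'
#' @param result list returned by [run_pipeline()].
#' @return character vector of report lines (also printable via `cat`).
#' @export
pipeline_report <- function(result) {
  s <- result$summary
  fmt <- function(x) formatC(x, digits = 3, format = "fg")
  lines <- c(
    "spikeroc pipeline report",
    "========================",
    sprintf("trials: %d (%d catch, %d neural-filtered)",
            result$manifest$counts$n_trials, result$manifest$counts$n_catch,
            result$manifest$counts$n_neural),
    sprintf("units: %d", result$manifest$counts$n_units),
    "",
    "type fractions (rows: type, cols: direction):",
    utils::capture.output(print(round(s$type_fractions, 3))),
    "",
    "RT-rate correlation tests:",
    utils::capture.output(print(s$r_tests, row.names = FALSE)),
    "",
    "MSI by type:",
    utils::capture.output(print(s$msi_by_type, row.names = FALSE)),
    "",
    "behavior (mean RT per session x modality):",
    utils::capture.output(print(result$behavior, row.names = FALSE))
  )
  lines
}
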