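# End-to-end orchestration: ingest or simulate, summarize, dose table,
# therapy analysis. Every run writes delimited-text artifacts plus a
# machine-readable manifest into the declared output directory and is
# bit-for-bit reproducible from (config, seed).

#' Build a run configuration
#'
#' The configuration drives [run_biodist_to_dose()] and
#' [run_therapy_analysis()]. For each data kind exactly one source must be
#' given: an input table path or a synthetic-generator spec.
#'
#' @param biodist list with either `input` (path to a biodistribution
#'   table) or `synthetic` (arguments for [synthetic_config()]).
#' @param therapy list with either `input` (path to a caliper table) or
#'   `synthetic` (arguments for [therapy_sim_config()] plus `arms`, a list
#'   of `list(group=, dose_gy=, n=)`).
#' @param imaging,therapy_nuclide names of the imaging surrogate and the
#'   therapy emitter in the registry.
#' @param registry_overrides extra nuclide definitions
#'   (see [nuclide_registry()]).
#' @param activities_mbq injected activities in MBq for the dose table.
#' @param tail_mode,t0_mode,method dosimetry options, see
#'   [time_integrated_activity()].
#' @param report_rounding_gy display rounding of the wide dose table.
#' @param endpoint_diameter_mm,observation_end_d,diameter therapy options,
#'   see [endpoint_time()].
#' @param normalized_day day at which normalized tumor volumes are
#'   reported (default 28).
#' @param seed master seed for all synthetic draws.
#' @return List of class `run_config`.
#' @export
run_config <- function(biodist = list(synthetic = list()),
                       therapy = NULL,
                       imaging = "In-111", therapy_nuclide = "Y-90",
                       registry_overrides = NULL,
                       activities_mbq = c(0.925, 1.85, 3.7),
                       tail_mode = "physical", t0_mode = "auto",
                       method = "analytic", report_rounding_gy = 0.1,
                       endpoint_diameter_mm = 12, observation_end_d = 56,
                       diameter = "max", normalized_day = 28,
                       seed = 1L) {
  check_one_source <- function(x, kind) {
    if (is.null(x)) return(invisible())
    if (sum(c("input", "synthetic") %in% names(x)) != 1L)
      stop_config(kind, " config needs exactly one of 'input' or ",
                  "'synthetic'")
  }
  check_one_source(biodist, "biodist")
  check_one_source(therapy, "therapy")
  if (any(activities_mbq <= 0)) stop_config("activities must be > 0")
  structure(list(
    biodist = biodist, therapy = therapy, imaging = imaging,
    therapy_nuclide = therapy_nuclide,
    registry_overrides = registry_overrides,
    activities_mbq = activities_mbq, tail_mode = tail_mode,
    t0_mode = t0_mode, method = method,
    report_rounding_gy = report_rounding_gy,
    endpoint_diameter_mm = endpoint_diameter_mm,
    observation_end_d = observation_end_d, diameter = diameter,
    normalized_day = normalized_day, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path JSON file.
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

write_manifest <- function(out_dir, config, seed, artifacts, settings) {
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  manifest <- list(
    tool = "ritkit", version = "0.1.0", seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    settings = settings, artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

biodist_records_from_config <- function(config, seed) {
  if (!is.null(config$biodist$input)) {
    log_msg("INFO", "reading biodistribution table: ",
            config$biodist$input)
    read_biodistribution(config$biodist$input)
  } else {
    args <- config$biodist$synthetic
    if (is.data.frame(args$organs) || is.list(args$organs))
      args$organs <- as.data.frame(args$organs)
    else args$organs <- NULL
    args <- args[!vapply(args, is.null, logical(1))]
    args$seed <- seed
    sc <- do.call(synthetic_config, args)
    log_msg("INFO", "simulating biodistribution cohort (n=",
            sc$n_per_group, "/arm, noise CV=", sc$noise_cv, ")")
    simulate_biodistribution(sc)
  }
}

#' Run the biodistribution-to-dose pipeline
#'
#' Ingests (or simulates) the biodistribution cohort, summarizes it into
#' per-group organ time-activity curves, checks the surrogate-to-therapy
#' nuclide substitution, and writes the absorbed-dose table for the
#' configured injected activities. Artifacts: `cohort.csv`, `curves.csv`,
#' `dose_long.csv`, `dose_wide.csv`, `config.json`, `manifest.json`.
#' Identical (config, seed) yields byte-identical artifacts.
#'
#' @param config a `run_config`.
#' @param out_dir output directory, created if needed.
#' @param seed overrides `config$seed` when given.
#' @return Invisibly, the long-format dose table.
#' @export
run_biodist_to_dose <- function(config, out_dir, seed = config$seed) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- nuclide_registry(config$registry_overrides)
  imaging <- builtin_nuclide(config$imaging, registry)
  therapy <- builtin_nuclide(config$therapy_nuclide, registry)
  log_msg("INFO", "dosimetry settings: tail_mode=", config$tail_mode,
          ", t0_mode=", config$t0_mode, ", method=", config$method,
          ", rounding=", config$report_rounding_gy, " Gy")
  chk <- surrogate_substitution_check(imaging, therapy)
  log_msg("INFO", sprintf(
    "surrogate check: half-life ratio %.4f, max decay discrepancy %.3g",
    chk$half_life_ratio, chk$max_decay_discrepancy))

  records <- biodist_records_from_config(config, seed)
  curves <- summarize_curves(records)
  doses <- dose_table(curves, config$activities_mbq * 1e6, therapy,
                      tail_mode = config$tail_mode,
                      t0_mode = config$t0_mode, method = config$method)

  utils::write.csv(as.data.frame(records),
                   file.path(out_dir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  write_curves(curves, file.path(out_dir, "curves.csv"))
  write_dose_table(doses, file.path(out_dir, "dose_long.csv"))
  utils::write.csv(format_dose_table_wide(doses,
                                          config$report_rounding_gy),
                   file.path(out_dir, "dose_wide.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, config, seed,
                 artifacts = c("cohort.csv", "curves.csv", "dose_long.csv",
                               "dose_wide.csv"),
                 settings = list(tail_mode = config$tail_mode,
                                 t0_mode = config$t0_mode,
                                 method = config$method,
                                 half_life_ratio = chk$half_life_ratio))
  log_msg("INFO", "wrote dose table for ",
          length(unique(doses$organ)), " organs x ",
          length(config$activities_mbq), " activities to ", out_dir)
  invisible(doses)
}

therapy_measurements_from_config <- function(config, seed) {
  if (!is.null(config$therapy$input)) {
    log_msg("INFO", "reading caliper table: ", config$therapy$input)
    read_caliper(config$therapy$input)
  } else {
    args <- config$therapy$synthetic
    arms <- args$arms
    if (is.null(arms))
      arms <- list(list(group = "control", dose_gy = 0, n = 5))
    if (is.data.frame(arms))
      arms <- split(arms, seq_len(nrow(arms)))
    args$arms <- NULL
    args <- args[!vapply(args, is.null, logical(1))]
    args$seed <- seed
    tc <- do.call(therapy_sim_config, args)
    tabs <- lapply(arms, function(arm)
      simulate_therapy(tc, arm$dose_gy, n = arm$n %||% 5,
                       group = arm$group %||%
                         sprintf("dose_%.3gGy", arm$dose_gy)))
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    class(out) <- c("tumor_measurements", "data.frame")
    out
  }
}

#' Run the therapy-outcome analysis
#'
#' Ingests (or simulates) caliper measurements and writes per-animal
#' volumes, normalized volumes at the configured day, endpoint survival
#' records and the per-group product-limit curves. An animal lacking a
#' baseline measurement is excluded from the normalized-volume table with
#' a warning; structural problems abort the run.
#'
#' @inheritParams run_biodist_to_dose
#' @return Invisibly, a list with `measurements`, `normalized`,
#'   `survival_records`, `survival_curves`.
#' @export
run_therapy_analysis <- function(config, out_dir, seed = config$seed) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$therapy))
    stop_config("config carries no therapy section")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meas <- therapy_measurements_from_config(config, seed)

  norm_rows <- list()
  for (id in unique(meas$animal_id)) {
    series <- meas[meas$animal_id == id, , drop = FALSE]
    nv <- tryCatch(
      normalized_volume(series, config$normalized_day),
      error = function(e) {
        warning("animal ", id, " excluded from normalized volumes: ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
    norm_rows[[id]] <- data.frame(animal_id = id, group = series$group[1],
                                  day = config$normalized_day,
                                  normalized_volume = nv)
  }
  normalized <- do.call(rbind, norm_rows)
  normalized <- normalized[!is.na(normalized$normalized_volume), ,
                           drop = FALSE]
  rownames(normalized) <- NULL

  recs <- survival_records(meas,
                           endpoint_diameter_mm =
                             config$endpoint_diameter_mm,
                           observation_end_d = config$observation_end_d,
                           diameter = config$diameter)
  curves <- lapply(split(recs, recs$group), function(g) {
    cv <- survival_curve(g)
    cbind(group = g$group[1], as.data.frame(cv))
  })
  curve_tab <- do.call(rbind, curves)
  rownames(curve_tab) <- NULL

  utils::write.csv(as.data.frame(meas), file.path(out_dir, "volumes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(normalized, file.path(out_dir, "normalized_volumes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(recs),
                   file.path(out_dir, "survival_records.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(curve_tab, file.path(out_dir, "survival_curves.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, config, seed,
                 artifacts = c("volumes.csv", "normalized_volumes.csv",
                               "survival_records.csv",
                               "survival_curves.csv"),
                 settings = list(endpoint_diameter_mm =
                                   config$endpoint_diameter_mm,
                                 observation_end_d =
                                   config$observation_end_d,
                                 diameter = config$diameter,
                                 normalized_day = config$normalized_day))
  log_msg("INFO", "therapy analysis for ",
          length(unique(meas$group)), " arm(s) written to ", out_dir)
  invisible(list(measurements = meas, normalized = normalized,
                 survival_records = recs, survival_curves = curve_tab))
}

#' Full pipeline run
#'
#' [run_biodist_to_dose()] into `out_dir/dose/` and, when a therapy
#' section is configured, [run_therapy_analysis()] into
#' `out_dir/therapy/`.
#'
#' @inheritParams run_biodist_to_dose
#' @return Invisibly, `list(doses=, therapy=)`.
#' @export
run_full <- function(config, out_dir, seed = config$seed) {
  doses <- run_biodist_to_dose(config, file.path(out_dir, "dose"), seed)
  ther <- if (!is.null(config$therapy))
    run_therapy_analysis(config, file.path(out_dir, "therapy"), seed)
  invisible(list(doses = doses, therapy = ther))
}
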