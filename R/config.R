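default_run_config <- function() {
  list(
    protocol = list(horizon = 180, dt = 1, injection_time = 60,
                    sampling_interval = 20, n_baseline_samples = 3,
                    cohort_size = 10L, noise_sd = 0.05, base_seed = 1L),
    ga = list(population_size = 64L, generations = 300L, crossover_rate = 0.7,
              mutation_rate = 0.15, mutation_scale = 0.10,
              mutation_scale_final = 0.003, elite_count = 2L,
              tournament_size = 3L, seed = 1L,
              fitness_weights = list(steady_state = 5, stability = 1e6,
                                     shape = 0.5),
              convergence_tolerance = 2e-4),
    conditions = c("sham", "depleted"),
    base_seed = 1L,
    output_dir = "necsim_out",
    targets_path = NULL
  )
}

#' Load and validate a run configuration
#'
#' JSON configuration with sections `protocol`, `ga`, and top-level keys
#' `conditions`, `base_seed`, `output_dir`, `targets_path`. Every field has
#' a documented default (see [dialysis_protocol()] and [ga_config()]);
#' unknown keys are rejected by name. An empty file yields the full default
#' configuration (180 min, 1-min steps, injection at 60 min, 10 mice,
#' packaged steady-state targets).
#'
#' @param path path to a JSON file, or `NULL` for pure defaults.
#' @return A validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(user)) {
      bad <- setdiff(names(user), names(cfg))
      if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
      for (section in c("protocol", "ga")) {
        if (!is.null(user[[section]])) {
          bad <- setdiff(names(user[[section]]), names(cfg[[section]]))
          if (length(bad)) {
            stop(sprintf("unknown %s keys: %s", section,
                         paste(bad, collapse = ", ")))
          }
          cfg[[section]][names(user[[section]])] <- user[[section]]
        }
      }
      for (key in setdiff(names(user), c("protocol", "ga"))) {
        cfg[[key]] <- user[[key]]
      }
    }
  }
  # validation by construction
  do.call(dialysis_protocol, cfg$protocol)
  do.call(ga_config, cfg$ga)
  if (!all(cfg$conditions %in% c("sham", "depleted"))) {
    stop("conditions must be a subset of {sham, depleted}")
  }
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @param cfg a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

config_protocol <- function(cfg) do.call(dialysis_protocol, cfg$protocol)

config_ga <- function(cfg) {
  ga <- cfg$ga
  ga$fitness_weights <- unlist(ga$fitness_weights)
  do.call(ga_config, ga)
}

report_to_list <- function(report) {
  test_list <- function(r) {
    out <- list(test_name = r$test_name, statistic = r$statistic, df = r$df,
                p_value = r$p_value, significant = r$significant,
                n_per_group = r$n_per_group, decision_trail = r$decision_trail)
    if (!is.null(r$sidak_p)) out$sidak_p <- r$sidak_p
    out
  }
  list(
    ne_timecourse = lapply(report$ne_timecourse, function(tc) {
      list(per_timepoint = lapply(tc$per_timepoint, test_list), m = tc$m,
           rm_anova = if (is.null(tc$rm_anova)) NULL else test_list(tc$rm_anova))
    }),
    baseline = lapply(report$baseline, test_list),
    firing_pre_post = lapply(report$firing_pre_post, test_list)
  )
}

#' Run the full pipeline: fit, simulate, analyze
#'
#' Fits the cohort, runs the requested conditions of the virtual
#' microdialysis experiment, compares them, and writes all outputs to
#' `out_dir`: the cohort CSV and per-mouse JSON files, a GA fit log,
#' trajectory / dialysis / activity CSVs, the statistics report JSON, and a
#' run manifest (configuration snapshot, package version, per-stage seeds,
#' MD5 checksums of every output) sufficient to reproduce the run.
#'
#' @param cfg a [load_run_config()] configuration.
#' @param out_dir output directory (created if needed); defaults to the
#'   configuration's `output_dir`.
#' @return Invisibly, a list with the cohort, the condition runs, the
#'   report (when both conditions ran), and the manifest path.
#' @export
run_pipeline <- function(cfg = load_run_config(), out_dir = cfg$output_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proto <- config_protocol(cfg)
  gacfg <- config_ga(cfg)
  targets <- steady_state_targets(cfg$targets_path)

  cohort <- fit_cohort(targets, gacfg, n_mice = proto$cohort_size,
                       base_seed = cfg$base_seed, t_c = proto$injection_time)
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
  fitlog <- do.call(rbind, lapply(cohort, function(m) {
    cbind(mouse_id = m$mouse_id, m$history)
  }))
  utils::write.csv(fitlog, file.path(out_dir, "fit_log.csv"), row.names = FALSE)
  for (m in cohort) {
    write_fitted_mouse_json(m, file.path(out_dir, paste0(m$mouse_id, ".json")))
  }

  runs <- list()
  for (cond in cfg$conditions) {
    run <- run_condition(cohort, cond, proto)
    runs[[cond]] <- run
    utils::write.csv(run$dialysis,
                     file.path(out_dir, paste0("dialysis_", cond, ".csv")),
                     row.names = FALSE)
    utils::write.csv(run$activity,
                     file.path(out_dir, paste0("activity_", cond, ".csv")),
                     row.names = FALSE)
    for (id in names(run$trajectories)) {
      write_trajectory_csv(run$trajectories[[id]],
                           file.path(out_dir,
                                     sprintf("trajectory_%s_%s.csv", cond, id)),
                           mouse_id = id)
    }
  }

  report <- NULL
  if (all(c("sham", "depleted") %in% names(runs))) {
    report <- compare_experiment(runs$sham, runs$depleted)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(report$group_means,
                     file.path(out_dir, "group_means.csv"), row.names = FALSE)
  }

  manifest_path <- write_run_manifest(cfg, out_dir)
  invisible(list(cohort = cohort, runs = runs, report = report,
                 manifest = manifest_path))
}

#' Serialize one fitted mouse as JSON
#'
#' @param mouse a `fitted_mouse`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fitted_mouse_json <- function(mouse, path) {
  obj <- list(mouse_id = mouse$mouse_id, condition = mouse$condition,
              seed = mouse$seed,
              parameters = as.list(unclass(mouse$parameters)),
              kernel = unclass(mouse$kernel), fitness = mouse$fitness,
              achieved_steady_state = as.list(mouse$achieved_steady_state),
              stability_verdict = mouse$stability_verdict,
              accepted = mouse$accepted,
              generations_run = mouse$generations_run)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the run manifest
#'
#' Records the configuration snapshot, package version, per-stage seeds,
#' MD5 checksums of every file in `out_dir`, and a timestamp. Deterministic
#' stages rerun from the manifest must reproduce the checksums bit for bit.
#'
#' @param cfg the `run_config` used.
#' @param out_dir directory whose files are checksummed.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(cfg, out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("necsim")),
    config = unclass(cfg),
    seeds = list(fit_base = cfg$base_seed,
                 simulate = lapply(stats::setNames(nm = cfg$conditions),
                   function(cond) {
                     vapply(seq_len(cfg$protocol$cohort_size), function(i) {
                       condition_seed(cfg$base_seed + i - 1L, cond)
                     }, numeric(1))
                   })),
    checksums = as.list(stats::setNames(unname(sums), files)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Reproduce a recorded run and verify checksums
#'
#' Reruns the full pipeline from the manifest's configuration snapshot into
#' a scratch directory and compares the MD5 checksum of every recorded
#' output. All stages are seeded, hence deterministic; any mismatch is
#' reported by file name.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param work_dir directory for the rerun (default a temp dir).
#' @return A list with `ok` (all checksums match), `mismatched`,
#'   `missing` file names.
#' @export
reproduce_run <- function(manifest_path, work_dir = tempfile("necsim_repro_")) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- default_run_config()
  for (key in names(manifest$config)) cfg[[key]] <- manifest$config[[key]]
  if (is.list(cfg$targets_path) && !length(cfg$targets_path)) {
    cfg$targets_path <- NULL
  }
  cfg <- structure(cfg, class = "run_config")
  run_pipeline(cfg, out_dir = work_dir)
  verify_manifest_checksums(manifest$checksums, work_dir)
}

verify_manifest_checksums <- function(recorded, work_dir) {
  missing <- character(); mismatched <- character()
  for (f in names(recorded)) {
    new <- unname(tools::md5sum(file.path(work_dir, f)))
    if (is.na(new)) missing <- c(missing, f)
    else if (!identical(new, recorded[[f]])) mismatched <- c(mismatched, f)
  }
  list(ok = !length(missing) && !length(mismatched),
       mismatched = mismatched, missing = missing, work_dir = work_dir)
}
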