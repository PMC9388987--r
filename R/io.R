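# Config serialization, packaged presets, output writers, manifests.
# Times are serialized as decimal minutes from clinic opening (clock 0 =
# opening). CSVs are comma-separated, '.' decimal, UTF-8, LF endings.

dist_to_list <- function(spec) {
  if (is.null(spec)) {
    return(NULL)
  }
  c(list(family = spec$family, shift = spec$shift), spec$params)
}

as_dist_spec <- function(x, what = "distribution") {
  if (is.null(x)) {
    return(NULL)
  }
  if (inherits(x, "vax_dist")) {
    return(x)
  }
  if (!is.list(x) || is.null(x$family)) {
    abort_config(paste0(
      "A ", what, " spec must be a list with at least a `family` key."
    ))
  }
  args <- x
  args$family <- NULL
  shift <- args$shift %||% 0
  args$shift <- NULL
  do.call(dist_spec, c(list(family = x$family, shift = shift), args))
}

config_keys <- c(
  "site", "level", "bookings_per_slot", "staffing", "seats",
  "reps", "seed", "no_show_prob", "adverse_prob", "noise", "walk_lag"
)

#' Load a scenario configuration from YAML or JSON
#'
#' Reads a config file, rejects unknown keys, fills defaults (2% no-shows,
#' 2% adverse reactions, 20 replications, Normal(-10, 5) arrival noise,
#' Uniform(0.5, 2) hub walking lags) and returns a validated
#' [scenario_config()]. The same schema is accepted in YAML (`.yaml`/`.yml`)
#' and JSON (`.json`).
#'
#' @param path Path to the config file.
#' @return A `vax_scenario`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort_io(paste0("Config file not found: ", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || length(raw) == 0) {
    abort_config(paste0(
      "Empty configuration. Required key: site; optional keys: ",
      paste(setdiff(config_keys, "site"), collapse = ", "), "."
    ))
  }
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0) {
    abort_config(paste0(
      "Unknown configuration key(s): ", paste(unknown, collapse = ", "), "."
    ))
  }
  if (is.null(raw$site)) {
    abort_config("Configuration must name a `site` ('hub' or 'gp').")
  }
  staffing <- raw$staffing
  if (!is.null(staffing)) staffing <- unlist(staffing)
  args <- list(
    site = raw$site,
    level = raw$level %||% "medium",
    bookings_per_slot = raw$bookings_per_slot,
    staffing = staffing,
    seats = raw$seats,
    reps = raw$reps %||% 20,
    seed = raw$seed %||% 1L,
    no_show_prob = raw$no_show_prob %||% 0.02,
    adverse_prob = raw$adverse_prob %||% 0.02
  )
  if (!is.null(raw$noise)) args$noise <- as_dist_spec(raw$noise, "noise")
  if (!is.null(raw$walk_lag)) {
    args$walk_lag <- as_dist_spec(raw$walk_lag, "walk-lag")
  }
  do.call(scenario_config, args)
}

config_to_list <- function(config) {
  out <- list(
    site = config$site,
    level = config$level,
    bookings_per_slot = config$bookings_per_slot,
    staffing = if (!is.null(config$staffing)) as.list(config$staffing),
    seats = config$seats,
    reps = config$reps,
    seed = config$seed,
    no_show_prob = config$no_show_prob,
    adverse_prob = config$adverse_prob,
    noise = dist_to_list(config$noise),
    walk_lag = dist_to_list(config$walk_lag)
  )
  out[!vapply(out, is.null, logical(1))]
}

#' Write a scenario configuration to YAML or JSON
#'
#' Round-trips with [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config A `vax_scenario`.
#' @param path Destination (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "vax_scenario")) {
    abort_config("`config` must be a `scenario_config()`.")
  }
  lst <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' Packaged scenario presets
#'
#' The six published baseline scenarios ship as config fixtures:
#' `hub-low`, `hub-medium`, `hub-high`, `gp-low`, `gp-medium`, `gp-high`.
#'
#' @param name Preset name, e.g. `"hub-medium"`. With no argument, lists
#'   available presets.
#' @return A `vax_scenario` (or a character vector of preset names).
#' @export
vax_preset <- function(name = NULL) {
  dir <- system.file("extdata", "presets", package = "vaxflow")
  available <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
  if (is.null(name)) {
    return(available)
  }
  if (!name %in% available) {
    abort_config(paste0(
      "Unknown preset '", name, "'. Available: ",
      paste(available, collapse = ", "), "."
    ))
  }
  load_config(file.path(dir, paste0(name, ".yaml")))
}

#' Write run outputs to a directory
#'
#' Writes one patient-log CSV per replication, a per-replication summary
#' CSV, a pooled summary CSV, a per-station utilisation CSV and a JSON run
#' manifest (full resolved configuration, base seed, per-replication seeds,
#' package version, timestamp). Column order is stable and a header row is
#' always present. Given the same platform, [run_from_manifest()] on the
#' manifest reproduces every CSV byte-for-byte.
#'
#' @param run A [run_baseline()] result (with `keep_logs = TRUE`).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(run, out_dir) {
  if (!inherits(run, "vax_run")) {
    abort_config("`run` must come from `run_baseline()`.")
  }
  if (is.null(run$logs)) {
    abort_config("Run was built with `keep_logs = FALSE`; no logs to write.")
  }
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort_io(paste0("Cannot create output directory: ", out_dir))
  }
  files <- character(0)
  for (r in seq_along(run$logs)) {
    f <- file.path(out_dir, sprintf("patient_log_rep%02d.csv", r))
    readr::write_csv(as_tibble(run$logs[[r]]), f)
    files <- c(files, f)
  }
  f_rep <- file.path(out_dir, "summary_replications.csv")
  readr::write_csv(run$summary$per_rep, f_rep)
  f_pool <- file.path(out_dir, "summary_pooled.csv")
  readr::write_csv(run$summary$pooled, f_pool)
  f_util <- file.path(out_dir, "utilisation.csv")
  readr::write_csv(run$summary$util, f_util)
  f_manifest <- file.path(out_dir, "manifest.json")
  manifest <- list(
    package = "vaxflow",
    version = as.character(utils::packageVersion("vaxflow")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_to_list(run$config),
    base_seed = run$config$seed,
    rep_seeds = run$seeds
  )
  jsonlite::write_json(manifest, f_manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(files, f_rep, f_pool, f_util, f_manifest))
}

#' Re-run a scenario from its manifest
#'
#' Rebuilds the scenario configuration recorded in a run manifest and
#' re-executes it, reproducing the original outputs.
#'
#' @param path Path to a `manifest.json` written by [write_outputs()].
#' @param keep_logs Passed to [run_baseline()].
#' @return A `vax_run`.
#' @export
run_from_manifest <- function(path, keep_logs = TRUE) {
  if (!file.exists(path)) {
    abort_io(paste0("Manifest not found: ", path))
  }
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(manifest$config)) {
    abort_config("Manifest has no `config` entry.")
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(manifest$config, tmp, auto_unbox = TRUE, digits = NA)
  config <- load_config(tmp)
  run_baseline(config, keep_logs = keep_logs)
}
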