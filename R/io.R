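#' Load a model configuration from a YAML file
#'
#' Keys mirror the published parameter names (`initial_igii`,
#' `initial_gks`, `initial_gi`, `initial_wokers_count` — that spelling is
#' honored, with `initial_workers_count` as an alias — `initial_sb_cost`,
#' `initial_sb_intention`) plus the simulator's own knobs
#' (`cultivation_weights`, `cultivation_gain`, `adoption_prob`, `field_sd`,
#' `worker_sd`, `ticks`, `grid_width`, `grid_height`, `seed`). An empty
#' file yields the full defaults; unknown keys are an error.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) configuration file.
#' @return A validated `wsb_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("failed to parse ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop(path, ": top level must be a key-value mapping",
                          call. = FALSE)
  if (!is.null(raw$cultivation_weights)) {
    raw$cultivation_weights <- unlist(raw$cultivation_weights)
  }
  validate_config(raw)
}

#' @keywords internal
.timeseries_table <- function(results_by_scenario) {
  rows <- lapply(names(results_by_scenario), function(nm) {
    runs <- results_by_scenario[[nm]]
    do.call(rbind, lapply(seq_along(runs), function(i) {
      r <- runs[[i]]
      data.frame(scenario = nm, replicate = i, seed = r$seed,
                 tick = 0:r$ticks,
                 exhibiting_count = r$exhibiting_count,
                 willing_count = r$willing_count,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(scenario = character(), replicate = integer(),
                      seed = integer(), tick = integer(),
                      exhibiting_count = integer(), willing_count = integer(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$scenario, out$replicate, out$tick), , drop = FALSE]
}

#' Write scenario outputs as CSV tables with a metadata sidecar
#'
#' Emits `timeseries.csv` (one row per scenario, replicate, tick),
#' `summary.csv` (one row per scenario), and `metadata.json` recording the
#' full configuration, seed schedule, and package version. Row order is
#' deterministic, so reruns with identical inputs are byte-identical.
#'
#' @param results Named list: scenario name -> list of `wsb_run`.
#' @param summaries Data frame of `wsb_summary` rows (or `NULL` to
#'   summarize `results` here).
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the file paths written.
#' @export
write_tables <- function(results, summaries = NULL, out_dir = ".") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  if (is.null(summaries)) {
    summaries <- do.call(rbind, lapply(names(results), function(nm) {
      summarize_replicates(results[[nm]], nm)
    }))
  }
  if (is.null(summaries)) {
    summaries <- data.frame(scenario = character(), replicates = integer(),
                            onset_median = numeric(), onset_iqr = numeric(),
                            plateau_tick_median = numeric(),
                            plateau_level_mean = numeric(),
                            plateau_fraction = numeric(),
                            n_no_onset = integer(), stringsAsFactors = FALSE)
  }
  ts_path <- file.path(out_dir, "timeseries.csv")
  sm_path <- file.path(out_dir, "summary.csv")
  meta_path <- file.path(out_dir, "metadata.json")

  utils::write.csv(.timeseries_table(results), ts_path, row.names = FALSE)
  utils::write.csv(as.data.frame(summaries), sm_path, row.names = FALSE)

  meta <- list(
    package = "wsbsim",
    version = as.character(utils::packageVersion("wsbsim")),
    scenarios = lapply(names(results), function(nm) {
      runs <- results[[nm]]
      list(name = nm,
           replicates = length(runs),
           seeds = vapply(runs, `[[`, integer(1), "seed"),
           config = if (length(runs) > 0) as_raw_config(runs[[1L]]$config))
    })
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(timeseries = ts_path, summary = sm_path, metadata = meta_path)
}
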