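#' Scenario specification
#'
#' A scenario is a named set of configuration overrides run for a fixed
#' number of replicates under a deterministic seed schedule: replicate i
#' (i = 1..replicates) uses seed `base_seed + i - 1`. Scenarios sharing a
#' `base_seed` are therefore seed-coupled, which makes between-scenario
#' contrasts paired comparisons.
#'
#' @param name Scenario name.
#' @param overrides Named list of configuration overrides (typically the
#'   IGII/GKS/GI means).
#' @param replicates Positive integer number of replicate runs.
#' @param base_seed First seed of the replicate schedule.
#' @return A `wsb_scenario` object.
#' @export
scenario_spec <- function(name, overrides = list(), replicates = 100L,
                          base_seed = 1L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("scenario 'name' must be a nonempty string", call. = FALSE)
  }
  if (!is.numeric(replicates) || length(replicates) != 1L ||
      replicates != round(replicates) || replicates < 1) {
    stop("'replicates' must be a positive integer", call. = FALSE)
  }
  if (!is.list(overrides)) stop("'overrides' must be a list", call. = FALSE)
  structure(list(name = name, overrides = overrides,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "wsb_scenario")
}

#' Run one scenario with replicates
#'
#' Applies the scenario's overrides to the base configuration and runs it
#' once per replicate seed.
#'
#' @param spec A `wsb_scenario`.
#' @param base Base `wsb_config` (or raw list).
#' @return List with `results` (list of `wsb_run`) and `summary`
#'   (a `wsb_summary` row).
#' @export
run_scenario <- function(spec, base = validate_config()) {
  stopifnot(inherits(spec, "wsb_scenario"))
  raw <- as_raw_config(base)
  raw <- utils::modifyList(raw, spec$overrides)
  seeds <- spec$base_seed + seq_len(spec$replicates) - 1L
  results <- lapply(seeds, function(s) {
    raw$seed <- s
    run_sim(validate_config(raw))
  })
  list(results = results, summary = summarize_replicates(results, spec$name))
}

#' Single-factor low/high experiment suite
#'
#' For each context factor (IGII, GKS, GI) in turn, runs a low-level
#' (mean 2) and a high-level (mean 8) scenario with all other parameters
#' at their defaults, under a shared seed schedule.
#'
#' @param base Base `wsb_config`.
#' @param replicates Replicates per scenario.
#' @param base_seed First seed of the shared schedule; defaults to the base
#'   config's seed.
#' @return Data frame of six `wsb_summary` rows, named `igii_low`,
#'   `igii_high`, `gks_low`, `gks_high`, `gi_low`, `gi_high`.
#' @export
single_variable_suite <- function(base = validate_config(), replicates = 100L,
                                  base_seed = NULL) {
  base <- validate_config(base)
  if (is.null(base_seed)) base_seed <- base$seed
  specs <- list(
    scenario_spec("igii_low",  list(initial_igii = 2), replicates, base_seed),
    scenario_spec("igii_high", list(initial_igii = 8), replicates, base_seed),
    scenario_spec("gks_low",   list(initial_gks = 2), replicates, base_seed),
    scenario_spec("gks_high",  list(initial_gks = 8), replicates, base_seed),
    scenario_spec("gi_low",    list(initial_gi = 2), replicates, base_seed),
    scenario_spec("gi_high",   list(initial_gi = 8), replicates, base_seed)
  )
  do.call(rbind, lapply(specs, function(s) run_scenario(s, base)$summary))
}

#' Multi-factor experiment suite
#'
#' The four combined scenarios, in (IGII, GI, GKS) order: (2,2,2),
#' (8,2,2), (8,8,2), (8,8,8), run under a shared seed schedule.
#'
#' @inheritParams single_variable_suite
#' @return Data frame of four `wsb_summary` rows in the stated order.
#' @export
multi_variable_suite <- function(base = validate_config(), replicates = 100L,
                                 base_seed = NULL) {
  base <- validate_config(base)
  if (is.null(base_seed)) base_seed <- base$seed
  lv <- list(
    igii2_gi2_gks2 = c(2, 2, 2),
    igii8_gi2_gks2 = c(8, 2, 2),
    igii8_gi8_gks2 = c(8, 8, 2),
    igii8_gi8_gks8 = c(8, 8, 8)
  )
  specs <- mapply(function(nm, v) {
    scenario_spec(nm,
                  list(initial_igii = v[1], initial_gi = v[2], initial_gks = v[3]),
                  replicates, base_seed)
  }, names(lv), lv, SIMPLIFY = FALSE)
  do.call(rbind, lapply(specs, function(s) run_scenario(s, base)$summary))
}

#' @keywords internal
.median_onset_at_gain <- function(raw, gain, replicates, base_seed) {
  raw$cultivation_gain <- gain
  seeds <- base_seed + seq_len(replicates) - 1L
  onsets <- vapply(seeds, function(s) {
    raw$seed <- s
    on <- onset_tick(run_sim(validate_config(raw)))
    if (is.na(on)) Inf else as.numeric(on)
  }, numeric(1))
  stats::median(onsets)
}

#' Calibrate the cultivation gain to a target onset
#'
#' The replicate-median onset tick is monotone nonincreasing in the gain
#' (more willingness per visit means earlier threshold crossing), so the
#' gain matching a target onset can be found by bisection. Stops when the
#' median onset equals the target or the bracket narrows below 1e-3, and
#' returns the midpoint gain.
#'
#' @param base Base `wsb_config`; its seed starts the replicate schedule.
#' @param target_onset_median Target median onset tick.
#' @param replicates Replicates per gain evaluation.
#' @param bounds Length-2 gain bracket `(low, high)`; the median onset at
#'   `low` must exceed the target and at `high` must fall below it.
#' @return The calibrated gain.
#' @export
calibrate_gain <- function(base = validate_config(), target_onset_median = 15,
                           replicates = 100L, bounds = c(0.05, 5)) {
  base <- validate_config(base)
  stopifnot(length(bounds) == 2L, bounds[1] > 0, bounds[1] < bounds[2])
  raw <- as_raw_config(base)
  f <- function(g) .median_onset_at_gain(raw, g, replicates, base$seed)
  lo <- bounds[1]; hi <- bounds[2]
  f_lo <- f(lo); f_hi <- f(hi)
  if (!(f_lo > target_onset_median && f_hi < target_onset_median)) {
    stop(sprintf(paste0("bounds do not bracket the target: median onset is %s ",
                        "at gain %.4g and %s at gain %.4g, target %s; ",
                        "widen the bounds"),
                 format(f_lo), lo, format(f_hi), hi,
                 format(target_onset_median)), call. = FALSE)
  }
  while ((hi - lo) >= 1e-3) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == target_onset_median) return(mid)
    if (fm > target_onset_median) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
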