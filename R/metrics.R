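#' First tick with any exhibited safety behavior
#'
#' The onset is the smallest tick at which at least one worker exhibits
#' safety behavior; `NA` if no worker ever does within the run.
#'
#' @param run A `wsb_run`.
#' @return Integer tick (0-based) or `NA_integer_`.
#' @export
onset_tick <- function(run) {
  stopifnot(inherits(run, "wsb_run"))
  hit <- which(run$exhibiting_count >= 1L)
  if (length(hit) == 0L) NA_integer_ else hit[1L] - 1L
}

#' Tick at which the willing count stabilizes
#'
#' Operationalizes "the adopter count remained relatively stable" as the
#' first tick at which the latent willing count reaches `fraction` of its
#' final value. The willing series is monotone (context fields are fixed
#' and cultivation only accumulates), so this first crossing is well
#' defined; the noisy exhibiting series is not used here.
#'
#' @param run A `wsb_run`.
#' @param fraction Plateau threshold in (0, 1]; default 0.95.
#' @return Integer tick (0-based), or `NA_integer_` if no worker is ever
#'   willing.
#' @export
plateau_tick <- function(run, fraction = 0.95) {
  stopifnot(inherits(run, "wsb_run"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("'fraction' must lie in (0, 1]", call. = FALSE)
  }
  final <- utils::tail(run$willing_count, 1L)
  if (final == 0L) return(NA_integer_)
  which(run$willing_count >= fraction * final)[1L] - 1L
}

#' Mean exhibiting count over the run's tail
#'
#' The plateau level around which the adopter count fluctuates: the mean
#' of the exhibiting series over the final `tail_window` ticks.
#'
#' @param run A `wsb_run`.
#' @param tail_window Number of final ticks to average; default 10.
#' @return Numeric plateau level (workers).
#' @export
plateau_level <- function(run, tail_window = 10L) {
  stopifnot(inherits(run, "wsb_run"))
  len <- length(run$exhibiting_count)
  if (!is.numeric(tail_window) || tail_window < 1L || tail_window > len) {
    stop("'tail_window' must be between 1 and the series length (", len, ")",
         call. = FALSE)
  }
  mean(utils::tail(run$exhibiting_count, tail_window))
}

#' Summarize replicate runs of one scenario
#'
#' Aggregates seeded replicates into onset and plateau statistics. Runs
#' without an onset are excluded from the onset median/IQR and counted
#' explicitly in `n_no_onset`, never dropped silently.
#'
#' @param results List of `wsb_run` objects with identical configurations
#'   up to seed.
#' @param name Scenario name.
#' @return One-row data frame of class `wsb_summary`: `scenario`,
#'   `replicates`, `onset_median`, `onset_iqr`, `plateau_tick_median`,
#'   `plateau_level_mean`, `plateau_fraction`, `n_no_onset`.
#' @export
summarize_replicates <- function(results, name) {
  if (length(results) == 0L) stop("no results to summarize", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "wsb_run")))
  digests <- vapply(results, `[[`, character(1), "config_digest")
  if (length(unique(digests)) != 1L) {
    stop("results mix different configurations; summarize one scenario at a time",
         call. = FALSE)
  }
  onsets <- vapply(results, onset_tick, integer(1))
  plats <- vapply(results, plateau_tick, integer(1))
  win <- min(10L, length(results[[1L]]$exhibiting_count))
  levels <- vapply(results, plateau_level, numeric(1), tail_window = win)
  n_workers <- results[[1L]]$n_workers
  ok <- !is.na(onsets)
  out <- data.frame(
    scenario = name,
    replicates = length(results),
    onset_median = if (any(ok)) stats::median(onsets[ok]) else NA_real_,
    onset_iqr = if (any(ok)) stats::IQR(onsets[ok]) else NA_real_,
    plateau_tick_median = if (any(!is.na(plats))) {
      stats::median(plats[!is.na(plats)])
    } else NA_real_,
    plateau_level_mean = mean(levels),
    plateau_fraction = if (n_workers > 0) mean(levels) / n_workers else NA_real_,
    n_no_onset = sum(!ok),
    stringsAsFactors = FALSE
  )
  class(out) <- c("wsb_summary", "data.frame")
  out
}
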