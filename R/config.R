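# Default cultivation gain. Derived by calibrate_gain() on the all-defaults
# baseline so that the median first-adoption tick over 100 replicates is 15;
# see the methods vignette for the procedure.
.WSB_DEFAULT_GAIN <- 0.7074

#' Grid specification for the toroidal site lattice
#'
#' @param width,height Positive integers, each at least 3 patches.
#' @return A `wsb_grid_spec` object with torus topology (both axes wrap).
#' @export
grid_spec <- function(width = 33L, height = 33L) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 3L || height < 3L) {
    stop("grid dimensions must be integers >= 3 (got ", width, "x", height, ")",
         call. = FALSE)
  }
  structure(list(width = width, height = height, topology = "torus"),
            class = "wsb_grid_spec")
}

.wsb_config_keys <- function() {
  c("initial_igii", "initial_gks", "initial_gi",
    "initial_workers_count", "initial_sb_cost", "initial_sb_intention",
    "adoption_prob", "field_sd", "worker_sd",
    "cultivation_weights", "cultivation_gain",
    "ticks", "grid_width", "grid_height", "seed")
}

.wsb_config_aliases <- function() {
  # Table-style spelling of the worker-count key is honored as an alias.
  c(initial_wokers_count = "initial_workers_count")
}

.check_range <- function(value, field, lo, hi, label) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < lo || value > hi) {
    stop(sprintf("'%s' must be a number in %s (got %s)",
                 field, label, paste(format(value), collapse = ",")),
         call. = FALSE)
  }
  as.numeric(value)
}

#' Validate and complete a model configuration
#'
#' Missing fields take the published site defaults: field means
#' (IGII/GKS/GI) of 2 on a 0-10 scale, 50 workers, mean safety-behavior
#' cost 45 and mean baseline willingness 20 on a 0-100 scale, and a
#' per-tick adoption probability of 0.8 among willing workers.
#'
#' @param raw Named list with any subset of configuration keys. Valid keys:
#'   `initial_igii`, `initial_gks`, `initial_gi`, `initial_workers_count`
#'   (alias `initial_wokers_count`), `initial_sb_cost`,
#'   `initial_sb_intention`, `adoption_prob`, `field_sd`, `worker_sd`,
#'   `cultivation_weights` (length-3, sums to 1), `cultivation_gain`,
#'   `ticks`, `grid_width`, `grid_height`, `seed`.
#' @return A fully populated `wsb_config` object.
#' @examples
#' cfg <- validate_config()
#' cfg$initial_workers_count  # 50
#' @export
validate_config <- function(raw = list()) {
  if (inherits(raw, "wsb_config")) return(raw)
  if (!is.list(raw)) stop("configuration must be a named list", call. = FALSE)
  if (length(raw) > 0 && (is.null(names(raw)) || any(names(raw) == ""))) {
    stop("all configuration entries must be named", call. = FALSE)
  }

  aliases <- .wsb_config_aliases()
  hit <- names(raw) %in% names(aliases)
  names(raw)[hit] <- aliases[names(raw)[hit]]

  unknown <- setdiff(names(raw), .wsb_config_keys())
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "\nvalid keys: ", paste(.wsb_config_keys(), collapse = ", "),
         call. = FALSE)
  }

  defaults <- list(
    initial_igii = 2, initial_gks = 2, initial_gi = 2,
    initial_workers_count = 50L,
    initial_sb_cost = 45, initial_sb_intention = 20,
    adoption_prob = 0.8,
    field_sd = 1, worker_sd = 1,
    cultivation_weights = c(igii = 1 / 3, gks = 1 / 3, gi = 1 / 3),
    cultivation_gain = .WSB_DEFAULT_GAIN,
    ticks = 50L,
    grid_width = 33L, grid_height = 33L,
    seed = 1L
  )
  cfg <- utils::modifyList(defaults, raw)

  cfg$initial_igii <- .check_range(cfg$initial_igii, "initial_igii", 0, 10, "0-10")
  cfg$initial_gks <- .check_range(cfg$initial_gks, "initial_gks", 0, 10, "0-10")
  cfg$initial_gi <- .check_range(cfg$initial_gi, "initial_gi", 0, 10, "0-10")
  cfg$initial_sb_cost <-
    .check_range(cfg$initial_sb_cost, "initial_sb_cost", 0, 100, "0-100")
  cfg$initial_sb_intention <-
    .check_range(cfg$initial_sb_intention, "initial_sb_intention", 0, 100, "0-100")

  nw <- cfg$initial_workers_count
  if (!is.numeric(nw) || length(nw) != 1L || is.na(nw) || nw != round(nw) ||
      nw < 0 || nw > 100) {
    stop("'initial_workers_count' must be an integer in 0-100", call. = FALSE)
  }
  cfg$initial_workers_count <- as.integer(nw)

  p <- cfg$adoption_prob
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("'adoption_prob' must lie in (0, 1]", call. = FALSE)
  }

  for (f in c("field_sd", "worker_sd")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("'", f, "' must be a nonnegative number", call. = FALSE)
    }
  }

  w <- cfg$cultivation_weights
  if (!is.numeric(w) || length(w) != 3L || anyNA(w) || any(w < 0)) {
    stop("'cultivation_weights' must be 3 nonnegative numbers", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-12) {
    stop("'cultivation_weights' must sum to 1 (within 1e-12); got sum ",
         format(sum(w), digits = 17), call. = FALSE)
  }
  names(cfg$cultivation_weights) <- c("igii", "gks", "gi")

  g <- cfg$cultivation_gain
  # gain 0 is allowed as a null model with frozen willingness
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g < 0) {
    stop("'cultivation_gain' must be a nonnegative number", call. = FALSE)
  }

  tk <- cfg$ticks
  if (!is.numeric(tk) || length(tk) != 1L || is.na(tk) || tk != round(tk) || tk < 1) {
    stop("'ticks' must be a positive integer", call. = FALSE)
  }
  cfg$ticks <- as.integer(tk)

  sd_ <- cfg$seed
  if (!is.numeric(sd_) || length(sd_) != 1L || is.na(sd_) || sd_ != round(sd_) ||
      sd_ < 0) {
    stop("'seed' must be a nonnegative integer", call. = FALSE)
  }
  cfg$seed <- as.integer(sd_)

  cfg$grid <- grid_spec(cfg$grid_width, cfg$grid_height)
  cfg$grid_width <- cfg$grid$width
  cfg$grid_height <- cfg$grid$height

  structure(cfg, class = "wsb_config")
}

#' @export
print.wsb_config <- function(x, ...) {
  cat("<wsb_config>\n")
  cat(sprintf("  context means (0-10): IGII %.2f, GKS %.2f, GI %.2f (sd %.2f)\n",
              x$initial_igii, x$initial_gks, x$initial_gi, x$field_sd))
  cat(sprintf("  workers: %d; cost mean %.1f, baseline willingness %.1f (sd %.2f)\n",
              x$initial_workers_count, x$initial_sb_cost,
              x$initial_sb_intention, x$worker_sd))
  cat(sprintf("  adoption prob %.2f; gain %.4f; weights (%.3f, %.3f, %.3f)\n",
              x$adoption_prob, x$cultivation_gain,
              x$cultivation_weights[1], x$cultivation_weights[2],
              x$cultivation_weights[3]))
  cat(sprintf("  grid %dx%d torus; %d ticks; seed %d\n",
              x$grid_width, x$grid_height, x$ticks, x$seed))
  invisible(x)
}

# Config stripped back to its raw key-value form (e.g., for scenario
# overrides or serialization). The derived `grid` entry is dropped.
#' @keywords internal
as_raw_config <- function(config) {
  config <- validate_config(config)
  out <- unclass(config)
  out$grid <- NULL
  out$cultivation_weights <- unname(out$cultivation_weights)
  out
}

# Opaque identifier for "same configuration up to seed" checks.
#' @keywords internal
config_digest <- function(config) {
  raw <- as_raw_config(config)
  raw$seed <- NULL
  paste(vapply(raw[order(names(raw))],
               function(v) paste(format(v, digits = 17), collapse = ","),
               character(1)),
        collapse = "|")
}
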