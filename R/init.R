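#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample the context fields of every patch
#'
#' Each patch carries fixed IGII, GKS, and GI levels drawn once at
#' initialization from Normal(site mean, `field_sd`) and clamped to the
#' 0-10 scale. Draws are consumed in row-major cell order with field order
#' (igii, gks, gi) within a cell, so a given stream state always yields the
#' same lattice.
#'
#' @param grid A `wsb_grid_spec`.
#' @param config A `wsb_config` supplying the three field means and `field_sd`.
#' @param rng A `wsb_rng` stream.
#' @return A `wsb_patchgrid`: matrices `igii`, `gks`, `gi` of dimension
#'   height x width, values in \[0, 10\].
#' @export
sample_patch_fields <- function(grid, config, rng) {
  config <- validate_config(config)
  n <- grid$width * grid$height
  z <- with_stream(rng, stats::rnorm(3L * n))
  zm <- matrix(z, nrow = 3L)  # column j = cell j (row-major); rows = fields
  as_field <- function(mean, zrow) {
    vals <- clamp(mean + config$field_sd * zrow, 0, 10)
    matrix(vals, nrow = grid$height, ncol = grid$width, byrow = TRUE)
  }
  structure(list(
    spec = grid,
    igii = as_field(config$initial_igii, zm[1L, ]),
    gks  = as_field(config$initial_gks,  zm[2L, ]),
    gi   = as_field(config$initial_gi,   zm[3L, ])
  ), class = "wsb_patchgrid")
}

#' Spawn the worker population
#'
#' Workers are placed uniformly over patches (several workers may share a
#' patch). Each worker's safety-behavior cost and baseline willingness are
#' drawn from Normal(site mean, `worker_sd`) and clamped to the 0-100
#' scale; accumulated (cultivated) willingness starts at zero and no worker
#' exhibits behavior before the first tick.
#'
#' @param config A `wsb_config`.
#' @param grid A `wsb_grid_spec`.
#' @param rng A `wsb_rng` stream.
#' @return Data frame with one row per worker: `id`, `row`, `col`,
#'   `sb_cost`, `base_intention`, `cultivated`, `exhibiting`.
#' @export
spawn_workers <- function(config, grid, rng) {
  config <- validate_config(config)
  n <- config$initial_workers_count
  draws <- with_stream(rng, {
    list(row = sample.int(grid$height, n, replace = TRUE),
         col = sample.int(grid$width, n, replace = TRUE),
         z_cost = stats::rnorm(n),
         z_int = stats::rnorm(n))
  })
  data.frame(
    id = seq_len(n),
    row = draws$row,
    col = draws$col,
    sb_cost = clamp(config$initial_sb_cost + config$worker_sd * draws$z_cost,
                    0, 100),
    base_intention = clamp(config$initial_sb_intention +
                             config$worker_sd * draws$z_int, 0, 100),
    cultivated = numeric(n),
    exhibiting = logical(n)
  )
}

#' Initialize a simulation world
#'
#' Builds the patch lattice and worker population from one master seed.
#' The seed spawns dedicated substreams for patch sampling, worker
#' sampling, movement, and behavior expression, so identical configurations
#' always yield identical worlds.
#'
#' @param config A `wsb_config` (or raw list passed through
#'   [validate_config()]).
#' @return A `wsb_state` at tick 0.
#' @export
init_world <- function(config) {
  config <- validate_config(config)
  streams <- rng_substreams(config$seed)
  grid <- sample_patch_fields(config$grid, config, streams$patch)
  workers <- spawn_workers(config, config$grid, streams$worker)
  structure(list(
    tick = 0L,
    grid = grid,
    workers = workers,
    streams = streams,
    config = config
  ), class = "wsb_state")
}

#' @export
print.wsb_state <- function(x, ...) {
  cat(sprintf("<wsb_state> tick %d; %d workers on %dx%d torus; %d exhibiting\n",
              x$tick, nrow(x$workers), x$grid$spec$height, x$grid$spec$width,
              sum(x$workers$exhibiting)))
  invisible(x)
}
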