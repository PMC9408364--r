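# The 8 Moore-neighborhood offsets, fixed order (row-major scan of the
# 3x3 block minus the center).
.moore_offsets <- matrix(c(-1L, -1L, -1L,  0L,  0L,  1L,  1L,  1L,
                           -1L,  0L,  1L, -1L,  1L, -1L,  0L,  1L),
                         ncol = 2L,
                         dimnames = list(NULL, c("drow", "dcol")))

#' @keywords internal
.wrap <- function(x, extent) ((x - 1L) %% extent) + 1L

#' Move workers one Moore step on the torus
#'
#' Every worker relocates to one of its 8 Moore neighbors, chosen
#' uniformly, with wrap-around on both axes (the working-track rule).
#' Exactly one draw is consumed per worker, in row order.
#'
#' @param positions Two-column matrix (or data frame) of `row`, `col`.
#' @param grid A `wsb_grid_spec` (any width/height >= 1; on a 1x1 torus all
#'   neighbors wrap back to the same cell).
#' @param rng A `wsb_rng` stream.
#' @return Matrix of new positions, columns `row`, `col`.
#' @export
move_worker <- function(positions, grid, rng) {
  pos <- as.matrix(positions)
  n <- nrow(pos)
  if (n == 0L) return(pos)
  pick <- with_stream(rng, sample.int(8L, n, replace = TRUE))
  cbind(row = .wrap(pos[, 1L] + .moore_offsets[pick, "drow"], grid$height),
        col = .wrap(pos[, 2L] + .moore_offsets[pick, "dcol"], grid$width))
}

#' Willingness-cultivation weights
#'
#' The per-visit contribution of a patch to a worker's willingness is a
#' weighted mean of the patch's three context fields (0-10 scale), scaled
#' by `gain` into willingness units (0-100 scale). The field influence
#' coefficients come from configuration; see the methods vignette for why
#' they are explicit parameters rather than fixed constants.
#'
#' @param w_igii,w_gks,w_gi Nonnegative weights summing to 1.
#' @param gain Positive scale factor, willingness units per field unit.
#' @return A `wsb_weights` object.
#' @export
cultivation_weights <- function(w_igii = 1 / 3, w_gks = 1 / 3, w_gi = 1 / 3,
                                gain = .WSB_DEFAULT_GAIN) {
  w <- c(igii = w_igii, gks = w_gks, gi = w_gi)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12) {
    stop("weights must be nonnegative and sum to 1 within 1e-12", call. = FALSE)
  }
  if (!is.numeric(gain) || gain < 0) stop("gain must be nonnegative", call. = FALSE)
  structure(list(w = w, gain = gain), class = "wsb_weights")
}

#' @keywords internal
.weights_from_config <- function(config) {
  w <- config$cultivation_weights
  cultivation_weights(w[[1L]], w[[2L]], w[[3L]], gain = config$cultivation_gain)
}

#' Per-visit willingness increment from a patch
#'
#' Returns `gain * (w_igii * igii + w_gks * gks + w_gi * gi)` for each
#' supplied patch. Nonnegative by construction, so cultivated willingness
#' only accumulates.
#'
#' @param cell_fields Numeric vector `(igii, gks, gi)` or an n x 3 matrix.
#' @param weights A `wsb_weights` object.
#' @return Nonnegative increment(s) on the willingness (0-100) scale.
#' @export
cultivation_increment <- function(cell_fields, weights) {
  stopifnot(inherits(weights, "wsb_weights"))
  m <- if (is.matrix(cell_fields)) cell_fields else matrix(cell_fields, ncol = 3L)
  drop(weights$gain * (m %*% weights$w))
}

#' Net willingness to behave safely
#'
#' Baseline willingness from other factors plus cultivated willingness,
#' minus the worker's safety-behavior cost. A worker is "willing" only when
#' this is strictly positive.
#'
#' @param workers Worker data frame (columns `base_intention`,
#'   `cultivated`, `sb_cost`).
#' @return Numeric vector of net willingness values.
#' @export
net_willingness <- function(workers) {
  workers$base_intention + workers$cultivated - workers$sb_cost
}

#' Stochastic behavior expression
#'
#' A willing worker exhibits safety behavior this tick with probability
#' `adoption_prob`; an unwilling worker never does. One uniform draw is
#' consumed per worker regardless of willingness, which keeps the behavior
#' stream aligned across scenarios that share a seed (used by coupled-seed
#' comparisons). Expression is re-evaluated every tick, not absorbing.
#'
#' @param willing Logical vector.
#' @param adoption_prob Probability in (0, 1].
#' @param rng A `wsb_rng` stream.
#' @return Logical vector, `TRUE` only where `willing` is `TRUE`.
#' @export
generate_behavior <- function(willing, adoption_prob, rng) {
  n <- length(willing)
  if (n == 0L) return(logical(0))
  u <- with_stream(rng, stats::runif(n))
  willing & (u <= adoption_prob)
}

#' Advance the simulation by one tick
#'
#' In fixed worker-id order: (1) move one Moore step; (2) add the new
#' patch's cultivation increment; (3) recompute net willingness; (4)
#' express behavior stochastically if willing. The tick counter then
#' advances and the per-tick tallies (`exhibiting`, `willing`) are stored
#' in `state$last_tallies`.
#'
#' @param state A `wsb_state`.
#' @return The updated `wsb_state`.
#' @export
step_world <- function(state) {
  stopifnot(inherits(state, "wsb_state"))
  cfg <- state$config
  w <- state$workers
  n <- nrow(w)
  if (n > 0L) {
    pos <- move_worker(cbind(w$row, w$col), state$grid$spec, state$streams$movement)
    w$row <- pos[, "row"]
    w$col <- pos[, "col"]
    idx <- cbind(w$row, w$col)
    fields <- cbind(state$grid$igii[idx], state$grid$gks[idx], state$grid$gi[idx])
    w$cultivated <- w$cultivated +
      cultivation_increment(fields, .weights_from_config(cfg))
    willing <- net_willingness(w) > 0
    w$exhibiting <- generate_behavior(willing, cfg$adoption_prob,
                                      state$streams$behavior)
  } else {
    willing <- logical(0)
  }
  state$workers <- w
  state$tick <- state$tick + 1L
  state$last_tallies <- c(exhibiting = sum(w$exhibiting), willing = sum(willing))
  state
}

#' Run a full seeded simulation
#'
#' Initializes the world and advances it `ticks` times, recording the
#' exhibiting and willing counts at every tick (including tick 0, where no
#' worker has yet been cultivated and none exhibits).
#'
#' @param config A `wsb_config` or raw configuration list.
#' @return A `wsb_run` with integer series `exhibiting_count` and
#'   `willing_count` indexed by tick 0..ticks, plus the seed, the config
#'   echo, and a config digest.
#' @export
run_sim <- function(config) {
  config <- validate_config(config)
  state <- init_world(config)
  ticks <- config$ticks
  exhibiting <- integer(ticks + 1L)
  willing <- integer(ticks + 1L)
  willing[1L] <- sum(net_willingness(state$workers) > 0)
  for (t in seq_len(ticks)) {
    state <- step_world(state)
    exhibiting[t + 1L] <- state$last_tallies[["exhibiting"]]
    willing[t + 1L] <- state$last_tallies[["willing"]]
  }
  structure(list(
    exhibiting_count = exhibiting,
    willing_count = willing,
    ticks = ticks,
    n_workers = config$initial_workers_count,
    seed = config$seed,
    config = config,
    config_digest = config_digest(config)
  ), class = "wsb_run")
}

#' @export
print.wsb_run <- function(x, ...) {
  on <- onset_tick(x)
  cat(sprintf("<wsb_run> seed %d; %d workers; %d ticks; onset %s; final exhibiting %d\n",
              x$seed, x$n_workers, x$ticks,
              if (is.na(on)) "none" else on,
              utils::tail(x$exhibiting_count, 1L)))
  invisible(x)
}
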