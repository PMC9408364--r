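#' @keywords internal
.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

#' @keywords internal
.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Create an independent random-number stream
#'
#' A stream is a small mutable object holding its own generator state, so
#' that draws for one model rule (say, movement) never shift the draws of
#' another (say, behavior expression). Streams never touch the caller's
#' global generator state.
#'
#' @param seed Integer seed for this stream.
#' @return An object of class `wsb_rng`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  e <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  .restore_global_seed(old)
  class(e) <- "wsb_rng"
  e
}

#' Evaluate an expression using a stream's generator state
#'
#' Swaps the stream's state into the global generator, evaluates `expr`,
#' saves the advanced state back into the stream, and restores whatever
#' global state existed before the call.
#'
#' @param stream A `wsb_rng` stream.
#' @param expr Expression performing random draws.
#' @return The value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "wsb_rng"))
  old <- .save_global_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    .restore_global_seed(old)
  }, add = TRUE)
  expr
}

#' Derive named substreams from one master seed
#'
#' The master seed deterministically spawns one independent stream per
#' model rule. Changing how one rule consumes randomness therefore cannot
#' perturb the draws of any other rule.
#'
#' @param seed Master seed (nonnegative integer).
#' @param names Character vector of stream names.
#' @return Named list of `wsb_rng` streams.
#' @export
rng_substreams <- function(seed,
                           names = c("patch", "worker", "movement", "behavior")) {
  root <- rng_stream(seed)
  sub_seeds <- with_stream(root, sample.int(.Machine$integer.max - 1L, length(names)))
  streams <- lapply(sub_seeds, rng_stream)
  names(streams) <- names
  streams
}
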