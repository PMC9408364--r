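# Homogeneous, noise-free limit: all patches identical, all workers
# identical, sure behavior expression. Onset has the closed form
# floor((cost - intention) / (2 * gain)) + 1 at the default means.
det_config <- function(...) {
  validate_config(utils::modifyList(
    list(field_sd = 0, worker_sd = 0, adoption_prob = 1, ticks = 60L),
    list(...)))
}

# Minimal wsb_run for metric unit tests, bypassing the simulator.
fake_run <- function(exhibiting, willing = exhibiting, n_workers = 50L,
                     seed = 1L, digest = "fake") {
  structure(list(exhibiting_count = as.integer(exhibiting),
                 willing_count = as.integer(willing),
                 ticks = length(exhibiting) - 1L,
                 n_workers = n_workers,
                 seed = seed,
                 config = NULL,
                 config_digest = digest),
            class = "wsb_run")
}

# Bare toroidal grid extents for dynamics helpers that do not need the
# >= 3 patch constraint of a site configuration.
bare_grid <- function(width, height) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 topology = "torus"),
            class = "wsb_grid_spec")
}
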