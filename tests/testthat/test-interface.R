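test_that("an empty configuration file yields full defaults", {
  f <- tempfile(fileext = ".yaml")
  file.create(f)
  cfg <- load_config(f)
  expect_identical(cfg$initial_workers_count, 50L)
  expect_equal(cfg$adoption_prob, 0.8)
})

test_that("configuration files honor the printed key spelling and reject unknowns", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("initial_wokers_count: 40", "initial_igii: 6.5"), f)
  cfg <- load_config(f)
  expect_identical(cfg$initial_workers_count, 40L)
  expect_equal(cfg$initial_igii, 6.5)

  g <- tempfile(fileext = ".yaml")
  writeLines("not_a_key: 3", g)
  err <- expect_error(load_config(g), "not_a_key")
  expect_match(conditionMessage(err), "valid keys")

  expect_error(load_config(tempfile()), "not found")
  h <- tempfile(fileext = ".yaml")
  writeLines(c("a: [unclosed"), h)
  expect_error(load_config(h), basename(h), fixed = TRUE)
})

test_that("list-valued cultivation weights parse from YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("cultivation_weights:", "  - 0.5", "  - 0.25", "  - 0.25"), f)
  cfg <- load_config(f)
  expect_equal(unname(cfg$cultivation_weights), c(0.5, 0.25, 0.25))
})

test_that("tables have dense deterministic rows and a metadata sidecar", {
  base <- validate_config(list(ticks = 50))
  res <- list(
    a = run_scenario(scenario_spec("a", list(), 3, 1), base)$results,
    b = run_scenario(scenario_spec("b", list(initial_igii = 8), 3, 1),
                     base)$results
  )
  d1 <- file.path(tempfile(), "out1")
  paths <- write_tables(res, NULL, d1)
  ts <- read.csv(paths[["timeseries"]])
  expect_identical(nrow(ts), 2L * 3L * 51L)
  expect_identical(names(ts), c("scenario", "replicate", "seed", "tick",
                                "exhibiting_count", "willing_count"))
  expect_true(!anyDuplicated(ts[c("scenario", "replicate", "tick")]))
  sm <- read.csv(paths[["summary"]])
  expect_identical(names(sm), c("scenario", "replicates", "onset_median",
                                "onset_iqr", "plateau_tick_median",
                                "plateau_level_mean", "plateau_fraction",
                                "n_no_onset"))
  meta <- jsonlite::read_json(paths[["metadata"]])
  expect_identical(meta$package, "wsbsim")
  expect_length(meta$scenarios, 2L)

  # rerun is byte-identical
  d2 <- file.path(tempfile(), "out2")
  paths2 <- write_tables(res, NULL, d2)
  for (k in c("timeseries", "summary")) {
    expect_identical(readLines(paths[[k]]), readLines(paths2[[k]]))
  }
})

test_that("empty results produce headers-only tables", {
  d <- tempfile()
  paths <- write_tables(list(), NULL, d)
  ts <- read.csv(paths[["timeseries"]])
  expect_identical(nrow(ts), 0L)
  expect_identical(ncol(ts), 6L)
})

test_that("cli run is deterministic and writes its outputs", {
  d1 <- tempfile(); d2 <- tempfile()
  code1 <- wsb_cli(c("run", "--seed", "7", "--ticks", "20",
                     "--replicates", "2", "--out", d1))
  code2 <- wsb_cli(c("run", "--seed", "7", "--ticks", "20",
                     "--replicates", "2", "--out", d2))
  expect_identical(code1, 0L)
  expect_identical(code2, 0L)
  expect_identical(readLines(file.path(d1, "timeseries.csv")),
                   readLines(file.path(d2, "timeseries.csv")))
})

test_that("cli suite --which multi emits four summary rows", {
  d <- tempfile()
  code <- wsb_cli(c("suite", "--which", "multi", "--replicates", "2",
                    "--out", d))
  expect_identical(code, 0L)
  sm <- read.csv(file.path(d, "summary.csv"))
  expect_identical(nrow(sm), 4L)
})

test_that("cli rejects unknown subcommands and flags with usage errors", {
  expect_identical(suppressMessages(wsb_cli("frobnicate")), 2L)
  expect_identical(suppressMessages(wsb_cli(c("run", "--bogus", "1"))), 1L)
  expect_identical(wsb_cli(character(0)), 2L)
})

test_that("cli calibrate recovers the closed-form gain from a config file", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("field_sd: 0", "worker_sd: 0", "adoption_prob: 1",
               "ticks: 60"), f)
  out <- capture.output(
    code <- wsb_cli(c("calibrate", "--config", f, "--target-onset", "17",
                      "--replicates", "1", "--bounds", "0.1,5"))
  )
  expect_identical(code, 0L)
  g <- as.numeric(sub(".*: ", "", out[grepl("cultivation_gain", out)]))
  expect_identical(floor(25 / (2 * g)) + 1, 17)
})
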