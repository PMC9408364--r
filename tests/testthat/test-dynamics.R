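test_that("a worker on a 1x1 torus stays on its only cell", {
  g <- bare_grid(1, 1)
  pos <- move_worker(cbind(1L, 1L), g, rng_stream(1))
  expect_identical(unname(pos[1, ]), c(1L, 1L))
})

test_that("Moore moves from a corner reach all 8 wrapped neighbors uniformly", {
  g <- bare_grid(3, 3)
  rng <- rng_stream(42)
  n <- 8000L
  dest <- move_worker(cbind(rep(1L, n), rep(1L, n)), g, rng)
  key <- paste(dest[, "row"], dest[, "col"])
  counts <- table(key)
  expect_identical(length(counts), 8L)          # all neighbors reachable
  expect_false("1 1" %in% names(counts))        # never stays put
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("seeded movement is reproducible", {
  g <- bare_grid(5, 5)
  path1 <- move_worker(cbind(rep(3L, 100), rep(3L, 100)), g, rng_stream(9))
  path2 <- move_worker(cbind(rep(3L, 100), rep(3L, 100)), g, rng_stream(9))
  expect_identical(path1, path2)
})

test_that("cultivation increment is the gain-scaled weighted field mean", {
  w <- cultivation_weights(1 / 3, 1 / 3, 1 / 3, gain = 0.6)
  expect_equal(cultivation_increment(c(2, 2, 2), w), 1.2)   # 2 * gain
  w2 <- cultivation_weights(1 / 3, 1 / 3, 1 / 3, gain = 0.75)
  expect_equal(cultivation_increment(c(8, 2, 2), w2), 3.0)
  w0 <- cultivation_weights(gain = 0)
  expect_equal(cultivation_increment(c(9, 9, 9), w0), 0)
  # vectorized over patches
  m <- rbind(c(2, 2, 2), c(8, 2, 2))
  expect_equal(cultivation_increment(m, w2), c(1.5, 3.0))
})

test_that("net willingness subtracts cost and willingness is strictly positive", {
  w <- data.frame(base_intention = 20, cultivated = c(0, 25, 25.1), sb_cost = 45)
  expect_equal(net_willingness(w), c(-25, 0, 0.1))
  expect_identical(net_willingness(w) > 0, c(FALSE, FALSE, TRUE))
})

test_that("behavior expression gates on willingness and matches its probability", {
  rng <- rng_stream(5)
  expect_false(generate_behavior(FALSE, 0.8, rng))
  expect_true(generate_behavior(TRUE, 1, rng))
  draws <- generate_behavior(rep(TRUE, 10000L), 0.8, rng_stream(17))
  expect_gt(mean(draws), 0.79)
  expect_lt(mean(draws), 0.81)
  mixed <- generate_behavior(c(FALSE, TRUE, FALSE), 1, rng_stream(3))
  expect_identical(mixed, c(FALSE, TRUE, FALSE))
})

test_that("a step with zero workers still advances the tick with zero tallies", {
  st <- init_world(validate_config(list(initial_workers_count = 0)))
  st2 <- step_world(st)
  expect_identical(st2$tick, 1L)
  expect_identical(unname(st2$last_tallies), c(0L, 0L))
})

test_that("the homogeneous sure-adoption limit crosses at the closed-form tick", {
  for (g in c(0.25, 0.5, 0.75, 1, 2)) {
    expected <- floor(25 / (2 * g)) + 1
    r <- run_sim(det_config(cultivation_gain = g, ticks = 60L))
    expect_identical(onset_tick(r), as.integer(expected))
    # all workers cross simultaneously and expression is sure
    expect_true(all(r$exhibiting_count[seq_len(expected)] == 0))
    expect_true(all(r$exhibiting_count[(expected + 1):61] == 50))
  }
})

test_that("runs are deterministic and tallies respect containment", {
  cfg <- validate_config(list(seed = 21))
  r1 <- run_sim(cfg)
  r2 <- run_sim(cfg)
  expect_identical(r1$exhibiting_count, r2$exhibiting_count)
  expect_identical(r1$willing_count, r2$willing_count)
  expect_true(all(r1$exhibiting_count <= r1$willing_count))
  expect_true(all(r1$willing_count <= 50))
  expect_true(all(r1$exhibiting_count >= 0))
})

test_that("zero gain freezes willingness and no behavior ever appears", {
  for (s in seq_len(50)) {
    r <- run_sim(validate_config(list(cultivation_gain = 0, seed = s,
                                      ticks = 30L)))
    expect_true(all(r$exhibiting_count == 0))
    expect_true(all(r$willing_count == 0))
  }
})

test_that("the willing count is nondecreasing over time", {
  for (s in c(1, 2, 3)) {
    for (igii in c(2, 8)) {
      r <- run_sim(validate_config(list(seed = s, initial_igii = igii)))
      expect_true(all(diff(r$willing_count) >= 0))
    }
  }
})

test_that("raising a context mean never delays onset under coupled seeds", {
  for (s in seq_len(20)) {
    lo <- run_sim(validate_config(list(seed = s, initial_igii = 2)))
    hi <- run_sim(validate_config(list(seed = s, initial_igii = 8)))
    o_lo <- onset_tick(lo)
    o_hi <- onset_tick(hi)
    if (!is.na(o_lo)) {
      expect_false(is.na(o_hi))
      expect_lte(o_hi, o_lo)
    }
    expect_true(all(hi$willing_count >= lo$willing_count))
  }
})

test_that("a saturated population exhibits binomial plateau fluctuation", {
  cfg <- validate_config(list(initial_sb_cost = 0, initial_sb_intention = 90,
                              ticks = 600L, seed = 4))
  r <- run_sim(cfg)
  expect_true(all(r$willing_count == 50))
  x <- r$exhibiting_count[-1]           # ticks 1..600, each Binomial(50, 0.8)
  expect_lt(abs(mean(x) - 40), 3 * sqrt(50 * 0.8 * 0.2 / length(x)))
  expect_gt(stats::var(x), 0.8 * 8)
  expect_lt(stats::var(x), 1.2 * 8)
})
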