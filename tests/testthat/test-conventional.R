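test_that("visit events collapse consecutive inside frames into one visit", {
  spec <- default_spec()
  hp <- hole_positions(spec)
  # straight pass through one dummy disk
  h <- hp[4, ]
  tr <- polyline_traj(rbind(h + c(-60, 0), h + c(60, 0)), step = 15)
  ev <- hole_visit_events(tr, spec)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$hole, 3L)
  # enter, leave, re-enter: two visits
  tr2 <- polyline_traj(rbind(h + c(-60, 0), h, h + c(-60, 0), h), step = 15)
  ev2 <- hole_visit_events(tr2, spec)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$hole, c(3L, 3L))
})

test_that("visit events match the per-frame oracle on random walks", {
  spec <- default_spec()
  set.seed(7)
  for (k in 1:50) {
    tr <- random_walk_traj(150, spec, step_sd = 40)
    ev <- hole_visit_events(tr, spec)
    orc <- oracle_visit_events(tr$frames$x, tr$frames$y, spec)
    expect_equal(ev, orc, ignore_attr = TRUE)
    expect_equal(count_errors(tr, spec),
                 sum(orc$hole != spec$target_index))
  }
})

test_that("latency is the first target-disk entry time", {
  spec <- default_spec()
  hp <- hole_positions(spec)
  # creep toward the target entering the disk at a known frame
  x <- c(seq(250, hp[1, 1] - 41, length.out = 150), hp[1, 1])
  y <- c(seq(250, hp[1, 2], length.out = 150), hp[1, 2])
  tr <- make_traj(x, y)
  lat <- latency_to_target(tr, spec)
  expect_true(attr(lat, "reached"))
  ev <- hole_visit_events(tr, spec)
  first <- ev$enter_frame[ev$hole == 0][1]
  expect_equal(as.numeric(lat), (first - 1) / 5)
  # never reaching: duration with flag
  tr2 <- make_traj(rep(250, 10), rep(250, 10))
  lat2 <- latency_to_target(tr2, spec)
  expect_false(attr(lat2, "reached"))
  expect_equal(as.numeric(lat2), 9 / 5)
})

test_that("spatial trials reach the target faster than serial ones", {
  spec <- default_spec()
  lat <- sapply(1:15, function(seed) {
    c(as.numeric(latency_to_target(simulate_trial(
        sim_params(strategy = "spatial", seed = seed), spec), spec)),
      as.numeric(latency_to_target(simulate_trial(
        sim_params(strategy = "serial", seed = seed), spec), spec)))
  })
  expect_lt(mean(lat[1, ]), mean(lat[2, ]))
})

test_that("travel distance sums successive step norms", {
  tr <- make_traj(c(0, 3, 6), c(0, 4, 8))
  expect_equal(travel_distance(tr), 10)
  expect_equal(travel_distance(make_traj(rep(5, 4), rep(5, 4))), 0)
  set.seed(9)
  x <- runif(60, 0, 500)
  y <- runif(60, 0, 500)
  brute <- sum(sapply(1:59, function(i) {
    sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }))
  expect_equal(travel_distance(make_traj(x, y)), brute)
  # rotation invariance
  spec <- arena_spec(target_index = 4)
  tr2 <- random_walk_traj(80, spec)
  expect_equal(travel_distance(canonical_transform(tr2, spec)),
               travel_distance(tr2), tolerance = 1e-9)
})

test_that("time near holes uses closed proximity disks", {
  spec <- default_spec()
  hp <- hole_positions(spec)
  tr <- make_traj(rep(hp[1, 1], 10), rep(hp[1, 2], 10))
  cnt <- time_near_holes(tr, spec)
  expect_equal(cnt[1], 10L)
  expect_equal(sum(cnt), 10L)
  # exactly on the 40-px boundary counts as inside
  edge <- hp[5, ] + c(40, 0)
  tr2 <- make_traj(rep(edge[1], 3), rep(edge[2], 3))
  expect_equal(time_near_holes(tr2, spec)[5], 3L)
  # brute-force cross-check
  set.seed(13)
  tr3 <- random_walk_traj(120, spec, step_sd = 40)
  brute <- sapply(seq_len(12), function(h) {
    sum(sqrt((tr3$frames$x - hp[h, 1])^2 +
               (tr3$frames$y - hp[h, 2])^2) <= 40)
  })
  expect_equal(time_near_holes(tr3, spec), as.integer(brute))
})

test_that("occupancy maps conserve probability mass and refine exactly", {
  spec <- default_spec()
  set.seed(17)
  tr <- random_walk_traj(300, spec, step_sd = 25)
  om <- occupancy_map(tr, spec, block_px = 20)
  expect_equal(sum(om$grid), 1)
  # all frames in one block
  tr2 <- make_traj(rep(250, 8), rep(250, 8))
  om2 <- occupancy_map(tr2, spec, block_px = 20)
  expect_equal(max(om2$grid), 1)
  expect_equal(sum(om2$grid > 0), 1)
  # halving the block size re-aggregates to the parent blocks
  fine <- occupancy_map(tr, spec, block_px = 10)
  agg <- matrix(0, nrow(om$grid), ncol(om$grid))
  for (i in seq_len(nrow(fine$grid))) {
    for (j in seq_len(ncol(fine$grid))) {
      agg[ceiling(i / 2), ceiling(j / 2)] <-
        agg[ceiling(i / 2), ceiling(j / 2)] + fine$grid[i, j]
    }
  }
  expect_equal(agg, unname(om$grid), tolerance = 1e-12)
})

test_that("daily averages are per-subject-day arithmetic means", {
  df <- data.frame(
    subject_id = rep(c("a", "b"), each = 3),
    day = 1L,
    n_errors = c(2, 4, 6, 1, 1, 4)
  )
  da <- daily_average(df, "n_errors")
  expect_equal(da$n_errors, c(4, 2))
  expect_equal(da$n_trials, c(3L, 3L))
  one <- daily_average(df[1, ], "n_errors")
  expect_equal(one$n_errors, 2)
  # brute-force on a random table
  set.seed(3)
  big <- data.frame(
    subject_id = sample(letters[1:4], 60, TRUE),
    day = sample(1:3, 60, TRUE),
    v = rnorm(60)
  )
  da2 <- daily_average(big, "v")
  for (r in seq_len(nrow(da2))) {
    expect_equal(da2$v[r], mean(big$v[big$subject_id == da2$subject_id[r] &
                                        big$day == da2$day[r]]))
  }
})
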