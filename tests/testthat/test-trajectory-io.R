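test_that("frame-indexed CSVs get times derived from the frame rate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,10,10", "1,12,10", "2,14,10"), path)
  tr <- read_points(path, frame_rate = 5)
  expect_equal(tr$frames$t, c(0, 0.2, 0.4))
  expect_equal(tr$frames$x, c(10, 12, 14))
  expect_equal(tr$n_dropped, 0L)
})

test_that("rows with non-finite coordinates are dropped and counted", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- sprintf("%d,%g,%g", 0:9, 100 + (0:9), 200)
  rows[4] <- "3,NaN,200"
  writeLines(rows, path)
  tr <- read_points(path)
  expect_equal(nrow(tr$frames), 9)
  expect_equal(tr$n_dropped, 1L)
})

test_that("tab-separated and headered dialects are sniffed", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t\tx\ty", "0\t10\t20", "0.2\t11\t21", "0.4\t12\t22"), path)
  tr <- read_points(path)
  expect_equal(tr$frames$t, c(0, 0.2, 0.4))
  expect_equal(tr$frames$y, c(20, 21, 22))
  # header remapping
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("idx,px,py", "0,1,2", "1,3,4"), path2)
  tr2 <- read_points(path2, columns = c(frame = "idx", x = "px", y = "py"))
  expect_equal(tr2$frames$x, c(1, 3))
})

test_that("write then read round-trips frames and metadata", {
  spec <- default_spec()
  tr <- simulate_trial(sim_params(strategy = "random", seed = 5), spec,
                       subject_id = "m07", day = 3L, trial = 2L)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "trial.csv")
  write_points(tr, path)
  back <- read_points(path, subject_id = "m07", day = 3L, trial = 2L,
                      entry = "LIFT")
  expect_equal(back$frames$x, tr$frames$x, tolerance = 1e-6)
  expect_equal(back$frames$y, tr$frames$y, tolerance = 1e-6)
  expect_equal(back$frames$t, tr$frames$t, tolerance = 1e-6)
  # reading a written copy of the read data is idempotent
  path2 <- file.path(dir, "again.csv")
  write_points(back, path2)
  again <- read_points(path2, subject_id = "m07", day = 3L, trial = 2L,
                       entry = "LIFT")
  expect_equal(again$frames, back$frames)
})

test_that("trial sets round-trip through manifest directories", {
  spec <- default_spec()
  ts <- simulate_cohort(2, list(sim_params(strategy = "spatial")), spec,
                        seed = 3)
  dir <- withr::local_tempdir()
  write_trial_set(ts, dir)
  back <- read_trial_set(file.path(dir, "manifest.csv"))
  expect_equal(length(back), length(ts))
  expect_equal(back$spec, ts$spec)
  k1 <- vapply(ts$trials, function(x) x$subject_id, character(1))
  k2 <- vapply(back$trials, function(x) x$subject_id, character(1))
  expect_setequal(k2, k1)
  expect_error(trial_set(c(ts$trials, ts$trials[1]), spec), "duplicate")
})

test_that("lift-start trimming returns the suffix past the release radius", {
  spec <- default_spec()
  # frames at centre distances 5, 10, 50, 60 along the x axis
  tr <- make_traj(spec$center[1] + c(5, 10, 50, 60), rep(spec$center[2], 4),
                  entry = "LIFT")
  out <- trim_lift_start(tr, spec, distance_threshold = 38)
  expect_equal(nrow(out$frames), 2)
  expect_equal(out$frames$x[1], spec$center[1] + 50)
  expect_false(out$invalid)

  # never exceeded: empty and invalid
  tr2 <- make_traj(spec$center[1] + rep(5, 6), rep(spec$center[2], 6),
                   entry = "LIFT")
  out2 <- trim_lift_start(tr2, spec, 38)
  expect_equal(nrow(out2$frames), 0)
  expect_true(out2$invalid)

  # threshold 0 keeps everything strictly off-centre
  tr3 <- make_traj(spec$center[1] + c(1, 2, 3), rep(spec$center[2], 3),
                   entry = "LIFT")
  expect_equal(nrow(trim_lift_start(tr3, spec, 0)$frames), 3)

  # MANUAL entry: warning, unchanged
  tr4 <- make_traj(spec$center[1] + c(5, 50), rep(spec$center[2], 2),
                   entry = "MANUAL")
  expect_warning(out4 <- trim_lift_start(tr4, spec, 38), "MANUAL")
  expect_equal(out4$frames, tr4$frames)
})

test_that("trimming always yields a contiguous suffix", {
  spec <- default_spec()
  set.seed(33)
  for (k in 1:20) {
    tr <- random_walk_traj(100, spec, entry = "LIFT")
    thr <- runif(1, 0, 200)
    out <- trim_lift_start(tr, spec, thr)
    n <- nrow(out$frames)
    if (n > 0) {
      expect_equal(out$frames,
                   tr$frames[(nrow(tr$frames) - n + 1):nrow(tr$frames), ],
                   ignore_attr = TRUE)
      d <- sqrt((out$frames$x[1] - spec$center[1])^2 +
                  (out$frames$y[1] - spec$center[2])^2)
      expect_gt(d, thr)
    }
  }
})

test_that("manual start threshold is the mean first-frame centre distance", {
  spec <- default_spec()
  t1 <- make_traj(spec$center[1] + c(30, 40), rep(spec$center[2], 2),
                  entry = "MANUAL", subject_id = "a")
  t2 <- make_traj(rep(spec$center[1], 2), spec$center[2] + c(50, 60),
                  entry = "MANUAL", subject_id = "b")
  expect_equal(manual_start_threshold(list(t1, t2), spec), 40)
})
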