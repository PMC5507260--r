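test_that("quadrant crosses count only centre traversals between quadrants", {
  spec <- default_spec()
  # start inside the centre zone, straight out to the target: no cross
  tr <- polyline_traj(rbind(c(250, 250), pt(45, 200, spec)), step = 10)
  expect_equal(quadrant_cross_count(tr, spec), 0L)
  # quadrant 0 -> through centre -> quadrant 2: one cross
  tr2 <- polyline_traj(rbind(pt(45, 150, spec), pt(225, 150, spec)),
                       step = 10)
  expect_equal(quadrant_cross_count(tr2, spec), 1L)
  # excursion returning to its own quadrant: no cross
  tr3 <- polyline_traj(rbind(pt(45, 150, spec), pt(50, 20, spec),
                             pt(55, 150, spec)), step = 10)
  expect_equal(quadrant_cross_count(tr3, spec), 0L)
})

test_that("quadrant crosses match the excursion oracle on random walks", {
  spec <- default_spec()
  set.seed(19)
  for (k in 1:40) {
    tr <- random_walk_traj(200, spec, step_sd = 35)
    expect_equal(quadrant_cross_count(tr, spec),
                 oracle_quadrant_crosses(tr$frames$x, tr$frames$y, spec))
  }
})

test_that("seriality is modular ring adjacency with reversals allowed", {
  expect_true(is_sequential(c(3, 4, 5, 6), 12))
  expect_false(is_sequential(c(3, 4, 6), 12))
  expect_true(is_sequential(c(11, 0, 1), 12))
  expect_true(is_sequential(c(3, 4, 3, 2), 12))   # reversal
  expect_true(is_sequential(c(5, 5, 5, 6), 12))   # duplicates collapse
  expect_true(is_sequential(c(7), 12))            # vacuous
  expect_true(is_sequential(integer(0), 12))
  expect_true(is_sequential(c(3, 5), 12, allow_skip = TRUE))
  expect_false(is_sequential(c(3, 6), 12, allow_skip = TRUE))
})

test_that("the decision rules assign spatial, serial, random in order", {
  spec <- default_spec()
  hp <- hole_positions(spec)
  ctr <- spec$center
  # crosses 0, errors 2 (holes 2 and 1 then the target): spatial
  tr_sp <- polyline_traj(rbind(ctr, hp[3, ], hp[2, ], hp[1, ]), step = 10)
  lab_sp <- classify_trial(tr_sp, spec)
  expect_equal(lab_sp$label, "spatial")
  expect_equal(lab_sp$n_quadrant_crosses, 0L)
  expect_equal(lab_sp$n_errors, 2L)
  # crosses 2 (two centre traversals into new quadrants), sequential: serial
  tr_se <- polyline_traj(rbind(pt(40, 150, spec), ctr, pt(220, 150, spec),
                               ctr, pt(130, 150, spec), hp[5, ], hp[6, ],
                               hp[7, ]), step = 10)
  lab_se <- classify_trial(tr_se, spec)
  expect_equal(lab_se$n_quadrant_crosses, 2L)
  expect_true(lab_se$sequential)
  expect_equal(lab_se$label, "serial")
  # crosses 3: random regardless of the visit sequence
  tr_ra <- polyline_traj(rbind(pt(40, 150, spec), ctr, pt(220, 150, spec),
                               ctr, pt(130, 150, spec), ctr,
                               pt(310, 150, spec), pt(310, 190, spec),
                               pt(260, 190, spec), pt(210, 190, spec),
                               hp[5, ], hp[6, ], hp[7, ]), step = 10)
  lab_ra <- classify_trial(tr_ra, spec)
  expect_equal(lab_ra$n_quadrant_crosses, 3L)
  expect_equal(lab_ra$label, "random")
})

test_that("every trial receives exactly one label and probe trials none", {
  spec <- default_spec()
  set.seed(23)
  for (k in 1:25) {
    tr <- random_walk_traj(120, spec, step_sd = 30)
    lab <- classify_trial(tr, spec)
    expect_true(lab$label %in% c("spatial", "serial", "random"))
  }
  probe <- random_walk_traj(50, spec, phase = "probe")
  expect_true(is.na(classify_trial(probe, spec)$label))
})

test_that("labels are invariant under joint rotation of path and target", {
  spec0 <- default_spec()
  set.seed(29)
  for (k in 1:10) {
    tr <- random_walk_traj(150, spec0, step_sd = 35)
    lab0 <- classify_trial(tr, spec0)$label
    for (ti in c(3L, 7L)) {
      spec_r <- arena_spec(target_index = ti)
      rot <- ti * 2 * pi / 12
      u <- tr$frames$x - 250
      v <- 250 - tr$frames$y
      tr_r <- make_traj(250 + u * cos(rot) - v * sin(rot),
                        250 - (u * sin(rot) + v * cos(rot)))
      expect_equal(classify_trial(tr_r, spec_r)$label, lab0)
    }
  }
})

test_that("daily usage counts and normalised proportions are correct", {
  labels <- data.frame(
    subject_id = rep("a", 3), day = 1L,
    label = c("spatial", "spatial", "random"),
    entry = "LIFT"
  )
  u <- daily_strategy_usage(labels, group_col = "entry")
  expect_equal(u$counts$spatial, 2)
  expect_equal(u$counts$serial, 0)
  expect_equal(u$counts$random, 1)
  p <- u$proportions
  expect_equal(sum(p$proportion), 1)
  expect_equal(p$proportion[p$label == "spatial"], 2 / 3)
})
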