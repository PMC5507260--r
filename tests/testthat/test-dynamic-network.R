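test_that("stationary and moving traces give the expected stop episodes", {
  spec <- default_spec()
  # stationary 20-frame trace: one episode at the point
  tr <- make_traj(rep(100, 20), rep(120, 20))
  st <- detect_stops(tr, spec)
  expect_equal(nrow(st), 1)
  expect_equal(st$start_frame, 1L)
  expect_equal(st$end_frame, 20L)
  expect_equal(c(st$x, st$y), c(100, 120))
  # constant 10 px/frame motion: window path length 40 >= 20, no stop
  tr2 <- make_traj(seq(0, 190, by = 10), rep(0, 20))
  expect_equal(nrow(detect_stops(tr2, spec)), 0)
  # shorter than the window: empty
  tr3 <- make_traj(c(0, 0, 0), c(0, 0, 0))
  expect_equal(nrow(detect_stops(tr3, spec)), 0)
})

test_that("two separated pauses give two episodes matching the oracle", {
  spec <- default_spec()
  set.seed(41)
  x <- c(rep(100, 10) + rnorm(10, 0, 1), seq(110, 300, by = 10),
         rep(310, 12) + rnorm(12, 0, 1))
  y <- rep(200, length(x))
  tr <- make_traj(x, y)
  st <- detect_stops(tr, spec)
  expect_equal(nrow(st), 2)
  orc <- oracle_stop_episodes(x, y, spec$stop_window, spec$stop_threshold)
  expect_equal(st[c("start_frame", "end_frame")], orc, ignore_attr = TRUE)
})

test_that("stop detection is translation and rotation invariant", {
  spec <- default_spec()
  set.seed(43)
  tr <- simulate_trial(sim_params(strategy = "random", seed = 2), spec)
  st <- detect_stops(tr, spec)
  # translate
  tt <- tr
  tt$frames$x <- tt$frames$x + 13.7
  tt$frames$y <- tt$frames$y - 8.2
  st_t <- detect_stops(tt, spec)
  expect_equal(st_t[c("start_frame", "end_frame")],
               st[c("start_frame", "end_frame")])
  # rotate about the centre
  a <- 1.1
  u <- tr$frames$x - 250
  v <- tr$frames$y - 250
  rt <- tr
  rt$frames$x <- 250 + u * cos(a) - v * sin(a)
  rt$frames$y <- 250 + u * sin(a) + v * cos(a)
  st_r <- detect_stops(rt, spec)
  expect_equal(st_r[c("start_frame", "end_frame")],
               st[c("start_frame", "end_frame")])
})

test_that("CCA forms one node per well-separated point group", {
  set.seed(47)
  g1 <- cbind(rnorm(20, 100, 1.5), rnorm(20, 100, 1.5))
  g2 <- cbind(rnorm(15, 200, 1.5), rnorm(15, 100, 1.5))
  pts <- rbind(g1, g2)[sample(35), ]
  cl <- cca_cluster(pts, threshold = 20)
  expect_equal(nrow(cl$centroids), 2)
  expect_true(cl$converged)
  # every point assigned exactly once and centroids are member means
  expect_equal(length(cl$assignment), 35)
  for (g in 1:2) {
    mem <- pts[cl$assignment == g, , drop = FALSE]
    expect_equal(unname(cl$centroids[g, ]), unname(colMeans(mem)),
                 tolerance = 1e-12)
  }
  # single point: one node at that point
  cl1 <- cca_cluster(matrix(c(3, 4), 1), 20)
  expect_equal(unname(cl1$centroids), matrix(c(3, 4), 1))
})

test_that("CCA partitions are order-independent on separated data", {
  set.seed(53)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    centers <- cbind(runif(k, 0, 500), runif(k, 0, 500))
    # enforce inter-cluster gaps > 3x threshold
    ok <- TRUE
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (sqrt(sum((centers[a, ] - centers[b, ])^2)) < 3 * 20 + 30) {
          ok <- FALSE
        }
      }
    }
    if (!ok) next
    pts <- do.call(rbind, lapply(seq_len(k), function(i) {
      cbind(rnorm(30, centers[i, 1], 3), rnorm(30, centers[i, 2], 3))
    }))
    ref <- cca_cluster(pts, 20)
    key <- function(cl, pts) {
      unname(split(seq_len(nrow(pts)), cl$assignment))
    }
    ref_part <- key(ref, pts)
    for (perm_i in 1:5) {
      perm <- sample(nrow(pts))
      cl <- cca_cluster(pts[perm, ], 20)
      # map permuted partition back to original indices
      back <- split(perm, cl$assignment)
      norm <- function(part) {
        unname(lapply(part[order(vapply(part, min, numeric(1)))], sort))
      }
      expect_equal(norm(back), norm(ref_part))
    }
  }
})

test_that("local networks link consecutive-stop node pairs without self-links", {
  spec <- default_spec()
  # three stops within 5 px: one node, no links
  stops <- data.frame(start_frame = c(1, 10, 20), end_frame = c(5, 14, 24),
                      x = c(100, 102, 101), y = c(50, 51, 50))
  net <- build_local_network(stops, spec)
  expect_equal(nrow(net$nodes), 1)
  expect_equal(net_links(net), 0)
  expect_equal(net$n_stops, 3L)
  # stops alternating between two far spots: 2 nodes, 1 link, count 3
  stops2 <- data.frame(start_frame = c(1, 10, 20, 30),
                       end_frame = c(5, 14, 24, 34),
                       x = c(100, 300, 100, 300), y = c(50, 50, 50, 50))
  net2 <- build_local_network(stops2, spec)
  expect_equal(nrow(net2$nodes), 2)
  expect_equal(net_links(net2), 1)
  expect_equal(max(net2$counts), 3)
  expect_equal(diag(net2$adjacency), rep(0, 2))
  # zero stops: empty network
  net0 <- build_local_network(detect_stops(
    make_traj(seq(0, 190, 10), rep(0, 20)), spec), spec)
  expect_equal(nrow(net0$nodes), 0)
})

test_that("adjacency equals brute-force transition tabulation on simulations", {
  spec <- default_spec()
  for (seed in 1:10) {
    tr <- simulate_trial(sim_params(strategy = "random", seed = seed), spec)
    stops <- detect_stops(tr, spec)
    if (nrow(stops) < 2) next
    net <- build_local_network(stops, spec)
    cl <- cca_cluster(cbind(stops$x, stops$y), spec$cca_threshold)
    k <- nrow(cl$centroids)
    A <- matrix(0, k, k)
    for (i in seq_len(nrow(stops) - 1)) {
      u <- cl$assignment[i]
      v <- cl$assignment[i + 1]
      if (u != v) A[u, v] <- A[v, u] <- 1
    }
    expect_equal(net$adjacency, A)
    # fixed point: node centroids are member means
    for (g in seq_len(k)) {
      mem <- which(cl$assignment == g)
      expect_equal(net$nodes$x[g], mean(stops$x[mem]), tolerance = 1e-9)
    }
  }
})

test_that("planted dwell sites are recovered as network order", {
  spec <- default_spec()
  hits <- 0L
  n_seeds <- 40L
  for (seed in seq_len(n_seeds)) {
    set.seed(seed + 7000)
    k <- sample(3:6, 1)
    # sites on the hole ring, >= 2 hole spacings apart (> 3x threshold)
    slots <- sort(sample(0:5, k) * 2)
    sites <- hole_positions(spec)[slots + 1, , drop = FALSE]
    p <- sim_params(strategy = "sites", dwell_sites = sites,
                    stop_rate = 0, speed_mean = 60, speed_sd = 10,
                    hole_dwell = 10L, start_dwell = 0L, max_duration = 60,
                    seed = seed)
    net <- build_local_network(detect_stops(simulate_trial(p, spec), spec),
                               spec)
    hits <- hits + (nrow(net$nodes) == k)
  }
  expect_gte(hits / n_seeds, 0.95)
})
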