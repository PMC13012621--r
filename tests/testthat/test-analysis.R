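make_frame <- function(pos, bonds = matrix(0L, 0, 4), ap2 = NULL,
                       time_us = 0) {
  n <- nrow(pos)
  if (is.null(ap2)) ap2 <- integer(n)
  fcl_frame(time_us, pos, matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE),
            ap2, bonds, ap2_free = 0)
}

test_that("cluster detection partitions the bond graph correctly", {
  # inert frame: no clusters
  f0 <- make_frame(matrix(runif(30, 0, 500), 10, 3))
  expect_equal(nrow(find_clusters(f0)), 0)

  # chain A-B-C with AP-2 on A: one membrane cluster, 3 clathrins, 1 AP-2
  pos <- rbind(c(100, 100, 2), c(130, 100, 2), c(160, 100, 2),
               c(400, 400, 400))
  bonds <- rbind(c(1L, 1L, 2L, 1L), c(2L, 2L, 3L, 1L))
  f <- make_frame(pos, bonds, ap2 = c(1L, 0L, 0L, 0L))
  cl <- find_clusters(f)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_clathrin, 3)
  expect_equal(cl$n_ap2, 1)
  expect_true(cl$is_membrane_bound)
  expect_false(cl$is_large)
  expect_setequal(cl$member_ids[[1]], 1:3)

  # an AP-2-bound monomer is a membrane cluster of one
  f2 <- make_frame(pos[1:2, ], ap2 = c(1L, 0L))
  cl2 <- find_clusters(f2)
  expect_equal(cl2$n_clathrin, 1)
  expect_true(cl2$is_membrane_bound)

  # every membrane-bound cluster contains at least one AP-2 by construction
  expect_true(all(cl$n_ap2[cl$is_membrane_bound] >= 1))
})

test_that("cluster detection agrees with a transitive-closure oracle", {
  set.seed(77)
  for (trial in 1:500) {
    n <- sample(2:50, 1)
    n_edges <- sample(0:min(60, n * 3 / 2), 1)
    # random matching over leg slots to keep each leg bound at most once
    free <- cbind(rep(1:n, each = 3), rep(1:3, n))
    edges <- matrix(0L, 0, 4)
    for (e in seq_len(n_edges)) {
      if (nrow(free) < 2) break
      k1 <- sample(nrow(free), 1)
      s1 <- free[k1, ]
      free <- free[-k1, , drop = FALSE]
      cand <- which(free[, 1] != s1[1])
      if (length(cand) == 0) break
      k2 <- cand[sample(length(cand), 1)]
      s2 <- free[k2, ]
      free <- free[-k2, , drop = FALSE]
      a <- min(s1[1], s2[1]); b <- max(s1[1], s2[1])
      sa <- if (a == s1[1]) s1[2] else s2[2]
      sb <- if (b == s2[1]) s2[2] else s1[2]
      edges <- rbind(edges, c(a, sa, b, sb))
    }
    pos <- matrix(runif(3 * n, 0, 1000), n, 3)
    ap2 <- as.integer(runif(n) < 0.3)
    f <- make_frame(pos, edges, ap2)
    cl <- find_clusters(f)

    comp <- brute_force_components(n, edges[, c(1, 3), drop = FALSE])
    in_play <- union(unique(as.integer(edges[, c(1, 3)])), which(ap2 == 1))
    expected_sets <- unname(split(seq_len(n), comp))
    expected_sets <- Filter(function(s) any(s %in% in_play), expected_sets)
    got_sets <- lapply(cl$member_ids, sort)
    expect_setequal(lapply(expected_sets, paste, collapse = ","),
                    lapply(got_sets, paste, collapse = ","))
  }
})

test_that("membrane-bound count equals an independent recount", {
  set.seed(5)
  pos <- matrix(runif(60, 0, 500), 20, 3)
  bonds <- rbind(c(1L, 1L, 2L, 1L), c(2L, 2L, 3L, 1L), c(5L, 1L, 6L, 1L))
  ap2 <- integer(20)
  ap2[c(1, 9)] <- 1L
  f <- make_frame(pos, bonds, ap2)
  # chain 1-2-3 via AP-2 on 1 (3 clathrins) + monomer 9 (1) = 4;
  # pair 5-6 has no AP-2 and does not count
  expect_equal(membrane_bound_clathrin_count(f), 4)
  expect_lte(membrane_bound_clathrin_count(f), f$n_clathrin)
  f_none <- make_frame(pos, bonds, integer(20))
  expect_equal(membrane_bound_clathrin_count(f_none), 0)
})

test_that("cluster areas match the hull-plus-dilation oracle", {
  r <- 12.5
  # degenerate hull: single clathrin footprint
  expect_equal(cluster_area(rbind(c(0, 0, 2)), r), pi * r^2 * 1e-6)
  expect_equal(cluster_area(rbind(c(0, 0, 2)), r), 4.9e-4, tolerance = 1e-2)

  # right triangle (0,0), (50,0), (0,50): shoelace + buffer oracle
  tri <- rbind(c(0, 0, 2), c(50, 0, 2), c(0, 50, 2))
  hull_area <- shoelace_area(tri[, 1:2])
  per <- 50 + 50 + sqrt(2) * 50
  expect_equal(cluster_area(tri, r),
               (hull_area + per * r + pi * r^2) * 1e-6, tolerance = 1e-12)
  expect_equal(hull_area, 1250)

  # collinear members: segment buffer
  seg <- rbind(c(0, 0, 2), c(30, 0, 2), c(60, 0, 2))
  expect_equal(cluster_area(seg, r), (2 * 60 * r + pi * r^2) * 1e-6)

  # monotone non-decreasing under adding a member
  set.seed(8)
  pts <- matrix(runif(40, 0, 200), 20, 2)
  pts <- cbind(pts, 2)
  areas <- vapply(2:20, function(k) cluster_area(pts[1:k, ], r), numeric(1))
  expect_true(all(diff(areas) >= -1e-12))
})

test_that("t_c is the first crossing of the 90 % plateau", {
  # constant positive series: immediately above threshold
  expect_equal(compute_tc(rep(50, 10), 0:9), 0)
  # fine linear ramp 0 -> 100 over 0-30 min: crossing just above 27 min
  times <- seq(0, 30, by = 0.01)
  counts <- 100 * times / 30
  expect_equal(compute_tc(counts, times), 27, tolerance = 0.05)
  expect_gt(compute_tc(counts, times), 27)  # strictly above 90
  # degenerate all-zero series: undefined
  expect_true(is.na(compute_tc(rep(0, 5), 1:5)))
})

test_that("pattern statistics pick the modal cluster number", {
  p <- pattern_statistics(rep(3L, 12))
  expect_equal(p$most_possible_pattern, 3)
  expect_equal(unname(p$frequencies), 1)

  series <- c(rep(1L, 10), rep(2L, 30), rep(3L, 5))
  p2 <- pattern_statistics(series)
  expect_equal(p2$most_possible_pattern, 2)
  expect_equal(unname(p2$frequencies["2"]), 30 / 45)
  expect_equal(sum(p2$frequencies), 1)
  expect_true(p2$most_possible_pattern %in% series)

  # ties break toward the smaller cluster number
  expect_equal(pattern_statistics(c(2L, 2L, 4L, 4L))$most_possible_pattern, 2)
  expect_error(pattern_statistics(integer(0)), "at least one frame")
})

test_that("mean cluster size averages the counted clusters only", {
  cl <- data.frame(n_clathrin = c(20, 15, 3),
                   is_membrane_bound = c(TRUE, TRUE, TRUE),
                   is_large = c(TRUE, TRUE, FALSE),
                   area = c(0.02, 0.04, 0.001))
  expect_equal(mean_cluster_size(clusters = cl), 0.03)
  one <- data.frame(n_clathrin = 20, is_membrane_bound = TRUE,
                    is_large = TRUE, area = 0.05)
  expect_equal(mean_cluster_size(clusters = one), 0.05)
  none <- data.frame(n_clathrin = 3, is_membrane_bound = TRUE,
                     is_large = FALSE, area = 0.001)
  expect_true(is.na(mean_cluster_size(clusters = none)))
})

test_that("dwelling times are run lengths with boundary censoring", {
  times <- seq(0, by = 0.1, length.out = 6) / 60  # 0.1 s frames, minutes
  dw <- dwelling_times(c(1L, 1L, 2L, 2L, 2L, 1L), times)
  expect_equal(nrow(dw), 3)
  expect_equal(dw$censored, c(TRUE, FALSE, TRUE))
  # interior dwell of pattern 2: three frames of 0.1 s
  expect_equal(dw$duration[2] * 60, 0.3, tolerance = 1e-12)
  d2 <- dwelling_times(c(1L, 1L, 2L, 2L, 2L, 1L), times, pattern = 2)
  expect_equal(nrow(d2), 1)
  # total dwell (censored included) equals the window length exactly
  expect_equal(sum(dw$duration) * 60, 0.6, tolerance = 1e-12)

  # single constant run: one censored dwell spanning the series
  dw1 <- dwelling_times(rep(4L, 100), seq(0, 9.9, by = 0.1))
  expect_equal(nrow(dw1), 1)
  expect_true(dw1$censored)
})

test_that("trajectory summaries assemble the per-frame statistics", {
  cfg <- desk_config(n_ap2 = 25, seed = 6, duration = 6e5,
                     frame_interval = 3e4)
  traj <- run_simulation(cfg)
  s <- analyze_trajectory(traj)
  expect_equal(nrow(s$per_frame), length(traj$frames))
  expect_true(all(s$per_frame$membrane_bound <= cfg$n_clathrin))
  if (!is.na(s$t_c)) {
    expect_equal(sum(s$pattern_frequencies), 1)
    expect_true(s$most_possible_pattern %in%
                  s$per_frame$n_counted_clusters)
  }
  # summaries are invariant under re-analysis (pure function of the frames)
  s2 <- analyze_trajectory(traj)
  expect_identical(s$per_frame, s2$per_frame)
})
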