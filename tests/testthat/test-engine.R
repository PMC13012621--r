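test_that("reflection mirrors coordinates into the closed box", {
  L <- 1000
  expect_equal(reflect_into_domain(c(10, 500, 990), L), c(10, 500, 990))
  expect_equal(reflect_into_domain(c(1.2 * L, 0, 0), L)[1], 0.8 * L)
  expect_equal(reflect_into_domain(c(-0.3 * L, 0, 0), L)[1], 0.3 * L)
  # two mirrors: 2.5L -> 1.5L' (at L) -> ... -> 0.5L
  expect_equal(reflect_into_domain(c(2.5 * L, 0, 0), L)[1], 0.5 * L)
  expect_error(reflect_into_domain(c(NaN, 0, 0), L), "non-finite")
  # result always inside for random out-of-box points
  set.seed(4)
  pts <- matrix(runif(300, -3 * L, 4 * L), ncol = 3)
  r <- reflect_into_domain(pts, L)
  expect_true(all(r >= 0 & r <= L))
})

test_that("diffusion proposals have the prescribed moments and zero-D limit", {
  spec0 <- diffusion_spec(c(0, 0, 0), c(0, 0, 0))
  m <- diffusion_step(c(1, 2, 3), c(1, 0, 0, 0), spec0, dt = 3)
  expect_equal(m$position, c(1, 2, 3))
  expect_equal(m$orientation, c(1, 0, 0, 0))

  # anisotropic spec: zero axes stay exactly zero, active axes match 2 D dt
  spec <- diffusion_spec(c(13, 13, 0), c(0, 0, 0.03))
  set.seed(9)
  disp <- t(replicate(5000, diffusion_step(c(0, 0, 0), c(1, 0, 0, 0),
                                           spec, dt = 3)$displacement))
  expect_true(all(disp[, 3] == 0))
  v <- apply(disp[, 1:2], 2, var)
  se <- 2 * 13 * 3 * sqrt(2 / 5000)
  expect_true(all(abs(v - 2 * 13 * 3) < 3 * se))
})

test_that("overlap resolution resamples conflicts and falls back to no move", {
  cur <- rbind(c(0, 0, 0), c(30, 0, 0))
  # proposals 8 nm apart: at least one must be resampled
  prop <- rbind(c(0, 0, 0), c(8, 0, 0))
  calls <- 0
  res <- resolve_overlaps(cur, prop, 10, resample = function(i) {
    calls <<- calls + 1
    cur[i, ] + c(20, 0, 0)
  })
  expect_gt(calls, 0)
  expect_gte(min(dist(res)), 10)

  # max_retries = 0: conflicting entities keep the pre-move pose
  res0 <- resolve_overlaps(cur, prop, 10, resample = function(i) prop[i, ],
                           max_retries = 0)
  expect_gte(min(dist(res0)), 10)
  expect_equal(res0, cur)

  # single entity: always accepted
  expect_equal(resolve_overlaps(cur[1, , drop = FALSE],
                                prop[1, , drop = FALSE], 10,
                                resample = function(i) stop("no")),
               prop[1, , drop = FALSE])
  expect_error(resolve_overlaps(rbind(c(0, 0, 0), c(5, 0, 0)), prop, 10,
                                resample = function(i) prop[i, ]),
               "already contains overlaps")
})

test_that("associations extending beyond the domain are rejected, faces included", {
  L <- 1000
  expect_false(reject_out_of_domain_association(rbind(c(500, 500, 500)), L))
  expect_true(reject_out_of_domain_association(rbind(c(500, 500, -2)), L))
  expect_true(reject_out_of_domain_association(rbind(c(500, 1001, 500)), L))
  # exactly on a face: accepted (closed domain)
  expect_false(reject_out_of_domain_association(rbind(c(0, 1000, 500)), L))
})

test_that("schedules resolve to piecewise-constant effective parameters", {
  min30 <- 30 * 60 * 1e6
  sch <- parameter_schedule(list(
    list(time = 0, n_ap2 = 200, k_cc_gated_mult = 50, d_clat_mult = 1 / 50),
    list(time = min30, n_ap2 = 100, k_cc_gated_mult = 1, d_clat_mult = 1)))
  cfg <- simulation_config(n_ap2 = 100, schedule = sch)

  # protocol in force on (0, 30 min)
  eff <- apply_schedule(cfg, 15 * 60 * 1e6)
  expect_equal(eff$n_ap2, 200L)
  expect_equal(eff$rates$k_cc_gated, cfg$rates$k_cc_gated * 50)
  expect_equal(eff$d_clat$d_trans, cfg$diffusion$clathrin$d_trans / 50)

  # reversal after 30 min
  eff2 <- apply_schedule(cfg, min30 + 1)
  expect_equal(eff2$n_ap2, 100L)
  expect_equal(eff2$rates$k_cc_gated, cfg$rates$k_cc_gated)
  expect_equal(eff2$d_clat$d_trans, cfg$diffusion$clathrin$d_trans)

  # before any breakpoint: baseline
  cfg2 <- simulation_config(n_ap2 = 100, schedule = parameter_schedule(
    list(list(time = 1e6, n_ap2 = 400))))
  expect_equal(apply_schedule(cfg2, 0)$n_ap2, 100L)

  expect_error(parameter_schedule(list(list(time = 0, bogus = 1))),
               "unknown schedule override")
  expect_error(parameter_schedule(list(list(time = 5), list(time = 5))),
               "strictly increasing")
})

test_that("the engine honours a mid-run AP-2 pool change", {
  cfg <- desk_config(n_ap2 = 10, duration = 6e3, frame_interval = 3e3)
  cfg$schedule <- parameter_schedule(list(list(time = 3e3, n_ap2 = 40)))
  st <- random_initial_condition(cfg, seed = 1)
  out <- engine_run(st, cfg, n_steps = 2000L, seed = 1)
  expect_equal(out$state$ap2_total, 40L)
  expect_equal(out$state$ap2_free + sum(out$state$ap2_bound),
               out$state$ap2_total)
})

test_that("runs are deterministic, conservative and stay inside the box", {
  cfg <- desk_config(n_ap2 = 25, seed = 42, duration = 6e4,
                     frame_interval = 6e3)  # 2e4 steps, 10 frames
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  # bit-identical repetition
  expect_identical(t1$frames, t2$frames)

  for (f in t1$frames) {
    expect_equal(f$n_clathrin, 60)
    expect_true(all(f$pos >= -1e-9 & f$pos <= cfg$box_edge + 1e-9))
    expect_equal(f$ap2_free + sum(f$ap2_bound), 25)
    if (nrow(f$bonds) > 0) {
      expect_true(all(f$bonds[, "mol_a"] < f$bonds[, "mol_b"]))
    }
    # excluded volume: no clathrin pair closer than 10 nm
    expect_gte(min(dist(f$pos)), 10 - 1e-9)
    # membrane-bound clathrins lie flat at the binding height
    flat <- which(f$ap2_bound != 0)
    if (length(flat) > 0) {
      expect_lt(max(abs(f$pos[flat, 3] - 2)), 1e-6)
    }
  }

  # sub-step duration: only the initial frame
  cfg0 <- desk_config(n_ap2 = 5, duration = 1, frame_interval = 3)
  t0 <- run_simulation(cfg0)
  expect_length(t0$frames, 1)
  expect_equal(t0$frames[[1]]$time_us, 0)
})

test_that("with all rates zero only positions change (pure diffusion limit)", {
  cfg <- desk_config(n_ap2 = 0, k_cc_gated = 0, k_ap2_clat = 0,
                     koff_cc = 0, koff_ap2_clat = 0,
                     duration = 1.5e4, frame_interval = 3)
  traj <- run_simulation(cfg)
  expect_true(all(vapply(traj$frames, function(f) nrow(f$bonds), 1L) == 0))
  expect_true(all(traj$event_counts == 0))

  # per-axis frame-to-frame displacement of each molecule is Gaussian with
  # variance 2 D dt_frame; increments touching the walls are excluded
  # because reflection folds their distribution
  pos <- vapply(traj$frames, function(f) f$pos, traj$frames[[1]]$pos)
  x <- c()
  for (a in 1:3) {
    p <- t(pos[, a, ])               # frames x molecules
    inc <- diff(p)
    ok <- p[-nrow(p), ] > 60 & p[-nrow(p), ] < 440 &
      p[-1, ] > 60 & p[-1, ] < 440
    x <- c(x, inc[ok])
  }
  expect_gt(length(x), 1e4)
  v_target <- 2 * 13 * 3
  # 2 % band: generous for sampling noise, far below any coefficient error
  expect_lt(abs(var(x) - v_target) / v_target, 0.02)
  set.seed(1)
  sub <- sample(x, 5000)
  ks <- suppressWarnings(stats::ks.test(sub / sqrt(v_target), "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bound-pair geometry from live simulation frames is exact", {
  # run an assembly-heavy desk simulation and measure every bond in every
  # frame: site separation must equal the 5 nm bond gap
  cfg <- desk_config(n_ap2 = 25, seed = 3, duration = 3e5,
                     frame_interval = 3e4)
  traj <- run_simulation(cfg)
  geom <- cfg$geometry
  n_checked <- 0
  for (f in traj$frames) {
    if (nrow(f$bonds) == 0) next
    for (k in seq_len(nrow(f$bonds))) {
      a <- f$bonds[k, "mol_a"]; b <- f$bonds[k, "mol_b"]
      ma <- rigid_molecule(a, "clathrin", f$pos[a, ], f$quat[a, ])
      mb <- rigid_molecule(b, "clathrin", f$pos[b, ], f$quat[b, ])
      sa <- site_world_coordinates(ma, geom)[f$bonds[k, "site_a"], ]
      sb <- site_world_coordinates(mb, geom)[f$bonds[k, "site_b"], ]
      expect_equal(sqrt(sum((sa - sb)^2)), geom$bond_gap, tolerance = 1e-6)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})
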