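test_that("Stokes-Einstein coefficients follow the closed forms and scaling laws", {
  env <- physical_environment(temperature = 298.15, viscosity = 8.9e-4)

  # independent hand evaluation of k_B T / (6 pi eta r) at r = 1 nm
  kBT <- 1.380649e-23 * 298.15
  d_si <- kBT / (6 * pi * 8.9e-4 * 1e-9)        # m^2/s
  expect_equal(stokes_einstein(1, env, "translational"), d_si * 1e12,
               tolerance = 1e-12)
  expect_equal(d_si * 1e12, 245.4, tolerance = 1e-3)  # ~2.45e2 um^2/s

  r_si <- kBT / (8 * pi * 8.9e-4 * (1e-9)^3)    # rad^2/s
  expect_equal(stokes_einstein(1, env, "rotational"), r_si * 1e-6,
               tolerance = 1e-12)

  # 1/r and 1/r^3 scaling
  expect_equal(stokes_einstein(1, env) / stokes_einstein(2, env), 2)
  expect_equal(stokes_einstein(1, env, "rotational") /
                 stokes_einstein(2, env, "rotational"), 8)

  expect_error(stokes_einstein(0, env), "radius")
  expect_error(stokes_einstein(-1, env), "radius")
  expect_error(physical_environment(temperature = -1), "temperature")
})

test_that("cluster diffusion composition matches the harmonic closed forms", {
  env <- physical_environment()
  cl <- clathrin_diffusion(env, d_iso = 13)

  # singleton: unchanged
  one <- compose_cluster_diffusion(list(cl))
  expect_equal(one$d_trans, cl$d_trans)
  expect_equal(one$d_rot, cl$d_rot)

  # two identical members: D/2 translational, D_R/8 rotational
  two <- compose_cluster_diffusion(list(cl, cl))
  expect_equal(two$d_trans, cl$d_trans / 2)
  expect_equal(two$d_rot, cl$d_rot / 8)

  # n identical members: D/n and D_R/n^3
  for (n in 1:6) {
    comp <- compose_cluster_diffusion(rep(list(cl), n))
    expect_equal(comp$d_trans, cl$d_trans / n)
    expect_equal(comp$d_rot, cl$d_rot / n^3, tolerance = 1e-12)
  }

  # membrane confinement: one AP-2 zeroes z-translation and x/y-rotation
  ap2 <- ap2_diffusion(env)
  mix <- compose_cluster_diffusion(list(ap2, cl, cl))
  expect_identical(mix$d_trans[3], 0)
  expect_identical(mix$d_rot[1], 0)
  expect_identical(mix$d_rot[2], 0)
  expect_gt(mix$d_trans[1], 0)
  expect_gt(mix$d_rot[3], 0)

  # monotone shrinkage: composition never exceeds the member minimum
  set.seed(42)
  for (rep in 1:20) {
    specs <- lapply(1:sample(2:5, 1), function(i) {
      diffusion_spec(runif(3, 0, 20), runif(3, 0, 1))
    })
    comp <- compose_cluster_diffusion(specs)
    mins_t <- do.call(pmin, lapply(specs, function(s) s$d_trans))
    mins_r <- do.call(pmin, lapply(specs, function(s) s$d_rot))
    expect_true(all(comp$d_trans <= mins_t + 1e-12))
    expect_true(all(comp$d_rot <= mins_r + 1e-12))
  }

  expect_error(compose_cluster_diffusion(list()), "non-empty")
})

test_that("site coordinates are rigid and respect the pinwheel symmetry", {
  geom <- clathrin_geometry()
  mol <- rigid_molecule(1, "clathrin", position = c(10, 20, 30))

  # identity orientation: offsets added verbatim
  s <- site_world_coordinates(mol, geom)
  expect_equal(s["leg1", ], c(10, 20, 30) + geom$leg_site_offsets[1, ])
  expect_equal(s["ap2", ], c(10, 20, 30) + geom$ap2_site_offset)

  # 120 degree rotation about the AP-2-site axis permutes the legs
  q120 <- quat_from_axis_angle(c(0, 0, 1), 2 * pi / 3)
  rot <- rigid_molecule(1, "clathrin", position = c(10, 20, 30),
                        orientation = q120)
  s2 <- site_world_coordinates(rot, geom)
  expect_lt(max(abs(s2["leg1", ] - s["leg2", ])), 1e-9)
  expect_lt(max(abs(s2["leg2", ] - s["leg3", ])), 1e-9)
  expect_lt(max(abs(s2["leg3", ] - s["leg1", ])), 1e-9)
  expect_lt(max(abs(s2["ap2", ] - s["ap2", ])), 1e-9)

  # rigidity: pairwise site distances invariant over random orientations
  set.seed(7)
  ref_d <- dist(s)
  qs <- random_quaternion(1000)
  for (k in seq_len(nrow(qs))) {
    m <- rigid_molecule(1, "clathrin",
                        position = runif(3, 0, 100), orientation = qs[k, ])
    expect_lt(max(abs(dist(site_world_coordinates(m, geom)) - ref_d)), 1e-9)
  }
})

test_that("head-to-head binding places the partner at the exact bond gap, coplanar", {
  geom <- clathrin_geometry()
  set.seed(11)
  for (rep in 1:25) {
    q <- random_quaternion(1)[1, ]
    a <- rigid_molecule(1, "clathrin", position = runif(3, 100, 900),
                        orientation = q)
    site <- sample(1:3, 1)
    b <- place_bound_partner(a, site, "clathrin_clathrin", geom,
                             partner_id = 2)
    sa <- site_world_coordinates(a, geom)[site, ]
    sb <- site_world_coordinates(b, geom)[1, ]
    # bound sites separated by exactly the 5 nm bond gap
    expect_equal(sqrt(sum((sa - sb)^2)), geom$bond_gap, tolerance = 1e-9)
    # centers at least the excluded diameter apart
    expect_gte(sqrt(sum((a$position - b$position)^2)),
               geom$excluded_diameter)
    # both centers and all six leg sites coplanar (within 1e-6 nm)
    pts <- rbind(a$position, b$position,
                 site_world_coordinates(a, geom)[1:3, ],
                 site_world_coordinates(b, geom)[1:3, ])
    centered <- sweep(pts, 2, colMeans(pts))
    sv <- svd(centered)$d
    expect_lt(sv[3], 1e-6)
    # AP-2 axes of the two bodies point to the same side of the plane
    na <- quat_rotate(a$orientation, c(0, 0, 1))
    nb <- quat_rotate(b$orientation, c(0, 0, 1))
    expect_equal(sum(na * nb), 1, tolerance = 1e-9)
  }
})

test_that("AP-2 binding flattens the clathrin onto the membrane", {
  geom <- clathrin_geometry()
  set.seed(3)
  for (rep in 1:25) {
    a <- rigid_molecule(5, "clathrin",
                        position = c(runif(2, 100, 400), runif(1, 2, 12)),
                        orientation = random_quaternion(1)[1, ])
    res <- place_bound_partner(a, 1, "clathrin_ap2", geom, partner_id = 9)
    # AP-2-site axis perpendicular to the membrane
    axis <- quat_rotate(res$clathrin$orientation, c(0, 0, -1))
    expect_equal(abs(axis[3]), 1, tolerance = 1e-9)
    # AP-2 on the membrane, directly beneath the site
    s <- site_world_coordinates(res$clathrin, geom)["ap2", ]
    expect_equal(s[3], 0, tolerance = 1e-9)
    expect_equal(res$ap2$position, c(s[1], s[2], 0), tolerance = 1e-9)
    # leg plane parallel to the membrane
    legs <- site_world_coordinates(res$clathrin, geom)[1:3, ]
    expect_lt(diff(range(legs[, 3])), 1e-9)
  }
})

test_that("six clathrins bound in a planar ring close the hexagon", {
  geom <- clathrin_geometry()
  set.seed(19)
  a <- rigid_molecule(1, "clathrin", position = c(500, 500, 500),
                      orientation = random_quaternion(1)[1, ])
  ring <- list(a)
  # walk around the ring: bind via leg 2 each time so consecutive bond
  # directions turn by 120 degrees in the shared plane
  for (k in 2:6) {
    ring[[k]] <- place_bound_partner(ring[[k - 1]], 2, "clathrin_clathrin",
                                     geom, partner_id = k)
  }
  virtual7 <- place_bound_partner(ring[[6]], 2, "clathrin_clathrin", geom,
                                  partner_id = 7)
  # the 7th placement lands back on the 1st: closure of the 120-degree
  # planar geometry
  expect_lt(sqrt(sum((virtual7$position - ring[[1]]$position)^2)),
            geom$bond_gap)
  # centers form a regular hexagon of side 2*leg_radius + bond_gap
  centers <- t(vapply(ring, function(m) m$position, numeric(3)))
  side <- 2 * geom$leg_radius + geom$bond_gap
  for (k in 1:6) {
    d <- sqrt(sum((centers[k, ] - centers[k %% 6 + 1, ])^2))
    expect_equal(d, side, tolerance = 1e-9)
  }
})

test_that("rigid molecule constructor enforces its invariants", {
  expect_error(rigid_molecule(1, "clathrin", orientation = c(1, 1, 0, 0)),
               "unit quaternion")
  expect_error(rigid_molecule(1, "ap2", position = c(0, 0, 5)), "membrane")
  expect_error(rigid_molecule(1, "clathrin",
                              bonds = list(c(1, 2, 1), c(1, 3, 2))),
               "at most once")
})
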