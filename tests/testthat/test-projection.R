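arr <- electrode_array()
Rc <- arr$cuff_inner_diameter_mm / 2

test_that("nearest_electrode matches collinear geometry and tie-breaks to pair 1", {
  # fascicle on pad 3's radius at 0.8 R_cuff: distance 0.2 R_cuff
  a3 <- arr$pad_angles_deg[3] * pi / 180
  f <- list(fascicle_id = "f", center_x_mm = 0.8 * Rc * sin(a3),
            center_y_mm = 0.8 * Rc * cos(a3), radius_mm = 0.05)
  ne <- nearest_electrode(f, arr)
  expect_equal(ne$pair_index, 3L)
  expect_equal(ne$distance_mm, 0.2 * Rc, tolerance = 1e-12)

  # exact center: all pads equidistant, tie to pair 1
  ctr <- list(fascicle_id = "c", center_x_mm = 0, center_y_mm = 0,
              radius_mm = 0.05)
  ne <- nearest_electrode(ctr, arr)
  expect_equal(ne$pair_index, 1L)
  expect_equal(ne$distance_mm, Rc, tolerance = 1e-12)
})

test_that("nearest_electrode agrees with an exhaustive distance scan", {
  set.seed(31)
  for (i in 1:60) {
    th <- runif(1, 0, 2 * pi); r <- runif(1, 0, 0.9)
    f <- list(fascicle_id = "f", center_x_mm = r * sin(th),
              center_y_mm = r * cos(th), radius_mm = 0.05)
    got <- nearest_electrode(f, arr)
    want <- oracle_nearest(f$center_x_mm, f$center_y_mm, arr)
    expect_equal(got$pair_index, want$pair_index)
    expect_equal(got$distance_mm, want$distance_mm, tolerance = 1e-12)
  }
})

test_that("project_fascicle preserves the nearest-electrode radial distance", {
  # touching the cuff under pad 7
  a7 <- arr$pad_angles_deg[7] * pi / 180
  f <- list(fascicle_id = "f", center_x_mm = (Rc - 1e-9) * sin(a7),
            center_y_mm = (Rc - 1e-9) * cos(a7), radius_mm = 0.05)
  pl <- project_fascicle(f, arr)
  expect_equal(pl$r_norm, 1, tolerance = 1e-6)
  expect_equal(pl$theta_deg, arr$pad_angles_deg[7], tolerance = 1e-6)
  expect_equal(pl$nearest_pair, 7L)

  # degenerate center convention
  ctr <- list(fascicle_id = "c", center_x_mm = 0, center_y_mm = 0,
              radius_mm = 0.05)
  pl <- project_fascicle(ctr, arr)
  expect_equal(pl$r_norm, 0)
  expect_equal(pl$theta_deg, 0)

  # identity: R_cuff * (1 - r_norm) equals the nearest-electrode distance
  set.seed(32)
  for (i in 1:40) {
    th <- runif(1, 0, 2 * pi); r <- runif(1, 0, 0.9)
    f <- list(fascicle_id = "f", center_x_mm = r * sin(th),
              center_y_mm = r * cos(th), radius_mm = 0.05)
    pl <- project_fascicle(f, arr)
    expect_equal(Rc * (1 - pl$r_norm), nearest_electrode(f, arr)$distance_mm,
                 tolerance = 1e-12)
  }

  # pad-snapped angular mode for sensitivity analysis
  pl <- project_fascicle(f, arr, angle = "pad")
  expect_equal(pl$theta_deg, arr$pad_angles_deg[pl$nearest_pair])
})

test_that("group maps rasterize disks with correct area and union semantics", {
  # no cardiac fascicles: all-zero map with a warning
  nerve <- make_nerve(90, 0.5, organ = "pulmonary", class = "afferent")
  expect_warning(m <- build_group_map(nerve, arr, "cardiac_efferent", 64),
                 "all-zero")
  expect_true(all(m$values == 0))

  # centered fascicle of normalized radius 0.1 on a 256 grid: pixel count
  # within 5% of the analytic disk area
  nerve <- make_nerve(0, 0, radius_mm = 0.1 * Rc)
  m <- build_group_map(nerve, arr, "cardiac_efferent", 256)
  expect_lt(abs(sum(m$values) - pi * (0.1 * 128)^2) / (pi * (0.1 * 128)^2),
            0.05)

  # overlapping fascicles never exceed 1
  nerve <- make_nerve(c(40, 42), c(0.5, 0.5), radius_mm = 0.15)
  m <- build_group_map(nerve, arr, "cardiac_efferent", 64)
  expect_true(all(m$values %in% c(0, 1)))
})

test_that("group maps match per-pixel point-in-disk enumeration exactly", {
  set.seed(33)
  for (rep in 1:4) {
    k <- sample(1:5, 1)
    nerve <- make_nerve(runif(k, 0, 360), runif(k, 0, 0.7),
                        radius_mm = runif(k, 0.04, 0.12))
    m <- build_group_map(nerve, arr, "cardiac_efferent", 64)
    expect_identical(m$values, oracle_group_map(nerve, arr,
                                                "cardiac_efferent", 64))
  }
})

test_that("alignment sends the cardiac efferent CoM to 0 and is idempotent", {
  nerve <- make_nerve(c(90, 250), c(0.5, 0.6),
                      organ = c("cardiac", "cardiopulmonary"),
                      class = c("efferent", "afferent"))
  maps <- list(
    cardiac_efferent = build_group_map(nerve, arr, "cardiac_efferent", 128),
    cardiac_afferent = build_group_map(nerve, arr, "cardiac_afferent", 128))
  expect_equal(center_of_mass(maps$cardiac_efferent)$angle_deg, 90,
               tolerance = 1)
  aligned <- align_maps(maps)
  a0 <- center_of_mass(aligned$cardiac_efferent)$angle_deg
  expect_lt(angular_difference(a0, 0), 1)

  # pixel census preserved within 2% by the resampling
  for (g in names(maps)) {
    expect_lt(abs(sum(aligned[[g]]$values) - sum(maps[[g]]$values)) /
                sum(maps[[g]]$values), 0.02)
  }

  # aligning an aligned set changes nothing but metadata noise
  again <- align_maps(aligned)
  expect_lt(angular_difference(
    center_of_mass(again$cardiac_efferent)$angle_deg, 0), 1)
  expect_lt(mean(abs(again$cardiac_afferent$values -
                       aligned$cardiac_afferent$values)), 0.02)

  # no reference: error
  empty <- suppressWarnings(build_group_map(
    make_nerve(0, 0.4, organ = "pulmonary", class = "afferent"),
    arr, "cardiac_efferent", 64))
  expect_error(align_maps(list(cardiac_efferent = empty)), "all zero")
})

test_that("rotating a nerve rotates unaligned CoMs equivariantly and leaves aligned maps invariant", {
  set.seed(34)
  base_theta <- c(80, 200, 210)
  base_r <- c(0.5, 0.55, 0.4)
  for (delta in c(30, 123.4, 260)) {
    n0 <- make_nerve(base_theta, base_r,
                     organ = c("cardiac", "cardiopulmonary",
                               "cardiopulmonary"),
                     class = c("efferent", "afferent", "afferent"))
    n1 <- make_nerve(base_theta + delta, base_r,
                     organ = c("cardiac", "cardiopulmonary",
                               "cardiopulmonary"),
                     class = c("efferent", "afferent", "afferent"))
    m0 <- build_group_map(n0, arr, "cardiac_afferent", 128)
    m1 <- build_group_map(n1, arr, "cardiac_afferent", 128)
    c0 <- center_of_mass(m0)$angle_deg
    c1 <- center_of_mass(m1)$angle_deg
    expect_lt(angular_difference(c1, c0 + delta), 1)

    a0 <- align_maps(list(
      cardiac_efferent = build_group_map(n0, arr, "cardiac_efferent", 128),
      cardiac_afferent = m0))
    a1 <- align_maps(list(
      cardiac_efferent = build_group_map(n1, arr, "cardiac_efferent", 128),
      cardiac_afferent = m1))
    expect_lt(angular_difference(
      center_of_mass(a1$cardiac_afferent)$angle_deg,
      center_of_mass(a0$cardiac_afferent)$angle_deg), 1.5)
  }
})
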