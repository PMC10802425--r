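arr <- electrode_array()

disk_map_at <- function(theta, r, radius = 0.1, grid = 256,
                        group = "cardiac_efferent", animal = "A1") {
  organ <- switch(group, cardiac_efferent = "cardiac",
                  cardiac_afferent = "cardiopulmonary",
                  pulmonary = "pulmonary",
                  laryngeal = "recurrent_laryngeal")
  cls <- if (group == "cardiac_efferent") "efferent" else "afferent"
  nerve <- make_nerve(theta, r * (arr$cuff_inner_diameter_mm / 2),
                      radius_mm = radius * arr$cuff_inner_diameter_mm / 2,
                      organ = organ, class = cls)
  m <- build_group_map(nerve, arr, group, grid)
  m$animal_id <- animal
  m
}

test_that("center of mass recovers symmetric configurations", {
  m <- disk_map_at(30, 0.5)
  com <- center_of_mass(m)
  expect_lt(angular_difference(com$angle_deg, 30), 0.5)
  expect_equal(com$r_norm, 0.5, tolerance = 0.01)

  # two equal-weight disks at +40 and -40: CoM on the symmetry axis
  nerve <- make_nerve(c(40, 320), c(0.6, 0.6), radius_mm = 0.08)
  m2 <- build_group_map(nerve, arr, "cardiac_efferent", 256)
  expect_lt(angular_difference(center_of_mass(m2)$angle_deg, 0), 0.5)

  z <- circular_map(matrix(0, 32, 32), "pulmonary", "binary")
  expect_error(center_of_mass(z), "all-zero")
})

test_that("center of mass equals the direct-summation oracle", {
  set.seed(61)
  for (i in 1:5) {
    v <- matrix(0, 64, 64)
    mask <- disk_mask(64)
    idx <- sample(which(mask), 40)
    v[idx] <- rnorm(40)
    m <- circular_map(v, "pulmonary", "response")
    got <- center_of_mass(m)
    want <- oracle_com(m)
    expect_equal(got$angle_deg, want$angle_deg, tolerance = 1e-10)
    expect_equal(got$r_norm, want$r_norm, tolerance = 1e-12)
    expect_equal(got$weight_total, want$weight_total, tolerance = 1e-12)
  }
})

com_stub <- function(group, animal, angle) {
  structure(list(group = group, animal_id = animal, angle_deg = angle,
                 r_norm = 0.5, weight_total = 1), class = "com")
}

test_that("group separation is exact on noiseless antipodal cohorts and excludes unmatched animals", {
  coms <- c(lapply(1:5, function(i) com_stub("cardiac_efferent",
                                             sprintf("A%d", i), 0)),
            lapply(1:5, function(i) com_stub("cardiac_afferent",
                                             sprintf("A%d", i), 180)))
  s <- suppressWarnings(group_separation(coms, "cardiac_efferent",
                                         "cardiac_afferent"))
  expect_equal(s$mean_deg, 180)
  expect_equal(s$sd_deg, 0)
  expect_equal(s$n, 5)
  expect_equal(s$per_animal_separation_deg, rep(180, 5))

  # an animal with one CoM missing is excluded
  s4 <- suppressWarnings(group_separation(coms[-1], "cardiac_efferent",
                                          "cardiac_afferent"))
  expect_equal(s4$n, 4)
  expect_length(s4$per_animal_separation_deg, 4)

  expect_error(group_separation(coms[c(1, 6)], "cardiac_efferent",
                                "cardiac_afferent"), "at least 2")
})

test_that("group separation recovers a planted 180-degree split under rotation and noise", {
  # direct simulation of CoM angles: per-animal cuff rotation unknown,
  # wrapped-normal noise SD 30 degrees on each group's angle
  set.seed(62)
  reps <- 500; N <- 10
  means <- numeric(reps)
  for (r in seq_len(reps)) {
    rot <- runif(N, 0, 360)
    coms <- c(
      lapply(seq_len(N), function(i) com_stub("cardiac_efferent",
        sprintf("A%d", i), wrap_360(rot[i] + rnorm(1, 0, 30)))),
      lapply(seq_len(N), function(i) com_stub("cardiac_afferent",
        sprintf("A%d", i), wrap_360(rot[i] + 180 + rnorm(1, 0, 30)))))
    means[r] <- group_separation(coms, "cardiac_efferent",
                                 "cardiac_afferent")$mean_deg
  }
  se <- sd(means)
  expect_lt(abs(mean(means) - 180), 3 * se)
})

test_that("angular ANOVA separates distinct clusters and not identical ones", {
  # identical angle multisets in both groups: no effect
  df <- data.frame(
    group = rep(c("a", "b"), each = 5),
    animal_id = rep(sprintf("A%d", 1:5), 2),
    angle_deg = rep(c(10, 20, 30, 40, 50), 2))
  res <- angular_anova(df)
  expect_gte(res$pairwise$p_adj[1], 0.99)

  # two tight clusters 170 degrees apart
  set.seed(63)
  df2 <- data.frame(
    group = rep(c("a", "b"), each = 5),
    animal_id = rep(sprintf("A%d", 1:5), 2),
    angle_deg = wrap_360(c(rnorm(5, 350, 5), rnorm(5, 160, 5))))
  res2 <- angular_anova(df2)
  expect_lt(res2$pairwise$p_adj[1], 0.05)
  expect_lt(res2$omnibus_p, 0.05)

  # groups straddling the 0/360 boundary stay on one branch
  ww <- angular_anova(df2, method = "watson_williams")
  expect_lt(ww$pairwise$p_adj[1], 0.05)

  expect_error(angular_anova(df2[df2$group == "a", ]), ">= 2 groups")
  dfz <- df2; dfz$angle_deg <- rep(c(10, 200), each = 5)
  expect_warning(angular_anova(dfz), "degenerate")
})

test_that("area fraction matches analytic areas", {
  full <- circular_map(disk_mask(128) + 0, "pulmonary", "binary")
  expect_equal(area_fraction(full), 100)
  empty <- circular_map(matrix(0, 128, 128), "pulmonary", "binary")
  expect_equal(area_fraction(empty), 0)

  # centered disk at half the radius covers a quarter of the disk
  pgx <- matrix(rep(seq(-1 + 1 / 128, 1 - 1 / 128, length = 128), 128),
                128, byrow = TRUE)
  pgy <- t(pgx)[128:1, ]
  half <- circular_map((pgx^2 + pgy^2 <= 0.25) + 0, "pulmonary", "binary")
  expect_equal(area_fraction(half), 25, tolerance = 1)
})

test_that("overlap identities hold for identity, disjointness and containment", {
  A <- disk_map_at(0, 0.5, radius = 0.2, grid = 128)
  o <- overlap(A, A)
  expect_equal(o$overlap_pct_of_a, 100)
  expect_equal(o$overlap_pct_of_b, 100)

  B <- disk_map_at(180, 0.5, radius = 0.2, grid = 128,
                   group = "cardiac_afferent")
  od <- overlap(A, B)
  expect_equal(od$overlap_pct_of_a, 0)
  expect_equal(od$overlap_pct_of_b, 0)

  # A strictly inside B with half the pixel count: 100 / ~50
  Bbig <- disk_map_at(0, 0.5, radius = 0.2 * sqrt(2), grid = 256)
  Asub <- disk_map_at(0, 0.5, radius = 0.2, grid = 256)
  oc <- overlap(Asub, Bbig)
  expect_equal(oc$overlap_pct_of_a, 100)
  expect_equal(oc$overlap_pct_of_b, 50, tolerance = 2)

  # dilation monotonicity: growing B cannot shrink the overlap of A
  o1 <- overlap(A, disk_map_at(30, 0.5, radius = 0.15, grid = 128))
  o2 <- overlap(A, disk_map_at(30, 0.5, radius = 0.3, grid = 128))
  expect_gte(o2$overlap_pct_of_a, o1$overlap_pct_of_a)

  # empty region: own percentage undefined, reported NA
  empty <- circular_map(matrix(0, 128, 128), "laryngeal", "binary")
  oe <- overlap(empty, A)
  expect_true(is.na(oe$overlap_pct_of_a))
  expect_equal(oe$overlap_pct_of_b, 0)

  expect_error(overlap(A, disk_map_at(0, 0.5, grid = 64)), "grids")
})
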