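# Shared fixture builders and independent brute-force oracles.

# a hand-built nerve with fascicles at chosen polar positions
make_nerve <- function(theta_deg, r_mm, radius_mm = 0.08,
                       organ = "cardiac", class = "efferent",
                       nerve_radius_mm = sqrt(2.68 / pi),
                       animal_id = "T1") {
  n <- length(theta_deg)
  rad <- theta_deg * pi / 180
  nerve_section(
    nerve_id = animal_id, animal_id = animal_id,
    nerve_radius_mm = nerve_radius_mm,
    fascicles = data.frame(
      fascicle_id = sprintf("f%d", seq_len(n)),
      center_x_mm = r_mm * sin(rad), center_y_mm = r_mm * cos(rad),
      radius_mm = rep_len(radius_mm, n),
      organ_label = rep_len(organ, n),
      fiber_class = rep_len(class, n)))
}

# ground truth stub with fixed effects, for hand-built nerves
make_truth <- function(rotation_deg = 0, direction = "tachycardia",
                       hr_eff = 7.8, hr_aff = 10.2) {
  structure(list(
    animal_id = "T1", rotation_deg = rotation_deg,
    group_angles_deg = c(cardiac_efferent = rotation_deg,
                         cardiac_afferent = wrap_360(180 + rotation_deg),
                         pulmonary = wrap_360(180 + rotation_deg),
                         laryngeal = wrap_360(45 + rotation_deg)),
    afferent_direction = direction,
    effect_pct = c(HR_efferent = hr_eff,
                   HR_afferent_tachycardia = hr_aff,
                   HR_afferent_bradycardia = hr_aff,
                   BR = 73, EtCO2 = 30, EMG = 100)),
    class = "ground_truth")
}

# noiseless config for deterministic response checks
quiet_config <- function(...) {
  cfg <- synthetic_config(...)
  cfg$noise_sd[] <- 0
  cfg
}

# brute-force center of mass: plain double loop over all pixels
oracle_com <- function(map) {
  g <- map$grid_size
  step <- 2 / g
  sx <- sy <- sw <- 0
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      w <- abs(map$values[i, j])
      if (w == 0) next
      x <- -1 + (j - 0.5) * step
      y <- 1 - (i - 0.5) * step
      sx <- sx + w * x; sy <- sy + w * y; sw <- sw + w
    }
  }
  list(angle_deg = wrap_360(atan2(sx / sw, sy / sw) * 180 / pi),
       r_norm = sqrt((sx / sw)^2 + (sy / sw)^2), weight_total = sw)
}

# brute-force nearest pad: explicit scan over all pads
oracle_nearest <- function(x_mm, y_mm, array) {
  R <- array$cuff_inner_diameter_mm / 2
  best_j <- NA_integer_; best_d <- Inf
  for (j in seq_len(array$n_pairs)) {
    a <- array$pad_angles_deg[j] * pi / 180
    px <- R * sin(a); py <- R * cos(a)
    d <- sqrt((x_mm - px)^2 + (y_mm - py)^2)
    if (d < best_d - 1e-15) { best_d <- d; best_j <- j }
  }
  list(pair_index = best_j, distance_mm = best_d)
}

# brute-force group map: per-pixel point-in-disk enumeration over the
# projected fascicles
oracle_group_map <- function(nerve, array, group, grid_size) {
  organs <- group_membership(group)
  f <- nerve$fascicles[nerve$fascicles$organ_label %in% organs, ,
                       drop = FALSE]
  step <- 2 / grid_size
  v <- matrix(0, grid_size, grid_size)
  placements <- lapply(seq_len(nrow(f)),
                       function(i) project_fascicle(f[i, ], array))
  for (i in seq_len(grid_size)) {
    for (j in seq_len(grid_size)) {
      x <- -1 + (j - 0.5) * step
      y <- 1 - (i - 0.5) * step
      if (x^2 + y^2 > 1) next
      for (pl in placements) {
        a <- pl$theta_deg * pi / 180
        cx <- pl$r_norm * sin(a); cy <- pl$r_norm * cos(a)
        if ((x - cx)^2 + (y - cy)^2 <= pl$radius_norm^2) {
          v[i, j] <- 1
          break
        }
      }
    }
  }
  v
}

# brute-force sector index of each pixel center
oracle_sector_index <- function(grid_size, array) {
  n <- array$n_pairs
  w <- 360 / n
  step <- 2 / grid_size
  k <- matrix(NA_integer_, grid_size, grid_size)
  for (i in seq_len(grid_size)) {
    for (j in seq_len(grid_size)) {
      x <- -1 + (j - 0.5) * step
      y <- 1 - (i - 0.5) * step
      if (x^2 + y^2 > 1) next
      th <- wrap_360(atan2(x, y) * 180 / pi)
      for (s in seq_len(n)) {
        lo <- array$pad_angles_deg[s] - w / 2
        d <- wrap_360(th - lo)
        if (d < w) { k[i, j] <- s; break }
      }
    }
  }
  k
}
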