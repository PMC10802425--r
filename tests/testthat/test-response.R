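arr <- electrode_array()

test_that("percent change uses mean for rate signals and RMS for EMG", {
  p <- stim_params(on_s = 10, off_s = 10)
  tr <- generate_trace(-8, "HR", p, baseline_level = 100, n_pairs = 2)
  expect_equal(percent_change(tr, 1), -8, tolerance = 1e-9)
  expect_equal(percent_change(tr, 2), -8, tolerance = 1e-9)

  flat <- generate_trace(0, "EtCO2", p, baseline_level = 40, n_pairs = 1)
  expect_equal(percent_change(flat, 1), 0)

  # EMG: alternating-sign baseline doubles in amplitude -> +100% RMS
  emg <- generate_trace(0, "EMG", p, baseline_level = 1, n_pairs = 1)
  t <- (seq_along(emg$samples) - 1) / emg$sampling_rate_Hz
  w <- emg$schedule
  sgn <- rep_len(c(1, -1), length(emg$samples))
  emg$samples <- sgn * ifelse(t >= w$on_start_s[1] & t < w$on_end_s[1], 2, 1)
  expect_equal(percent_change(emg, 1), 100, tolerance = 1e-9)

  zero <- generate_trace(0, "HR", p, baseline_level = 1, n_pairs = 1)
  zero$samples[] <- 0
  expect_error(percent_change(zero, 1), "zero")

  full <- trace_to_table(generate_trace(rep(-8, 14), "HR", p, 100), "n1")
  expect_s3_class(full, "response_table")
  expect_equal(full$pct_change, rep(-8, 14), tolerance = 1e-9)
})

test_that("sector maps write each pair's value onto its sector exactly", {
  v <- numeric(14); v[1] <- -10
  tab <- response_table("n1", modality = "HR", condition = "pre_vagotomy",
                        pct_change = v)
  m <- build_sector_map(tab, arr, 64)
  idx <- oracle_sector_index(64, arr)
  mask <- !is.na(idx)
  expect_true(all(m$values[mask & idx == 1] == -10))
  expect_true(all(m$values[mask & idx != 1] == 0))

  # uniform table -> uniform disk
  tabu <- response_table("n1", modality = "HR", condition = "pre_vagotomy",
                         pct_change = rep(-3, 14))
  mu <- build_sector_map(tabu, arr, 64)
  expect_true(all(mu$values[mask] == -3))
  expect_true(all(mu$values[!mask] == 0))

  # sectors partition the disk nearly evenly (within 1% of disk/14)
  counts <- table(idx[mask])
  expect_length(counts, 14)
  expect_true(all(abs(counts - sum(mask) / 14) <= 0.01 * sum(mask)))

  # absolute-sum identity over the sector partition
  set.seed(41)
  pct <- rnorm(14, 0, 5)
  tabr <- response_table("n1", modality = "HR", condition = "pre_vagotomy",
                         pct_change = pct)
  mr <- build_sector_map(tabr, arr, 64)
  expect_equal(sum(abs(mr$values)),
               sum(abs(pct) * as.numeric(counts)), tolerance = 1e-9)
})

test_that("per-sector read-back reproduces the input table exactly", {
  set.seed(42)
  pct <- rnorm(14, 0, 8)
  tab <- response_table("n1", modality = "HR", condition = "pre_vagotomy",
                        pct_change = pct)
  m <- build_sector_map(tab, arr, 128)
  expect_equal(sector_means(m, arr), pct, tolerance = 1e-12)
})

test_that("response-map alignment recenters, preserves values, and is idempotent", {
  v <- numeric(14); v[7] <- -12   # single responsive sector at 154.3 deg
  tab <- response_table("n1", modality = "HR", condition = "pre_vagotomy",
                        pct_change = v)
  m <- build_sector_map(tab, arr, 128)
  expect_equal(center_of_mass(m)$angle_deg, arr$pad_angles_deg[7],
               tolerance = 0.5)
  al <- align_response_maps(list(cardiac_efferent = m))$cardiac_efferent
  expect_lt(angular_difference(center_of_mass(al)$angle_deg, 0), 0.5)
  # responsive pixels straddle the top
  pg_theta <- atan2(matrix(rep(seq(-1 + 1 / 128, 1 - 1 / 128, length = 128),
                               128), 128, byrow = TRUE),
                    matrix(rep(seq(1 - 1 / 128, -1 + 1 / 128, length = 128),
                               128), 128))
  nz <- which(al$values != 0, arr.ind = TRUE)
  ang <- wrap_360(pg_theta[nz] * 180 / pi)
  expect_true(any(ang < 90) && any(ang > 270))

  # value multiset preserved within resampling tolerance
  expect_lt(abs(sum(al$values) - sum(m$values)) / abs(sum(m$values)), 0.02)
  expect_lt(abs(min(al$values) - (-12)), 1e-9)

  # idempotence
  again <- align_response_maps(list(cardiac_efferent = al))$cardiac_efferent
  expect_lt(mean(abs(again$values - al$values)), 0.05)
})

test_that("effective pairs honor threshold and sign conventions", {
  mk <- function(v, condition = "pre_vagotomy", modality = "HR")
    response_table("n1", modality = modality, condition = condition,
                   pct_change = v)
  v <- numeric(14); v[1] <- -8; v[2] <- -7
  expect_equal(effective_pairs(mk(v)), c(1L, 2L))
  expect_length(effective_pairs(mk(numeric(14))), 0)
  vp <- numeric(14); vp[1] <- 8
  expect_length(effective_pairs(mk(vp)), 0)   # wrong sign for efferent HR
  # post-vagotomy HR admits either direction
  expect_equal(effective_pairs(mk(vp, condition = "post_vagotomy")), 1L)

  expect_true(is_selective(mk(-c(rep(8, 6), rep(0, 8)))))
  expect_false(is_selective(mk(-c(rep(8, 7), rep(0, 7)))))
  expect_true(is_selective(mk(-c(rep(8, 7), rep(0, 7))), max_pairs = 7))
  expect_true(is_selective(mk(numeric(14))))
})

test_that("titration walks amplitude into the selective window", {
  mk <- function(v) response_table("n1", modality = "HR",
                                   condition = "pre_vagotomy",
                                   pct_change = v)
  # already selective with 2 responsive pairs: returned unchanged
  two <- function(amp) { v <- numeric(14); v[1:2] <- -8; mk(v) }
  res <- titrate(two, start = stim_params(amplitude_mA = 1))
  expect_equal(res$params$amplitude_mA, 1)
  expect_equal(nrow(res$trajectory), 1)

  # monotone recruitment: responsive count grows with amplitude; the
  # selective window is verified independently by scanning the model
  monotone <- function(amp) {
    n <- min(14L, max(0L, floor(amp)))
    v <- numeric(14); if (n > 0) v[seq_len(n)] <- -8
    mk(v)
  }
  res <- titrate(monotone, start = stim_params(amplitude_mA = 40),
                 step_fraction = 0.25)
  n_fin <- length(effective_pairs(res$table))
  expect_true(n_fin >= 1 && n_fin <= 6)
  # oracle: amplitudes in [1, 7) are the selective-with-response window
  expect_true(res$params$amplitude_mA >= 1 &&
                res$params$amplitude_mA < 7)

  # also terminates when starting from below the window
  res_up <- titrate(monotone, start = stim_params(amplitude_mA = 0.05))
  expect_true(res_up$params$amplitude_mA >= 1 &&
                res_up$params$amplitude_mA < 7)

  # a dead model fails with the trajectory attached
  dead <- function(amp) mk(numeric(14))
  err <- tryCatch(titrate(dead, max_iters = 10),
                  titration_failure = function(e) e)
  expect_s3_class(err, "titration_failure")
  expect_equal(nrow(err$trajectory), 10)
})

test_that("titrated synthetic responses have efferent maps that are never positive", {
  set.seed(43)
  cfg <- synthetic_config()
  cfg$noise_sd[] <- 0
  for (i in 1:10) {
    repeat {
      g <- generate_nerve(cfg, "A")
      if (any(g$nerve$fascicles$organ_label == "cardiac")) break
    }
    model <- titration_model(g$nerve, arr, "HR", "pre_vagotomy", g$truth, cfg)
    res <- titrate(model)
    expect_true(all(res$table$pct_change <= 0))
    m <- build_sector_map(res$table, arr, 64)
    expect_true(all(m$values <= 0))
  }
})
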