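# Synthetic cohort generator: nerves with planted angular organization,
# a distance-decay recruitment model, and per-pair physiological
# responses.  Ground truth (cuff rotation, planted group angles,
# afferent reflex direction) is carried alongside each nerve so that
# downstream estimates can be checked against what was planted.

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the study conditions the analysis assumes: five
#' organ-label groups with mean/SD fascicle counts 1.2±0.5 (cardiac),
#' 10.2±1.8 (recurrent laryngeal), 10.4±1.9 (pulmonary), 1.4±0.6
#' (cardiopulmonary) and 6±2 (laryngopulmonary), total 29.2 per nerve;
#' cardiac fascicles planted opposite the pulmonary region (separation
#' 180 degrees), with cardiopulmonary (cardiac afferent) and
#' laryngopulmonary fascicles placed about the pulmonary center;
#' unknown uniform per-animal cuff rotation; recruitment thresholds
#' 1 / 5 / 0.2 / 0.8 mA at zero distance for cardiac efferent, cardiac
#' afferent, laryngeal and pulmonary targets with exponential distance
#' scaling; afferent heart-rate reflex direction tachycardia with
#' probability 0.6 (bradycardia otherwise), tachycardia persisting and
#' bradycardia abolished after double vagotomy.
#'
#' @param n_animals number of animals in a cohort.
#' @param group_counts named list of `c(mean, sd)` fascicle counts per
#'   organ label.
#' @param group_center_angles_deg named vector of planted placement
#'   centers (degrees, pre-rotation) for `cardiac`,
#'   `recurrent_laryngeal` and `pulmonary`; cardiopulmonary and
#'   laryngopulmonary fascicles are placed about the pulmonary center.
#' @param angular_spread_deg SD of the wrapped-normal angular placement
#'   noise about each group center, degrees; a scalar (shared by all
#'   groups) or a named vector per organ label.
#' @param cuff_rotation_mode `"uniform_random"` (independent unknown
#'   rotation per animal) or `"none"`.
#' @param nerve_radius_mm radius of the circularized nerve outline, mm.
#' @param fascicle_radius_median_mm,fascicle_radius_sdlog,fascicle_radius_max_mm
#'   log-normal equivalent-radius distribution of fascicles (median,
#'   sdlog, hard cap), mm.
#' @param recruitment list with `decay_length_mm` (exponential distance
#'   constant of the activation threshold), `base_threshold_mA` (named,
#'   per target group, threshold at zero distance), `response_effects`
#'   (named list of `c(mean, sd)` full-recruitment effect magnitudes in
#'   percent, drawn once per animal and target) and `effect_floor_pct`
#'   (lower truncation of those draws, keeping every animal's full
#'   response observable, as in the protocol where responses were
#'   identified in all animals).
#' @param noise_sd named per-modality SD of additive measurement noise
#'   on percent changes.
#' @param afferent_delay_s onset delay of the reflex (afferent) response
#'   in simulated traces, s.
#' @param afferent_direction_prob probability that an animal's afferent
#'   reflex is tachycardia.
#' @param seed optional integer seed making cohort generation a pure
#'   function of the configuration.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_animals = 10L,
    group_counts = list(
      cardiac             = c(mean = 1.2,  sd = 0.5),
      recurrent_laryngeal = c(mean = 10.2, sd = 1.8),
      pulmonary           = c(mean = 10.4, sd = 1.9),
      cardiopulmonary     = c(mean = 1.4,  sd = 0.6),
      laryngopulmonary    = c(mean = 6.0,  sd = 2.0)),
    group_center_angles_deg = c(cardiac = 0, recurrent_laryngeal = 45,
                                pulmonary = 180),
    angular_spread_deg = c(cardiac = 5, recurrent_laryngeal = 25,
                           pulmonary = 25, cardiopulmonary = 15,
                           laryngopulmonary = 25),
    cuff_rotation_mode = c("uniform_random", "none"),
    nerve_radius_mm = sqrt(2.68 / pi),
    fascicle_radius_median_mm = 0.07,
    fascicle_radius_sdlog = 0.30,
    fascicle_radius_max_mm = 0.15,
    recruitment = list(
      decay_length_mm = 0.4,
      base_threshold_mA = c(cardiac_efferent = 1, cardiac_afferent = 5,
                            laryngeal = 0.2, pulmonary = 0.8),
      response_effects = list(
        HR_efferent = c(mean = 7.8, sd = 3.4),
        HR_afferent_tachycardia = c(mean = 10.2, sd = 5.3),
        HR_afferent_bradycardia = c(mean = 5.0, sd = 3.1),
        BR = c(mean = 73, sd = 21),
        EtCO2 = c(mean = 30, sd = 10),
        EMG = c(mean = 100, sd = 30)),
      effect_floor_pct = 6.5),
    noise_sd = c(HR = 0.5, BR = 5, EtCO2 = 2, EMG = 5),
    afferent_delay_s = 2,
    afferent_direction_prob = 0.6,
    seed = NULL) {
  cuff_rotation_mode <- match.arg(cuff_rotation_mode)
  stopifnot(n_animals >= 0,
            afferent_direction_prob >= 0, afferent_direction_prob <= 1,
            nerve_radius_mm > 0, angular_spread_deg >= 0,
            fascicle_radius_median_mm > 0,
            recruitment$decay_length_mm > 0,
            all(recruitment$base_threshold_mA > 0))
  if (!all(organ_labels() %in% names(group_counts)))
    stop("`group_counts` must name all of: ",
         paste(organ_labels(), collapse = ", "))
  structure(
    list(n_animals = as.integer(n_animals), group_counts = group_counts,
         group_center_angles_deg = group_center_angles_deg,
         angular_spread_deg = angular_spread_deg,
         cuff_rotation_mode = cuff_rotation_mode,
         nerve_radius_mm = nerve_radius_mm,
         fascicle_radius_median_mm = fascicle_radius_median_mm,
         fascicle_radius_sdlog = fascicle_radius_sdlog,
         fascicle_radius_max_mm = fascicle_radius_max_mm,
         recruitment = recruitment, noise_sd = noise_sd,
         afferent_delay_s = afferent_delay_s,
         afferent_direction_prob = afferent_direction_prob,
         seed = seed),
    class = "synthetic_config")
}

# planted placement center of an organ label, pre-rotation; the two
# mixed labels are placed about the pulmonary center
placement_center <- function(config, label) {
  centers <- config$group_center_angles_deg
  if (label %in% c("cardiopulmonary", "laryngopulmonary"))
    unname(centers["pulmonary"])
  else
    unname(centers[label])
}

# per-label angular placement spread (scalar config value recycled)
group_spread <- function(config, label) {
  s <- config$angular_spread_deg
  if (length(s) == 1L && is.null(names(s))) return(unname(s))
  if (!label %in% names(s))
    stop("`angular_spread_deg` names no entry for '", label, "'")
  unname(s[[label]])
}

# fiber-class composition per organ label (proportions of
# afferent / efferent / mixed fascicles)
fiber_class_probs <- function(label) {
  switch(label,
    cardiac             = c(afferent = 0,     efferent = 1,     mixed = 0),
    pulmonary           = c(afferent = 0.885, efferent = 0.019, mixed = 0.096),
    cardiopulmonary     = c(afferent = 0.714, efferent = 0,     mixed = 0.286),
    recurrent_laryngeal = c(afferent = 0.177, efferent = 0.647, mixed = 0.177),
    laryngopulmonary    = c(afferent = 0.567, efferent = 0.133, mixed = 0.300))
}

#' Generate one synthetic nerve with ground truth
#'
#' Draws per-group fascicle counts (rounded normal, floored at 0),
#' places fascicles at wrapped-normal angles about their rotated group
#' centers and uniform radii in an annulus, rejection-samples to avoid
#' overlapping fascicle disks (up to 1000 attempts per fascicle, then
#' the radius is shrunk), and assigns fiber classes from the per-group
#' composition (purely cardiac fascicles are always efferent).
#'
#' @param config a [synthetic_config()].
#' @param animal_id identifier for the generated animal/nerve.
#' @param rotation_deg cuff rotation to apply; `NULL` draws it
#'   according to `config$cuff_rotation_mode`.
#' @return list with elements `nerve` (a [nerve_section()]) and `truth`
#'   (class `ground_truth`: `rotation_deg`, `group_angles_deg` for the
#'   four map groups after rotation, `afferent_direction`).
#' @export
generate_nerve <- function(config, animal_id = "A1", rotation_deg = NULL) {
  if (is.null(rotation_deg))
    rotation_deg <- if (config$cuff_rotation_mode == "uniform_random")
      stats::runif(1, 0, 360) else 0
  R <- config$nerve_radius_mm
  placed <- list()
  fid <- 0L
  for (label in organ_labels()) {
    gc <- config$group_counts[[label]]
    n <- max(0L, as.integer(round(stats::rnorm(1, gc[["mean"]], gc[["sd"]]))))
    if (n == 0L) next
    center <- placement_center(config, label) + rotation_deg
    spread <- group_spread(config, label)
    cls <- sample(c("afferent", "efferent", "mixed"), n, replace = TRUE,
                  prob = fiber_class_probs(label))
    for (k in seq_len(n)) {
      fid <- fid + 1L
      rad <- min(stats::rlnorm(1, log(config$fascicle_radius_median_mm),
                               config$fascicle_radius_sdlog),
                 config$fascicle_radius_max_mm)
      # the angle is the planted structure: drawn once and kept, so
      # packing rejections cannot tilt the angular distribution; only
      # the radial position is resampled on a clash, and the radius is
      # shrunk when the ray is crowded
      theta <- center + stats::rnorm(1, 0, spread)
      shrinks <- 0L
      px <- vapply(placed, `[[`, 0, "x")
      py <- vapply(placed, `[[`, 0, "y")
      pr <- vapply(placed, `[[`, 0, "r")
      repeat {
        r_cand <- pmin(stats::runif(1000L, 0.15 * R, 0.9 * R), R - rad)
        r_cand <- r_cand[r_cand >= 0]     # containment clamp
        xy_cand <- pol2cart(theta, r_cand)
        ok <- if (length(placed)) {
          d2 <- outer(xy_cand[, 1], px, `-`)^2 + outer(xy_cand[, 2], py, `-`)^2
          rowSums(d2 < outer(rep(rad, nrow(d2)), pr, `+`)^2) == 0L
        } else rep(TRUE, length(r_cand))
        hit <- which(ok)[1]
        if (length(r_cand) && !is.na(hit)) {
          xy <- xy_cand[hit, ]
          break
        }
        rad <- rad * 0.8
        shrinks <- shrinks + 1L
        if (shrinks > 25L)
          stop("could not pack fascicles without overlap; ",
               "use smaller fascicle radii")
        if (rad < 0.02)  # last resort on a fully blocked ray
          theta <- center + stats::rnorm(1, 0, spread)
      }
      placed[[fid]] <- list(x = xy[[1]], y = xy[[2]], r = rad, label = label,
                            class = if (label == "cardiac") "efferent"
                                    else cls[k])
    }
  }
  fasc <- if (length(placed)) {
    data.frame(
      fascicle_id = sprintf("%s_f%02d", animal_id, seq_along(placed)),
      center_x_mm = vapply(placed, `[[`, 0, "x"),
      center_y_mm = vapply(placed, `[[`, 0, "y"),
      radius_mm = vapply(placed, `[[`, 0, "r"),
      organ_label = vapply(placed, `[[`, "", "label"),
      fiber_class = vapply(placed, `[[`, "", "class"))
  } else {
    data.frame(fascicle_id = character(0), center_x_mm = numeric(0),
               center_y_mm = numeric(0), radius_mm = numeric(0),
               organ_label = character(0), fiber_class = character(0))
  }
  nerve <- nerve_section(nerve_id = animal_id, animal_id = animal_id,
                         nerve_radius_mm = R, fascicles = fasc)
  centers <- config$group_center_angles_deg
  eff <- config$recruitment$response_effects
  floor_pct <- config$recruitment$effect_floor_pct
  draw_effect <- function(ms) {
    for (i in seq_len(100L)) {
      x <- stats::rnorm(1, ms[["mean"]], ms[["sd"]])
      if (x >= floor_pct) return(x)
    }
    floor_pct
  }
  truth <- structure(list(
    animal_id = as.character(animal_id),
    rotation_deg = wrap_360(rotation_deg),
    group_angles_deg = wrap_360(c(
      cardiac_efferent = unname(centers["cardiac"]) + rotation_deg,
      cardiac_afferent = unname(centers["pulmonary"]) + rotation_deg,
      pulmonary = unname(centers["pulmonary"]) + rotation_deg,
      laryngeal = unname(centers["recurrent_laryngeal"]) + rotation_deg)),
    afferent_direction = if (stats::runif(1) < config$afferent_direction_prob)
      "tachycardia" else "bradycardia",
    effect_pct = vapply(eff, draw_effect, 0)),
    class = "ground_truth")
  list(nerve = nerve, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws `config$n_animals` independent nerves (each with its own cuff
#' rotation when `cuff_rotation_mode = "uniform_random"`).  With
#' `config$seed` set, the cohort is a pure function of the
#' configuration.
#'
#' @param config a [synthetic_config()].
#' @return list with `nerves` and `truths`, each a named list of length
#'   `n_animals`.
#' @export
generate_cohort <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- sprintf("A%02d", seq_len(config$n_animals))
  out <- lapply(ids, function(id) generate_nerve(config, id))
  list(nerves = stats::setNames(lapply(out, `[[`, "nerve"), ids),
       truths = stats::setNames(lapply(out, `[[`, "truth"), ids))
}

# modality/condition -> target selection, sign and full-recruitment
# effect magnitude; NULL when no response is expected (abolished
# pathway)
response_rule <- function(modality, condition, truth, config) {
  e <- truth$effect_pct
  if (modality == "HR") {
    if (condition == "pre_vagotomy") {
      return(list(organs = "cardiac", threshold_key = "cardiac_efferent",
                  sign = -1, effect = unname(e["HR_efferent"])))
    }
    # post (single or double) vagotomy: afferent reflex via
    # cardiopulmonary fascicles
    dir <- truth$afferent_direction
    if (condition == "post_double_vagotomy" && dir == "bradycardia")
      return(NULL)  # left-vagal efferent arc cut: bradycardia abolished
    return(list(organs = "cardiopulmonary", threshold_key = "cardiac_afferent",
                sign = if (dir == "tachycardia") 1 else -1,
                effect = unname(e[paste0("HR_afferent_", dir)])))
  }
  if (modality %in% c("BR", "EtCO2"))
    return(list(organs = c("pulmonary", "cardiopulmonary",
                           "laryngopulmonary"),
                threshold_key = "pulmonary", sign = -1,
                effect = unname(e[modality])))
  if (modality == "EMG")
    return(list(organs = c("recurrent_laryngeal", "laryngopulmonary"),
                threshold_key = "laryngeal", sign = 1,
                effect = unname(e["EMG"])))
  stop("unknown modality: ", modality)
}

# Noise-free per-pair response signal (percent change), length n_pairs.
# Recruitment saturates: pair j's response is the animal's
# full-recruitment effect scaled by the fraction of the target group's
# fascicle area whose activation threshold pair j exceeds.
response_signal <- function(nerve, array, amplitude_mA, modality, condition,
                            truth, config) {
  modality <- match.arg(modality, c("HR", "BR", "EtCO2", "EMG"))
  condition <- match.arg(condition, c("pre_vagotomy", "post_vagotomy",
                                      "post_double_vagotomy"))
  rule <- response_rule(modality, condition, truth, config)
  n <- array$n_pairs
  if (is.null(rule)) return(numeric(n))
  f <- nerve$fascicles
  f <- f[f$organ_label %in% rule$organs, , drop = FALSE]
  if (!nrow(f)) return(numeric(n))
  pads <- pad_coords(array)
  base <- config$recruitment$base_threshold_mA[[rule$threshold_key]]
  lambda <- config$recruitment$decay_length_mm
  area <- pi * f$radius_mm^2
  total <- sum(area)
  out <- numeric(n)
  for (j in seq_len(n)) {
    d <- sqrt((f$center_x_mm - pads[j, 1])^2 +
              (f$center_y_mm - pads[j, 2])^2)
    act <- amplitude_mA >= base * exp(d / lambda)
    if (any(act))
      out[j] <- rule$sign * rule$effect * sum(area[act]) / total
  }
  out
}

#' Simulate a per-pair response table
#'
#' Applies the distance-decay recruitment model: fascicle `f` is
#' activated by pair `j` iff `amplitude_mA >= base_threshold *
#' exp(d_fj / decay_length_mm)` with `d_fj` the centroid-to-pad
#' distance, and pair `j`'s noise-free response is the modality gain
#' times the total activated target fascicle area, signed by the
#' physiology: pre-vagotomy HR is negative (bradycardia via purely
#' cardiac efferent fascicles); post-vagotomy HR is a reflex through
#' cardiopulmonary afferent fascicles whose sign is the animal's true
#' afferent direction, with tachycardia persisting and bradycardia
#' abolished after double vagotomy; BR/EtCO2 are negative via pulmonary
#' fascicles; EMG is positive via laryngeal fascicles.  Gaussian
#' measurement noise (`config$noise_sd[modality]`) is added per pair.
#'
#' @param nerve a [nerve_section()].
#' @param array an [electrode_array()].
#' @param params a [stim_params()] (its `amplitude_mA` drives
#'   recruitment).
#' @param modality one of `"HR"`, `"BR"`, `"EtCO2"`, `"EMG"`.
#' @param condition one of `"pre_vagotomy"`, `"post_vagotomy"`,
#'   `"post_double_vagotomy"`.
#' @param truth the nerve's `ground_truth`.
#' @param config the [synthetic_config()] holding the recruitment model.
#' @return a [response_table()].
#' @export
simulate_responses <- function(nerve, array, params, modality, condition,
                               truth, config) {
  sig <- response_signal(nerve, array, params$amplitude_mA, modality,
                         condition, truth, config)
  sd <- config$noise_sd[[modality]]
  noise <- if (sd > 0) stats::rnorm(length(sig), 0, sd) else 0
  response_table(nerve$nerve_id, nerve$animal_id, modality, condition,
                 pct_change = sig + noise, stim = params)
}

#' Deterministic amplitude-response model for titration
#'
#' Returns a function `amplitude_mA -> response_table` with one frozen
#' noise draw shared by every evaluation, so that repeated calls at the
#' same amplitude are identical (the determinism the titration loop
#' requires).
#'
#' @inheritParams simulate_responses
#' @return a function of one argument (`amplitude_mA`).
#' @export
titration_model <- function(nerve, array, modality, condition, truth, config) {
  sd <- config$noise_sd[[modality]]
  noise <- if (sd > 0) stats::rnorm(array$n_pairs, 0, sd)
           else numeric(array$n_pairs)
  force(nerve); force(array); force(modality); force(condition)
  force(truth); force(config)
  function(amplitude_mA) {
    sig <- response_signal(nerve, array, amplitude_mA, modality, condition,
                           truth, config)
    response_table(nerve$nerve_id, nerve$animal_id, modality, condition,
                   pct_change = sig + noise,
                   stim = stim_params(amplitude_mA = amplitude_mA))
  }
}

#' Simulate a physiological trial trace
#'
#' Builds a sampled time series for a pulse-train schedule: baseline
#' level with optional noise, and during each on-window the level steps
#' to `baseline * (1 + response/100)` once `delay_s` has elapsed (the
#' reflex onset delay; the first `delay_s` seconds of each window stay
#' at baseline).  The stimulation schedule is embedded in the returned
#' object.
#'
#' @param response signed percent change; a scalar (same response in
#'   every window) or one value per pair.
#' @param modality one of `"HR"`, `"BR"`, `"EtCO2"`, `"EMG"`.
#' @param params a [stim_params()]; `on_s` / `off_s` set the schedule.
#' @param baseline_level baseline signal level (must be positive).
#' @param delay_s response onset delay within each on-window, s.
#' @param n_pairs number of on-windows (electrode pairs stimulated
#'   sequentially).
#' @param sampling_rate_Hz sampling rate of the trace.
#' @param noise_sd SD of additive Gaussian sample noise, in signal
#'   units.
#' @return an object of class `trial_trace` with fields `modality`,
#'   `sampling_rate_Hz`, `samples`, `schedule` (data frame
#'   `pair_index`, `on_start_s`, `on_end_s`) and `baseline_window_s`.
#' @export
generate_trace <- function(response, modality = "HR", params = stim_params(),
                           baseline_level = 100, delay_s = 0,
                           n_pairs = if (length(response) > 1L)
                             length(response) else 14L,
                           sampling_rate_Hz = 10, noise_sd = 0) {
  if (!isTRUE(baseline_level > 0)) stop("`baseline_level` must be positive")
  if (delay_s >= params$on_s)
    warning("`delay_s` is not shorter than the on-window: ",
            "the response is never expressed")
  resp <- rep_len(response, n_pairs)
  dt <- 1 / sampling_rate_Hz
  total_s <- params$off_s + n_pairs * (params$on_s + params$off_s)
  t <- seq(0, total_s - dt, by = dt)
  level <- rep(baseline_level, length(t))
  on_start <- params$off_s + (seq_len(n_pairs) - 1L) *
    (params$on_s + params$off_s)
  on_end <- on_start + params$on_s
  for (k in seq_len(n_pairs)) {
    act <- t >= on_start[k] + delay_s & t < on_end[k]
    level[act] <- baseline_level * (1 + resp[k] / 100)
  }
  if (noise_sd > 0) level <- level + stats::rnorm(length(level), 0, noise_sd)
  structure(
    list(modality = modality, sampling_rate_Hz = sampling_rate_Hz,
         samples = level,
         schedule = data.frame(pair_index = seq_len(n_pairs),
                               on_start_s = on_start, on_end_s = on_end),
         baseline_window_s = params$off_s),
    class = "trial_trace")
}
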