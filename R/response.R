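# In-vivo arm: percent-change extraction from trial traces, 14-sector
# back-projection maps, and the selectivity / amplitude-titration logic
# of the stimulation protocol.

#' Percent change of one stimulation window
#'
#' Baseline is the full off-period immediately preceding the pair's
#' on-window.  HR/BR/EtCO2 use window means,
#' `100 * (mean_on - mean_base) / mean_base`; EMG uses window RMS,
#' `100 * (RMS_on - RMS_base) / RMS_base`.
#'
#' @param trace a `trial_trace` (see [generate_trace()]).
#' @param pair_index which scheduled on-window to evaluate.
#' @return signed percent change.
#' @export
percent_change <- function(trace, pair_index) {
  sch <- trace$schedule
  row <- sch[sch$pair_index == pair_index, ]
  if (nrow(row) != 1L)
    stop("pair ", pair_index, " has no on-window in the trace schedule")
  t <- (seq_along(trace$samples) - 1L) / trace$sampling_rate_Hz
  on <- t >= row$on_start_s & t < row$on_end_s
  base <- t >= row$on_start_s - trace$baseline_window_s & t < row$on_start_s
  if (!any(on) || !any(base))
    stop("trace does not cover the on/baseline windows of pair ", pair_index)
  stat <- if (trace$modality == "EMG") {
    function(x) sqrt(mean(x^2))
  } else {
    mean
  }
  b <- stat(trace$samples[base])
  if (abs(b) < .Machine$double.eps)
    stop("baseline ", if (trace$modality == "EMG") "RMS" else "mean",
         " is zero: percent change undefined for pair ", pair_index)
  100 * (stat(trace$samples[on]) - b) / b
}

#' Extract a full response table from a trace
#'
#' Applies [percent_change()] to every scheduled pair.
#'
#' @param trace a `trial_trace`.
#' @param nerve_id,animal_id identifiers for the table.
#' @param condition experimental condition label.
#' @return a [response_table()].
#' @export
trace_to_table <- function(trace, nerve_id = "n1", animal_id = nerve_id,
                           condition = "pre_vagotomy") {
  pct <- vapply(trace$schedule$pair_index,
                function(k) percent_change(trace, k), 0)
  response_table(nerve_id, animal_id, trace$modality, condition, pct)
}

#' Back-project a response table onto 14 angular sectors
#'
#' Subdivides the disk into `n_pairs` equal sectors centered on the pad
#' angles (sector k covers `[pad_k - w/2, pad_k + w/2)` with
#' `w = 360/n_pairs`) and writes the pair's percent change onto every
#' pixel of its sector.
#'
#' @param table a [response_table()].
#' @param array an [electrode_array()] (pads assumed equally spaced).
#' @param grid_size pixels per raster side.
#' @return a [circular_map()] of kind `response`, rotation 0; its
#'   `group` is taken from the table's modality/condition
#'   (HR pre-vagotomy = cardiac_efferent, HR post-vagotomy =
#'   cardiac_afferent, BR/EtCO2 = pulmonary, EMG = laryngeal).
#' @export
build_sector_map <- function(table, array, grid_size = 256L) {
  n <- array$n_pairs
  if (length(table$pct_change) != n)
    stop("response table has ", length(table$pct_change),
         " entries but the array has ", n, " pairs")
  w <- 360 / n
  pg <- pixel_grid(grid_size)
  # sector index of each pixel: half-open [pad_k - w/2, pad_k + w/2)
  k <- (floor(wrap_360(pg$theta - array$pad_angles_deg[1] + w / 2) / w) %% n) + 1L
  v <- matrix(table$pct_change[k], grid_size, grid_size)
  v[!pg$mask] <- 0
  group <- if (table$modality == "HR") {
    if (table$condition == "pre_vagotomy") "cardiac_efferent"
    else "cardiac_afferent"
  } else if (table$modality %in% c("BR", "EtCO2")) "pulmonary"
  else "laryngeal"
  circular_map(v, group = group, kind = "response",
               animal_id = table$animal_id, rotation_applied_deg = 0)
}

#' Per-sector read-back of a sector map
#'
#' Mean map value over each sector's disk pixels; inverse of
#' [build_sector_map()] for unrotated maps.
#'
#' @param map a response [circular_map()].
#' @param array the [electrode_array()] that defined the sectors.
#' @return numeric vector of length `n_pairs`.
#' @export
sector_means <- function(map, array) {
  n <- array$n_pairs
  w <- 360 / n
  pg <- pixel_grid(map$grid_size)
  k <- (floor(wrap_360(pg$theta - array$pad_angles_deg[1] + w / 2) / w) %% n) + 1L
  vapply(seq_len(n),
         function(j) mean(map$values[pg$mask & k == j]), 0)
}

#' Effective (responsive) electrode pairs
#'
#' Pairs whose percent change exceeds the threshold in magnitude with
#' the sign expected for the modality: negative for efferent HR and for
#' BR/EtCO2, positive for EMG; either sign for post-vagotomy HR, where
#' the reflex direction differs between animals.
#'
#' @param table a [response_table()].
#' @param threshold_pct magnitude threshold defining an observed
#'   response (percent).
#' @param direction `"auto"` (from modality/condition as above),
#'   `"negative"`, `"positive"`, or `"any"`.
#' @return integer vector of responsive pair indices (possibly empty).
#' @export
effective_pairs <- function(table, threshold_pct = 5,
                            direction = c("auto", "negative", "positive",
                                          "any")) {
  direction <- match.arg(direction)
  stopifnot(threshold_pct > 0)
  if (direction == "auto") {
    direction <- if (table$modality %in% c("BR", "EtCO2")) "negative"
    else if (table$modality == "EMG") "positive"
    else if (table$condition == "pre_vagotomy") "negative"  # efferent HR
    else "any"
  }
  x <- table$pct_change
  ok <- abs(x) >= threshold_pct
  if (direction == "negative") ok <- ok & x < 0
  if (direction == "positive") ok <- ok & x > 0
  which(ok)
}

#' Selectivity criterion
#'
#' A stimulation setting is spatially selective when the target
#' response is observed on fewer than half of the electrode pairs.  The
#' strict reading (at most 6 of 14) is the default; `max_pairs = 7`
#' gives the inclusive reading.
#'
#' @inheritParams effective_pairs
#' @param max_pairs largest responsive-pair count still counted as
#'   selective.
#' @return logical.
#' @export
is_selective <- function(table, threshold_pct = 5, max_pairs = 6L,
                         direction = "auto") {
  length(effective_pairs(table, threshold_pct, direction)) <= max_pairs
}

#' Titrate stimulation amplitude to a selective response
#'
#' Emulates the trial-and-error protocol: starting from `start`, the
#' amplitude is multiplied by `1 - step_fraction` while the response is
#' non-selective (too many responsive pairs) and by `1 + step_fraction`
#' while no pair responds, stopping at the first amplitude that is
#' selective with at least one responsive pair.
#'
#' @param stim_model function `amplitude_mA -> response_table`,
#'   deterministic for a fixed amplitude (see [titration_model()]).
#' @param start a [stim_params()] with the starting amplitude.
#' @param step_fraction multiplicative step, in (0, 1).
#' @param max_iters iteration cap; exceeding it (e.g. no amplitude
#'   yields any response, or the selective window is missed by
#'   oscillation) raises a `titration_failure` error carrying the
#'   amplitude/response-count trajectory in its `trajectory` field.
#' @param threshold_pct,max_pairs,direction selectivity criterion,
#'   passed to [effective_pairs()].
#' @return list with `params` (final [stim_params()]), `table` (the
#'   response at the final amplitude) and `trajectory` (data frame of
#'   visited amplitudes and responsive-pair counts).
#' @export
titrate <- function(stim_model, start = starting_params("cardiac_efferent"),
                    step_fraction = 0.25, max_iters = 60L,
                    threshold_pct = 5, max_pairs = 6L, direction = "auto") {
  stopifnot(step_fraction > 0, step_fraction < 1)
  amp <- start$amplitude_mA
  amps <- numeric(max_iters)
  neffs <- integer(max_iters)
  for (it in seq_len(max_iters)) {
    tab <- stim_model(amp)
    n_eff <- length(effective_pairs(tab, threshold_pct, direction))
    amps[it] <- amp
    neffs[it] <- n_eff
    if (n_eff >= 1L && n_eff <= max_pairs) {
      out <- start
      out$amplitude_mA <- amp
      return(list(params = out, table = tab,
                  trajectory = data.frame(amplitude_mA = amps[1:it],
                                          n_effective = neffs[1:it])))
    }
    amp <- if (n_eff == 0L) amp * (1 + step_fraction)
           else amp * (1 - step_fraction)
  }
  cond <- structure(
    class = c("titration_failure", "error", "condition"),
    list(message = paste0("titration did not reach a selective response in ",
                          max_iters, " iterations"),
         call = sys.call(),
         trajectory = data.frame(amplitude_mA = amps,
                                 n_effective = neffs)))
  stop(cond)
}
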