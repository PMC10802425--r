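#' Cuff electrode array geometry
#'
#' Describes a circumferential multi-pair cuff: `n_pairs` pad pairs at
#' fixed angular positions on the inner wall of a tubular cuff.  The
#' default is the 14-pair double-ring array used for spatially selective
#' vagus nerve stimulation: pads of 3.00 x 0.35 mm on a cuff of 2.7 mm
#' inner diameter, pairs equally spaced around the circumference with
#' pair 1 at the top (0 degrees).
#'
#' @param n_pairs number of electrode pairs; defaults to
#'   `length(pad_angles_deg)` if angles are given, else 14.
#' @param pad_angles_deg angular position of each pair, degrees clockwise
#'   from top, strictly increasing, all in `[0, 360)`.  Default: equally
#'   spaced starting at 0.
#' @param cuff_inner_diameter_mm inner diameter of the cuff, mm.
#' @param pad_length_mm,pad_width_mm pad dimensions, mm (metadata only).
#' @return an object of class `electrode_array`.
#' @examples
#' arr <- electrode_array()
#' arr$pad_angles_deg[1:3]
#' @export
electrode_array <- function(n_pairs = NULL,
                            pad_angles_deg = NULL,
                            cuff_inner_diameter_mm = 2.7,
                            pad_length_mm = 3.00,
                            pad_width_mm = 0.35) {
  if (is.null(n_pairs))
    n_pairs <- if (is.null(pad_angles_deg)) 14L else length(pad_angles_deg)
  n_pairs <- as.integer(n_pairs)
  if (is.null(pad_angles_deg)) {
    pad_angles_deg <- seq(0, 360, length.out = n_pairs + 1L)[seq_len(n_pairs)]
  }
  if (length(pad_angles_deg) != n_pairs)
    stop("`pad_angles_deg` must have length `n_pairs` (", n_pairs, ")")
  if (any(pad_angles_deg < 0 | pad_angles_deg >= 360))
    stop("`pad_angles_deg` must lie in [0, 360)")
  if (is.unsorted(pad_angles_deg, strictly = TRUE))
    stop("`pad_angles_deg` must be strictly increasing")
  if (!isTRUE(cuff_inner_diameter_mm > 0))
    stop("`cuff_inner_diameter_mm` must be positive")
  structure(
    list(n_pairs = n_pairs,
         pad_angles_deg = as.numeric(pad_angles_deg),
         cuff_inner_diameter_mm = cuff_inner_diameter_mm,
         pad_length_mm = pad_length_mm,
         pad_width_mm = pad_width_mm),
    class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("Cuff electrode array: %d pairs, %.2f mm inner diameter\n",
              x$n_pairs, x$cuff_inner_diameter_mm))
  cat("  pad angles (deg from top, clockwise): ",
      paste(formatC(x$pad_angles_deg, format = "f", digits = 1),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# cuff radius, mm
cuff_radius <- function(array) array$cuff_inner_diameter_mm / 2

# pad centre coordinates (mm) in the cross-section plane
pad_coords <- function(array) {
  pol2cart(array$pad_angles_deg, cuff_radius(array))
}

#' Stimulation parameter set
#'
#' A biphasic pulse-train parameter bundle.  Field defaults are the
#' cardiac efferent starting point of the selective stimulation
#' protocol: 1 mA, 1 ms, 10 Hz, 15 s on / 15 s off.
#'
#' @param amplitude_mA pulse amplitude, mA.
#' @param pulse_width_us pulse width, microseconds.
#' @param frequency_Hz pulse repetition rate, Hz.
#' @param on_s,off_s stimulation and rest durations, s.
#' @return an object of class `stim_params`.
#' @export
stim_params <- function(amplitude_mA = 1, pulse_width_us = 1000,
                        frequency_Hz = 10, on_s = 15, off_s = 15) {
  vals <- c(amplitude_mA = amplitude_mA, pulse_width_us = pulse_width_us,
            frequency_Hz = frequency_Hz, on_s = on_s, off_s = off_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all stimulation parameters must be strictly positive")
  structure(as.list(vals), class = "stim_params")
}

#' Protocol starting parameters per target function
#'
#' Starting stimulation parameters of the trial-and-error selective
#' stimulation protocol for each target: cardiac efferent
#' (pre-vagotomy) 1 mA / 1 ms / 10 Hz / 15 s, cardiac afferent
#' (post-vagotomy) 5 mA / 2 ms / 10 Hz / 15 s, laryngeal
#' 0.2 mA / 50 us / 20 Hz / 5 s, pulmonary 0.8 mA / 50 us / 20 Hz / 15 s.
#'
#' @param target one of `"cardiac_efferent"`, `"cardiac_afferent"`,
#'   `"laryngeal"`, `"pulmonary"`.
#' @return a [stim_params()] object.
#' @export
starting_params <- function(target = c("cardiac_efferent", "cardiac_afferent",
                                       "laryngeal", "pulmonary")) {
  target <- match.arg(target)
  switch(target,
    cardiac_efferent = stim_params(1,   1000, 10, 15, 15),
    cardiac_afferent = stim_params(5,   2000, 10, 15, 15),
    laryngeal        = stim_params(0.2,   50, 20,  5,  5),
    pulmonary        = stim_params(0.8,   50, 20, 15, 15))
}
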