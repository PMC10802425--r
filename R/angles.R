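# Angular conventions used throughout the package:
#   angles are degrees, measured CLOCKWISE from the 12 o'clock ("top")
#   direction when the nerve cross-section is viewed from the cranial
#   aspect (x rightward, y upward).  A point at angle theta and radius r
#   therefore sits at (x, y) = r * (sin(theta), cos(theta)).

#' Wrap angles into [0, 360)
#'
#' @param theta_deg numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
wrap_360 <- function(theta_deg) {
  out <- theta_deg %% 360
  out[out < 0] <- out[out < 0] + 360
  out[out == 360] <- 0   # tiny negative inputs land exactly on 360
  out
}

#' Wrap angles into (-180, 180]
#'
#' @param theta_deg numeric vector of angles in degrees.
#' @return signed angles in `(-180, 180]`.
#' @export
wrap_180 <- function(theta_deg) {
  out <- wrap_360(theta_deg)
  out[out > 180] <- out[out > 180] - 360
  out
}

#' Unsigned angular difference on the circle
#'
#' The separation between two directions, always in `[0, 180]`:
#' `min(|a - b| mod 360, 360 - |a - b| mod 360)`.
#'
#' @param a_deg,b_deg angles in degrees (vectorized).
#' @return separation in degrees, in `[0, 180]`.
#' @examples
#' angular_difference(350, 10)  # 20
#' angular_difference(90, 270)  # 180
#' @export
angular_difference <- function(a_deg, b_deg) {
  d <- abs(a_deg - b_deg) %% 360
  pmin(d, 360 - d)
}

#' Circular mean of angles
#'
#' Mean direction of a set of angles via the mean resultant vector.
#'
#' @param theta_deg angles in degrees.
#' @return mean direction in `[0, 360)`; `NaN` if the resultant has
#'   zero length.
#' @export
circular_mean <- function(theta_deg) {
  rad <- theta_deg * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < .Machine$double.eps^0.5) return(NaN)
  wrap_360(atan2(s, c) * 180 / pi)
}

# polar (deg clockwise from top) -> cartesian
pol2cart <- function(theta_deg, r) {
  rad <- theta_deg * pi / 180
  cbind(x = r * sin(rad), y = r * cos(rad))
}

# cartesian -> angle deg clockwise from top, in [0, 360)
cart2theta <- function(x, y) wrap_360(atan2(x, y) * 180 / pi)
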