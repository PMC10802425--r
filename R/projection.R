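# Co-registration of traced fascicles onto the normalized circular
# cross-section anchored to the cuff.  The radial coordinate preserves
# each fascicle's distance to its nearest electrode pad
# (r_norm = (R_cuff - d) / R_cuff); the angular coordinate keeps the
# fascicle's own angle about the nerve centroid, preserving the
# circumferential ordering the sector back-projection relies on.

#' Nearest electrode pair of a fascicle
#'
#' Euclidean distance from the fascicle centroid to each pad center
#' (pads on the circle of radius `cuff_inner_diameter/2`, nerve centered
#' in the cuff); ties go to the lowest pair index.
#'
#' @param fascicle one row of a nerve's fascicle table (or any list
#'   with `center_x_mm` / `center_y_mm`).
#' @param array an [electrode_array()].
#' @return list with `pair_index` and `distance_mm`.
#' @export
nearest_electrode <- function(fascicle, array) {
  pads <- pad_coords(array)
  d <- sqrt((pads[, 1] - fascicle$center_x_mm)^2 +
            (pads[, 2] - fascicle$center_y_mm)^2)
  # ties (within floating noise) go to the lowest pair index
  j <- which(d <= min(d) + 1e-9)[1]
  list(pair_index = as.integer(j), distance_mm = d[j])
}

#' Project a fascicle onto the normalized cross-section
#'
#' Radial placement preserves the nearest-electrode distance:
#' `r_norm = clamp((R_cuff - distance) / R_cuff, 0, 1)`; the angle is
#' the fascicle's own angular coordinate about the nerve centroid
#' (degenerate center case maps to 0 degrees), or optionally the
#' nearest pad's angle (`angle = "pad"`, for sensitivity analysis).
#' The equivalent radius is normalized by the cuff radius.
#'
#' @param fascicle one row of a fascicle table.
#' @param array an [electrode_array()].
#' @param angle `"fascicle"` (default) keeps the fascicle's own angle;
#'   `"pad"` snaps to the nearest pad's angle.
#' @return list of class `placement` with `fascicle_id`, `theta_deg`,
#'   `r_norm`, `radius_norm`, `nearest_pair`.
#' @export
project_fascicle <- function(fascicle, array,
                             angle = c("fascicle", "pad")) {
  angle <- match.arg(angle)
  ne <- nearest_electrode(fascicle, array)
  R <- cuff_radius(array)
  r_norm <- min(max((R - ne$distance_mm) / R, 0), 1)
  theta <- if (angle == "pad") {
    array$pad_angles_deg[ne$pair_index]
  } else if (fascicle$center_x_mm == 0 && fascicle$center_y_mm == 0) {
    0
  } else {
    cart2theta(fascicle$center_x_mm, fascicle$center_y_mm)
  }
  structure(
    list(fascicle_id = fascicle$fascicle_id, theta_deg = theta,
         r_norm = r_norm, radius_norm = fascicle$radius_mm / R,
         nearest_pair = ne$pair_index),
    class = "placement")
}

#' Binary presence map of one functional group
#'
#' Projects every fascicle of the group onto the unit disk and
#' rasterizes each as a filled disk (pixels whose centers fall inside
#' the projected fascicle outline are set to 1; union over fascicles).
#'
#' @param nerve a [nerve_section()].
#' @param array an [electrode_array()].
#' @param group one of [map_groups()].
#' @param grid_size pixels per raster side.
#' @param membership optional override of [group_membership()].
#' @param angle passed to [project_fascicle()].
#' @return a [circular_map()] of kind `binary`, rotation 0.
#' @export
build_group_map <- function(nerve, array, group, grid_size = 256L,
                            membership = NULL,
                            angle = c("fascicle", "pad")) {
  group <- match.arg(group, map_groups())
  organs <- group_membership(group, membership)
  f <- nerve$fascicles
  f <- f[f$organ_label %in% organs, , drop = FALSE]
  pg <- pixel_grid(grid_size)
  v <- matrix(0, grid_size, grid_size)
  if (!nrow(f)) {
    warning("nerve ", nerve$nerve_id, " has no fascicles in group '",
            group, "': all-zero map")
  } else {
    for (i in seq_len(nrow(f))) {
      pl <- project_fascicle(f[i, ], array, angle = angle)
      c_xy <- pol2cart(pl$theta_deg, pl$r_norm)
      inside <- (pg$X - c_xy[1])^2 + (pg$Y - c_xy[2])^2 <=
        pl$radius_norm^2
      v[inside] <- 1
    }
    v[!pg$mask] <- 0
  }
  circular_map(v, group = group, kind = "binary",
               animal_id = nerve$animal_id, rotation_applied_deg = 0)
}

#' Rotationally align one animal's maps to the cardiac efferent
#' reference
#'
#' Computes the center-of-mass angle of the `cardiac_efferent` map
#' (absolute-value weights) and rotates every map in the set by its
#' negation, so that after alignment the cardiac efferent center of
#' mass sits at 0 degrees (top).  Binary maps are resampled
#' nearest-neighbor and re-thresholded; response maps bilinearly.
#'
#' @param maps named list of [circular_map()]s of one animal, including
#'   a `cardiac_efferent` entry.
#' @param reference_group group whose center of mass defines the
#'   reference angle.
#' @return the aligned maps (same names), each with
#'   `rotation_applied_deg` recorded.
#' @export
align_maps <- function(maps, reference_group = "cardiac_efferent") {
  groups <- vapply(maps, `[[`, "", "group")
  ref <- maps[[match(reference_group, groups)]]
  if (is.null(ref))
    stop("no '", reference_group, "' map in the set: cannot align")
  if (all(ref$values == 0))
    stop("the '", reference_group,
         "' map is all zero: no alignment reference")
  ref_angle <- center_of_mass(ref)$angle_deg
  lapply(maps, rotate_map, angle_deg = -ref_angle)
}

#' @rdname align_maps
#' @export
align_response_maps <- align_maps
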