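#' A traced nerve cross-section
#'
#' One nerve's tracing at the cuff level: the nerve outline radius and a
#' table of fascicles, each with its centroid (mm, origin at the nerve
#' centroid, x rightward, y upward viewed from the cranial aspect), its
#' equivalent radius, the organ whose fibers it carries, and its fiber
#' class.
#'
#' @param nerve_id,animal_id identifiers.
#' @param nerve_radius_mm radius of the (circularized) nerve outline, mm.
#' @param fascicles data frame with columns `fascicle_id`,
#'   `center_x_mm`, `center_y_mm`, `radius_mm`, `organ_label`,
#'   `fiber_class`.
#' @return an object of class `nerve_section`.
#' @export
nerve_section <- function(nerve_id, animal_id, nerve_radius_mm, fascicles) {
  if (!isTRUE(nerve_radius_mm > 0))
    stop("`nerve_radius_mm` must be positive")
  cols <- c("fascicle_id", "center_x_mm", "center_y_mm", "radius_mm",
            "organ_label", "fiber_class")
  fascicles <- as.data.frame(fascicles)
  missing <- setdiff(cols, names(fascicles))
  if (length(missing))
    stop("fascicle table is missing column(s): ",
         paste(missing, collapse = ", "))
  fascicles <- fascicles[cols]
  if (nrow(fascicles)) {
    bad <- !fascicles$organ_label %in% organ_labels()
    if (any(bad))
      stop("unknown organ_label(s): ",
           paste(unique(fascicles$organ_label[bad]), collapse = ", "),
           " (allowed: ", paste(organ_labels(), collapse = ", "), ")")
    bad <- !fascicles$fiber_class %in% c("afferent", "efferent", "mixed")
    if (any(bad))
      stop("unknown fiber_class(es): ",
           paste(unique(fascicles$fiber_class[bad]), collapse = ", "))
    if (any(fascicles$radius_mm <= 0))
      stop("fascicle radius_mm must be positive")
    d <- sqrt(fascicles$center_x_mm^2 + fascicles$center_y_mm^2)
    out <- d > nerve_radius_mm + 1e-9
    if (any(out))
      stop("fascicle centroid(s) beyond the nerve radius: ",
           paste(fascicles$fascicle_id[out], collapse = ", "))
  }
  structure(
    list(nerve_id = as.character(nerve_id),
         animal_id = as.character(animal_id),
         nerve_radius_mm = nerve_radius_mm,
         fascicles = fascicles),
    class = "nerve_section")
}

#' @export
print.nerve_section <- function(x, ...) {
  cat(sprintf("<nerve_section> %s (animal %s): radius %.3f mm, %d fascicles\n",
              x$nerve_id, x$animal_id, x$nerve_radius_mm, nrow(x$fascicles)))
  if (nrow(x$fascicles))
    print(table(x$fascicles$organ_label))
  invisible(x)
}

#' Membership of fascicles in a functional group
#'
#' Maps the five tracing organ labels onto the four mapped functional
#' groups using a "contains fibers of that organ" rule:
#' `cardiac_efferent` = purely cardiac fascicles (all efferent),
#' `cardiac_afferent` = cardiopulmonary fascicles (the cardiac afferent
#' carriers), `pulmonary` = pulmonary + cardiopulmonary +
#' laryngopulmonary, `laryngeal` = recurrent laryngeal +
#' laryngopulmonary.
#'
#' @param group one of [map_groups()].
#' @param membership optional named list overriding the default
#'   organ-label sets.
#' @return character vector of organ labels belonging to `group`.
#' @export
group_membership <- function(group, membership = NULL) {
  group <- match.arg(group, map_groups())
  default <- list(
    cardiac_efferent = "cardiac",
    cardiac_afferent = "cardiopulmonary",
    pulmonary = c("pulmonary", "cardiopulmonary", "laryngopulmonary"),
    laryngeal = c("recurrent_laryngeal", "laryngopulmonary"))
  if (!is.null(membership)) default[names(membership)] <- membership
  default[[group]]
}

#' A 14-pair response table
#'
#' Physiological percent-change responses of one modality for one
#' nerve/condition: exactly one signed percent change per electrode
#' pair.
#'
#' @param nerve_id,animal_id identifiers.
#' @param modality one of `"HR"`, `"BR"`, `"EtCO2"`, `"EMG"`.
#' @param condition one of `"pre_vagotomy"`, `"post_vagotomy"`,
#'   `"post_double_vagotomy"`.
#' @param pct_change numeric vector, one finite value per pair, indexed
#'   1..n_pairs.
#' @param stim optional [stim_params()] used for the trial.
#' @return an object of class `response_table`.
#' @export
response_table <- function(nerve_id, animal_id = nerve_id,
                           modality = c("HR", "BR", "EtCO2", "EMG"),
                           condition = c("pre_vagotomy", "post_vagotomy",
                                         "post_double_vagotomy"),
                           pct_change, stim = NULL) {
  modality <- match.arg(modality)
  condition <- match.arg(condition)
  if (any(!is.finite(pct_change)))
    stop("`pct_change` must be finite for every pair")
  structure(
    list(nerve_id = as.character(nerve_id),
         animal_id = as.character(animal_id),
         modality = modality, condition = condition,
         pct_change = as.numeric(pct_change), stim = stim),
    class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("<response_table> %s / %s / %s\n", x$nerve_id, x$modality,
              x$condition))
  v <- formatC(x$pct_change, format = "f", digits = 1)
  cat("  % change by pair: ", paste(v, collapse = " "), "\n", sep = "")
  invisible(x)
}
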