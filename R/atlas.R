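# Cross-animal atlas maps: pixel-wise averages of aligned per-animal
# maps.  For binary sources the average is already the
# fraction-of-animals semantics (0 = no animal, 1 = every animal has
# that group at the location); response sources are averaged in
# magnitude and peak-normalized to 1.

#' Build a cross-animal atlas map
#'
#' @param maps list of aligned per-animal [circular_map()]s of one
#'   group, one grid size; each must have its rotation recorded
#'   (i.e. have been through [align_maps()]).
#' @param source_kind `"binary"` (fascicle presence maps) or
#'   `"response"` (back-projection maps); default taken from the maps.
#' @return an `atlas_map` (also a `circular_map` of kind `atlas`) with
#'   `n_animals` and `source_kind` fields.
#' @export
build_atlas <- function(maps, source_kind = NULL) {
  if (!length(maps)) stop("need at least one map")
  groups <- vapply(maps, `[[`, "", "group")
  sizes <- vapply(maps, `[[`, 0L, "grid_size")
  kinds <- vapply(maps, `[[`, "", "kind")
  if (length(unique(groups)) != 1L)
    stop("maps mix groups: ", paste(unique(groups), collapse = ", "))
  if (length(unique(sizes)) != 1L)
    stop("maps mix grid sizes: ", paste(unique(sizes), collapse = ", "))
  if (is.null(source_kind)) source_kind <- unique(kinds)
  if (length(source_kind) != 1L ||
      !source_kind %in% c("binary", "response"))
    stop("`source_kind` must be one of 'binary', 'response'")
  unaligned <- vapply(maps, function(m) is.na(m$rotation_applied_deg),
                      TRUE)
  if (any(unaligned))
    stop(sum(unaligned), " map(s) have no recorded rotation: ",
         "align the set before atlas averaging")
  n <- length(maps)
  acc <- Reduce(`+`, lapply(maps, function(m)
    if (source_kind == "response") abs(m$values) else m$values))
  v <- acc / n
  if (source_kind == "response") {
    mx <- max(v)
    if (mx > 0) v <- v / mx       # peak-normalize; all-zero stays zero
  }
  out <- circular_map(v, group = groups[1], kind = "atlas",
                      animal_id = NA_character_, rotation_applied_deg = 0)
  out$n_animals <- n
  out$source_kind <- source_kind
  class(out) <- c("atlas_map", class(out))
  out
}

#' Threshold an atlas into a binary region
#'
#' Pixels with atlas value strictly above `tau` form the region.  The
#' default is the union region (`tau = 0`) for binary-sourced atlases
#' and the half-peak region (`tau = 0.5`) for response-sourced ones.
#'
#' @param atlas an `atlas_map`.
#' @param tau threshold in `[0, 1)`.
#' @return a binary [circular_map()] of the same group.
#' @export
atlas_support <- function(atlas, tau = NULL) {
  if (is.null(tau))
    tau <- if (identical(atlas$source_kind, "response")) 0.5 else 0
  stopifnot(tau >= 0, tau < 1)
  circular_map((atlas$values > tau) + 0, group = atlas$group,
               kind = "binary", animal_id = NA_character_,
               rotation_applied_deg = 0)
}
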