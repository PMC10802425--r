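# On-disk interchange formats.  All tables are comma-separated UTF-8
# with a mandatory header row and "." decimals; maps are a CSV numeric
# grid plus a JSON sidecar (<path>.json) carrying the metadata needed
# to re-interpret the raster.

fasc_cols <- c("nerve_id", "animal_id", "nerve_radius_mm", "fascicle_id",
               "x_mm", "y_mm", "radius_mm", "organ_label", "fiber_class")

#' Read a fascicle tracing table
#'
#' Parses a CSV of traced fascicle centroids (columns `nerve_id`,
#' `animal_id`, `nerve_radius_mm`, `fascicle_id`, `x_mm`, `y_mm`,
#' `radius_mm`, `organ_label`, `fiber_class`) into one
#' [nerve_section()] per distinct `nerve_id`, validating the organ
#' vocabulary and centroid containment.
#'
#' @param path CSV file path.
#' @return list of [nerve_section()] objects (possibly empty).
#' @export
read_fascicle_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(fasc_cols, names(df))
  if (length(missing))
    stop("fascicle table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(df)) return(list())
  lapply(split(df, df$nerve_id)[unique(df$nerve_id)], function(d) {
    r <- unique(d$nerve_radius_mm)
    if (length(r) != 1L)
      stop("nerve ", d$nerve_id[1], " has inconsistent nerve_radius_mm")
    nerve_section(
      nerve_id = d$nerve_id[1], animal_id = d$animal_id[1],
      nerve_radius_mm = r,
      fascicles = data.frame(
        fascicle_id = d$fascicle_id,
        center_x_mm = d$x_mm, center_y_mm = d$y_mm,
        radius_mm = d$radius_mm, organ_label = d$organ_label,
        fiber_class = d$fiber_class))
  })
}

#' Write fascicle tracings to CSV
#'
#' Inverse of [read_fascicle_table()].
#'
#' @param nerves a [nerve_section()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fascicle_table <- function(nerves, path) {
  if (inherits(nerves, "nerve_section")) nerves <- list(nerves)
  rows <- lapply(nerves, function(n) {
    f <- n$fascicles
    if (!nrow(f)) return(NULL)
    data.frame(nerve_id = n$nerve_id, animal_id = n$animal_id,
               nerve_radius_mm = n$nerve_radius_mm,
               fascicle_id = f$fascicle_id, x_mm = f$center_x_mm,
               y_mm = f$center_y_mm, radius_mm = f$radius_mm,
               organ_label = f$organ_label, fiber_class = f$fiber_class)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(fasc_cols)),
                                        fasc_cols))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-pair response tables
#'
#' Parses a CSV with columns `nerve_id`, `modality`, `pair_index`,
#' `pct_change` and optionally `animal_id`, `condition` (default
#' `pre_vagotomy`), `amplitude_mA`, `pulse_width_us`, `frequency_Hz`.
#' Each (`nerve_id`, `modality`, `condition`) block must contain exactly
#' one row per pair index 1..`n_pairs`.
#'
#' @param path CSV file path.
#' @param n_pairs expected number of pairs per table.
#' @return list of [response_table()] objects.
#' @export
read_response_table <- function(path, n_pairs = 14L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nerve_id", "modality", "pair_index", "pct_change")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("response table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!"condition" %in% names(df)) df$condition <- "pre_vagotomy"
  if (!"animal_id" %in% names(df)) df$animal_id <- df$nerve_id
  key <- paste(df$nerve_id, df$modality, df$condition, sep = "\r")
  lapply(split(df, key)[unique(key)], function(d) {
    idx <- d$pair_index
    if (anyDuplicated(idx))
      stop("duplicate pair_index ", paste(unique(idx[duplicated(idx)]),
                                          collapse = ", "),
           " for nerve ", d$nerve_id[1], " / ", d$modality[1])
    absent <- setdiff(seq_len(n_pairs), idx)
    if (length(absent))
      stop("missing pair_index ", paste(absent, collapse = ", "),
           " for nerve ", d$nerve_id[1], " / ", d$modality[1])
    d <- d[order(idx), ]
    stim <- if (all(c("amplitude_mA", "pulse_width_us", "frequency_Hz") %in%
                    names(d)))
      stim_params(d$amplitude_mA[1], d$pulse_width_us[1], d$frequency_Hz[1])
    response_table(d$nerve_id[1], d$animal_id[1], d$modality[1],
                   d$condition[1], d$pct_change, stim = stim)
  })
}

#' Write response tables to CSV
#'
#' Inverse of [read_response_table()].
#'
#' @param tables a [response_table()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(tables, path) {
  if (inherits(tables, "response_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, function(t) {
    n <- length(t$pct_change)
    d <- data.frame(nerve_id = t$nerve_id, animal_id = t$animal_id,
                    modality = t$modality, condition = t$condition,
                    pair_index = seq_len(n), pct_change = t$pct_change)
    if (!is.null(t$stim)) {
      d$amplitude_mA <- t$stim$amplitude_mA
      d$pulse_width_us <- t$stim$pulse_width_us
      d$frequency_Hz <- t$stim$frequency_Hz
    }
    d
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a circular map raster
#'
#' Writes the numeric grid as headerless CSV and a JSON sidecar
#' (`<path>.json`) carrying `grid_size`, `group`, `animal_id`,
#' `rotation_applied_deg`, `kind` (plus `n_animals` / `source_kind` for
#' atlases).  [read_map()] reproduces the values bit-exactly (full
#' precision serialization).
#'
#' @param map a [circular_map()] or atlas map.
#' @param path output CSV path for the grid.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  txt <- apply(map$values, 1L,
               function(row) paste(sprintf("%.17g", row), collapse = ","))
  writeLines(txt, path)
  meta <- list(grid_size = map$grid_size, group = map$group,
               animal_id = map$animal_id,
               rotation_applied_deg = map$rotation_applied_deg,
               kind = map$kind)
  if (!is.null(map$n_animals)) meta$n_animals <- map$n_animals
  if (!is.null(map$source_kind)) meta$source_kind <- map$source_kind
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a circular map raster
#'
#' Inverse of [write_map()].
#'
#' @param path CSV path written by [write_map()].
#' @return a [circular_map()] (class `atlas_map` too if the sidecar says
#'   so).
#' @export
read_map <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar file ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  v <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(v) <- NULL
  storage.mode(v) <- "double"
  if (nrow(v) != meta$grid_size || ncol(v) != meta$grid_size)
    stop("grid in ", path, " does not match sidecar grid_size")
  m <- circular_map(v, group = meta$group, kind = meta$kind,
                    animal_id = if (is.null(meta$animal_id)) NA_character_
                                else meta$animal_id,
                    rotation_applied_deg =
                      if (is.null(meta$rotation_applied_deg)) NA_real_
                      else meta$rotation_applied_deg)
  if (!is.null(meta$n_animals)) {
    m$n_animals <- meta$n_animals
    m$source_kind <- meta$source_kind
    class(m) <- c("atlas_map", class(m))
  }
  m
}

#' Write electrode-array geometry
#'
#' Serializes an [electrode_array()] as JSON.
#'
#' @param array an [electrode_array()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_electrode_array <- function(array, path) {
  jsonlite::write_json(unclass(array), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read electrode-array geometry
#'
#' Inverse of [write_electrode_array()].
#'
#' @param path JSON path.
#' @return an [electrode_array()].
#' @export
read_electrode_array <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  electrode_array(n_pairs = m$n_pairs, pad_angles_deg = m$pad_angles_deg,
                  cuff_inner_diameter_mm = m$cuff_inner_diameter_mm,
                  pad_length_mm = m$pad_length_mm,
                  pad_width_mm = m$pad_width_mm)
}
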