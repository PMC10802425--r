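#' Circular raster map over the unit disk
#'
#' The common raster container for all cross-section maps: a square
#' `grid_size x grid_size` matrix whose pixel centers are mapped onto
#' the square `[-1, 1]^2` (row 1 at the top), with the nerve
#' cross-section occupying the inscribed unit disk.  Pixels whose
#' centers fall outside the disk are always 0.
#'
#' Three kinds of map share the container: `binary` (fascicle presence,
#' values 0/1), `response` (per-sector physiological percent change,
#' signed), and `atlas` (cross-animal fraction, values in `[0, 1]`).
#'
#' @param values numeric square matrix.
#' @param group functional group of the map: one of `"laryngeal"`,
#'   `"pulmonary"`, `"cardiac_efferent"`, `"cardiac_afferent"`.
#' @param kind one of `"binary"`, `"response"`, `"atlas"`.
#' @param animal_id identifier of the contributing animal (`NA` for an
#'   atlas).
#' @param rotation_applied_deg rotation already applied to the raster,
#'   degrees clockwise; `NA` until the map has been aligned.
#' @return an object of class `circular_map`.
#' @seealso [build_group_map()], [build_sector_map()], [build_atlas()]
#' @export
circular_map <- function(values, group, kind = c("binary", "response", "atlas"),
                         animal_id = NA_character_,
                         rotation_applied_deg = NA_real_) {
  kind <- match.arg(kind)
  group <- match.arg(group, map_groups())
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("`values` must be a square matrix")
  g <- nrow(values)
  mask <- disk_mask(g)
  if (any(values[!mask] != 0))
    stop("pixels outside the disk mask must be 0")
  if (kind == "binary" && !all(values %in% c(0, 1)))
    stop("a binary map may only hold values 0 and 1")
  if (kind == "atlas" && (any(values < 0) || any(values > 1)))
    stop("an atlas map must hold values in [0, 1]")
  structure(
    list(values = values, grid_size = g, group = group, kind = kind,
         animal_id = animal_id,
         rotation_applied_deg = rotation_applied_deg),
    class = "circular_map")
}

#' Functional group labels
#'
#' The four functional groups mapped over the cross-section.
#' @return character vector of the four group names.
#' @export
map_groups <- function() {
  c("laryngeal", "pulmonary", "cardiac_efferent", "cardiac_afferent")
}

#' Organ-label vocabulary of fascicle tracings
#'
#' The five organ labels assigned to traced fascicles.
#' @return character vector of the five organ labels.
#' @export
organ_labels <- function() {
  c("cardiac", "recurrent_laryngeal", "pulmonary", "cardiopulmonary",
    "laryngopulmonary")
}

# Pixel-center coordinate vectors for a g-grid: col j center x, row i
# center y, both in [-1, 1]; row 1 is the top of the image.
pixel_axes <- function(grid_size) {
  step <- 2 / grid_size
  x <- -1 + (seq_len(grid_size) - 0.5) * step
  list(x = x, y = rev(x))  # y decreases with row index
}

# cache of disk masks / coordinate grids keyed by grid size
.map_cache <- new.env(parent = emptyenv())

# Full pixel-center coordinate matrices (grid_size^2 each).
pixel_grid <- function(grid_size) {
  key <- paste0("g", grid_size)
  got <- .map_cache[[key]]
  if (!is.null(got)) return(got)
  ax <- pixel_axes(grid_size)
  X <- matrix(ax$x, grid_size, grid_size, byrow = TRUE)
  Y <- matrix(ax$y, grid_size, grid_size)
  out <- list(X = X, Y = Y, mask = X^2 + Y^2 <= 1,
              theta = cart2theta(X, Y), r = sqrt(X^2 + Y^2))
  .map_cache[[key]] <- out
  out
}

#' Disk mask for a grid size
#'
#' Logical matrix marking pixels whose center lies inside the unit disk
#' inscribed in the raster.
#'
#' @param grid_size pixels per side.
#' @return `grid_size x grid_size` logical matrix.
#' @export
disk_mask <- function(grid_size) pixel_grid(grid_size)$mask

#' @export
print.circular_map <- function(x, ...) {
  cat(sprintf("<circular_map> %s / %s, %dx%d grid", x$kind, x$group,
              x$grid_size, x$grid_size))
  if (!is.na(x$animal_id)) cat(", animal ", x$animal_id, sep = "")
  if (!is.na(x$rotation_applied_deg))
    cat(sprintf(", rotated %.2f deg", x$rotation_applied_deg))
  nz <- sum(x$values != 0)
  cat(sprintf("; %d nonzero pixels\n", nz))
  invisible(x)
}

#' @export
plot.circular_map <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- sprintf("%s (%s)", x$group, x$kind)
  v <- x$values
  # orient so the top row is drawn at the top
  img <- t(v[rev(seq_len(nrow(v))), , drop = FALSE])
  pal <- grDevices::hcl.colors(64, "viridis")
  graphics::image(img, axes = FALSE, asp = 1, col = pal, main = main, ...)
  invisible(x)
}

#' Rotate a circular map about its center
#'
#' Rotates the raster by `angle_deg` clockwise (the direction of
#' increasing map angle).  Binary maps are resampled nearest-neighbor
#' and re-thresholded at 0.5; response and atlas maps are resampled
#' bilinearly.  Pixels sampling outside the disk read 0.
#'
#' @param map a [circular_map()].
#' @param angle_deg rotation, degrees clockwise from top.
#' @param method `"auto"` (nearest for binary, bilinear otherwise),
#'   `"nearest"` or `"bilinear"`.
#' @return the rotated map; `rotation_applied_deg` is accumulated.
#' @export
rotate_map <- function(map, angle_deg,
                       method = c("auto", "nearest", "bilinear")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (map$kind == "binary") "nearest" else "bilinear"
  g <- map$grid_size
  pg <- pixel_grid(g)
  # output pixel at p reads input at the point rotated by -angle
  rad <- -angle_deg * pi / 180
  xs <- pg$X * cos(rad) + pg$Y * sin(rad)
  ys <- -pg$X * sin(rad) + pg$Y * cos(rad)
  step <- 2 / g
  # fractional (row, col) indices of the source point
  cj <- (xs + 1) / step + 0.5
  ri <- (1 - ys) / step + 0.5
  v <- map$values
  out <- matrix(0, g, g)
  if (method == "nearest") {
    rn <- round(ri); cn <- round(cj)
    ok <- rn >= 1 & rn <= g & cn >= 1 & cn <= g
    out[ok] <- v[cbind(rn[ok], cn[ok])]
  } else {
    r0 <- floor(ri); c0 <- floor(cj)
    fr <- ri - r0; fc <- cj - c0
    gv <- function(rr, cc) {
      ok <- rr >= 1 & rr <= g & cc >= 1 & cc <= g
      z <- numeric(length(rr))
      z[ok] <- v[cbind(rr[ok], cc[ok])]
      z
    }
    out[] <- (1 - fr) * (1 - fc) * gv(r0, c0) +
             (1 - fr) * fc       * gv(r0, c0 + 1L) +
             fr       * (1 - fc) * gv(r0 + 1L, c0) +
             fr       * fc       * gv(r0 + 1L, c0 + 1L)
  }
  if (map$kind == "binary") out <- (out >= 0.5) + 0
  out[!pg$mask] <- 0
  prev <- map$rotation_applied_deg
  map$values <- out
  map$rotation_applied_deg <-
    wrap_360(if (is.na(prev)) angle_deg else prev + angle_deg)
  map
}
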