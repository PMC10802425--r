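# Spatial statistics on circular maps: centers of mass in polar form,
# circular angular separations, ANOVA with multiple comparisons on
# unwrapped angles, area fractions and pairwise region overlaps.

#' Center of mass of a circular map
#'
#' Cartesian centroid of pixel centers weighted by the absolute map
#' value, reported in polar form (angle clockwise from top).
#'
#' @param map a [circular_map()].
#' @return object of class `com`: `group`, `animal_id`, `angle_deg` in
#'   `[0, 360)`, `r_norm`, `weight_total`.
#' @export
center_of_mass <- function(map) {
  w <- abs(map$values)
  tot <- sum(w)
  if (tot == 0)
    stop("all-zero map: center of mass undefined (group '",
         map$group, "', animal ", map$animal_id, ")")
  pg <- pixel_grid(map$grid_size)
  x <- sum(w * pg$X) / tot
  y <- sum(w * pg$Y) / tot
  structure(
    list(group = map$group, animal_id = map$animal_id,
         angle_deg = cart2theta(x, y), r_norm = sqrt(x^2 + y^2),
         weight_total = tot),
    class = "com")
}

#' @export
print.com <- function(x, ...) {
  cat(sprintf("<com> %s / %s: angle %.1f deg, r %.3f\n",
              x$group, x$animal_id, x$angle_deg, x$r_norm))
  invisible(x)
}

# collect coms (list of `com` or data.frame) into a data.frame
com_frame <- function(coms) {
  if (is.data.frame(coms)) return(coms)
  do.call(rbind, lapply(coms, function(c)
    data.frame(group = c$group, animal_id = c$animal_id,
               angle_deg = c$angle_deg, r_norm = c$r_norm)))
}

#' Per-animal angular separation of two groups
#'
#' Matches animals having a defined center of mass in both groups
#' (others are excluded), computes each animal's signed circular
#' difference of CoM angles, and summarizes with the circular mean
#' direction (reported as an unsigned separation in `[0, 180]`) and the
#' circular SD about it.  The circular mean is unbiased at a true
#' separation of 180 degrees, where a linear mean of folded `[0, 180]`
#' differences would be pulled downward.  The p-value is the pairwise
#' comparison from [angular_anova()] restricted to the two groups.
#'
#' @param coms list of `com` objects (or a data.frame with `group`,
#'   `animal_id`, `angle_deg`) covering both groups.
#' @param group_a,group_b the two group names.
#' @return object of class `separation_result`: `group_pair`,
#'   `per_animal_separation_deg` (folded, `[0, 180]`), `mean_deg`,
#'   `sd_deg`, `p_value`, `n`.
#' @export
group_separation <- function(coms, group_a, group_b) {
  df <- com_frame(coms)
  a <- df[df$group == group_a, ]
  b <- df[df$group == group_b, ]
  ids <- intersect(a$animal_id, b$animal_id)
  if (length(ids) < 2L)
    stop("need at least 2 animals with both CoMs defined; have ",
         length(ids))
  da <- a$angle_deg[match(ids, a$animal_id)]
  db <- b$angle_deg[match(ids, b$animal_id)]
  signed <- wrap_180(da - db)
  mu <- circular_mean(signed)
  dev <- wrap_180(signed - mu)
  sd_deg <- stats::sd(dev)
  p <- tryCatch(
    angular_anova(df[df$group %in% c(group_a, group_b), ])$pairwise$p_adj[1],
    error = function(e) NA_real_)
  structure(
    list(group_pair = c(group_a, group_b),
         per_animal_separation_deg = angular_difference(da, db),
         mean_deg = abs(wrap_180(mu)), sd_deg = sd_deg, p_value = p,
         n = length(ids)),
    class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation> %s vs %s: %.0f +/- %.0f deg (n = %d, p = %s)\n",
              x$group_pair[1], x$group_pair[2], x$mean_deg, x$sd_deg, x$n,
              format.pval(x$p_value, digits = 2)))
  invisible(x)
}

# Unwrap angles for linear ANOVA: within each group, deviations are
# taken about the group's circular mean (so a group straddling 0/360
# stays coherent); the group means themselves are then placed on the
# branch of the pooled circular mean, so that no two groups end up 360
# degrees apart by branch choice.
unwrap_angles <- function(angles, group) {
  M <- circular_mean(angles)
  if (is.nan(M)) M <- 0
  out <- numeric(length(angles))
  for (g in unique(group)) {
    i <- group == g
    mu <- circular_mean(angles[i])
    if (is.nan(mu)) mu <- M
    out[i] <- M + wrap_180(mu - M) + wrap_180(angles[i] - mu)
  }
  out
}

#' ANOVA with multiple comparisons on CoM angles
#'
#' Each group's angles are unwrapped about the group's circular mean,
#' then compared by one-way fixed-effects ANOVA with Tukey-Kramer
#' pairwise comparisons (the default), or by the Watson-Williams
#' circular test with Holm-adjusted pairwise tests
#' (`method = "watson_williams"`).
#'
#' @param coms list of `com` objects or a data.frame with `group`,
#'   `animal_id`, `angle_deg`; at least 2 groups with at least 2
#'   animals each.
#' @param method `"anova"` or `"watson_williams"`.
#' @return list with `omnibus_p`, `pairwise` (data frame `group_a`,
#'   `group_b`, `p_adj`), and the underlying `fit`.
#' @export
angular_anova <- function(coms, method = c("anova", "watson_williams")) {
  method <- match.arg(method)
  df <- com_frame(coms)
  tab <- table(df$group)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 groups with >= 2 animals each")
  df$group <- factor(df$group)
  df$unwrapped <- unwrap_angles(df$angle_deg, df$group)
  groups <- levels(df$group)
  if (method == "anova") {
    vars <- tapply(df$unwrapped, df$group, stats::var)
    if (all(vars < .Machine$double.eps))
      warning("zero angular variance within every group: ",
              "the F statistic is degenerate")
    fit <- stats::aov(unwrapped ~ group, data = df)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(
      group_a = vapply(pairs, `[`, "", 2L),
      group_b = vapply(pairs, `[`, "", 1L),
      p_adj = unname(tk[, "p adj"]))
    list(omnibus_p = omnibus_p, pairwise = pairwise, fit = fit,
         method = "anova")
  } else {
    ww <- function(a, g) {
      g <- factor(g)
      k <- nlevels(g); N <- length(a)
      rad <- a * pi / 180
      Rg <- tapply(seq_along(a), g, function(i)
        sqrt(sum(sin(rad[i]))^2 + sum(cos(rad[i]))^2))
      Rt <- sqrt(sum(sin(rad))^2 + sum(cos(rad))^2)
      rbar <- sum(Rg) / N
      K <- 1 + 3 / (8 * est_kappa(rbar))  # small-sample correction
      Fstat <- K * ((N - k) * (sum(Rg) - Rt)) / ((k - 1) * (N - sum(Rg)))
      stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
    }
    omnibus_p <- ww(df$angle_deg, df$group)
    combs <- utils::combn(groups, 2)
    praw <- apply(combs, 2, function(gp) {
      sub <- df[df$group %in% gp, ]
      ww(sub$angle_deg, droplevels(sub$group))
    })
    pairwise <- data.frame(group_a = combs[1, ], group_b = combs[2, ],
                           p_adj = stats::p.adjust(praw, "holm"))
    list(omnibus_p = omnibus_p, pairwise = pairwise, fit = NULL,
         method = "watson_williams")
  }
}

# ML estimate of the von Mises concentration from mean resultant length
est_kappa <- function(rbar) {
  if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
  else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
}

#' Area fraction of a binary region
#'
#' Percent of unit-disk pixels set in the region.
#'
#' @param region a binary [circular_map()].
#' @return percent of the disk, in `[0, 100]`.
#' @export
area_fraction <- function(region) {
  mask <- disk_mask(region$grid_size)
  100 * sum(region$values[mask] != 0) / sum(mask)
}

#' Overlap of two binary regions
#'
#' Intersection pixel count as a percent of each region's own area.
#' An empty region's own percentage is undefined and reported `NA`.
#'
#' @param region_a,region_b binary [circular_map()]s on the same grid.
#' @return object of class `overlap_result`: `group_pair`,
#'   `area_pct_a`, `area_pct_b` (percent of disk),
#'   `overlap_pct_of_a`, `overlap_pct_of_b`.
#' @export
overlap <- function(region_a, region_b) {
  if (region_a$grid_size != region_b$grid_size)
    stop("regions are on different grids (", region_a$grid_size, " vs ",
         region_b$grid_size, ")")
  A <- region_a$values != 0
  B <- region_b$values != 0
  I <- sum(A & B)
  structure(
    list(group_pair = c(region_a$group, region_b$group),
         area_pct_a = area_fraction(region_a),
         area_pct_b = area_fraction(region_b),
         overlap_pct_of_a = if (sum(A)) 100 * I / sum(A) else NA_real_,
         overlap_pct_of_b = if (sum(B)) 100 * I / sum(B) else NA_real_),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap> %s (%.1f%% of disk) vs %s (%.1f%% of disk): %s / %s\n",
              x$group_pair[1], x$area_pct_a, x$group_pair[2], x$area_pct_b,
              ifelse(is.na(x$overlap_pct_of_a), "NA",
                     sprintf("%.0f%%", x$overlap_pct_of_a)),
              ifelse(is.na(x$overlap_pct_of_b), "NA",
                     sprintf("%.0f%%", x$overlap_pct_of_b))))
  invisible(x)
}
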