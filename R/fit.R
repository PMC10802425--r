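# The cohort-level model object.  `vagus_atlas()` takes the traced
# nerves (microCT arm) and/or the per-pair response tables (ephys arm)
# of a cohort and carries out the full mapping analysis for each arm:
# per-animal maps -> rotational alignment to the cardiac efferent
# reference -> centers of mass -> cross-animal atlases -> separations,
# ANOVA, areas and overlaps.

group_pairs <- function() {
  utils::combn(map_groups(), 2)
}

# analyze one technique arm from per-animal map sets
analyze_arm <- function(maps_by_animal, source_kind, tau = NULL,
                        anova_method = "anova") {
  # drop animals without a usable alignment reference
  usable <- vapply(maps_by_animal, function(maps) {
    ref <- maps[["cardiac_efferent"]]
    !is.null(ref) && any(ref$values != 0)
  }, TRUE)
  excluded <- names(maps_by_animal)[!usable]
  maps_by_animal <- maps_by_animal[usable]
  if (!length(maps_by_animal))
    stop("no animal has a nonempty cardiac_efferent reference map")
  aligned <- lapply(maps_by_animal, align_maps)
  coms <- list()
  for (an in names(aligned)) {
    for (g in names(aligned[[an]])) {
      m <- aligned[[an]][[g]]
      if (any(m$values != 0)) coms[[length(coms) + 1L]] <- center_of_mass(m)
    }
  }
  com_df <- com_frame(coms)
  atlases <- list()
  supports <- list()
  for (g in map_groups()) {
    gm <- lapply(aligned, `[[`, g)
    gm <- gm[!vapply(gm, is.null, TRUE)]
    if (!length(gm)) next
    atlases[[g]] <- build_atlas(gm, source_kind = source_kind)
    supports[[g]] <- atlas_support(atlases[[g]], tau = tau)
  }
  areas <- vapply(supports, area_fraction, 0)
  pairs <- group_pairs()
  seps <- lapply(seq_len(ncol(pairs)), function(i) {
    tryCatch(group_separation(com_df, pairs[1, i], pairs[2, i]),
             error = function(e) NULL)
  })
  names(seps) <- paste(pairs[1, ], pairs[2, ], sep = " vs ")
  ovls <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- supports[[pairs[1, i]]]; b <- supports[[pairs[2, i]]]
    if (is.null(a) || is.null(b)) NULL else overlap(a, b)
  })
  names(ovls) <- names(seps)
  anova_res <- tryCatch(angular_anova(com_df, method = anova_method),
                        error = function(e) NULL)
  list(maps = aligned, coms = com_df, atlases = atlases,
       supports = supports, areas = areas, separations = seps,
       overlaps = ovls, anova = anova_res, excluded = excluded,
       n_animals = length(aligned))
}

# group a flat list of response tables into per-animal map sets
sector_maps_by_animal <- function(responses, array, grid_size) {
  maps_by_animal <- list()
  for (tab in responses) {
    m <- build_sector_map(tab, array, grid_size)
    an <- tab$animal_id
    maps_by_animal[[an]][[m$group]] <- m
  }
  maps_by_animal
}

#' Fit the cross-sectional organization model of a cohort
#'
#' Runs the complete two-arm mapping analysis.  The microCT arm
#' projects each nerve's traced fascicles onto the normalized circular
#' cross-section and builds binary group maps; the ephys arm
#' back-projects per-pair physiological responses onto 14 angular
#' sectors.  Each animal's four maps are rotationally aligned so its
#' cardiac efferent center of mass sits at 0 degrees, per-animal
#' centers of mass are extracted, cross-animal atlases are averaged,
#' and the angular organization is quantified (pairwise separations
#' with circular means, ANOVA with Tukey-Kramer comparisons, area
#' fractions, region overlaps).
#'
#' @param nerves list of [nerve_section()]s (microCT arm), or `NULL`.
#' @param responses list of [response_table()]s (ephys arm), or `NULL`.
#' @param array the [electrode_array()] shared by both arms.
#' @param grid_size raster resolution of all maps.
#' @param tau_response atlas support threshold for the response arm.
#' @param anova_method passed to [angular_anova()].
#' @return an object of class `vagus_atlas` with elements `microct`
#'   and/or `ephys` (each as returned by the per-arm analysis), plus
#'   `array` and `grid_size`.
#' @examples
#' cfg <- synthetic_config(n_animals = 4, seed = 7)
#' cohort <- generate_cohort(cfg)
#' fit <- vagus_atlas(nerves = cohort$nerves, grid_size = 64)
#' coef(fit)
#' @export
vagus_atlas <- function(nerves = NULL, responses = NULL,
                        array = electrode_array(), grid_size = 128L,
                        tau_response = 0.5, anova_method = "anova") {
  if (is.null(nerves) && is.null(responses))
    stop("supply `nerves` (microCT arm) and/or `responses` (ephys arm)")
  out <- list(array = array, grid_size = grid_size)
  if (!is.null(nerves)) {
    maps_by_animal <- lapply(nerves, function(nv) {
      ms <- suppressWarnings(lapply(
        map_groups(),
        function(g) build_group_map(nv, array, g, grid_size)))
      stats::setNames(ms, map_groups())
    })
    names(maps_by_animal) <- vapply(nerves, `[[`, "", "animal_id")
    out$microct <- analyze_arm(maps_by_animal, "binary", tau = 0,
                               anova_method = anova_method)
  }
  if (!is.null(responses)) {
    maps_by_animal <- sector_maps_by_animal(responses, array, grid_size)
    out$ephys <- analyze_arm(maps_by_animal, "response",
                             tau = tau_response,
                             anova_method = anova_method)
  }
  class(out) <- "vagus_atlas"
  out
}

#' @export
print.vagus_atlas <- function(x, ...) {
  cat("Cross-sectional organization fit (vagus_atlas)\n")
  for (arm in c("microct", "ephys")) {
    a <- x[[arm]]
    if (is.null(a)) next
    cat(sprintf("  %s arm: %d animals", arm, a$n_animals))
    if (length(a$excluded))
      cat(" (excluded: ", paste(a$excluded, collapse = ", "), ")", sep = "")
    cat("\n")
    s <- a$separations[["cardiac_efferent vs cardiac_afferent"]]
    if (!is.null(s))
      cat(sprintf("    cardiac efferent vs afferent separation: %.0f +/- %.0f deg (p = %s)\n",
                  s$mean_deg, s$sd_deg, format.pval(s$p_value, digits = 2)))
  }
  invisible(x)
}

#' @export
summary.vagus_atlas <- function(object, ...) {
  out <- list()
  for (arm in c("microct", "ephys")) {
    if (!is.null(object[[arm]]))
      out[[arm]] <- summary_report(object, technique = arm)
  }
  class(out) <- "summary.vagus_atlas"
  out
}

#' @export
print.summary.vagus_atlas <- function(x, ...) {
  for (arm in names(x)) {
    cat("==", arm, "arm ==\n")
    cat("Area fractions (% of disk):\n")
    print(x[[arm]]$areas, row.names = FALSE)
    cat("Angular separations (deg):\n")
    print(x[[arm]]$separations, row.names = FALSE, digits = 3)
    cat("Region overlaps (% of each region):\n")
    print(x[[arm]]$overlaps, row.names = FALSE, digits = 3)
    cat("\n")
  }
  invisible(x)
}

#' Cohort summary tables for one technique
#'
#' Assembles the per-group atlas area fractions, the six pairwise
#' angular separations (circular mean, SD, adjusted p) and the six
#' pairwise region overlaps into plain data frames.  Note that the
#' alignment step pins the cardiac efferent center of mass to 0
#' degrees, so that group's between-animal angular variance is deflated
#' by construction.
#'
#' @param fit a [vagus_atlas()] object.
#' @param technique `"microct"` or `"ephys"`.
#' @return list of data frames `areas`, `separations`, `overlaps`.
#' @export
summary_report <- function(fit, technique = c("microct", "ephys")) {
  technique <- match.arg(technique)
  a <- fit[[technique]]
  if (is.null(a)) stop("fit has no ", technique, " arm")
  areas <- data.frame(group = names(a$areas),
                      area_pct = unname(a$areas))
  seps <- do.call(rbind, lapply(names(a$separations), function(nm) {
    s <- a$separations[[nm]]
    if (is.null(s)) return(NULL)
    data.frame(pair = nm, mean_deg = s$mean_deg, sd_deg = s$sd_deg,
               p_adj = s$p_value, n = s$n)
  }))
  ovls <- do.call(rbind, lapply(names(a$overlaps), function(nm) {
    o <- a$overlaps[[nm]]
    if (is.null(o)) return(NULL)
    data.frame(pair = nm, overlap_pct_of_a = o$overlap_pct_of_a,
               overlap_pct_of_b = o$overlap_pct_of_b)
  }))
  list(areas = areas, separations = seps, overlaps = ovls)
}

#' Write a cohort report to disk
#'
#' One CSV per summary table plus a human-readable text digest.
#'
#' @param fit a [vagus_atlas()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (arm in c("microct", "ephys")) {
    if (is.null(fit[[arm]])) next
    rep <- summary_report(fit, arm)
    for (nm in names(rep))
      utils::write.csv(rep[[nm]],
                       file.path(dir, paste0(arm, "_", nm, ".csv")),
                       row.names = FALSE)
  }
  txt <- utils::capture.output(print(summary(fit)))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
coef.vagus_atlas <- function(object, ...) {
  out <- list()
  for (arm in c("microct", "ephys")) {
    a <- object[[arm]]
    if (is.null(a)) next
    ang <- tapply(a$coms$angle_deg, a$coms$group, circular_mean)
    names(ang) <- paste(arm, names(ang), sep = ".")
    out[[arm]] <- ang
  }
  unlist(out)
}

#' @export
residuals.vagus_atlas <- function(object, ...) {
  out <- NULL
  for (arm in c("microct", "ephys")) {
    a <- object[[arm]]
    if (is.null(a)) next
    d <- a$coms
    mu <- tapply(d$angle_deg, d$group, circular_mean)
    out <- rbind(out, data.frame(
      technique = arm, group = d$group, animal_id = d$animal_id,
      resid_deg = wrap_180(d$angle_deg - mu[d$group])))
  }
  out
}

#' @export
plot.vagus_atlas <- function(x, technique = c("microct", "ephys"), ...) {
  technique <- match.arg(technique)
  a <- x[[technique]]
  if (is.null(a)) stop("fit has no ", technique, " arm")
  n <- length(a$atlases)
  old <- graphics::par(mfrow = c(1, max(n, 1)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (g in names(a$atlases)) plot(a$atlases[[g]], main = g)
  invisible(x)
}

#' @export
simulate.vagus_atlas <- function(object, nsim = 1, seed = NULL,
                                 config = synthetic_config(), ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, {
    cfg <- config
    cfg$seed <- NULL
    generate_cohort(cfg)
  }, simplify = FALSE)
}

#' Simulate the full stimulation protocol of a cohort
#'
#' For each animal, runs the titration loop for each requested target
#' (cardiac efferent HR pre-vagotomy, cardiac afferent HR
#' post-vagotomy, pulmonary EtCO2, laryngeal EMG) from the protocol's
#' starting parameters and collects the response table at the titrated
#' amplitude.  Animals for which titration fails for a target (e.g. a
#' nerve with no fascicle of the target group) contribute no table for
#' that target.
#'
#' @param cohort a [generate_cohort()] result.
#' @param array an [electrode_array()].
#' @param config the [synthetic_config()] holding the recruitment
#'   model.
#' @param targets subset of `c("cardiac_efferent", "cardiac_afferent",
#'   "pulmonary", "laryngeal")`.
#' @return list with `responses` (flat list of [response_table()]s) and
#'   `titration` (data frame of final amplitudes and effective-pair
#'   counts per animal and target).
#' @export
cohort_responses <- function(cohort, array = electrode_array(),
                             config = synthetic_config(),
                             targets = c("cardiac_efferent",
                                         "cardiac_afferent",
                                         "pulmonary", "laryngeal")) {
  spec <- list(
    cardiac_efferent = list(modality = "HR", condition = "pre_vagotomy"),
    cardiac_afferent = list(modality = "HR", condition = "post_vagotomy"),
    pulmonary        = list(modality = "EtCO2", condition = "pre_vagotomy"),
    laryngeal        = list(modality = "EMG", condition = "pre_vagotomy"))
  responses <- list()
  rows <- list()
  for (an in names(cohort$nerves)) {
    nerve <- cohort$nerves[[an]]
    truth <- cohort$truths[[an]]
    for (tg in targets) {
      sp <- spec[[tg]]
      model <- titration_model(nerve, array, sp$modality, sp$condition,
                               truth, config)
      res <- tryCatch(titrate(model, start = starting_params(tg)),
                      titration_failure = function(e) NULL)
      if (is.null(res)) next
      responses[[length(responses) + 1L]] <- res$table
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = an, target = tg,
        amplitude_mA = res$params$amplitude_mA,
        n_effective = length(effective_pairs(res$table)))
    }
  }
  list(responses = responses,
       titration = if (length(rows)) do.call(rbind, rows) else
         data.frame(animal_id = character(0), target = character(0),
                    amplitude_mA = numeric(0), n_effective = integer(0)))
}

#' Re-run the cohort analysis from files on disk
#'
#' Loads `fascicles.csv` (tracing tables), `responses.csv` (per-pair
#' response tables) and optionally `electrode_array.json` from a
#' directory and fits [vagus_atlas()].  At least one of the two data
#' files must be present.
#'
#' @param dir directory holding the cohort files.
#' @param grid_size raster resolution.
#' @param ... passed to [vagus_atlas()].
#' @return a [vagus_atlas()] object.
#' @export
reproduce_cohort <- function(dir, grid_size = 128L, ...) {
  f_fasc <- file.path(dir, "fascicles.csv")
  f_resp <- file.path(dir, "responses.csv")
  f_geom <- file.path(dir, "electrode_array.json")
  if (!file.exists(f_fasc) && !file.exists(f_resp))
    stop("directory ", dir, " holds neither fascicles.csv nor ",
         "responses.csv: nothing to analyze")
  array <- if (file.exists(f_geom)) read_electrode_array(f_geom)
           else electrode_array()
  nerves <- if (file.exists(f_fasc)) read_fascicle_table(f_fasc)
  responses <- if (file.exists(f_resp)) read_response_table(f_resp,
                                                            array$n_pairs)
  vagus_atlas(nerves = nerves, responses = responses, array = array,
              grid_size = grid_size, ...)
}

#' Recover the cardiac afferent-efferent separation of one cohort
#'
#' The minimal estimation path for the planted cardiac separation:
#' per-animal cardiac efferent and cardiac afferent maps (microCT
#' projection or titrated-stimulation back-projection), rotational
#' alignment, centers of mass, and the circular separation summary.
#' Animals without a usable cardiac efferent reference are excluded.
#'
#' @param cohort a [generate_cohort()] result.
#' @param arm `"microct"` (binary fascicle maps) or `"ephys"`
#'   (simulated titrated responses back-projected onto sectors).
#' @param array an [electrode_array()].
#' @param config the [synthetic_config()] (needed for the ephys arm's
#'   recruitment model).
#' @param grid_size raster resolution.
#' @return a [group_separation()] result (class `separation_result`).
#' @export
cardiac_separation <- function(cohort, arm = c("microct", "ephys"),
                               array = electrode_array(),
                               config = synthetic_config(),
                               grid_size = 64L) {
  arm <- match.arg(arm)
  coms <- list()
  for (an in names(cohort$nerves)) {
    nerve <- cohort$nerves[[an]]
    truth <- cohort$truths[[an]]
    maps <- if (arm == "microct") {
      suppressWarnings(list(
        cardiac_efferent = build_group_map(nerve, array, "cardiac_efferent",
                                           grid_size),
        cardiac_afferent = build_group_map(nerve, array, "cardiac_afferent",
                                           grid_size)))
    } else {
      tabs <- lapply(
        list(list(tg = "cardiac_efferent", mod = "HR", cond = "pre_vagotomy"),
             list(tg = "cardiac_afferent", mod = "HR", cond = "post_vagotomy")),
        function(sp) {
          model <- titration_model(nerve, array, sp$mod, sp$cond, truth,
                                   config)
          res <- tryCatch(titrate(model, start = starting_params(sp$tg)),
                          titration_failure = function(e) NULL)
          if (is.null(res)) NULL else res$table
        })
      if (any(vapply(tabs, is.null, TRUE))) next
      ms <- lapply(tabs, build_sector_map, array = array,
                   grid_size = grid_size)
      stats::setNames(ms, vapply(ms, `[[`, "", "group"))
    }
    if (all(maps$cardiac_efferent$values == 0) ||
        all(maps$cardiac_afferent$values == 0)) next
    aligned <- align_maps(maps)
    # resampling can wipe a near-single-pixel map; skip such animals
    if (any(vapply(aligned, function(m) all(m$values == 0), TRUE))) next
    for (m in aligned) coms[[length(coms) + 1L]] <- center_of_mass(m)
  }
  group_separation(coms, "cardiac_efferent", "cardiac_afferent")
}
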