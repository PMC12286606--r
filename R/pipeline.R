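#' Run the full track-analysis pipeline
#'
#' Executes the configured stages in order - link (when a spot table is
#' given), filter, per-track motion analysis, polarity (when a geometry is
#' given), fusion detection - and returns a run report with exact
#' attrition accounting at every stage. With an output directory in
#' `config$paths$out`, all intermediate tables are written as CSV. The
#' pipeline is deterministic for a fixed config and input.
#'
#' @param config an `analysis_config` from [read_config()].
#' @param spots optional spot table (`frame, x_um, y_um, z_um, ...`);
#'   linked with the configured linker.
#' @param tracks optional pre-linked track table; exactly one of `spots`
#'   or `tracks` must be supplied.
#' @param geometry optional [cell_geometry()] enabling polarity and
#'   direction/position classification.
#' @param timelapse_end_s end of the recording (s), for fusion scoring.
#' @return list (class `run_report`) with per-stage counts, the motion
#'   summary, track angles and fusion events, the config hash and seed.
#' @export
run_pipeline <- function(config = read_config(), spots = NULL,
                         tracks = NULL, geometry = NULL,
                         timelapse_end_s = NULL) {
  if (is.null(spots) == is.null(tracks))
    rm_stop("supply exactly one of spots or tracks")
  stages <- list()
  if (!is.null(spots)) {
    lp <- linker_params(config$linker$max_link_dist_um,
                        config$linker$max_gap_frames,
                        config$linker$prediction_weight,
                        profile = config$profile)
    tracks <- link_tracks(spots, lp)
    stages$linking <- list(n_spots_in = nrow(spots),
                           n_spots_linked = nrow(tracks),
                           n_tracks = length(unique(tracks$track_id)))
  }
  n_in <- length(unique(tracks$track_id))
  filtered <- filter_tracks(tracks, config$filter$min_spots,
                            config$filter$min_displacement_um)
  n_kept <- length(unique(filtered$track_id))
  stages$filtering <- list(n_tracks_in = n_in, n_tracks_kept = n_kept,
                           n_tracks_removed = n_in - n_kept,
                           removed_ids = attr(filtered, "removed"))
  classified <- if (n_kept > 0)
    analyze_tracks(filtered, geometry,
                   fit_fraction = config$msd$fit_fraction,
                   min_spots_msd = config$msd$min_spots_msd,
                   long_threshold_um = config$displacement$long_threshold_um,
                   angle_band = config$angle_band)
  else NULL
  summary <- if (!is.null(classified)) summarize_motion(classified) else NULL
  angles <- if (!is.null(geometry) && n_kept > 0)
    track_angles(filtered, geometry) else NULL
  fus <- if (n_kept > 1)
    detect_fusions(filtered,
                   fusion_params(config$fusion$d_res_um,
                                 config$fusion$t_min_s),
                   timelapse_end_s = timelapse_end_s)
  else empty_fusion_events()
  report <- list(stages = stages, classified = classified,
                 summary = summary, angles = angles, fusions = fus,
                 base_fraction = if (!is.null(angles) && nrow(angles) > 0)
                   base_fraction(angles) else NULL,
                 config_hash = config_hash(config), seed = config$seed,
                 version = as.character(utils::packageVersion("ribbonmotion")))
  class(report) <- "run_report"
  out_dir <- config$paths$out
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_track_table(filtered, file.path(out_dir, "tracks_filtered.csv"))
    if (!is.null(classified))
      write.csv(classified, file.path(out_dir, "per_track.csv"),
                row.names = FALSE)
    if (!is.null(angles))
      write.csv(angles, file.path(out_dir, "angles.csv"), row.names = FALSE)
    write.csv(fus, file.path(out_dir, "fusions.csv"), row.names = FALSE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  if (!is.null(x$stages$linking))
    cat(sprintf("  linking: %d spots -> %d tracks\n",
                x$stages$linking$n_spots_in, x$stages$linking$n_tracks))
  cat(sprintf("  filtering: %d -> %d tracks (%d removed)\n",
              x$stages$filtering$n_tracks_in, x$stages$filtering$n_tracks_kept,
              x$stages$filtering$n_tracks_removed))
  if (!is.null(x$summary))
    cat(sprintf("  directional fraction: %.3f, long-track fraction: %.3f\n",
                x$summary$directional_fraction, x$summary$long_fraction))
  if (!is.null(x$base_fraction))
    cat(sprintf("  base-directed: %d/%d (%.1f%%)\n",
                x$base_fraction$n_base, x$base_fraction$n_total,
                x$base_fraction$percent))
  cat(sprintf("  fusion events: %d\n", nrow(x$fusions)))
  invisible(x)
}

#' Descriptive comparison of two or more conditions
#'
#' Per-group means and standard errors of the summary quantities
#' (directional fraction, long-track fraction, and optionally fusion rate
#' and puncta counts), with differences relative to the first (reference)
#' group reported descriptively. Hypothesis testing is deliberately not
#' performed here.
#'
#' @param groups named list; each element is a list of per-sample
#'   [analyze_tracks()] tables (one table per sample).
#' @param fusion_counts optional named list of per-sample fusion counts
#'   per group.
#' @return data.frame with one row per group and metric: `group, metric,
#'   n_samples, mean, sem, diff_vs_ref`; single-sample groups carry `NA`
#'   SEM.
#' @export
compare_groups <- function(groups, fusion_counts = NULL) {
  if (length(groups) < 2) rm_stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    rm_stop("groups must be named")
  rows <- list()
  ref <- NULL
  for (g in names(groups)) {
    samples <- groups[[g]]
    if (length(samples) == 0) rm_stop("group '%s' has zero samples", g)
    dirf <- vapply(samples, function(s) {
      cls <- s$motion_class[!is.na(s$motion_class)]
      if (length(cls)) mean(cls == "directional") else NA_real_
    }, numeric(1))
    longf <- vapply(samples, function(s) mean(s$long_track), numeric(1))
    met <- list(directional_fraction = dirf, long_fraction = longf)
    if (!is.null(fusion_counts) && g %in% names(fusion_counts))
      met$fusion_rate <- as.numeric(fusion_counts[[g]])
    for (m in names(met)) {
      v <- met[[m]][!is.na(met[[m]])]
      mu <- mean(v)
      sem <- if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        group = g, metric = m, n_samples = length(v), mean = mu, sem = sem)
    }
  }
  out <- do.call(rbind, rows)
  ref_name <- names(groups)[1]
  ref_means <- out[out$group == ref_name, c("metric", "mean")]
  out$diff_vs_ref <- out$mean -
    ref_means$mean[match(out$metric, ref_means$metric)]
  out
}
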