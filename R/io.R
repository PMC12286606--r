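#' Write a track table to CSV
#'
#' Public track tables use micrometres and seconds with columns
#' `track_id, frame, t_seconds, x_um, y_um, z_um` and an optional `label`.
#'
#' @param tracks internal track table (`track_id, frame, t_s, x_um, y_um,
#'   z_um`, optional `label`).
#' @param path output CSV path.
#' @export
write_track_table <- function(tracks, path) {
  out <- tracks
  names(out)[names(out) == "t_s"] <- "t_seconds"
  keep <- intersect(c("track_id", "frame", "t_seconds", "x_um", "y_um",
                      "z_um", "label"), names(out))
  write.csv(out[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a track or spot table from CSV
#'
#' Two column profiles are supported: `native` (the format written by
#' [write_track_table()]) and `imaris` (position exports with columns
#' `Position X/Y/Z`, `Time`, and `TrackID`). Units are normalized to
#' micrometres and seconds. For Imaris-style exports where `Time` is a
#' frame index, supply `dt` to convert (`t = (Time - 1) dt`).
#'
#' @param path CSV file.
#' @param profile `"native"` or `"imaris"`.
#' @param dt frame interval (s) for frame-indexed `Time` columns.
#' @return data.frame `track_id, frame, t_s, x_um, y_um, z_um` (plus
#'   `label` when present).
#' @export
read_track_table <- function(path, profile = c("native", "imaris"),
                             dt = NULL) {
  profile <- match.arg(profile)
  if (!file.exists(path)) rm_stop("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE)
  if (profile == "native") {
    need <- c("track_id", "frame", "t_seconds", "x_um", "y_um", "z_um")
    miss <- setdiff(need, names(df))
    if (length(miss)) rm_stop("missing columns: %s",
                              paste(miss, collapse = ", "))
    out <- data.frame(track_id = df$track_id, frame = df$frame,
                      t_s = df$t_seconds, x_um = df$x_um, y_um = df$y_um,
                      z_um = df$z_um)
    if ("label" %in% names(df)) out$label <- df$label
    return(out)
  }
  need <- c("Position X", "Position Y", "Position Z", "Time", "TrackID")
  miss <- setdiff(need, names(df))
  if (length(miss)) rm_stop("missing columns: %s",
                            paste(miss, collapse = ", "))
  tm <- df[["Time"]]
  if (!is.null(dt)) {
    frame <- as.integer(tm)
    t_s <- (frame - 1) * dt
  } else {
    t_s <- as.numeric(tm)
    steps <- sort(unique(t_s))
    step <- if (length(steps) > 1) min(diff(steps)) else 1
    frame <- as.integer(round(t_s / step)) + 1L
  }
  data.frame(track_id = df[["TrackID"]], frame = frame, t_s = t_s,
             x_um = df[["Position X"]], y_um = df[["Position Y"]],
             z_um = df[["Position Z"]])
}

#' Write an image stack as multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are ordered TZYX (time outermost); the sidecar (`<path>.json`)
#' carries the voxel size, frame interval and array shape needed to
#' rebuild the stack.
#'
#' @param stack an [image_stack()].
#' @param path output `.tif` path.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  nd <- length(d)
  # TIFF float samples live in [0, 1]; the scale is kept in the sidecar
  scale <- max(stack$data, 1e-12)
  dat <- stack$data / scale
  pages <- list()
  if (nd == 3) {
    for (k in seq_len(d[3])) pages[[k]] <- dat[, , k]
  } else {
    i <- 0
    for (t in seq_len(d[4])) for (k in seq_len(d[3])) {
      i <- i + 1
      pages[[i]] <- dat[, , k, t]
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(voxel_size_um = stack$voxel_size, dt_s = stack$dt,
               shape_yxzt = d, intensity_scale = scale,
               page_order = "TZYX")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path `.tif` path (with `<path>.json` sidecar alongside).
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    rm_stop("stack or sidecar missing for %s", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape_yxzt)
  arr <- array(0, d)
  if (length(d) == 3) {
    for (k in seq_len(d[3])) arr[, , k] <- pages[[k]]
  } else {
    i <- 0
    for (t in seq_len(d[4])) for (k in seq_len(d[3])) {
      i <- i + 1
      arr[, , k, t] <- pages[[i]]
    }
  }
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  arr <- arr * scale
  image_stack(arr, meta$voxel_size_um,
              dt = if (is.null(meta$dt_s)) NULL else meta$dt_s)
}

# ---- analysis configuration ------------------------------------------------

config_defaults <- function() {
  list(
    profile = "ribbon",           # or "eb3"
    seed = 1L,
    linker = list(max_link_dist_um = NULL, max_gap_frames = NULL,
                  prediction_weight = 1),
    detection = list(expected_diameter_um = 0.427, quality_threshold = 5),
    filter = list(min_spots = 5, min_displacement_um = 0),
    msd = list(fit_fraction = 0.25, min_spots_msd = 10),
    displacement = list(long_threshold_um = 1.0),
    fusion = list(d_res_um = 0.3, t_min_s = 300),
    staging = list(z_interval_um = 0.425),
    thresholds = list(live_ribbon = 97, treatment = 28),
    angle_band = c(60, 120),
    paths = list(out = NULL)
  )
}

#' Read and validate an analysis configuration
#'
#' YAML configuration with defaults equal to the published assay
#' parameters. Unknown keys are rejected; supplied keys override defaults
#' (nested lists merge by key). Assay profile `"eb3"` switches the linker
#' and filter defaults to the comet assay (1 um / 3 frames, more than 5
#' spots, automatic displacement threshold).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list merged over the file (same rules).
#' @return validated configuration list (class `analysis_config`).
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) rm_stop("unknown config keys: %s",
                               paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  if (!cfg$profile %in% c("ribbon", "eb3"))
    rm_stop("profile must be 'ribbon' or 'eb3'")
  if (cfg$profile == "eb3") {
    if (is.null(user$detection$expected_diameter_um))
      cfg$detection$expected_diameter_um <- 0.534
    if (is.null(user$filter$min_spots)) cfg$filter$min_spots <- 6
    if (is.null(user$filter$min_displacement_um))
      cfg$filter$min_displacement_um <- "auto"
  }
  with(cfg, {
    stopifnot(msd$fit_fraction > 0, msd$fit_fraction <= 1,
              msd$min_spots_msd >= 2, displacement$long_threshold_um > 0,
              fusion$d_res_um > 0, fusion$t_min_s >= 0,
              staging$z_interval_um > 0)
  })
  class(cfg) <- "analysis_config"
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(cfg)), f)
  unname(tools::md5sum(f))
}
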