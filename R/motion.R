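#' Time-averaged mean squared displacement of a track
#'
#' For a track sampled at uniform interval `dt`, the time-averaged MSD at
#' lag `tau = k dt` is the mean over all pairs of points `k` frames apart
#' of their squared 3D separation. Pairs whose frame interval contains a
#' gap-closed (missing) frame are excluded rather than interpolated, so the
#' estimator never uses fabricated positions.
#'
#' @param track data.frame `frame, t_s, x_um, y_um, z_um` (one track).
#' @param min_points MSD eligibility: tracks with fewer points are
#'   rejected (default 10, the exponent-analysis filter).
#' @return data.frame `lag_s, msd_um2, n_pairs` (lags `k = 1 .. N-1`),
#'   with the track's `dt` as an attribute.
#' @examples
#' p <- motion_params("directed", v = 0.1, sigma_loc = 0, dt = 10,
#'                    n_frames = 12)
#' pr <- compute_msd(simulate_track(p))
#' all.equal(pr$msd_um2, (0.1 * pr$lag_s)^2)
#' @export
compute_msd <- function(track, min_points = 10) {
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  if (n < min_points) rm_stop("track has %d points; %d required", n, min_points)
  fr <- track$frame
  dts <- diff(track$t_s) / diff(fr)
  if (max(abs(dts - dts[1])) > 1e-6 * max(abs(dts[1]), 1))
    rm_stop("non-uniform sampling interval")
  dt <- dts[1]
  present <- logical(max(fr) - min(fr) + 1)
  present[fr - min(fr) + 1] <- TRUE
  pos <- as.matrix(track[, c("x_um", "y_um", "z_um")])
  row_of <- integer(length(present))
  row_of[fr - min(fr) + 1] <- seq_len(n)
  n_frames <- length(present)
  k_max <- n_frames - 1
  lag_s <- msd <- numeric(k_max)
  n_pairs <- integer(k_max)
  cp <- c(0, cumsum(present))
  for (k in seq_len(k_max)) {
    # pair (i, i+k) valid when every frame i..i+k is present
    i_all <- seq_len(n_frames - k)
    ok <- i_all[cp[i_all + k + 1] - cp[i_all] == k + 1]
    lag_s[k] <- k * dt
    if (length(ok) == 0) { msd[k] <- NA_real_; n_pairs[k] <- 0L; next }
    d <- pos[row_of[ok + k], , drop = FALSE] - pos[row_of[ok], , drop = FALSE]
    msd[k] <- mean(rowSums(d^2))
    n_pairs[k] <- length(ok)
  }
  out <- data.frame(lag_s = lag_s, msd_um2 = msd, n_pairs = n_pairs)
  attr(out, "dt") <- dt
  out
}

#' Fit the MSD power-law exponent alpha
#'
#' Ordinary least squares of `log(msd)` on `log(tau)` over the first
#' `fit_fraction` of the available lags (at least 2), the conventional
#' log-log fit of `MSD = C tau^alpha`. Only the first 25% of the MSD curve
#' is used by default, where the time-averaged estimator is reliable.
#' Zero-MSD lags are excluded from the fit and flagged.
#'
#' @param profile output of [compute_msd()].
#' @param fit_fraction fraction of lags to fit (default 0.25).
#' @return list with `alpha`, `log_prefactor`, `r_squared`, `n_lags_fit`,
#'   `dropped_zero_lags`.
#' @export
fit_alpha <- function(profile, fit_fraction = 0.25) {
  k_all <- nrow(profile)
  k_fit <- max(2, ceiling(fit_fraction * k_all))
  sub <- profile[seq_len(min(k_fit, k_all)), , drop = FALSE]
  usable <- !is.na(sub$msd_um2) & sub$msd_um2 > 0 & sub$n_pairs > 0
  dropped <- sum(!usable)
  sub <- sub[usable, , drop = FALSE]
  if (nrow(sub) < 2)
    rm_stop("degenerate MSD profile: fewer than 2 positive lags in the fit window")
  fit <- lm(log(msd_um2) ~ log(lag_s), data = sub)
  sm <- suppressWarnings(summary(fit)) # exact power laws fit perfectly
  list(alpha = unname(coef(fit)[2]),
       log_prefactor = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       n_lags_fit = nrow(sub),
       dropped_zero_lags = dropped)
}

#' Classify motion from the fitted exponent
#'
#' `alpha > 1` indicates directional motion with velocity; `alpha = 1`
#' Brownian motion; `alpha < 1` confined motion or subdiffusion. Reported
#' classes are binary (`directional` vs `confined`), with the boundary
#' `alpha = 1` assigned to `confined` so the two classes partition all
#' tracks.
#'
#' @param fit output of [fit_alpha()], or a numeric alpha.
#' @return `"directional"` or `"confined"`.
#' @export
classify_motion <- function(fit) {
  alpha <- if (is.list(fit)) fit$alpha else fit
  if (!is.finite(alpha)) rm_stop("alpha must be finite")
  if (alpha > 1) "directional" else "confined"
}

#' Track displacement (start to end)
#'
#' The Euclidean 3D distance between the first and last point of the
#' track; tracks with displacement strictly greater than 1 um are flagged
#' as long tracks, the displacement criterion indicative of directed
#' motion.
#'
#' @param track data.frame with `frame, x_um, y_um, z_um`.
#' @param long_threshold_um threshold (um), default 1, strict.
#' @return list with `displacement_um` and `long_track`.
#' @export
track_displacement <- function(track, long_threshold_um = 1.0) {
  if (nrow(track) < 2) rm_stop("track needs at least 2 points")
  track <- track[order(track$frame), , drop = FALSE]
  p0 <- as.numeric(track[1, c("x_um", "y_um", "z_um")])
  p1 <- as.numeric(track[nrow(track), c("x_um", "y_um", "z_um")])
  d <- sqrt(sum((p1 - p0)^2))
  list(displacement_um = d, long_track = d > long_threshold_um)
}

#' Direction and axial position of a long track
#'
#' Classifies a long track's direction from the angle of its net
#' displacement to the apex-to-base axis: below the lower band edge it is
#' base-directed, above the upper edge apex-directed, otherwise
#' undetermined. The axial position is `above_nucleus` or `below_nucleus`
#' by the track's mean coordinate along the axis versus the nucleus plane.
#'
#' @param track data.frame with `frame, x_um, y_um, z_um`.
#' @param geometry a [cell_geometry()].
#' @param angle_band numeric length 2, degrees; default `c(60, 120)`.
#' @return list with `direction` (`"base"`, `"apex"`, `"undetermined"`)
#'   and `position` (`"above_nucleus"`, `"below_nucleus"`).
#' @export
assign_direction_and_position <- function(track, geometry,
                                          angle_band = c(60, 120)) {
  if (is.null(geometry)) rm_stop("geometry must be supplied")
  pos <- as.matrix(track[order(track$frame), c("x_um", "y_um", "z_um")])
  ang <- tryCatch(track_angle(track, geometry)$angle_deg,
                  error = function(e) NA_real_)
  direction <- if (is.na(ang)) "undetermined"
    else if (ang < angle_band[1]) "base"
    else if (ang > angle_band[2]) "apex"
    else "undetermined"
  mean_ax <- mean(axis_coordinate(pos, geometry))
  position <- if (mean_ax > geometry$nucleus_plane) "below_nucleus"
              else "above_nucleus"
  list(direction = direction, position = position)
}

#' Per-track motion analysis of a track set
#'
#' Runs displacement, MSD/alpha (for tracks meeting the MSD eligibility)
#' and, when a geometry is given, direction/position classification for
#' every track in a track table.
#'
#' @param tracks track table (`track_id, frame, t_s, x_um, y_um, z_um`).
#' @param geometry optional [cell_geometry()].
#' @param fit_fraction lag fraction for the alpha fit.
#' @param min_spots_msd MSD eligibility (default 10 points).
#' @param long_threshold_um displacement criterion (default 1 um).
#' @param angle_band direction band, degrees.
#' @return data.frame `track_id, n_spots, displacement_um, long_track,
#'   alpha, r_squared, motion_class, direction, position`; tracks whose
#'   alpha fit is degenerate carry `NA` alpha and are excluded from the
#'   motion classes.
#' @export
analyze_tracks <- function(tracks, geometry = NULL, fit_fraction = 0.25,
                           min_spots_msd = 10, long_threshold_um = 1.0,
                           angle_band = c(60, 120)) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    disp <- track_displacement(tr, long_threshold_um)
    alpha <- r2 <- NA_real_
    mclass <- NA_character_
    if (nrow(tr) >= min_spots_msd) {
      fit <- tryCatch(
        fit_alpha(compute_msd(tr, min_points = min_spots_msd), fit_fraction),
        error = function(e) NULL)
      if (!is.null(fit)) {
        alpha <- fit$alpha; r2 <- fit$r_squared
        mclass <- classify_motion(fit)
      }
    }
    direction <- position <- NA_character_
    if (!is.null(geometry) && disp$long_track) {
      dp <- assign_direction_and_position(tr, geometry, angle_band)
      direction <- dp$direction; position <- dp$position
    }
    data.frame(track_id = id, n_spots = nrow(tr),
               displacement_um = disp$displacement_um,
               long_track = disp$long_track, alpha = alpha,
               r_squared = r2, motion_class = mclass,
               direction = direction, position = position)
  })
  do.call(rbind, rows)
}

#' Summaries of a classified track set
#'
#' Fractions of directional motion (`alpha > 1`), of long tracks
#' (displacement above the 1 um criterion), and direction / position
#' breakdowns of the long tracks, plus the alpha values for distribution
#' comparisons.
#'
#' @param classified output of [analyze_tracks()].
#' @return list with `n_tracks`, `directional_fraction`,
#'   `confined_fraction`, `long_fraction`, `direction_breakdown`,
#'   `position_breakdown`, `alpha`.
#' @export
summarize_motion <- function(classified) {
  if (nrow(classified) == 0) rm_stop("empty track set")
  cls <- classified$motion_class[!is.na(classified$motion_class)]
  dir_frac <- if (length(cls)) mean(cls == "directional") else NA_real_
  long_frac <- mean(classified$long_track)
  brk <- function(x, levels) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(setNames(rep(NA_real_, length(levels)), levels))
    tb <- table(factor(x, levels = levels))
    as.numeric(tb) / length(x) -> fr
    setNames(fr, levels)
  }
  list(n_tracks = nrow(classified),
       n_classified = length(cls),
       directional_fraction = dir_frac,
       confined_fraction = if (length(cls)) 1 - dir_frac else NA_real_,
       long_fraction = long_frac,
       direction_breakdown = brk(classified$direction,
                                 c("base", "apex", "undetermined")),
       position_breakdown = brk(classified$position,
                                c("above_nucleus", "below_nucleus")),
       alpha = classified$alpha[!is.na(classified$alpha)])
}
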