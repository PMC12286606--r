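#' @title Motion model parameters for trajectory simulation
#'
#' @description Parameters of the three motion classes the exponent analysis
#' distinguishes: `confined` (reflected Brownian motion inside a spherical
#' corral), `brownian` (free diffusion), and `directed` (constant velocity
#' plus residual diffusion). Units are micrometres and seconds throughout.
#'
#' @param model one of `"confined"`, `"brownian"`, `"directed"`.
#' @param D diffusion coefficient (um^2/s), `>= 0`.
#' @param v speed (um/s), directed model only.
#' @param direction unit vector (length 2 or 3) of travel, directed only;
#'   may also be `"base"` or `"apex"`, resolved against a geometry at
#'   simulation time.
#' @param R_conf corral radius (um), confined only, `> 0`.
#' @param sigma_loc per-axis localization noise s.d. (um); the default
#'   0.02 um is half the xy voxel of the imaging convention used here.
#' @param dt frame interval (s), `> 0`.
#' @param n_frames number of frames, `>= 2`.
#' @param seed optional integer seed making the track reproducible.
#'
#' @return A `motion_params` object (validated list).
#' @export
motion_params <- function(model = c("brownian", "directed", "confined"),
                          D = 0, v = 0, direction = c(1, 0, 0),
                          R_conf = NULL, sigma_loc = 0.02,
                          dt = 5, n_frames = 100, seed = NULL) {
  model <- match.arg(model)
  if (D < 0) rm_stop("D must be >= 0")
  if (v < 0) rm_stop("v must be >= 0")
  if (dt <= 0) rm_stop("dt must be > 0")
  if (n_frames < 2) rm_stop("n_frames must be >= 2")
  if (model == "confined") {
    if (is.null(R_conf) || R_conf <= 0)
      rm_stop("confined model requires R_conf > 0")
  }
  if (model == "directed" && is.numeric(direction)) {
    if (length(direction) == 2) direction <- c(direction, 0)
    nrm <- sqrt(sum(direction^2))
    if (nrm == 0) rm_stop("direction must be a nonzero vector")
    direction <- direction / nrm
  }
  structure(list(model = model, D = D, v = v, direction = direction,
                 R_conf = R_conf, sigma_loc = sigma_loc, dt = dt,
                 n_frames = n_frames, seed = seed),
            class = "motion_params")
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a single 3D trajectory
#'
#' Positions are generated at times `(k - 1) * dt`, `k = 1..n_frames`.
#' Brownian steps are independent per-axis Gaussian increments with variance
#' `2 * D * dt`; the directed model adds `v * dt * direction` per frame;
#' the confined model reflects each Brownian proposal at the sphere of
#' radius `R_conf` centred on the start point (with sub-stepping so single
#' steps stay well below the corral radius). Localization noise
#' (`sigma_loc`, i.i.d. per frame per axis) is added last.
#'
#' @param params a [motion_params()] object.
#' @param start numeric length 3, start position (um).
#' @return A data.frame with columns `frame`, `t_s`, `x_um`, `y_um`, `z_um`.
#' @examples
#' p <- motion_params("directed", v = 0.1, direction = c(1, 0, 0),
#'                    sigma_loc = 0, dt = 10, n_frames = 5)
#' simulate_track(p) # moves 1 um in x per frame
#' @export
simulate_track <- function(params, start = c(0, 0, 0)) {
  if (!inherits(params, "motion_params")) rm_stop("params must be motion_params")
  start <- as.numeric(start)
  if (length(start) == 2) start <- c(start, 0)
  n <- params$n_frames
  with_seed(params$seed, {
    pos <- switch(params$model,
      brownian = brownian_path(start, params$D, params$dt, n),
      directed = directed_path(start, params$D, params$v, params$direction,
                               params$dt, n),
      confined = confined_path(start, params$D, params$R_conf, params$dt, n))
    if (params$sigma_loc > 0)
      pos <- pos + matrix(rnorm(3 * n, sd = params$sigma_loc), n, 3)
    data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) * params$dt,
               x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
  })
}

brownian_path <- function(start, D, dt, n) {
  inc <- matrix(rnorm(3 * (n - 1), sd = sqrt(2 * D * dt)), n - 1, 3)
  steps <- apply(inc, 2, cumsum)
  if (n == 2) steps <- matrix(steps, 1, 3)
  rbind(start, sweep(steps, 2, -start))
}

directed_path <- function(start, D, v, direction, dt, n) {
  drift <- matrix(rep(v * dt * direction, each = n - 1), n - 1, 3)
  inc <- drift + matrix(rnorm(3 * (n - 1), sd = sqrt(2 * D * dt)), n - 1, 3)
  steps <- apply(inc, 2, cumsum)
  if (n == 2) steps <- matrix(steps, 1, 3)
  rbind(start, sweep(steps, 2, -start))
}

# Reflected Brownian motion in the sphere of radius R about `start`.
# A proposal leaving the sphere is mirror-reflected at the boundary; steps
# are sub-divided so a single sub-step stays well below R, avoiding
# tunnelling through the corral.
confined_path <- function(start, D, R, dt, n) {
  n_sub <- max(1L, ceiling(2 * D * dt / (R / 4)^2))
  sd_sub <- sqrt(2 * D * dt / n_sub)
  pos <- matrix(0, n, 3)
  cur <- c(0, 0, 0) # in corral coordinates
  pos[1, ] <- cur
  for (k in 2:n) {
    for (s in seq_len(n_sub)) {
      cand <- cur + rnorm(3, sd = sd_sub)
      cur <- reflect_in_sphere(cur, cand, R)
    }
    pos[k, ] <- cur
  }
  sweep(pos, 2, -start)
}

# Mirror-reflect the segment from p0 to p1 at the sphere |x| = R (one
# reflection; the residual is clipped to the boundary in the rare case it
# is still outside).
reflect_in_sphere <- function(p0, p1, R) {
  r1 <- sqrt(sum(p1^2))
  if (r1 <= R) return(p1)
  d <- p1 - p0
  a <- sum(d^2)
  b <- 2 * sum(p0 * d)
  cc <- sum(p0^2) - R^2
  disc <- b^2 - 4 * a * cc
  if (disc < 0 || a == 0) { # numerical corner: project back inside
    return(p1 * (R / r1))
  }
  t_hit <- (-b + sqrt(disc)) / (2 * a)
  t_hit <- min(max(t_hit, 0), 1)
  hit <- p0 + t_hit * d
  nrml <- hit / sqrt(sum(hit^2))
  rest <- p1 - hit
  reflected <- rest - 2 * sum(rest * nrml) * nrml
  out <- hit + reflected
  r_out <- sqrt(sum(out^2))
  if (r_out > R) out <- out * (R / r_out)
  out
}

#' Simulate a labeled mixture of trajectories
#'
#' Generates a set of tracks from a mixture of motion models, carrying
#' per-track ground-truth labels for parameter-recovery and classification
#' tests.
#'
#' @param mixture list of `list(params = <motion_params>, count = <n>)`.
#' @param geometry optional [cell_geometry()]; when supplied, start points
#'   are placed inside the cell and symbolic directions (`"base"`,
#'   `"apex"`) are resolved against the axis.
#' @param seed integer seed (drives start points and all paths).
#' @param box when no geometry is given, starts are drawn uniformly in
#'   `[0, box[i]]` per axis; default `c(10, 10, 3)` um.
#' @return A `labeled_track_set`: list with `tracks` (data.frame of
#'   `track_id, frame, t_s, x_um, y_um, z_um`), `labels` (data.frame of
#'   `track_id, label`), and `geometry`.
#' @export
simulate_trackset <- function(mixture, geometry = NULL, seed = NULL,
                              box = c(10, 10, 3)) {
  if (length(mixture) == 0) rm_stop("mixture must be non-empty")
  counts <- vapply(mixture, function(m) as.numeric(m$count), numeric(1))
  if (any(counts < 0)) rm_stop("counts must be >= 0")
  with_seed(seed, {
    tracks <- list(); labels <- list(); id <- 0L
    for (m in mixture) {
      p <- m$params
      if (identical(p$direction, "base") || identical(p$direction, "apex")) {
        if (is.null(geometry))
          rm_stop("symbolic direction needs a geometry")
        u <- geometry$axis_unit
        p$direction <- if (identical(p$direction, "base")) u else -u
      }
      for (i in seq_len(m$count)) {
        id <- id + 1L
        start <- if (is.null(geometry)) runif(3) * box else
          random_point_in_cell(geometry)
        tr <- simulate_track(p, start)
        tr <- cbind(track_id = id, tr)
        tracks[[id]] <- tr
        labels[[id]] <- data.frame(track_id = id, label = p$model)
      }
    }
    structure(list(tracks = do.call(rbind, tracks),
                   labels = do.call(rbind, labels),
                   geometry = geometry),
              class = "labeled_track_set")
  })
}

# Uniform point in a tube of radius 1/4 axis length around the cell axis.
random_point_in_cell <- function(geometry) {
  t_ax <- runif(1, 0.1, 0.9) * geometry$axis_length_um
  perp <- rnorm(3)
  perp <- perp - sum(perp * geometry$axis_unit) * geometry$axis_unit
  perp <- perp / sqrt(sum(perp^2)) * runif(1, 0, geometry$axis_length_um / 4)
  geometry$apex_point + t_ax * geometry$axis_unit + perp
}

#' Simulate a field of plus-end comet tracks in a polarized cell
#'
#' Growing microtubule plus ends imaged as comets move along the cell's
#' apical-basal axis; a fraction `p_base` grows toward the base. Each comet
#' is a short directed track along the +/- axis with wrapped-Gaussian
#' angular jitter in the xy plane.
#'
#' @param geometry a [cell_geometry()].
#' @param n number of comets, `> 0`.
#' @param p_base probability a comet is base-directed, in `[0, 1]`.
#' @param v comet speed (um/s).
#' @param lifetime_frames frames per comet track.
#' @param dt frame interval (s).
#' @param jitter_deg s.d. of the angular jitter around the axis (degrees).
#' @param sigma_loc localization noise s.d. (um).
#' @param seed integer seed.
#' @return A `labeled_track_set`; `labels$label` is `"base"` or `"apex"`.
#' @export
simulate_comet_field <- function(geometry, n, p_base = 0.8, v = 0.1,
                                 lifetime_frames = 6, dt = 7,
                                 jitter_deg = 15, sigma_loc = 0.02,
                                 seed = NULL) {
  if (n <= 0) rm_stop("n must be > 0")
  if (p_base < 0 || p_base > 1) rm_stop("p_base must be in [0, 1]")
  with_seed(seed, {
    to_base <- runif(n) < p_base
    ang0 <- geometry$axis_angle_deg
    tracks <- vector("list", n)
    for (i in seq_len(n)) {
      ang <- ang0 + (if (to_base[i]) 0 else 180) + rnorm(1, sd = jitter_deg)
      dir <- c(cos(ang * pi / 180), sin(ang * pi / 180), 0)
      p <- motion_params("directed", D = 0, v = v, direction = dir,
                         sigma_loc = sigma_loc, dt = dt,
                         n_frames = lifetime_frames)
      tr <- simulate_track(p, random_point_in_cell(geometry))
      tracks[[i]] <- cbind(track_id = i, tr)
    }
    structure(list(tracks = do.call(rbind, tracks),
                   labels = data.frame(track_id = seq_len(n),
                                       label = ifelse(to_base, "base", "apex")),
                   geometry = geometry),
              class = "labeled_track_set")
  })
}

#' Simulate a pair of tracks that converge and fuse
#'
#' Two puncta approach a meeting point from opposite sides at constant
#' speed, meet at `meet_frame`, and then stay coincident (within the
#' localization noise) for `post_frames` frames while diffusing together.
#' This is the constructed positive for fusion detection: an event is a
#' pair that can no longer be resolved separately and stays together.
#'
#' @param meet_point numeric length 3 (um).
#' @param meet_frame frame index at which the pair becomes coincident,
#'   `>= 2`.
#' @param post_frames number of coincident frames after (and including)
#'   the meeting; `>= 0`. With `post_frames = 0` the tracks cross at one
#'   frame and separate again (a constructed negative).
#' @param params list of simulation knobs: `dt` (s), `sigma_loc` (um),
#'   `approach_step_um` (per-frame approach step), `D_post` (shared
#'   diffusion after fusion, um^2/s). Missing entries take defaults
#'   `dt = 50, sigma_loc = 0.02, approach_step_um = 0.3, D_post = 1e-4`.
#' @param seed integer seed.
#' @return list with `track_a`, `track_b` (data.frames with `track_id`),
#'   and `event` (`track_id_a`, `track_id_b`, `merge_frame`,
#'   `merge_time_s`).
#' @export
simulate_fusion_pair <- function(meet_point = c(5, 5, 1), meet_frame = 10,
                                 post_frames = 8, params = list(),
                                 seed = NULL) {
  if (meet_frame < 2) rm_stop("meet_frame must be >= 2")
  if (post_frames < 0) rm_stop("post_frames must be >= 0")
  dflt <- list(dt = 50, sigma_loc = 0.02, approach_step_um = 0.3,
               D_post = 1e-4)
  params <- utils::modifyList(dflt, params)
  dt <- params$dt
  with_seed(seed, {
    dir_a <- c(1, 0, 0); dir_b <- c(-1, 0, 0)
    pre <- meet_frame - 1
    step <- params$approach_step_um
    n_tot <- meet_frame + post_frames
    mk <- function(dirv) {
      approach <- t(vapply(pre:1, function(k) meet_point - k * step * dirv,
                           numeric(3)))
      rbind(approach, matrix(rep(meet_point, post_frames + 1), ncol = 3,
                             byrow = TRUE))
    }
    pos_a <- mk(dir_a)[seq_len(n_tot), , drop = FALSE]
    pos_b <- mk(dir_b)[seq_len(n_tot), , drop = FALSE]
    if (post_frames == 0) { # cross and separate: diverge after the meeting
      # truncate at the crossing, then continue outward
      n_after <- pre # symmetric separation
      sep_a <- t(vapply(seq_len(n_after), function(k)
        meet_point + k * step * dir_a, numeric(3)))
      sep_b <- t(vapply(seq_len(n_after), function(k)
        meet_point + k * step * dir_b, numeric(3)))
      pos_a <- rbind(pos_a, sep_a)
      pos_b <- rbind(pos_b, sep_b)
      n_tot <- nrow(pos_a)
    } else if (post_frames > 1) {
      # shared diffusion after fusion
      inc <- matrix(rnorm(3 * post_frames, sd = sqrt(2 * params$D_post * dt)),
                    post_frames, 3)
      wob <- apply(inc, 2, cumsum)
      if (post_frames == 1) wob <- matrix(wob, 1, 3)
      rows <- (meet_frame + 1):n_tot
      pos_a[rows, ] <- pos_a[rows, , drop = FALSE] + wob
      pos_b[rows, ] <- pos_b[rows, , drop = FALSE] + wob
    }
    noise <- function(m) m + matrix(rnorm(length(m), sd = params$sigma_loc),
                                    nrow(m), 3)
    pos_a <- noise(pos_a); pos_b <- noise(pos_b)
    mk_df <- function(id, m) data.frame(
      track_id = id, frame = seq_len(nrow(m)), t_s = (seq_len(nrow(m)) - 1) * dt,
      x_um = m[, 1], y_um = m[, 2], z_um = m[, 3])
    list(track_a = mk_df(1L, pos_a), track_b = mk_df(2L, pos_b),
         event = list(track_id_a = 1L, track_id_b = 2L,
                      merge_frame = meet_frame,
                      merge_time_s = (meet_frame - 1) * dt))
  })
}
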