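# Shared fixtures and independent oracles for the test suite.

# A cell standing along +y: apex near the top of the stack, base below,
# axis angle 90 degrees, nucleus plane 4 um from the apex.
make_geom <- function() {
  cell_geometry(c(5, 1, 1), c(5, 9, 1), nucleus_plane = 4)
}

# Straight-line constant-velocity spot table: one row per frame per spot.
ballistic_spots <- function(starts, vels, n_frames, dt = 1) {
  do.call(rbind, lapply(seq_len(n_frames), function(f) {
    do.call(rbind, lapply(seq_len(nrow(starts)), function(s) {
      p <- starts[s, ] + (f - 1) * vels[s, ]
      data.frame(frame = f, t_s = (f - 1) * dt,
                 x_um = p[1], y_um = p[2], z_um = p[3],
                 truth_id = s)
    }))
  }))
}

# Brute-force frame-by-frame linking oracle for small scenes (no gaps):
# enumerates every one-to-one assignment between active track heads and
# next-frame detections, maximizing the number of allowed links
# (distance <= gate) and minimizing total squared distance among those.
# Prediction is constant-velocity with weight w, like the linker under test,
# but the assignment itself is exhaustive enumeration, not the Hungarian
# solver. Returns a list of integer vectors of spot row indices.
oracle_link <- function(spots, gate, w = 1) {
  spots <- spots[order(spots$frame), , drop = FALSE]
  P <- as.matrix(spots[, c("x_um", "y_um", "z_um")])
  frames <- sort(unique(spots$frame))
  act <- list() # list(rows, r, r_prev)
  done <- list()
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det <- which(spots$frame == f)
    if (length(act) == 0) {
      for (j in det) act[[length(act) + 1]] <- list(rows = j, r = P[j, ],
                                                    r_prev = NULL)
      next
    }
    preds <- t(vapply(act, function(a) {
      if (is.null(a$r_prev)) a$r else a$r + w * (a$r - a$r_prev)
    }, numeric(3)))
    n_a <- length(act); n_d <- length(det)
    D2 <- outer(seq_len(n_a), seq_len(n_d), Vectorize(function(i, j)
      sum((preds[i, ] - P[det[j], ])^2)))
    allowed <- sqrt(D2) <= gate
    # enumerate assignments of tracks to (detections or none)
    best <- NULL
    enum <- function(i, used, links, cost) {
      if (i > n_a) {
        score <- c(-length(links) / 2, cost)
        if (is.null(best) ||
            score[1] < best$score[1] ||
            (score[1] == best$score[1] && score[2] < best$score[2] - 1e-12)) {
          best <<- list(links = links, score = score)
        }
        return(invisible())
      }
      enum(i + 1, used, links, cost) # track i unmatched
      for (j in seq_len(n_d)) {
        if (!used[j] && allowed[i, j]) {
          u <- used; u[j] <- TRUE
          enum(i + 1, u, c(links, i, j), cost + D2[i, j])
        }
      }
    }
    enum(1, rep(FALSE, n_d), integer(0), 0)
    links <- best$links
    matched_tracks <- integer(0); matched_dets <- integer(0)
    if (length(links)) {
      m <- matrix(links, ncol = 2, byrow = TRUE)
      matched_tracks <- m[, 1]; matched_dets <- m[, 2]
    }
    new_act <- list()
    for (i in seq_len(n_a)) {
      k <- match(i, matched_tracks)
      if (!is.na(k)) {
        a <- act[[i]]
        j <- det[matched_dets[k]]
        a$r_prev <- a$r; a$r <- P[j, ]; a$rows <- c(a$rows, j)
        new_act[[length(new_act) + 1]] <- a
      } else {
        done[[length(done) + 1]] <- act[[i]]$rows # max_gap = 0 oracle
      }
    }
    for (j in setdiff(seq_len(n_d), matched_dets)) {
      new_act[[length(new_act) + 1]] <- list(rows = det[j], r = P[det[j], ],
                                             r_prev = NULL)
    }
    act <- new_act
  }
  for (a in act) done[[length(done) + 1]] <- a$rows
  Filter(function(rw) length(rw) >= 2, done)
}

# canonical representation of a linked result: sorted list of sorted
# spot-id vectors
track_partition <- function(tracks) {
  sp <- unname(split(tracks$spot_id, tracks$track_id))
  sp <- lapply(sp, sort)
  sp[order(vapply(sp, function(v) v[1], numeric(1)))]
}
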