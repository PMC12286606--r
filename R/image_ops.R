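#' Translational drift correction of a time series
#'
#' Registers every frame of a 4D stack to the first frame by maximizing the
#' 3D cross-correlation (computed via FFT), i.e. rigid translational
#' registration. Offsets are refined to subvoxel precision by a parabolic
#' fit around the correlation peak; frames are shifted back by the rounded
#' offset (edge voxels are filled with the frame median).
#'
#' @param series a 4D [image_stack()] (`y, x, z, t`).
#' @return list with `registered` (an [image_stack()]) and `offsets`
#'   (`t x 3` matrix of per-frame drift in voxels, columns
#'   `row, col, slice`; frame 1 is the reference with zero offset).
#' @export
correct_drift <- function(series) {
  if (!inherits(series, "image_stack") || length(dim(series$data)) != 4)
    rm_stop("correct_drift needs a 4D image_stack")
  d <- dim(series$data)
  nt <- d[4]
  if (nt < 2) rm_stop("need at least 2 frames")
  ref <- series$data[, , , 1]
  if (all(ref == 0)) rm_stop("all-zero frame: nothing to register")
  f_ref <- fft(ref)
  offsets <- matrix(0, nt, 3,
                    dimnames = list(NULL, c("row", "col", "slice")))
  out <- series$data
  for (t in 2:nt) {
    mov <- series$data[, , , t]
    if (all(mov == 0)) rm_stop("all-zero frame: nothing to register")
    cc <- Re(fft(f_ref * Conj(fft(mov)), inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    sh <- pk - 1
    # wrap circular lags to signed shifts
    sh <- ifelse(sh > d[1:3] / 2, sh - d[1:3], sh)
    sub <- vapply(1:3, function(ax) parabolic_peak(cc, pk, ax, d[1:3]),
                  numeric(1))
    off <- -(sh + sub) # drift of frame t relative to frame 1
    offsets[t, ] <- off
    out[, , , t] <- shift_volume(mov, round(-off))
  }
  list(registered = image_stack(out, series$voxel_size, dt = series$dt),
       offsets = offsets)
}

# quadratic interpolation of the correlation peak along one axis
parabolic_peak <- function(cc, pk, ax, dims) {
  i <- pk[ax]
  ip <- if (i == 1) dims[ax] else i - 1
  im <- if (i == dims[ax]) 1 else i + 1
  at <- function(j) {
    q <- pk; q[ax] <- j
    cc[q[1], q[2], q[3]]
  }
  y0 <- at(ip); y1 <- at(i); y2 <- at(im)
  den <- y0 - 2 * y1 + y2
  if (den == 0) return(0)
  del <- 0.5 * (y0 - y2) / den
  max(min(del, 0.5), -0.5)
}

# integer-shift a 3D volume, padding exposed voxels with the median
shift_volume <- function(vol, sh) {
  d <- dim(vol)
  fill <- median(vol)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- sh[ax]
    if (s >= 0) {
      dst[[ax]] <- (1 + s):d[ax]; src[[ax]] <- 1:(d[ax] - s)
    } else {
      dst[[ax]] <- 1:(d[ax] + s); src[[ax]] <- (1 - s):d[ax]
    }
    if (length(src[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable Gaussian blur of a 3D array; sigma per axis in voxels.
gauss_blur3d <- function(arr, sigma) {
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- exp(-((-r:r)^2) / (2 * sigma[ax]^2))
    k <- k / sum(k)
    arr <- conv_axis(arr, k, ax, r)
  }
  arr
}

# Convolve along one axis with replicate-edge padding.
conv_axis <- function(arr, k, ax, r) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  dm <- dim(a)
  m <- matrix(a, dm[1], prod(dm[-1]))
  mp <- rbind(m[rep(1, r), , drop = FALSE], m,
              m[rep(nrow(m), r), , drop = FALSE])
  f <- stats::filter(mp, k, sides = 2)
  f <- f[(r + 1):(r + dm[1]), , drop = FALSE]
  a2 <- array(as.numeric(f), dm)
  aperm(a2, order(perm))
}

# 3D Laplacian with physical spacings (negated so blobs give positive peaks)
neg_laplacian3d <- function(arr, spacing) {
  d <- dim(arr)
  out <- array(0, d)
  for (ax in 1:3) {
    up <- shift_axis(arr, ax, 1L)
    dn <- shift_axis(arr, ax, -1L)
    out <- out + (up + dn - 2 * arr) / spacing[ax]^2
  }
  -out
}

shift_axis <- function(arr, ax, s) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  j <- pmin(pmax(idx[[ax]] + s, 1L), d[ax]) # replicate edges
  idx[[ax]] <- j
  arr[idx[[1]], idx[[2]], idx[[3]]]
}

#' Detect diffraction-limited spots in a 3D volume
#'
#' Band-pass filters the volume with a Laplacian-of-Gaussian at the scale
#' set by the expected spot diameter, finds local maxima with a minimum
#' separation of one diameter, refines each to a subvoxel centroid
#' (intensity-weighted over a 3x3x3 neighbourhood), and reports a quality
#' per spot (the filter response normalized by the robust noise level of
#' the filtered volume). Spots below `quality_threshold` are dropped.
#'
#' @param volume a 3D [image_stack()].
#' @param expected_diameter_um expected xy spot diameter (um); the ribbon
#'   and comet conventions are 0.427 and 0.534 um.
#' @param quality_threshold minimum quality (default 5).
#' @return data.frame `spot_id, x_um, y_um, z_um, quality`.
#' @export
detect_spots <- function(volume, expected_diameter_um = 0.427,
                         quality_threshold = 5) {
  if (!inherits(volume, "image_stack") || length(dim(volume$data)) != 3)
    rm_stop("detect_spots needs a 3D image_stack")
  if (expected_diameter_um <= 0) rm_stop("expected_diameter_um must be > 0")
  vs <- volume$voxel_size
  if (expected_diameter_um < min(vs[1:2]))
    rm_stop("expected diameter is smaller than one voxel")
  sigma_um <- expected_diameter_um / (2 * sqrt(2))
  sigma_vox <- c(sigma_um / vs[2], sigma_um / vs[1], sigma_um / vs[3])
  sm <- gauss_blur3d(volume$data, sigma_vox)
  resp <- neg_laplacian3d(sm, c(vs[2], vs[1], vs[3])) * sigma_um^2
  noise <- mad(resp)
  if (noise == 0) noise <- sd(resp)
  if (is.na(noise) || noise == 0) {
    return(data.frame(spot_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      quality = numeric(0)))
  }
  q <- resp / noise
  peaks <- local_maxima3d(q)
  # drop border maxima: the Laplacian is unreliable at replicated edges
  marg <- pmax(ceiling(c(sigma_vox[2], sigma_vox[1], sigma_vox[3])), 1) + 1
  d <- dim(q)
  inb <- peaks[, 1] > marg[1] & peaks[, 1] <= d[1] - marg[1] &
         peaks[, 2] > marg[2] & peaks[, 2] <= d[2] - marg[2] &
         peaks[, 3] > marg[3] & peaks[, 3] <= d[3] - marg[3]
  peaks <- peaks[inb, , drop = FALSE]
  if (nrow(peaks) == 0)
    return(data.frame(spot_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      quality = numeric(0)))
  peaks <- peaks[q[peaks] >= quality_threshold, , drop = FALSE]
  if (nrow(peaks) == 0)
    return(data.frame(spot_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      quality = numeric(0)))
  qv <- q[peaks]
  ord <- order(qv, decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  qv <- qv[ord]
  pos <- voxel_to_pos(peaks, vs)
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      later <- (i + 1):nrow(peaks)
      dd <- sqrt(rowSums(sweep(pos[later, , drop = FALSE], 2, pos[i, ])^2))
      keep[later][dd < expected_diameter_um] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  qv <- qv[keep]
  cen <- t(vapply(seq_len(nrow(peaks)), function(i)
    subvoxel_centroid(sm, peaks[i, ]), numeric(3)))
  posc <- voxel_to_pos(cen, vs)
  data.frame(spot_id = seq_len(nrow(peaks)), x_um = posc[, 1],
             y_um = posc[, 2], z_um = posc[, 3], quality = qv)
}

# strict local maxima over the 26-neighbourhood (ties broken toward the
# lexicographically first voxel via >=)
local_maxima3d <- function(arr) {
  d <- dim(arr)
  is_max <- array(TRUE, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    nb <- shift_axis(shift_axis(shift_axis(arr, 1, di), 2, dj), 3, dk)
    is_max <- is_max & (arr >= nb)
  }
  # exclude flat interiors of constant regions by requiring > somewhere
  any_less <- array(FALSE, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    nb <- shift_axis(shift_axis(shift_axis(arr, 1, di), 2, dj), 3, dk)
    any_less <- any_less | (arr > nb)
  }
  which(is_max & any_less, arr.ind = TRUE)
}

subvoxel_centroid <- function(arr, vox) {
  d <- dim(arr)
  rr <- max(1, vox[1] - 1):min(d[1], vox[1] + 1)
  cc <- max(1, vox[2] - 1):min(d[2], vox[2] + 1)
  ss <- max(1, vox[3] - 1):min(d[3], vox[3] + 1)
  w <- arr[rr, cc, ss, drop = FALSE]
  w <- w - min(w)
  if (sum(w) == 0) return(as.numeric(vox))
  wi <- apply(w, 1, sum); wj <- apply(w, 2, sum); wk <- apply(w, 3, sum)
  c(sum(rr * wi) / sum(wi), sum(cc * wj) / sum(wj), sum(ss * wk) / sum(wk))
}

#' Segment and count 3D puncta
#'
#' Thresholds the volume, optionally splits touching objects by a
#' marker-based watershed on the Euclidean distance transform, labels
#' connected components (26-connectivity), applies the size filter, and
#' returns one record per object. This mirrors the threshold / watershed /
#' 3D-object-counting sequence used for live ribbon counting, with the
#' object-counter defaults `min_size = 0`, `max_size = 183500` voxels.
#'
#' @param volume a 3D [image_stack()].
#' @param intensity_threshold voxels `>=` this value are foreground; must
#'   lie within the intensity range of the volume.
#' @param split_touching split touching objects via watershed (default
#'   TRUE).
#' @param min_size_vox,max_size_vox inclusive size filter in voxels.
#' @param seed_sep_um minimum separation of watershed seeds (um); default
#'   0.4, about one ribbon spot diameter.
#' @return data.frame `punctum_id, x_um, y_um, z_um, volume_voxels,
#'   volume_um3`.
#' @export
segment_puncta_3d <- function(volume, intensity_threshold,
                              split_touching = TRUE, min_size_vox = 0,
                              max_size_vox = 183500, seed_sep_um = 0.4) {
  if (!inherits(volume, "image_stack") || length(dim(volume$data)) != 3)
    rm_stop("segment_puncta_3d needs a 3D image_stack")
  if (min_size_vox > max_size_vox) rm_stop("min_size_vox > max_size_vox")
  rng <- range(volume$data)
  if (intensity_threshold < rng[1] || intensity_threshold > rng[2])
    rm_stop("intensity_threshold %g outside intensity range [%g, %g]",
            intensity_threshold, rng[1], rng[2])
  vs <- volume$voxel_size
  mask <- array(as.integer(volume$data >= intensity_threshold),
                dim = dim(volume$data))
  dims <- as.integer(dim(mask))
  if (sum(mask) == 0) {
    return(empty_puncta())
  }
  if (split_touching) {
    edt <- cpp_edt3d(mask, dims, vs[2], vs[1], vs[3])
    seeds <- watershed_seeds(edt, mask, vs, seed_sep_um)
    lab <- cpp_watershed3d(edt, seeds, mask, dims)
  } else {
    lab <- cpp_label3d(mask, dims, 26L)
  }
  tab <- tabulate(lab[lab > 0])
  ids <- which(tab >= min_size_vox & tab <= max_size_vox & tab >= 1)
  if (length(ids) == 0) return(empty_puncta())
  recs <- lapply(seq_along(ids), function(i) {
    vox <- which(lab == ids[i], arr.ind = TRUE)
    cen <- colMeans(voxel_to_pos(vox, vs))
    data.frame(punctum_id = i, x_um = cen[1], y_um = cen[2], z_um = cen[3],
               volume_voxels = nrow(vox),
               volume_um3 = nrow(vox) * prod(vs))
  })
  do.call(rbind, recs)
}

empty_puncta <- function() {
  data.frame(punctum_id = integer(0), x_um = numeric(0), y_um = numeric(0),
             z_um = numeric(0), volume_voxels = integer(0),
             volume_um3 = numeric(0))
}

# Seeds for the watershed: local maxima of the distance transform.
# Discretization makes EDT maxima come in flat plateaus, so maxima voxels
# are first collapsed to one representative per connected plateau, then
# merged greedily so no two seeds are closer than seed_sep_um.
watershed_seeds <- function(edt, mask, vs, seed_sep_um) {
  d <- dim(mask)
  pk <- local_maxima3d(edt)
  pk <- pk[mask[pk] > 0, , drop = FALSE]
  if (nrow(pk) == 0) pk <- which(edt == max(edt), arr.ind = TRUE)[1, , drop = FALSE]
  if (nrow(pk) > 1) {
    pk_mask <- array(0L, d)
    pk_mask[pk] <- 1L
    pl <- cpp_label3d(pk_mask, as.integer(d), 26L)
    pk <- do.call(rbind, lapply(seq_len(max(pl)), function(lbl) {
      vox <- which(pl == lbl, arr.ind = TRUE)
      best <- which.max(edt[vox])
      vox[best, , drop = FALSE]
    }))
  }
  v <- edt[pk]
  ord <- order(v, decreasing = TRUE)
  pk <- pk[ord, , drop = FALSE]
  pos <- voxel_to_pos(pk, vs)
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i] || i == nrow(pk)) next
    later <- (i + 1):nrow(pk)
    dd <- sqrt(rowSums(sweep(pos[later, , drop = FALSE], 2, pos[i, ])^2))
    keep[later][dd < seed_sep_um] <- FALSE
  }
  pk <- pk[keep, , drop = FALSE]
  seeds <- array(0L, d)
  seeds[pk] <- seq_len(nrow(pk))
  seeds
}

#' Assign puncta to the apical or basal compartment
#'
#' Projects each punctum centroid onto the apex-to-base axis; centroids
#' past the nucleus plane (toward the base) are `basal`, the rest
#' `apical` — the live-counting convention that ribbons below the nucleus
#' are basal and all others apical.
#'
#' @param puncta data.frame with `x_um, y_um, z_um` (e.g. from
#'   [segment_puncta_3d()] or a scene ground truth).
#' @param geometry a [cell_geometry()].
#' @return the input with a `compartment` column; per-compartment counts
#'   are attached as `attr(, "counts")`.
#' @export
classify_apical_basal <- function(puncta, geometry) {
  if (is.null(geometry)) rm_stop("geometry must be supplied")
  if (nrow(puncta) == 0) {
    puncta$compartment <- character(0)
    attr(puncta, "counts") <- c(apical = 0L, basal = 0L)
    return(puncta)
  }
  ax <- as.numeric(axis_coordinate(
    as.matrix(puncta[, c("x_um", "y_um", "z_um")]), geometry))
  puncta$compartment <- ifelse(ax > geometry$nucleus_plane, "basal", "apical")
  attr(puncta, "counts") <- c(
    apical = sum(puncta$compartment == "apical"),
    basal = sum(puncta$compartment == "basal"))
  puncta
}

# Grayscale opening (erosion then dilation) with a (2r+1)-square window and
# replicated edges: the background estimate of the rolling-ball subtraction.
# Separable running min/max keeps it O(r) per pixel; like the rolling ball,
# it removes features narrower than the window and commutes with adding a
# constant.
gray_opening2d <- function(m, r) {
  gray_filter2d(gray_filter2d(m, r, pmin), r, pmax)
}

gray_filter2d <- function(m, r, reducer) {
  run <- function(mat) { # along rows (dim 1), replicate edges
    out <- mat
    n <- nrow(mat)
    for (s in seq_len(r)) {
      up <- mat[pmin(pmax(seq_len(n) + s, 1L), n), , drop = FALSE]
      dn <- mat[pmin(pmax(seq_len(n) - s, 1L), n), , drop = FALSE]
      out <- reducer(out, up, dn)
    }
    out
  }
  t(run(t(run(m))))
}

#' Quantify 2D puncta areas from a maximum projection
#'
#' Max-projects the volume along z, subtracts the background with a
#' rolling-ball-style morphological opening, thresholds, splits touching
#' objects with a 2D watershed on the distance transform, and returns the
#' areas (um^2) of all objects at least `min_area_um2` — the fixed-sample
#' area pipeline with its 0.002 um^2 minimum size filter.
#'
#' @param volume a 3D [image_stack()].
#' @param rolling_ball_radius_px structuring-element radius in pixels
#'   (default 50, the conventional plugin default).
#' @param threshold intensity threshold applied after background
#'   subtraction.
#' @param min_area_um2 minimum object area (um^2), default 0.002.
#' @param split_touching apply the watershed split (default TRUE).
#' @return numeric vector of object areas in um^2.
#' @export
quantify_areas_2d <- function(volume, rolling_ball_radius_px = 50,
                              threshold, min_area_um2 = 0.002,
                              split_touching = TRUE) {
  if (!inherits(volume, "image_stack") || length(dim(volume$data)) != 3)
    rm_stop("quantify_areas_2d needs a 3D image_stack")
  if (rolling_ball_radius_px < 1) rm_stop("rolling_ball_radius_px must be >= 1")
  vs <- volume$voxel_size
  proj <- apply(volume$data, c(1, 2), max)
  r <- round(rolling_ball_radius_px)
  bg <- gray_opening2d(proj, r)
  sub <- pmax(proj - bg, 0)
  if (threshold > max(sub)) {
    warning("threshold above maximum background-subtracted intensity; no objects")
    return(numeric(0))
  }
  mask <- sub >= threshold
  if (split_touching) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm)
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  lab <- as.integer(lab)
  counts <- tabulate(lab[lab > 0])
  areas <- counts * vs[1] * vs[2]
  areas[areas >= min_area_um2]
}

#' Developmental stage from kinocilium height
#'
#' The kinocilium height is the number of z slices between its tip and base
#' times the z interval; height bins define the stage: early `[0, 1.5)`,
#' intermediate `[1.5, 10)`, late `[10, 18]`, mature `(18, Inf)` um.
#'
#' @param n_z_slices number of z slices spanned by the kinocilium (may be
#'   a vector), `>= 0`.
#' @param z_interval_um z-slice interval (um), default 0.425.
#' @return data.frame `n_z_slices, kinocilium_height_um, stage`.
#' @examples
#' stage_cell(10) # 4.25 um -> intermediate
#' @export
stage_cell <- function(n_z_slices, z_interval_um = 0.425) {
  if (any(n_z_slices < 0)) rm_stop("n_z_slices must be >= 0")
  h <- n_z_slices * z_interval_um
  stage <- ifelse(h < 1.5, "early",
           ifelse(h < 10, "intermediate",
           ifelse(h <= 18, "late", "mature")))
  data.frame(n_z_slices = n_z_slices, kinocilium_height_um = h,
             stage = stage)
}
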