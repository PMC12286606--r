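#' Rendering parameters for synthetic image stacks
#'
#' Describes how point emitters are rendered into a confocal-like 3D stack:
#' each emitter contributes an anisotropic Gaussian of the given amplitude
#' over a constant background, with optional shot noise applied last.
#'
#' @param voxel_size `(dx, dy, dz)` in um; default `c(0.04, 0.04, 0.17)`,
#'   the acquisition convention for the ribbon stacks.
#' @param psf_sigma `(sigma_xy, sigma_z)` in um.
#' @param spot_amplitude peak counts added by one emitter.
#' @param background constant background counts.
#' @param noise_model `"poisson"` (on signal + background), `"none"`, or
#'   `list(model = "gaussian", sd = <counts>)`.
#' @param stack_shape `(nx, ny, nz)` voxels.
#' @return A `render_params` object.
#' @export
render_params <- function(voxel_size = c(0.04, 0.04, 0.17),
                          psf_sigma = c(0.1, 0.25),
                          spot_amplitude = 200, background = 10,
                          noise_model = "poisson",
                          stack_shape = c(64, 64, 16)) {
  if (any(voxel_size <= 0) || any(psf_sigma <= 0) || spot_amplitude <= 0 ||
      background < 0 || any(stack_shape < 1))
    rm_stop("render parameters must be positive")
  structure(list(voxel_size = as.numeric(voxel_size),
                 psf_sigma = as.numeric(psf_sigma),
                 spot_amplitude = spot_amplitude, background = background,
                 noise_model = noise_model,
                 stack_shape = as.integer(stack_shape)),
            class = "render_params")
}

#' Image stack container
#'
#' A 3D (`y, x, z`) or 4D (`y, x, z, t`) non-negative intensity array with
#' voxel size metadata (um) and, for time series, the frame interval (s).
#' The centre of voxel `(i, j, k)` (row, column, slice) sits at physical
#' position `x = (j - 0.5) dx`, `y = (i - 0.5) dy`, `z = (k - 0.5) dz`.
#'
#' @param data 3D or 4D numeric array.
#' @param voxel_size `(dx, dy, dz)` um.
#' @param dt frame interval (s), 4D only.
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, voxel_size, dt = NULL) {
  nd <- length(dim(data))
  if (!(nd %in% c(3, 4))) rm_stop("data must be a 3D or 4D array")
  if (any(dim(data) < 1)) rm_stop("all dimensions must be >= 1")
  if (any(voxel_size <= 0)) rm_stop("voxel sizes must be > 0")
  if (any(data < 0)) rm_stop("intensities must be >= 0")
  structure(list(data = data, voxel_size = as.numeric(voxel_size), dt = dt),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %s voxels, voxel %s um%s\n",
              paste(dim(x$data), collapse = " x "),
              paste(x$voxel_size, collapse = " x "),
              if (!is.null(x$dt)) sprintf(", dt %g s", x$dt) else ""))
  invisible(x)
}

# um position -> fractional voxel index (row, col, slice)
pos_to_voxel <- function(pos, voxel_size) {
  pos <- rbind(pos)
  cbind(pos[, 2] / voxel_size[2] + 0.5,   # row from y
        pos[, 1] / voxel_size[1] + 0.5,   # col from x
        pos[, 3] / voxel_size[3] + 0.5)   # slice from z
}

# voxel index (row, col, slice) -> um position (x, y, z) of the voxel centre
voxel_to_pos <- function(vox, voxel_size) {
  vox <- rbind(vox)
  cbind((vox[, 2] - 0.5) * voxel_size[1],
        (vox[, 1] - 0.5) * voxel_size[2],
        (vox[, 3] - 0.5) * voxel_size[3])
}

render_volume <- function(positions, rp) {
  nx <- rp$stack_shape[1]; ny <- rp$stack_shape[2]; nz <- rp$stack_shape[3]
  vol <- array(rp$background, dim = c(ny, nx, nz))
  if (is.null(positions) || NROW(positions) == 0) return(vol)
  positions <- rbind(positions)
  lim <- c(nx * rp$voxel_size[1], ny * rp$voxel_size[2], nz * rp$voxel_size[3])
  if (any(positions < 0) || any(sweep(positions, 2, lim) > 0))
    rm_stop("emitter position outside the stack bounds")
  sx <- rp$psf_sigma[1] / rp$voxel_size[1]
  sy <- rp$psf_sigma[1] / rp$voxel_size[2]
  sz <- rp$psf_sigma[2] / rp$voxel_size[3]
  for (s in seq_len(nrow(positions))) {
    v <- pos_to_voxel(positions[s, ], rp$voxel_size)
    ri <- v[1]; cj <- v[2]; sk <- v[3]
    rows <- max(1, floor(ri - 4 * sy)):min(ny, ceiling(ri + 4 * sy))
    cols <- max(1, floor(cj - 4 * sx)):min(nx, ceiling(cj + 4 * sx))
    slcs <- max(1, floor(sk - 4 * sz)):min(nz, ceiling(sk + 4 * sz))
    gy <- exp(-((rows - ri)^2) / (2 * sy^2))
    gx <- exp(-((cols - cj)^2) / (2 * sx^2))
    gz <- exp(-((slcs - sk)^2) / (2 * sz^2))
    spot <- rp$spot_amplitude * (gy %o% gx %o% gz)
    vol[rows, cols, slcs] <- vol[rows, cols, slcs] + spot
  }
  vol
}

apply_noise <- function(vol, noise_model) {
  if (identical(noise_model, "none")) return(vol)
  if (identical(noise_model, "poisson")) {
    return(array(rpois(length(vol), lambda = vol), dim = dim(vol)))
  }
  if (is.list(noise_model) && identical(noise_model$model, "gaussian")) {
    return(pmax(vol + array(rnorm(length(vol), sd = noise_model$sd),
                            dim = dim(vol)), 0))
  }
  rm_stop("unknown noise model")
}

#' Render emitters into a synthetic image stack
#'
#' @param positions either an `n x 3` matrix / data.frame of `(x, y, z)`
#'   positions in um (a static scene), or a track table (columns
#'   `frame, x_um, y_um, z_um`) rendered per frame into a 4D stack.
#' @param rp a [render_params()] object.
#' @param frame optional single frame index: render only that frame of a
#'   track table.
#' @param dt frame interval recorded in the metadata of a 4D render (s).
#' @param seed integer seed for the noise.
#' @return An [image_stack()].
#' @examples
#' rp <- render_params(noise_model = "none", stack_shape = c(32, 32, 8))
#' st <- render_stack(cbind(0.6, 0.6, 0.6), rp)
#' which(st$data == max(st$data), arr.ind = TRUE)
#' @export
render_stack <- function(positions, rp, frame = NULL, dt = NULL,
                         seed = NULL) {
  with_seed(seed, {
    if (is.data.frame(positions) && "frame" %in% names(positions)) {
      if (!is.null(frame)) {
        sub <- positions[positions$frame == frame, , drop = FALSE]
        vol <- render_volume(as.matrix(sub[, c("x_um", "y_um", "z_um")]), rp)
        return(image_stack(apply_noise(vol, rp$noise_model), rp$voxel_size))
      }
      frames <- sort(unique(positions$frame))
      vols <- lapply(frames, function(f) {
        sub <- positions[positions$frame == f, , drop = FALSE]
        apply_noise(render_volume(
          as.matrix(sub[, c("x_um", "y_um", "z_um")]), rp), rp$noise_model)
      })
      data4 <- array(unlist(vols),
                     dim = c(dim(vols[[1]]), length(frames)))
      return(image_stack(data4, rp$voxel_size, dt = dt))
    }
    pos <- if (NROW(positions) == 0) NULL else as.matrix(rbind(positions))
    vol <- render_volume(pos, rp)
    image_stack(apply_noise(vol, rp$noise_model), rp$voxel_size)
  })
}

#' Build a rendered scene of apical and basal puncta with ground truth
#'
#' Places `n_apical` emitters on the apical side of the nucleus plane and
#' `n_basal` on the basal side (along the cell axis of `geometry`), renders
#' them, and returns the stack together with the ground-truth puncta table.
#' Emitters are rejection-sampled to keep a minimum pairwise separation so
#' rendered spots stay resolvable.
#'
#' @param geometry a [cell_geometry()] whose apex and base lie inside the
#'   physical bounds of the stack described by `rp`.
#' @param n_apical,n_basal puncta counts per compartment, `>= 0`.
#' @param rp a [render_params()].
#' @param min_sep_um minimum pairwise emitter separation (um).
#' @param seed integer seed.
#' @return list with `stack` (an [image_stack()]) and `truth` (data.frame
#'   `x_um, y_um, z_um, compartment`).
#' @export
make_puncta_scene <- function(geometry, n_apical, n_basal, rp,
                              min_sep_um = 1, seed = NULL) {
  if (n_apical < 0 || n_basal < 0) rm_stop("counts must be >= 0")
  lim <- c(rp$stack_shape[1] * rp$voxel_size[1],
           rp$stack_shape[2] * rp$voxel_size[2],
           rp$stack_shape[3] * rp$voxel_size[3])
  margin <- c(3 * rp$psf_sigma[1], 3 * rp$psf_sigma[1], 2 * rp$psf_sigma[2])
  with_seed(seed, {
    pts <- matrix(numeric(0), 0, 3)
    want <- c(rep("apical", n_apical), rep("basal", n_basal))
    for (side in want) {
      placed <- FALSE
      for (try in seq_len(2000)) {
        cand <- margin + runif(3) * (lim - 2 * margin)
        ax <- as.numeric(axis_coordinate(cand, geometry))
        ok_side <- if (side == "apical") ax < geometry$nucleus_plane
                   else ax > geometry$nucleus_plane
        if (!ok_side) next
        if (nrow(pts) > 0) {
          dists <- sqrt(rowSums(sweep(pts, 2, cand)^2))
          if (min(dists) < min_sep_um) next
        }
        pts <- rbind(pts, cand)
        placed <- TRUE
        break
      }
      if (!placed)
        rm_stop("scene too small to place puncta at separation %g um",
                min_sep_um)
    }
    truth <- if (length(want) == 0)
      data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                 compartment = character(0))
    else
      data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
                 compartment = want)
    stack <- render_stack(if (nrow(pts)) pts else matrix(numeric(0), 0, 3), rp)
    list(stack = stack, truth = truth)
  })
}
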