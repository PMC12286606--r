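#' Cell geometry: the apical-basal axis and the nucleus plane
#'
#' Hair cells are polarized, with the hair bundle at the apex and the
#' synaptic compartment at the base. Track polarity and apical/basal
#' compartment calls are made relative to this axis. The convention follows
#' the comet analysis: a track moving toward the base has angle 0 degrees,
#' toward the apex 180 degrees.
#'
#' @param apex_point numeric length 2 or 3, apex position in micrometres.
#' @param base_point numeric length 2 or 3, base position in micrometres.
#' @param nucleus_plane scalar coordinate along the apex-to-base axis (in
#'   micrometres from the apex projection) separating "above nucleus"
#'   (apical side) from "below nucleus" (basal side). Must lie strictly
#'   between the apex and base projections.
#'
#' @return An object of class `cell_geometry` with fields `apex_point`,
#'   `base_point`, `axis_angle_deg` (xy angle of base minus apex, in
#'   `[0, 360)`), `axis_unit` (3D unit vector apex to base) and
#'   `nucleus_plane`.
#' @examples
#' g <- cell_geometry(c(0, 0, 0), c(10, 0, 0), nucleus_plane = 6)
#' g$axis_angle_deg # 0
#' @export
cell_geometry <- function(apex_point, base_point, nucleus_plane) {
  apex_point <- as.numeric(apex_point)
  base_point <- as.numeric(base_point)
  if (length(apex_point) == 2) apex_point <- c(apex_point, 0)
  if (length(base_point) == 2) base_point <- c(base_point, 0)
  if (length(apex_point) != 3 || length(base_point) != 3)
    rm_stop("apex_point and base_point must have length 2 or 3")
  axis_vec <- base_point - apex_point
  len <- sqrt(sum(axis_vec^2))
  if (len == 0) rm_stop("apex_point and base_point must differ")
  ang <- atan2(axis_vec[2], axis_vec[1]) * 180 / pi
  ang <- ang %% 360
  if (missing(nucleus_plane) || is.null(nucleus_plane))
    nucleus_plane <- len / 2
  if (!(nucleus_plane > 0 && nucleus_plane < len))
    rm_stop("nucleus_plane must lie strictly between apex (0) and base (%.3g)",
            len)
  structure(
    list(apex_point = apex_point, base_point = base_point,
         axis_unit = axis_vec / len, axis_length_um = len,
         axis_angle_deg = ang, nucleus_plane = nucleus_plane),
    class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "cell_geometry: apex (%s) -> base (%s), axis angle %.2f deg, nucleus plane at %.3g um\n",
    paste(signif(x$apex_point, 4), collapse = ", "),
    paste(signif(x$base_point, 4), collapse = ", "),
    x$axis_angle_deg, x$nucleus_plane))
  invisible(x)
}

# Project 3D positions (matrix n x 3, um) onto the apex->base axis;
# returns the signed coordinate in um with 0 at the apex projection.
axis_coordinate <- function(pos, geometry) {
  pos <- rbind(pos)
  sweep(pos, 2, geometry$apex_point) %*% geometry$axis_unit
}
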