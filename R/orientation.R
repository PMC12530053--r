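# Angle conventions, handedness, layer statistics and helix geometry for
# reconstructed fibril-axis fields.
#
# Convention (fixed package-wide): the in-plane angle phi_ip is measured from
# the +x (horizontal scan) axis in [0, 180); the out-of-plane angle theta is
# signed, |theta| measured from the +z (beam) axis - 0 deg means the fibril
# points along the beam, 90 deg means it lies in the scan plane - and
# sign(theta) = sign(a_y) after restriction to the positive-z hemisphere.

#' Convert a unit fibril axis to (in-plane, out-of-plane) angles
#'
#' @param a_hat unit 3-vector with `a_z >= 0`.
#' @return list with `in_plane_deg` in `[0, 180)`, `out_of_plane_deg` in
#'   `[-90, 90]`, and `zero_y` (TRUE when `a_y = 0`, where the sign is
#'   undefined and theta is reported non-negative).
#' @export
angles_from_axis <- function(a_hat) {
  if (abs(sqrt(sum(a_hat^2)) - 1) > 1e-6)
    sed3d_error("axis must be a unit vector", "sed3d_value_error")
  if (a_hat[3] < -1e-12)
    sed3d_error("axis must lie in the positive-z hemisphere",
                "sed3d_value_error")
  phi <- mod180(rad2deg(atan2(a_hat[2], a_hat[1])))
  th <- rad2deg(acos(max(-1, min(1, a_hat[3]))))
  zero_y <- a_hat[2] == 0
  if (!zero_y) th <- sign(a_hat[2]) * th
  list(in_plane_deg = phi, out_of_plane_deg = th, zero_y = zero_y)
}

#' Convert (in-plane, out-of-plane) angles to a unit axis
#'
#' Inverse of [angles_from_axis()]; the returned axis always lies in the
#' positive-z hemisphere.
#'
#' @param in_plane_deg in-plane angle, degrees.
#' @param out_of_plane_deg signed out-of-plane angle, degrees in
#'   `[-90, 90]`.
#' @return unit 3-vector.
#' @export
axis_from_angles <- function(in_plane_deg, out_of_plane_deg) {
  s <- if (out_of_plane_deg >= 0) 1 else -1
  t <- deg2rad(abs(out_of_plane_deg))
  p <- deg2rad(in_plane_deg)
  c(s * sin(t) * cos(p), s * sin(t) * sin(p), cos(t))
}

#' Angle between two fibril axes
#'
#' Axes are sign-ambiguous, so the relationship between two of them is
#' `arccos` of the absolute value of their dot product, in `[0, 90]`.
#'
#' @param a1,a2 unit 3-vectors.
#' @return angle in degrees.
#' @export
orientation_relationship <- function(a1, a2) {
  rad2deg(acos(min(1, abs(sum(a1 * a2)))))
}

#' Per-region orientation statistics
#'
#' Summarizes an orientation field over labelled regions (cell-wall layers):
#' circular mean and dispersion of the in-plane angle (period 180 degrees),
#' arithmetic mean and sd of the signed out-of-plane angle (signs encode
#' handedness and must not be wrapped), pixel count, and a handedness label
#' from the sign of the mean out-of-plane angle (`positive_theta`, default
#' `"left"`, names the handedness of positive-theta layers for the given
#' lumen geometry).
#'
#' @param field an [orientation_field()].
#' @param regions integer label matrix (0 = unlabelled), same shape.
#' @param positive_theta handedness label assigned to layers with positive
#'   mean out-of-plane angle; the opposite label goes to negative layers.
#' @param erode shrink each region by this many pixels before averaging;
#'   interface pixels mix neighbouring layers (finite beam size, registration
#'   residuals), so excluding a thin boundary band gives cleaner per-layer
#'   means.
#' @return data frame with one row per region label.
#' @export
layer_stats <- function(field, regions, positive_theta = c("left", "right"),
                        erode = 0L) {
  positive_theta <- match.arg(positive_theta)
  negative_theta <- setdiff(c("left", "right"), positive_theta)
  stopifnot(identical(dim(regions), dim(field$valid)))
  labs <- sort(unique(regions[regions > 0]))
  use <- field$valid & !field$degenerate
  out <- lapply(labs, function(L) {
    rmask <- regions == L
    if (erode > 0) for (k in seq_len(erode)) rmask <- erode3(rmask)
    sel <- which(rmask & use)
    n <- length(sel)
    if (n == 0)
      return(data.frame(label = L, n_pixels = 0L, in_plane_deg = NA_real_,
                        out_of_plane_deg = NA_real_, in_plane_sd = NA_real_,
                        out_of_plane_sd = NA_real_, handedness = NA_character_))
    np <- prod(dim(field$valid))
    ax <- field$axes[sel]; ay <- field$axes[sel + np]
    az <- field$axes[sel + 2 * np]
    phi <- mod180(rad2deg(atan2(ay, ax)))
    th <- rad2deg(acos(pmax(-1, pmin(1, az)))) * ifelse(ay >= 0, 1, -1)
    phi_mean <- circ_mean180(phi)
    phi_sd <- circ_sd180(phi)
    th_mean <- mean(th)
    th_sd <- stats::sd(th)
    data.frame(label = L, n_pixels = n, in_plane_deg = phi_mean,
               out_of_plane_deg = th_mean, in_plane_sd = phi_sd,
               out_of_plane_sd = if (is.na(th_sd)) 0 else th_sd,
               handedness = if (th_mean >= 0) positive_theta else negative_theta)
  })
  do.call(rbind, out)
}

# Circular mean of axial angles (period 180 deg) via angle doubling.
circ_mean180 <- function(phi_deg) {
  z <- exp(2i * deg2rad(phi_deg))
  mod180(rad2deg(Arg(mean(z)) / 2))
}

# Circular standard deviation of axial angles, degrees.
circ_sd180 <- function(phi_deg) {
  R <- Mod(mean(exp(2i * deg2rad(phi_deg))))
  if (R >= 1) return(0)
  rad2deg(sqrt(-2 * log(R))) / 2
}

#' Classify the helical handedness of a fibril axis
#'
#' For a fibril winding helically around a cell, the handedness at a wall
#' point follows from the signs of the axis components along the local
#' tangent `t = cell_axis x radial_out` and the cell axis: the product
#' `s = (a . t)(a . cell_axis)` is positive for a right-handed and negative
#' for a left-handed winding, and is invariant under the axis sign flip
#' `a -> -a`. Axes winding purely around the hoop (or purely axially) are
#' indeterminate.
#'
#' @param a_hat unit fibril axis.
#' @param cell_axis unit vector along the cell's extended axis.
#' @param radial_out unit vector pointing radially away from the lumen;
#'   must be orthogonal to `cell_axis` within 1 degree.
#' @param eps indeterminacy band on the product `s`.
#' @return `"left"`, `"right"`, or `"indeterminate"`.
#' @export
classify_handedness <- function(a_hat, cell_axis, radial_out,
                                eps = sin(deg2rad(2))) {
  if (abs(sum(cell_axis * radial_out)) > sin(deg2rad(1)))
    sed3d_error("cell_axis and radial_out must be orthogonal within 1 degree",
                "sed3d_geometry_error")
  tangent <- c(cell_axis[2] * radial_out[3] - cell_axis[3] * radial_out[2],
               cell_axis[3] * radial_out[1] - cell_axis[1] * radial_out[3],
               cell_axis[1] * radial_out[2] - cell_axis[2] * radial_out[1])
  s <- sum(a_hat * tangent) * sum(a_hat * cell_axis)
  if (s > eps) "right" else if (s < -eps) "left" else "indeterminate"
}

#' Helix pitch from helix angle and circumference
#'
#' The helix angle is measured between the helical fibril path and the
#' extended axis of the cell; the pitch is the distance along that axis for
#' one complete loop, `pitch = circumference / tan(helix_angle)`.
#'
#' @param helix_angle_deg helix angle in degrees, strictly inside (0, 90).
#' @param circumference_um cell circumference, micrometres.
#' @return pitch in micrometres.
#' @export
helix_pitch <- function(helix_angle_deg, circumference_um) {
  if (!is.finite(helix_angle_deg) || helix_angle_deg <= 0 ||
      helix_angle_deg >= 90)
    sed3d_error("helix angle must lie strictly inside (0, 90) degrees",
                "sed3d_value_error")
  if (circumference_um <= 0)
    sed3d_error("circumference must be > 0", "sed3d_value_error")
  circumference_um / tan(deg2rad(helix_angle_deg))
}

#' Reference layer orientations of oat husk cell walls
#'
#' Published per-layer mean fibril orientations of transversely and
#' longitudinally sectioned oat husk cell walls, measured with this
#' reconstruction technique: in-plane angle, signed out-of-plane angle
#' (alternating signs mark the alternating helical handedness of successive
#' layers), and the handedness implied by the lumen geometry of the mapped
#' region. Useful as worked-example input and as a phantom specification.
#'
#' @param section `"transverse"` (7 layers) or `"longitudinal"` (4 layers).
#' @return data frame with columns `layer`, `in_plane_deg`,
#'   `out_of_plane_deg`, `handedness`.
#' @export
oat_layer_orientations <- function(section = c("transverse", "longitudinal")) {
  section <- match.arg(section)
  if (section == "transverse")
    data.frame(layer = 1:7,
               in_plane_deg = c(33, 47, 27, 43, 36, 45, 27),
               out_of_plane_deg = c(56, -61, 60, -62, 78, -65, 63),
               handedness = c("left", "right", "left", "right", "left",
                              "right", "left"))
  else
    data.frame(layer = 1:4,
               in_plane_deg = c(155, 54, 147, 58),
               out_of_plane_deg = c(-67, -51, -61, -54),
               handedness = c("left", "right", "left", "right"))
}

#' Mean orientation relationship between consecutive layers
#'
#' Converts per-layer (in-plane, out-of-plane) means to unit axes and takes
#' `arccos |a_i . a_j|` for each requested consecutive layer pair, then
#' averages. This is the standard summary of how strongly successive wall
#' layers cross each other.
#'
#' @param layers data frame with columns `in_plane_deg`, `out_of_plane_deg`
#'   (e.g. from [oat_layer_orientations()] or [layer_stats()]).
#' @param pairs list of integer pairs (row indices); default: all
#'   consecutive pairs.
#' @return list with `pairwise_deg` and `mean_deg`.
#' @export
interlayer_relationship <- function(layers, pairs = NULL) {
  n <- nrow(layers)
  if (is.null(pairs)) pairs <- lapply(seq_len(n - 1), function(i) c(i, i + 1))
  axes <- lapply(seq_len(n), function(i)
    axis_from_angles(layers$in_plane_deg[i], layers$out_of_plane_deg[i]))
  pw <- vapply(pairs, function(p)
    orientation_relationship(axes[[p[1]]], axes[[p[2]]]), numeric(1))
  list(pairwise_deg = pw, mean_deg = mean(pw))
}

#' Export layer statistics as CSV
#'
#' @param stats data frame from [layer_stats()].
#' @param csv_path output path.
#' @return invisibly, the path.
#' @export
write_layer_stats <- function(stats, csv_path) {
  utils::write.csv(stats, csv_path, row.names = FALSE)
  invisible(csv_path)
}
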