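# Shared fixtures: analytic test images, small phantoms, angle helpers.

# Sum-of-Gaussians scalar field evaluated at arbitrary coordinates (used to
# build registration fixtures without interpolation artifacts).
gauss_field <- function(x, y, params) {
  out <- 0
  for (p in params)
    out <- out + p$a * exp(-((y - p$cy)^2 + (x - p$cx)^2) / (2 * p$s^2))
  out
}

random_blob_params <- function(n = 12, lim = c(10, 54), seed = 4) {
  set.seed(seed)
  lapply(seq_len(n), function(k)
    list(cx = runif(1, lim[1], lim[2]), cy = runif(1, lim[1], lim[2]),
         s = runif(1, 4, 9), a = runif(1, 0.5, 2)))
}

blob_matrix <- function(shape, params) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  gauss_field(cc, rr, params)
}

# A frame with a single Gaussian spot (plus optional uniform offset).
spot_frame <- function(shape, r0, c0, A = 100, sigma = 1.5, offset = 0) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  offset + A * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma^2))
}

# Frame with a Bragg spot at ring radius and given azimuth (degrees), in the
# package's detector convention (azimuth from +x/cols, row = +y).
ring_spot_frame <- function(shape, radius_px, az_deg, A = 100, sigma = 1.2,
                            pair = FALSE, offset = 0) {
  ctr <- (shape + 1) / 2
  p <- az_deg * pi / 180
  f <- spot_frame(shape, ctr[1] + radius_px * sin(p),
                  ctr[2] + radius_px * cos(p), A, sigma, offset)
  if (pair)
    f <- f + spot_frame(shape, ctr[1] - radius_px * sin(p),
                        ctr[2] - radius_px * cos(p), A, sigma, 0)
  f
}

# Seven-layer annular helical phantom patterned on the transverse oat husk
# layer table.
oat_helical_phantom <- function(shape = c(96L, 96L), step_nm = 220,
                                center_px = NULL) {
  tab <- oat_layer_orientations("transverse")
  layers <- data.frame(r_in_um = seq(3, 9, 1), r_out_um = seq(4, 10, 1),
                       helix_angle_deg = abs(tab$out_of_plane_deg),
                       handedness = tab$handedness)
  make_phantom(layers, "annular", shape = shape, step_nm = step_nm,
               center_px = center_px)
}

three_layer_phantom <- function(shape = c(32L, 32L), step_nm = 200) {
  layers <- data.frame(r_in_um = c(0.6, 1.4, 2.2), r_out_um = c(1.4, 2.2, 3.0),
                       in_plane_deg = c(33, 47, 27),
                       out_of_plane_deg = c(56, -61, 60))
  make_phantom(layers, "annular", shape = shape, step_nm = step_nm)
}

# Angular error (degrees) between sign-ambiguous unit axes.
axis_error_deg <- function(a, b) {
  acos(pmin(1, abs(rowSums(a * b)))) * 180 / pi
}

# Per-pixel axis error between an orientation field and a phantom, on pixels
# valid and non-degenerate in the field and carrying a phantom axis.
field_vs_phantom_err <- function(fld, ph) {
  np <- prod(dim(ph$labels))
  ok <- fld$valid & !fld$degenerate & ph$labels > 0 & !is.na(fld$axes[, , 1])
  idx <- which(ok)
  A <- cbind(fld$axes[idx], fld$axes[idx + np], fld$axes[idx + 2 * np])
  B <- cbind(ph$axes[idx], ph$axes[idx + np], ph$axes[idx + 2 * np])
  axis_error_deg(A, B)
}
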