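#' Acquisition metadata for one tilt of a diffraction scan
#'
#' Bundles the geometry and dose-relevant parameters of a scanning electron
#' diffraction acquisition at a single sample tilt. The tilt axis is the
#' vertical (y, slow-scan) direction of the scan grid; `tilt_deg` is the
#' signed rotation about it.
#'
#' @param tilt_deg signed tilt angle about the vertical axis, degrees
#'   (`|tilt_deg| < 90`).
#' @param step_nm scan step size in nm (> 0).
#' @param recip_pixel_inv_A reciprocal-space detector pixel size,
#'   inverse Angstrom per pixel (> 0).
#' @param camera_shape integer length-2, detector rows x cols.
#' @param beam_current_pA beam current in pA.
#' @param dwell_ms dwell time per scan position in ms.
#' @param beam_diameter_nm beam diameter in nm.
#' @return an object of class `acq_meta`.
#' @export
acq_meta <- function(tilt_deg = 0, step_nm = 100, recip_pixel_inv_A = 0.005,
                     camera_shape = c(128L, 128L), beam_current_pA = 2,
                     dwell_ms = 5, beam_diameter_nm = 8) {
  if (!is.finite(step_nm) || step_nm <= 0)
    sed3d_error("step_nm must be > 0", "sed3d_value_error")
  if (!is.finite(recip_pixel_inv_A) || recip_pixel_inv_A <= 0)
    sed3d_error("recip_pixel_inv_A must be > 0", "sed3d_value_error")
  if (!is.finite(tilt_deg) || abs(tilt_deg) >= 90)
    sed3d_error("|tilt_deg| must be < 90", "sed3d_value_error")
  structure(list(tilt_deg = tilt_deg, step_nm = step_nm,
                 recip_pixel_inv_A = recip_pixel_inv_A,
                 camera_shape = as.integer(camera_shape),
                 beam_current_pA = beam_current_pA, dwell_ms = dwell_ms,
                 beam_diameter_nm = beam_diameter_nm),
            class = "acq_meta")
}

#' 4D diffraction stack for one tilt
#'
#' Holds the raw 4D data cube `(scan_y, scan_x, det_ky, det_kx)` for one tilt
#' angle together with its [acq_meta()] and the per-frame beam-centre
#' coordinates. The scan raster is row-major with x (columns) as the fast
#' axis; the origin is top-left and y increases downward.
#'
#' @param data non-negative 4D array `(scan_y, scan_x, det_ky, det_kx)`.
#' @param meta an [acq_meta()].
#' @param center per-frame beam centre, array `(scan_y, scan_x, 2)` holding
#'   (row, col) detector coordinates; defaults to the geometric centre.
#' @param frame_valid logical matrix marking frames with usable signal;
#'   defaults to all `TRUE`.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(data, meta, center = NULL, frame_valid = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (!identical(as.integer(dim(data)[3:4]), meta$camera_shape))
    sed3d_error("detector dims of data do not match meta$camera_shape",
                "sed3d_format_error")
  if (min(data) < 0) sed3d_error("negative intensities", "sed3d_value_error")
  ny <- dim(data)[1]; nx <- dim(data)[2]
  if (is.null(center)) {
    g <- detector_center(meta$camera_shape)
    center <- array(rep(g, each = ny * nx), dim = c(ny, nx, 2))
  }
  bad <- center[, , 1] < 1 | center[, , 1] > meta$camera_shape[1] |
         center[, , 2] < 1 | center[, , 2] > meta$camera_shape[2]
  if (any(bad))
    sed3d_error("beam centre outside detector bounds", "sed3d_value_error")
  if (is.null(frame_valid)) frame_valid <- matrix(TRUE, ny, nx)
  structure(list(data = data, meta = meta, center = center,
                 frame_valid = frame_valid),
            class = "frame_stack")
}

# Geometric detector centre in 1-based (row, col) pixel coordinates.
detector_center <- function(camera_shape) (camera_shape + 1) / 2

#' A scalar quantity on the scan grid
#'
#' @param values numeric matrix on the scan grid.
#' @param units free-text unit label.
#' @return an object of class `scalar_map`.
#' @export
scalar_map <- function(values, units = "counts") {
  stopifnot(is.matrix(values))
  structure(list(values = values, units = units), class = "scalar_map")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<frame_stack> %d x %d scan, %d x %d detector, tilt %+.1f deg\n",
              d[1], d[2], d[3], d[4], x$meta$tilt_deg))
  invisible(x)
}

#' Reassemble a raw frame stream into a raster-ordered 4D stack
#'
#' At low magnification the scan coils add a small systematic beam tilt that
#' shifts each diffraction pattern on the detector in proportion to the beam
#' position. Given per-frame estimates of that shift, frames recorded as a
#' flat (possibly shuffled) stream are placed back into their 2D raster
#' positions: frames are grouped into rows by the slow-axis shift coordinate
#' and ordered within each row by the fast-axis coordinate.
#'
#' @param frames 3D array `(frame, det_ky, det_kx)` or list of 2D frames.
#' @param scan_shape integer length-2 `(rows, cols)`.
#' @param drift_model data frame or matrix with per-frame shift estimates:
#'   columns `shift_x` (fast axis) and `shift_y` (slow axis), detector pixels.
#' @param meta an [acq_meta()] for the assembled stack.
#' @param tol tolerance (pixels) for non-monotone fast-axis shifts in a row.
#' @return a [frame_stack()]; the inverse permutation (stream index of each
#'   raster position, row-major) is attached as attribute `stream_order`.
#' @export
reassemble_stream <- function(frames, scan_shape, drift_model, meta,
                              tol = 0.25) {
  if (is.list(frames) && !is.array(frames))
    frames <- simplify2array(frames, higher = TRUE) |> aperm(c(3, 1, 2))
  stopifnot(length(dim(frames)) == 3)
  nr <- as.integer(scan_shape[1]); nc <- as.integer(scan_shape[2])
  nf <- dim(frames)[1]
  if (nf != nr * nc)
    sed3d_error(sprintf("got %d frames for a %d x %d grid", nf, nr, nc),
                "sed3d_size_error")
  dm <- as.data.frame(drift_model)
  stopifnot(all(c("shift_x", "shift_y") %in% names(dm)), nrow(dm) == nf)
  # rows: sort by slow-axis shift, chunk into nr groups of nc frames
  by_y <- order(dm$shift_y, dm$shift_x)
  perm <- integer(nf)
  for (r in seq_len(nr)) {
    idx <- by_y[((r - 1) * nc + 1):(r * nc)]
    ord <- idx[order(dm$shift_x[idx])]
    dx <- diff(dm$shift_x[ord])
    if (any(dx < -tol))
      sed3d_error(sprintf("non-monotone fast-axis shift in row %d", r),
                  "sed3d_ordering_error")
    perm[((r - 1) * nc + 1):(r * nc)] <- ord
  }
  dat <- array(0, dim = c(nr, nc, dim(frames)[2], dim(frames)[3]))
  for (i in seq_len(nf)) {
    r <- (i - 1) %/% nc + 1; c_ <- (i - 1) %% nc + 1
    dat[r, c_, , ] <- frames[perm[i], , ]
  }
  st <- frame_stack(dat, meta)
  attr(st, "stream_order") <- perm
  st
}

# Shift a 2D image by (dy, dx) with bilinear interpolation, zero padding.
shift_bilinear <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  r <- seq_len(nr) - dy; c_ <- seq_len(nc) - dx
  r0 <- floor(r); c0 <- floor(c_)
  fr <- r - r0; fc <- c_ - c0
  at <- function(ri, ci) {
    ok_r <- ri >= 1 & ri <= nr; ok_c <- ci >= 1 & ci <= nc
    out <- matrix(0, nr, nc)
    out[ok_r, ok_c] <- img[ri[ok_r], ci[ok_c]]
    out
  }
  wr <- matrix(fr, nr, nc); wc <- matrix(fc, nr, nc, byrow = TRUE)
  at(r0, c0) * (1 - wr) * (1 - wc) + at(r0 + 1, c0) * wr * (1 - wc) +
    at(r0, c0 + 1) * (1 - wr) * wc + at(r0 + 1, c0 + 1) * wr * wc
}

# Centre of mass of img restricted to a disk of radius `radius` around the
# geometric centre; returns c(row, col) or NULL if the window is empty.
com_in_window <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  ctr <- detector_center(c(nr, nc))
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  w <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= radius^2
  tot <- sum(img[w])
  if (tot <= 0) return(NULL)
  c(sum((img * w) * rr) / tot, sum((img * w) * cc) / tot)
}

#' Centre the direct beam of every diffraction pattern
#'
#' Applies a centre-of-mass beam-shift correction: each pattern is translated
#' (sub-pixel, bilinear interpolation) so that the centre of mass of the
#' intensity inside a disk of radius `window_radius` around the geometric
#' detector centre coincides with that centre. Frames whose window holds no
#' intensity are flagged invalid and left unshifted.
#'
#' @param stack a [frame_stack()].
#' @param window_radius disk radius in detector pixels; must be smaller than
#'   half the detector extent.
#' @return the centred [frame_stack()] with updated `center` and
#'   `frame_valid`.
#' @export
center_patterns <- function(stack, window_radius = 10) {
  ks <- stack$meta$camera_shape
  if (window_radius >= min(ks) / 2)
    sed3d_error("window_radius must be < half the detector extent",
                "sed3d_value_error")
  ny <- dim(stack$data)[1]; nx <- dim(stack$data)[2]
  ctr <- detector_center(ks)
  for (r in seq_len(ny)) for (c_ in seq_len(nx)) {
    img <- stack$data[r, c_, , ]
    com <- com_in_window(img, window_radius)
    if (is.null(com)) {
      stack$frame_valid[r, c_] <- FALSE
      next
    }
    dy <- ctr[1] - com[1]; dx <- ctr[2] - com[2]
    if (abs(dy) > 1e-12 || abs(dx) > 1e-12)
      stack$data[r, c_, , ] <- shift_bilinear(img, dy, dx)
    stack$center[r, c_, ] <- ctr
  }
  stack
}

#' Virtual-detector image
#'
#' Integrates intensity inside a software-defined detector region for every
#' scan position, yielding a real-space image (standard virtual imaging used
#' here for registration and QC).
#'
#' @param stack a [frame_stack()].
#' @param region either a logical detector mask (rows x cols) or a list
#'   `list(r_inner_inv_A=, r_outer_inv_A=)` describing an annulus around the
#'   detector centre in reciprocal units.
#' @return a [scalar_map()] of summed counts.
#' @export
virtual_image <- function(stack, region = NULL) {
  ks <- stack$meta$camera_shape
  if (is.null(region)) region <- matrix(TRUE, ks[1], ks[2])
  if (is.list(region) && !is.matrix(region)) {
    ctr <- detector_center(ks)
    rr <- matrix(seq_len(ks[1]), ks[1], ks[2])
    cc <- matrix(seq_len(ks[2]), ks[1], ks[2], byrow = TRUE)
    rad_px <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) *
      stack$meta$recip_pixel_inv_A
    region <- rad_px >= region$r_inner_inv_A & rad_px <= region$r_outer_inv_A
  }
  stopifnot(is.matrix(region), identical(dim(region), as.integer(ks)))
  if (!any(region)) sed3d_error("empty detector region", "sed3d_value_error")
  ny <- dim(stack$data)[1]; nx <- dim(stack$data)[2]
  idx <- which(as.vector(region))
  vals <- matrix(0, ny, nx)
  for (c_ in seq_len(nx)) {      # per scan column, avoids stack duplication
    blk <- stack$data[, c_, , , drop = FALSE]
    dim(blk) <- c(ny, prod(ks))
    vals[, c_] <- rowSums(blk[, idx, drop = FALSE])
  }
  scalar_map(vals, units = "counts")
}

#' Electron dose delivered per scan position
#'
#' Computes the fluence `(current x dwell / e) / (pi (d/2)^2)` treating the
#' beam as a uniform disk of the stated diameter. Note that defining the beam
#' area by a narrower width measure (e.g. FWHM of a non-uniform profile)
#' yields proportionally smaller areas and larger doses; the full-diameter
#' disk is used here.
#'
#' @param meta an [acq_meta()].
#' @return dose in electrons per square Angstrom.
#' @export
estimate_dose <- function(meta) {
  with(meta, {
    if (!all(is.finite(c(beam_current_pA, dwell_ms, beam_diameter_nm))) ||
        beam_current_pA <= 0 || dwell_ms <= 0 || beam_diameter_nm <= 0)
      sed3d_error("beam current, dwell and diameter must be > 0",
                  "sed3d_value_error")
    electrons <- beam_current_pA * 1e-12 * dwell_ms * 1e-3 / 1.602176634e-19
    area_A2 <- pi * (beam_diameter_nm * 10 / 2)^2
    electrons / area_A2
  })
}

#' Export a scalar map as 32-bit TIFF and/or CSV
#'
#' @param map a [scalar_map()].
#' @param tiff_path,csv_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_scalar_map <- function(map, tiff_path = NULL, csv_path = NULL) {
  if (!is.null(tiff_path)) {
    v <- map$values
    rng <- range(v, finite = TRUE)
    tiff::writeTIFF(if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0,
                    tiff_path, bits.per.sample = 32L)
  }
  if (!is.null(csv_path))
    utils::write.csv(map$values, csv_path, row.names = FALSE)
  invisible(c(tiff_path, csv_path))
}
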