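#' Configuration of the (200)-ring virtual detectors
#'
#' Defines the ring of square virtual detectors used to reduce each
#' diffraction pattern to an azimuthal intensity profile. The default radius
#' corresponds to the cellulose I-beta (200) reflection (d200 ~ 3.88 A,
#' |g| ~ 0.258 1/A); the diffraction vector of that reflection is normal to
#' the fibril long axis, so the in-plane fibril direction is perpendicular to
#' the Bragg azimuth.
#'
#' @param radius_inv_A ring radius, inverse Angstrom.
#' @param box_inv_A side of each square virtual detector, inverse Angstrom.
#' @param n_detectors number of detectors around the full ring (even).
#' @param quality_threshold default validity threshold on the first-harmonic
#'   to DC Fourier ratio of the folded profile. The default was calibrated on
#'   the synthetic render model so that pure-noise frames pass at a rate of
#'   at most 5 percent.
#' @return an object of class `ring_config`.
#' @export
ring_config <- function(radius_inv_A = 0.258, box_inv_A = 0.04,
                        n_detectors = 360L, quality_threshold = 0.10) {
  if (radius_inv_A <= 0 || box_inv_A <= 0)
    sed3d_error("radius and box must be > 0", "sed3d_value_error")
  if (n_detectors %% 2 != 0)
    sed3d_error("n_detectors must be even", "sed3d_value_error")
  structure(list(radius_inv_A = radius_inv_A, box_inv_A = box_inv_A,
                 n_detectors = as.integer(n_detectors),
                 quality_threshold = quality_threshold),
            class = "ring_config")
}

# Sparse (n_detectors x n_pixels) matrix averaging detector-pixel intensities
# into ring bins. Detector k (k = 0 .. n-1) is a square box of side
# box_inv_A centred at radius radius_inv_A and azimuth k * (360/n) degrees;
# azimuth 0 along +x (columns), increasing counter-clockwise; pixels count by
# centre-in-box. Pixel order matches as.vector() of a (ky, kx) matrix.
ring_mapping <- function(cfg, camera_shape, recip_pixel_inv_A) {
  nky <- camera_shape[1]; nkx <- camera_shape[2]
  ctr <- detector_center(camera_shape)
  r_px <- cfg$radius_inv_A / recip_pixel_inv_A
  half <- cfg$box_inv_A / recip_pixel_inv_A / 2
  if (ctr[1] - r_px - half < 1 || ctr[1] + r_px + half > nky ||
      ctr[2] - r_px - half < 1 || ctr[2] + r_px + half > nkx)
    sed3d_error("virtual-detector ring does not fit on the detector",
                "sed3d_geometry_error")
  n <- cfg$n_detectors
  az <- (seq_len(n) - 1) * (360 / n) * pi / 180
  bx <- ctr[2] + r_px * cos(az)   # box centre, column coordinate
  by <- ctr[1] + r_px * sin(az)   # box centre, row coordinate
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  span <- ceiling(half)
  for (k in seq_len(n)) {
    rs <- max(1, floor(by[k] - span)):min(nky, ceiling(by[k] + span))
    cs <- max(1, floor(bx[k] - span)):min(nkx, ceiling(bx[k] + span))
    rr <- rep(rs, times = length(cs)); cc <- rep(cs, each = length(rs))
    inbox <- abs(rr - by[k]) <= half & abs(cc - bx[k]) <= half
    idx <- (cc[inbox] - 1L) * nky + rr[inbox]
    if (length(idx) == 0) next
    ii <- c(ii, rep.int(k, length(idx)))
    jj <- c(jj, idx)
    xx <- c(xx, rep.int(1 / length(idx), length(idx)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, nky * nkx))
}

#' Azimuthal intensity profile of one diffraction pattern
#'
#' Places `n_detectors` square virtual detectors in a ring around the direct
#' beam at the (200) radius and records the mean intensity in each, as a
#' function of azimuth. Friedel pairs make the profile 180-degree periodic,
#' so the two half-turns are folded (averaged) into a 180-bin curve, and a
#' Fourier quality ratio is attached.
#'
#' @param pattern centred 2D diffraction pattern (rows = ky, cols = kx).
#' @param cfg a [ring_config()].
#' @param recip_pixel_inv_A reciprocal pixel size, inverse Angstrom.
#' @return an `azimuthal_profile`: list with `raw` (full ring), `folded`
#'   (half ring), `quality`.
#' @export
ring_profile <- function(pattern, cfg = ring_config(), recip_pixel_inv_A) {
  M <- ring_mapping(cfg, dim(pattern), recip_pixel_inv_A)
  raw <- as.numeric(M %*% as.vector(pattern))
  folded <- fold_profile(raw)
  structure(list(raw = raw, folded = folded, quality = quality_ratio(folded)),
            class = "azimuthal_profile")
}

# Average antipodal bins: folded[i] = (raw[i] + raw[i + n/2]) / 2.
fold_profile <- function(raw) {
  n <- length(raw)
  (raw[seq_len(n / 2)] + raw[seq_len(n / 2) + n / 2]) / 2
}

#' Fourier quality ratio of a folded azimuthal curve
#'
#' Ratio of the first frequency bin to the DC component of the discrete
#' Fourier transform of the folded profile. A single well-defined Bragg peak
#' concentrates power in the first harmonic (one period over the half-turn),
#' so a higher ratio indicates a more defined peak; flat or pure-noise
#' curves score near zero.
#'
#' @param folded folded (half-ring) intensity curve, non-negative.
#' @return dimensionless ratio `|F1|/|F0|` (0 for an all-zero curve, with
#'   attribute `valid = FALSE`).
#' @export
quality_ratio <- function(folded) {
  if (any(folded < 0)) sed3d_error("negative intensities", "sed3d_value_error")
  f0 <- sum(folded)
  if (f0 <= 0) return(structure(0, valid = FALSE))
  k <- seq_along(folded) - 1
  f1 <- sum(folded * exp(-2i * pi * k / length(folded)))
  Mod(f1) / f0
}

#' Azimuth of the Bragg peak in a folded profile
#'
#' Position of the global maximum, refined to sub-bin precision by a
#' circular three-point parabolic fit (refinement can be disabled). Ties are
#' broken toward the lowest bin index.
#'
#' @param folded folded intensity curve (bin i = azimuth `(i-1) * 180/n`).
#' @param refine logical; apply parabolic sub-bin refinement.
#' @return azimuth in degrees, in `[0, 180)`.
#' @export
peak_azimuth <- function(folded, refine = TRUE) {
  n <- length(folded)
  if (diff(range(folded)) == 0)
    sed3d_error("flat profile has no defined peak", "sed3d_peak_error")
  i0 <- which.max(folded)           # which.max takes the first (lowest) tie
  step <- 180 / n
  if (!refine) return(mod180((i0 - 1) * step))
  yl <- folded[(i0 - 2) %% n + 1]
  y0 <- folded[i0]
  yr <- folded[i0 %% n + 1]
  den <- yl - 2 * y0 + yr
  delta <- if (abs(den) < .Machine$double.eps) 0 else 0.5 * (yl - yr) / den
  delta <- max(-0.5, min(0.5, delta))
  mod180((i0 - 1 + delta) * step)
}

#' Azimuth map for one tilt
#'
#' Container for the per-scan-pixel Bragg azimuth (mod 180 degrees), its
#' Fourier quality score and the validity mask, tagged with the source tilt.
#'
#' @param phi_deg matrix of peak azimuths in degrees (`NA` where invalid).
#' @param quality matrix of quality ratios.
#' @param valid logical matrix.
#' @param tilt_deg source tilt angle.
#' @return an object of class `azimuth_map`.
#' @export
azimuth_map_obj <- function(phi_deg, quality, valid, tilt_deg) {
  stopifnot(identical(dim(phi_deg), dim(quality)),
            identical(dim(phi_deg), dim(valid)))
  phi_deg[!valid] <- NA_real_
  structure(list(phi_deg = phi_deg, quality = quality, valid = valid,
                 tilt_deg = tilt_deg), class = "azimuth_map")
}

#' Extract the Bragg azimuth at every scan position
#'
#' Reduces a centred diffraction stack to an [azimuth_map_obj()]: each
#' pattern's ring profile is folded, scored, and its peak azimuth extracted.
#' Pixels whose quality ratio falls below the threshold (or whose ring holds
#' no intensity, or whose frame was flagged invalid upstream) are marked
#' invalid; per-pixel geometry failures never abort the whole map.
#'
#' @param stack a centred [frame_stack()].
#' @param cfg a [ring_config()].
#' @param quality_threshold validity threshold; defaults to the value stored
#'   in `cfg`.
#' @param refine sub-bin peak refinement (see [peak_azimuth()]).
#' @return an `azimuth_map`.
#' @export
azimuth_map <- function(stack, cfg = ring_config(),
                        quality_threshold = cfg$quality_threshold,
                        refine = TRUE) {
  ny <- dim(stack$data)[1]; nx <- dim(stack$data)[2]
  ks <- stack$meta$camera_shape
  M <- ring_mapping(cfg, ks, stack$meta$recip_pixel_inv_A)
  # frames as columns, scan order column-major in (y, x); processed one scan
  # column at a time so large stacks are never duplicated in memory
  prof <- matrix(0, cfg$n_detectors, ny * nx)    # n_detectors x n_frames
  for (c_ in seq_len(nx)) {
    blk <- stack$data[, c_, , , drop = FALSE]    # ny x 1 x ky x kx
    dim(blk) <- c(ny, prod(ks))
    prof[, (c_ - 1) * ny + seq_len(ny)] <- as.matrix(M %*% t(blk))
  }
  nb <- cfg$n_detectors / 2
  folded <- (prof[seq_len(nb), , drop = FALSE] +
             prof[seq_len(nb) + nb, , drop = FALSE]) / 2
  f0 <- colSums(folded)
  k <- seq_len(nb) - 1
  w <- exp(-2i * pi * k / nb)
  f1 <- Mod(as.vector(crossprod(folded, w)))
  quality <- ifelse(f0 > 0, f1 / pmax(f0, .Machine$double.xmin), 0)
  valid <- f0 > 0 & quality >= quality_threshold & as.vector(stack$frame_valid)
  phi <- rep(NA_real_, ny * nx)
  step <- 180 / nb
  idx <- which(valid)
  if (length(idx)) {
    i0 <- max.col(t(folded[, idx, drop = FALSE]), ties.method = "first")
    if (refine) {
      get_bin <- function(off) folded[cbind((i0 - 1 + off) %% nb + 1, idx)]
      yl <- get_bin(-1); y0 <- get_bin(0); yr <- get_bin(1)
      den <- yl - 2 * y0 + yr
      delta <- ifelse(abs(den) < .Machine$double.eps, 0,
                      pmax(-0.5, pmin(0.5, 0.5 * (yl - yr) / den)))
      phi[idx] <- mod180((i0 - 1 + delta) * step)
    } else phi[idx] <- mod180((i0 - 1) * step)
    # flat-profile frames have no defined peak
    flat_prof <- apply(folded[, idx, drop = FALSE], 2,
                       function(v) diff(range(v)) == 0)
    if (any(flat_prof)) {
      valid[idx[flat_prof]] <- FALSE
      phi[idx[flat_prof]] <- NA_real_
    }
  }
  azimuth_map_obj(matrix(phi, ny, nx), matrix(quality, ny, nx),
                  matrix(valid, ny, nx), stack$meta$tilt_deg)
}

#' Export an azimuth map to CSV (and optionally TIFF images)
#'
#' @param amap an `azimuth_map`.
#' @param csv_path CSV output with columns row, col, phi_deg, quality, valid.
#' @param phi_tiff,quality_tiff optional TIFF paths.
#' @return invisibly, the CSV path.
#' @export
write_azimuth_map <- function(amap, csv_path, phi_tiff = NULL,
                              quality_tiff = NULL) {
  d <- dim(amap$phi_deg)
  df <- data.frame(row = rep(seq_len(d[1]), d[2]),
                   col = rep(seq_len(d[2]), each = d[1]),
                   phi_deg = as.vector(amap$phi_deg),
                   quality = as.vector(amap$quality),
                   valid = as.vector(amap$valid))
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(phi_tiff)) {
    v <- amap$phi_deg / 180; v[is.na(v)] <- 0
    tiff::writeTIFF(v, phi_tiff, bits.per.sample = 32L)
  }
  if (!is.null(quality_tiff)) {
    q <- amap$quality / max(amap$quality, 1e-12)
    tiff::writeTIFF(pmin(q, 1), quality_tiff, bits.per.sample = 32L)
  }
  invisible(csv_path)
}
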