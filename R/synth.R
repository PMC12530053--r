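# Ground-truth phantoms and the diffraction forward model. These emulate the
# study conditions of the real acquisitions: multilayered helical cell-wall
# textures with alternating handedness, a single vertical tilt axis at
# 0 / +45 / -45 degrees, circular azimuthal noise, and signal-free
# lumen / resin / middle-lamella regions.

#' Noise specification for the forward model
#'
#' @param azimuth_sigma_deg sd of wrapped-Gaussian noise on Bragg azimuths.
#' @param background_level mean Poisson background, counts per detector
#'   pixel.
#' @param peak_snr Bragg-peak amplitude over the background Poisson noise sd
#'   (amplitude = `peak_snr * sqrt(background_level)`; the amplitude itself
#'   when the background is zero).
#' @param seed RNG seed, recorded in all outputs.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(azimuth_sigma_deg = 3, background_level = 1,
                       peak_snr = 30, seed = 1L) {
  if (azimuth_sigma_deg < 0)
    sed3d_error("sigma must be >= 0", "sed3d_value_error")
  structure(list(azimuth_sigma_deg = azimuth_sigma_deg,
                 background_level = background_level, peak_snr = peak_snr,
                 seed = seed), class = "noise_spec")
}

#' Build a ground-truth fibril-axis phantom
#'
#' Two geometries emulating the sectioning directions of real cell walls:
#' `"annular"` places concentric layers around a lumen (transverse section);
#' each layer is either a helical winding - axis
#' `cos(a) z + h sin(a) t(psi)` from a `helix_angle_deg` and `handedness`
#' column, with `t` the local hoop tangent, so the axis rotates around the
#' ring and passes through the degenerate zero-y directions at the top and
#' bottom - or a constant axis from `in_plane_deg`/`out_of_plane_deg`.
#' `"bands"` stacks horizontal bands of constant axis (longitudinal
#' section). Pixels inside the lumen or beyond the outermost layer carry no
#' axis and label 0 (no signal).
#'
#' @param layers data frame; for `"annular"`, columns `r_in_um`, `r_out_um`
#'   plus either (`helix_angle_deg`, `handedness`) or (`in_plane_deg`,
#'   `out_of_plane_deg`); for `"bands"`, columns `y_in_um`, `y_out_um`,
#'   `in_plane_deg`, `out_of_plane_deg`.
#' @param geometry `"annular"` or `"bands"`.
#' @param shape scan grid (rows, cols).
#' @param step_nm scan step in nm.
#' @param center_px lumen centre (row, col) for annular geometry; defaults
#'   to the grid centre.
#' @return an object of class `phantom`: `axes` (ny, nx, 3), `labels`,
#'   `step_nm`, `layers`, `geometry`.
#' @export
make_phantom <- function(layers, geometry = c("annular", "bands"),
                         shape = c(128L, 128L), step_nm = 100,
                         center_px = NULL) {
  geometry <- match.arg(geometry)
  ny <- shape[1]; nx <- shape[2]
  axes <- array(NA_real_, c(ny, nx, 3))
  labels <- matrix(0L, ny, nx)
  rngcol <- if (geometry == "annular") c("r_in_um", "r_out_um")
            else c("y_in_um", "y_out_um")
  iv <- layers[, rngcol]
  if (any(iv[, 2] <= iv[, 1]))
    sed3d_error("layer extents must have positive width", "sed3d_spec_error")
  o <- order(iv[, 1])
  if (any(iv[o[-1], 1] < iv[o[-nrow(iv)], 2] - 1e-9))
    sed3d_error("layers overlap", "sed3d_spec_error")
  helical <- "helix_angle_deg" %in% names(layers)
  rr <- matrix(seq_len(ny), ny, nx)
  cc <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  if (geometry == "annular") {
    if (is.null(center_px)) center_px <- (shape + 1) / 2
    dx <- (cc - center_px[2]) * step_nm / 1000
    dy <- (rr - center_px[1]) * step_nm / 1000
    rad <- sqrt(dx^2 + dy^2)
    psi <- atan2(dy, dx)
    for (i in seq_len(nrow(layers))) {
      sel <- rad >= layers$r_in_um[i] & rad < layers$r_out_um[i]
      if (!any(sel)) next
      labels[sel] <- i
      if (helical) {
        alpha <- deg2rad(layers$helix_angle_deg[i])
        h <- if (layers$handedness[i] == "right") 1 else -1
        # hoop tangent t = z x radial_out; snap numerical dust so the
        # analytically-zero y component at the top/bottom of the ring is
        # exactly zero (these are the degenerate directions)
        tx <- -sin(psi[sel]); ty <- cos(psi[sel])
        tx[abs(tx) < 1e-12] <- 0; ty[abs(ty) < 1e-12] <- 0
        ax <- h * sin(alpha) * tx
        ay <- h * sin(alpha) * ty
        az <- rep(cos(alpha), sum(sel))
      } else {
        a <- axis_from_angles(layers$in_plane_deg[i],
                              layers$out_of_plane_deg[i])
        ax <- rep(a[1], sum(sel)); ay <- rep(a[2], sum(sel))
        az <- rep(a[3], sum(sel))
      }
      # hemisphere restriction (helical tangents can point anywhere)
      flip <- az < 0 | (az == 0 & ay < 0)
      ax[flip] <- -ax[flip]; ay[flip] <- -ay[flip]; az[flip] <- -az[flip]
      np <- ny * nx
      idx <- which(sel)
      axes[idx] <- ax; axes[idx + np] <- ay; axes[idx + 2 * np] <- az
    }
  } else {
    yy <- (rr - 0.5) * step_nm / 1000
    for (i in seq_len(nrow(layers))) {
      sel <- yy >= layers$y_in_um[i] & yy < layers$y_out_um[i]
      if (!any(sel)) next
      labels[sel] <- i
      a <- axis_from_angles(layers$in_plane_deg[i], layers$out_of_plane_deg[i])
      np <- ny * nx
      idx <- which(sel)
      axes[idx] <- a[1]; axes[idx + np] <- a[2]; axes[idx + 2 * np] <- a[3]
    }
  }
  structure(list(axes = axes, labels = labels, step_nm = step_nm,
                 layers = layers, geometry = geometry),
            class = "phantom")
}

#' Bragg azimuth produced by a fibril axis at a given tilt
#'
#' The forward model of one measurement: rotate the axis into the tilted
#' frame, `a' = Ry(omega) a`; the (200) diffraction vector lies normal to
#' the fibril, so the observed peak azimuth is the in-plane direction
#' orthogonal to the projection of `a'`, `phi = atan2(-a'_x, a'_y) mod 180`.
#' An axis parallel to the beam at this tilt excites the whole ring
#' uniformly and yields no defined azimuth (`NA`).
#'
#' @param a_hat unit 3-vector.
#' @param omega_deg tilt in degrees.
#' @return azimuth in degrees in `[0, 180)`, or `NA` if degenerate
#'   (full ring).
#' @export
forward_azimuth <- function(a_hat, omega_deg) {
  w <- deg2rad(omega_deg)
  apx <- cos(w) * a_hat[1] + sin(w) * a_hat[3]
  apy <- a_hat[2]
  if (apx^2 + apy^2 < 1e-16) return(NA_real_)
  if (apy == 0) return(90)   # zero-y axes project to 90 deg at every tilt
  mod180(rad2deg(atan2(-apx, apy)))
}

# Vectorized forward azimuth over component vectors.
forward_azimuth_vec <- function(ax, ay, az, omega_deg) {
  w <- deg2rad(omega_deg)
  apx <- cos(w) * ax + sin(w) * az
  apy <- ay
  phi <- mod180(rad2deg(atan2(-apx, apy)))
  phi[which(apy == 0)] <- 90
  phi[which(apx^2 + apy^2 < 1e-16)] <- NA_real_
  phi
}

# Sample positions seen by the tilted scan grid, in zero-tilt pixel
# coordinates (foreshortening about the grid centre), nearest phantom pixel.
tilted_lookup <- function(shape, omega_deg) {
  ny <- shape[1]; nx <- shape[2]
  cx <- (nx + 1) / 2
  cols <- round((seq_len(nx) - cx) / cos(deg2rad(omega_deg)) + cx)
  list(rows = seq_len(ny), cols = cols,
       in_field = cols >= 1 & cols <= nx)
}

#' Simulate per-tilt azimuth maps from a phantom
#'
#' The azimuth-level forward model (no detector rendering): for each tilt
#' the scan grid samples the foreshortened phantom, every signal pixel
#' yields its forward azimuth plus wrapped-Gaussian noise, and no-signal or
#' full-ring-degenerate pixels are invalid. Deterministic for a fixed seed,
#' which is recorded in the output.
#'
#' @param phantom a [make_phantom()] phantom.
#' @param tilts distinct tilt angles in degrees (must include the intended
#'   reference tilt 0 for downstream alignment).
#' @param noise a [noise_spec()]; only `azimuth_sigma_deg` and `seed` are
#'   used here.
#' @param foreshorten sample each tilted map on its foreshortened grid
#'   (nearest-neighbour), as the instrument does; with `FALSE` all maps are
#'   generated directly on the common zero-tilt grid, isolating the
#'   reconstruction from resampling effects (the mode used for solver
#'   fidelity studies).
#' @return list of `azimuth_map`s (one per tilt), with attribute `seed`.
#' @export
simulate_azimuth_maps <- function(phantom, tilts = c(0, 45, -45),
                                  noise = noise_spec(), foreshorten = TRUE) {
  if (anyDuplicated(tilts))
    sed3d_error("tilts must be distinct", "sed3d_value_error")
  if (!is.null(noise$seed)) set.seed(noise$seed)
  d <- dim(phantom$labels)
  np <- prod(d)
  maps <- lapply(tilts, function(w) {
    lk <- tilted_lookup(d, if (foreshorten) w else 0)
    colmap <- ifelse(lk$in_field, lk$cols, NA_integer_)
    src <- outer(seq_len(d[1]), colmap, function(r, c_) (c_ - 1L) * d[1] + r)
    ax <- phantom$axes[src]; ay <- phantom$axes[src + np]
    az <- phantom$axes[src + 2 * np]
    phi <- forward_azimuth_vec(ax, ay, az, w)
    valid <- !is.na(phi)
    if (noise$azimuth_sigma_deg > 0)
      phi[valid] <- mod180(phi[valid] +
        stats::rnorm(sum(valid), 0, noise$azimuth_sigma_deg))
    azimuth_map_obj(matrix(phi, d[1], d[2]),
                    matrix(as.numeric(valid), d[1], d[2]),
                    matrix(valid, d[1], d[2]), w)
  })
  attr(maps, "seed") <- noise$seed
  maps
}

# Gaussian patch helper: expected counts of a spot of amplitude A and width
# sigma centred at (r0, c0), evaluated on integer pixels within +-span.
add_poisson_spot <- function(frame, r0, c0, A, sigma, span = 5L) {
  nr <- nrow(frame); nc <- ncol(frame)
  rs <- max(1L, floor(r0 - span)):min(nr, ceiling(r0 + span))
  cs <- max(1L, floor(c0 - span)):min(nc, ceiling(c0 + span))
  if (length(rs) == 0 || length(cs) == 0) return(frame)
  lam <- A * exp(-(outer((rs - r0)^2, (cs - c0)^2, "+")) / (2 * sigma^2))
  frame[rs, cs] <- frame[rs, cs] + stats::rpois(length(lam), lam)
  frame
}

#' Render synthetic diffraction patterns for one tilt
#'
#' The full detector-level forward model: every signal pixel produces a
#' centred pattern with a direct beam, Poisson background, and a Friedel
#' pair of Gaussian Bragg spots on the (200) ring at the (noisy) forward
#' azimuth; full-ring-degenerate pixels get a uniform ring instead. Only the
#' (200) pair is rendered - it is the only reflection the analysis uses.
#'
#' @param phantom a [make_phantom()] phantom.
#' @param omega_deg tilt angle.
#' @param cfg a [ring_config()].
#' @param detector list with `shape` (rows, cols) and `recip_pixel_inv_A`.
#' @param noise a [noise_spec()].
#' @param spot_sigma_px Gaussian spot width on the detector, pixels.
#' @return a [frame_stack()] (patterns already centred by construction).
#' @export
render_patterns <- function(phantom, omega_deg, cfg = ring_config(),
                            detector = list(shape = c(128L, 128L),
                                            recip_pixel_inv_A = 0.005),
                            noise = noise_spec(), spot_sigma_px = 1.2) {
  ks <- as.integer(detector$shape)
  rp <- detector$recip_pixel_inv_A
  r_px <- cfg$radius_inv_A / rp
  half_box <- cfg$box_inv_A / rp / 2
  if (r_px + half_box + spot_sigma_px >= min(ks) / 2)
    sed3d_error("ring does not fit on the detector", "sed3d_geometry_error")
  if (!is.null(noise$seed)) set.seed(noise$seed + round(omega_deg))
  d <- dim(phantom$labels)
  np <- prod(d)
  lk <- tilted_lookup(d, omega_deg)
  colmap <- ifelse(lk$in_field, lk$cols, NA_integer_)
  src <- outer(seq_len(d[1]), colmap, function(r, c_) (c_ - 1L) * d[1] + r)
  axm <- phantom$axes[src]; aym <- phantom$axes[src + np]
  azm <- phantom$axes[src + 2 * np]
  phi <- matrix(forward_azimuth_vec(axm, aym, azm, omega_deg), d[1], d[2])
  has_axis <- !is.na(src) & !is.na(axm)
  ring_degen <- matrix(has_axis & is.na(phi), d[1], d[2])
  if (noise$azimuth_sigma_deg > 0) {
    ok <- !is.na(phi)
    phi[ok] <- mod180(phi[ok] + stats::rnorm(sum(ok), 0,
                                             noise$azimuth_sigma_deg))
  }
  A <- if (noise$background_level > 0)
    noise$peak_snr * sqrt(noise$background_level) else noise$peak_snr
  ctr <- detector_center(ks)
  npx <- prod(ks)
  bg <- noise$background_level
  # allocate once in the final (scan_y, scan_x, ky, kx) layout; frames are
  # drawn one at a time to keep the peak footprint at a single copy
  data <- numeric(np * npx)
  dim(data) <- c(d[1], d[2], ks[1], ks[2])
  # uniform-ring template for degenerate pixels
  rr <- matrix(seq_len(ks[1]), ks[1], ks[2])
  cc <- matrix(seq_len(ks[2]), ks[1], ks[2], byrow = TRUE)
  radm <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
  ring_mask <- abs(radm - r_px) <= 1.5 * spot_sigma_px
  lam_ring <- 2 * A * 2 * pi * spot_sigma_px^2 / max(sum(ring_mask), 1)
  beam_A <- 50 * max(A, 1)
  for (r in seq_len(d[1])) for (c_ in seq_len(d[2])) {
    fr <- if (bg > 0) matrix(as.double(stats::rpois(npx, bg)), ks[1], ks[2])
          else matrix(0, ks[1], ks[2])
    fr <- add_poisson_spot(fr, ctr[1], ctr[2], beam_A, 1.5)
    if (!is.na(phi[r, c_])) {
      p <- deg2rad(phi[r, c_])
      fr <- add_poisson_spot(fr, ctr[1] + r_px * sin(p),
                             ctr[2] + r_px * cos(p), A, spot_sigma_px)
      fr <- add_poisson_spot(fr, ctr[1] - r_px * sin(p),
                             ctr[2] - r_px * cos(p), A, spot_sigma_px)
    } else if (ring_degen[r, c_]) {
      fr[ring_mask] <- fr[ring_mask] + stats::rpois(sum(ring_mask), lam_ring)
    }
    data[r, c_, , ] <- fr
  }
  meta <- acq_meta(tilt_deg = omega_deg, step_nm = phantom$step_nm,
                   recip_pixel_inv_A = rp, camera_shape = ks)
  frame_stack(data, meta)
}
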