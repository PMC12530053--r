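# Per-pixel 3D fibril-axis reconstruction. Each tilt contributes a measured
# Bragg azimuth phi; q' = [cos phi, sin phi, 0] lies on the circle orthogonal
# to the fibril axis in the tilted frame and is back-rotated to zero-tilt
# coordinates by q = Ry(-omega) q'. The fibril axis a is the direction
# best-orthogonal to all q_i, found exactly by a cross product for two
# measurements and by iterative averaged projections otherwise.

#' In-plane q-vector from a Bragg azimuth
#'
#' @param phi_deg azimuth in degrees.
#' @return unit 3-vector `[cos phi, sin phi, 0]`.
#' @export
qvec_from_azimuth <- function(phi_deg) {
  p <- deg2rad(phi_deg)
  c(cos(p), sin(p), 0)
}

# Rotation about the y (tilt) axis by omega degrees.
rot_y <- function(omega_deg) {
  w <- deg2rad(omega_deg)
  matrix(c(cos(w), 0, -sin(w),
           0, 1, 0,
           sin(w), 0, cos(w)), 3, 3)
}

#' Back-rotate a tilted-frame q-vector to zero-tilt sample coordinates
#'
#' @param q_prime unit 3-vector measured in the tilted frame.
#' @param omega_deg source tilt in degrees.
#' @return `Ry(-omega) q_prime`.
#' @export
back_rotate <- function(q_prime, omega_deg) {
  as.numeric(rot_y(-omega_deg) %*% q_prime)
}

# Flip a unit vector into the positive-z hemisphere (the axis sign is
# arbitrary); ties broken toward positive y, then positive x.
hemisphere <- function(a) {
  if (a[3] < 0 || (a[3] == 0 && (a[2] < 0 || (a[2] == 0 && a[1] < 0)))) -a
  else a
}

axis_estimate <- function(a_hat, residual, n, degenerate = FALSE,
                          iterations = 0L) {
  structure(list(a_hat = a_hat, residual = residual,
                 n_measurements = as.integer(n), degenerate = degenerate,
                 iterations = as.integer(iterations)),
            class = "axis_estimate")
}

#' Exact fibril axis from two q-measurements
#'
#' Two independent q-vectors determine the axis exactly as their normalized
#' cross product. Nearly (anti)parallel measurements leave the axis
#' under-determined and are flagged degenerate.
#'
#' @param q1,q2 unit 3-vectors.
#' @param tol degeneracy tolerance on the cross-product norm.
#' @return an `axis_estimate`.
#' @export
axis_from_two <- function(q1, q2, tol = 1e-8) {
  cp <- c(q1[2] * q2[3] - q1[3] * q2[2],
          q1[3] * q2[1] - q1[1] * q2[3],
          q1[1] * q2[2] - q1[2] * q2[1])
  nrm <- sqrt(sum(cp^2))
  if (nrm < tol)
    return(axis_estimate(c(NA_real_, NA_real_, NA_real_), NA_real_, 2,
                         degenerate = TRUE))
  axis_estimate(hemisphere(cp / nrm), 0, 2)
}

# Scatter matrix S = (1/N) sum q_i q_i^T of an N x 3 matrix of unit rows.
scatter_matrix <- function(Q) crossprod(Q) / nrow(Q)

# Deterministic initial axis: cross product of the two most orthogonal q's.
ap_init <- function(Q) {
  n <- nrow(Q)
  best <- c(1, 0, 0); best_n <- -1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cp <- c(Q[i, 2] * Q[j, 3] - Q[i, 3] * Q[j, 2],
            Q[i, 3] * Q[j, 1] - Q[i, 1] * Q[j, 3],
            Q[i, 1] * Q[j, 2] - Q[i, 2] * Q[j, 1])
    nn <- sqrt(sum(cp^2))
    if (nn > best_n) { best_n <- nn; best <- cp }
  }
  if (best_n < 1e-12) return(NULL)
  best / best_n
}

#' Best-fit fibril axis by iterative averaged projections
#'
#' Finds the unit axis most orthogonal to a set of measured q-vectors. Each
#' iteration projects the current estimate onto the plane orthogonal to every
#' measurement, `P_i(a) = a - (a . q_i) q_i`, averages the projections,
#' `b_k = (1/N) sum_i P_i(a_k)`, and renormalizes onto the unit sphere,
#' `a_{k+1} = b_k / |b_k|`. The signed projection form is used, making the
#' iteration invariant to the arbitrary sign of each `q_i` (azimuths are
#' defined mod 180 degrees); `verbatim_projection = TRUE` switches to the
#' non-sign-invariant variant `a - |a . q_i| q_i` for comparison. On
#' non-degenerate input the fixed point is the eigenvector of the smallest
#' eigenvalue of the q scatter matrix.
#'
#' @param qs N x 3 matrix (or list) of unit q-vectors, N >= 2.
#' @param init optional initial unit axis; default is the cross product of
#'   the two most orthogonal measurements (deterministic).
#' @param tol convergence threshold on the iterate step norm.
#' @param max_iter iteration cap.
#' @param eigen_gap_tol relative gap between the two smallest scatter
#'   eigenvalues below which the axis is declared degenerate.
#' @param verbatim_projection use the absolute-value projection form.
#' @return an `axis_estimate` (unit axis in the positive-z hemisphere,
#'   rms residual of `a . q_i`, iteration count, degeneracy flag).
#' @export
averaged_projections <- function(qs, init = NULL, tol = 1e-10,
                                 max_iter = 1000L, eigen_gap_tol = 0.05,
                                 verbatim_projection = FALSE) {
  Q <- if (is.list(qs)) do.call(rbind, qs) else as.matrix(qs)
  n <- nrow(Q)
  if (n < 2) sed3d_error("need at least two measurements", "sed3d_value_error")
  S <- scatter_matrix(Q)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  gap <- (ev[2] - ev[1]) / max(ev[2], .Machine$double.xmin)
  # an absolute floor catches the exactly-degenerate case (both smallest
  # eigenvalues at numerical zero), where the relative gap is meaningless
  degen <- gap < eigen_gap_tol || ev[2] < 1e-14
  a <- init
  if (is.null(a)) a <- ap_init(Q)
  if (is.null(a))   # all q parallel
    return(axis_estimate(c(NA_real_, NA_real_, NA_real_), NA_real_, n,
                         degenerate = TRUE))
  a <- a / sqrt(sum(a^2))
  restarted <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d <- as.numeric(Q %*% a)
    if (verbatim_projection) d <- abs(d)
    b <- a - colSums(Q * d) / n
    nb <- sqrt(sum(b^2))
    if (nb < 1e-12) {
      if (!restarted) {
        restarted <- TRUE
        a <- a + c(1e-3, -2e-3, 3e-3)
        a <- a / sqrt(sum(a^2))
        next
      }
      return(axis_estimate(c(NA_real_, NA_real_, NA_real_), NA_real_, n,
                           degenerate = TRUE, iterations = it))
    }
    a_new <- b / nb
    step <- sqrt(sum((a_new - a)^2))
    a <- a_new
    if (step < tol) break
  }
  a <- hemisphere(a)
  res <- sqrt(mean(as.numeric(Q %*% a)^2))
  axis_estimate(a, res, n, degenerate = degen, iterations = it)
}

#' Per-pixel orientation field
#'
#' @param axes array `(ny, nx, 3)` of unit axes (`NA` where undefined).
#' @param residual matrix of rms residuals.
#' @param valid logical matrix: signal present at >= 2 tilts.
#' @param degenerate logical matrix: axis under-determined.
#' @return an object of class `orientation_field`.
#' @export
orientation_field <- function(axes, residual, valid, degenerate) {
  stopifnot(length(dim(axes)) == 3, dim(axes)[3] == 3,
            identical(dim(axes)[1:2], dim(valid)))
  structure(list(axes = axes, residual = residual, valid = valid,
                 degenerate = degenerate), class = "orientation_field")
}

# Closed-form eigenvalues of symmetric 3x3 matrices, vectorized over pixels.
# Inputs are the six unique components; returns the two smallest eigenvalues
# per pixel (l1 <= l2). Standard trigonometric (Smith) formula.
eig3_smallest2 <- function(sxx, syy, szz, sxy, sxz, syz) {
  p1 <- sxy^2 + sxz^2 + syz^2
  q <- (sxx + syy + szz) / 3
  p2 <- (sxx - q)^2 + (syy - q)^2 + (szz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  l1 <- l2 <- numeric(length(sxx))
  small <- p < 1e-30
  l1[small] <- q[small]; l2[small] <- q[small]
  if (any(!small)) {
    i <- !small
    bxx <- (sxx[i] - q[i]) / p[i]; byy <- (syy[i] - q[i]) / p[i]
    bzz <- (szz[i] - q[i]) / p[i]
    bxy <- sxy[i] / p[i]; bxz <- sxz[i] / p[i]; byz <- syz[i] / p[i]
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmax(-1, pmin(1, detB / 2))
    phi <- acos(r) / 3
    e1 <- q[i] + 2 * p[i] * cos(phi + 2 * pi / 3)   # smallest
    e3 <- q[i] + 2 * p[i] * cos(phi)                # largest
    e2 <- 3 * q[i] - e1 - e3
    l1[i] <- e1; l2[i] <- e2
  }
  list(l1 = l1, l2 = l2)
}

#' Reconstruct the 3D fibril axis at every pixel of an aligned tilt series
#'
#' For each pixel with valid azimuths at two or more tilts, builds the
#' back-rotated q-vectors and solves for the axis best-orthogonal to all of
#' them (cross product for exactly two, averaged projections otherwise; the
#' whole field is solved in a vectorized sweep). Pixels whose q scatter
#' matrix has two nearly equal smallest eigenvalues are flagged degenerate -
#' with a single vertical tilt axis this captures exactly the fibril
#' directions with zero y-component, for which every tilt sees the same
#' azimuth and the 3D axis is under-determined. Pixels valid at fewer than
#' two tilts are invalid. No failure aborts the field; everything lands in
#' the masks.
#'
#' @param series a `tilt_series` from [align_series()].
#' @param tol,max_iter,eigen_gap_tol solver controls, see
#'   [averaged_projections()].
#' @return an [orientation_field()].
#' @export
reconstruct_field <- function(series, tol = 1e-10, max_iter = 1000L,
                              eigen_gap_tol = 0.05) {
  maps <- series$maps
  nt <- length(maps)
  d <- dim(maps[[1]]$phi_deg)
  np <- prod(d)
  phis <- vapply(maps, function(m) as.vector(m$phi_deg), numeric(np))
  vals <- vapply(maps, function(m) as.vector(m$valid), logical(np))
  if (is.null(dim(phis))) { phis <- matrix(phis, np); vals <- matrix(vals, np) }
  nvalid <- rowSums(vals)
  valid <- nvalid >= 2
  # q-vectors for every (pixel, tilt): qx, qy, qz as np x nt matrices
  qx <- qy <- qz <- matrix(0, np, nt)
  for (t in seq_len(nt)) {
    w <- deg2rad(series$tilts_deg[t])
    p <- deg2rad(phis[, t])
    # Ry(-w) [cos p, sin p, 0]
    qx[, t] <- cos(w) * cos(p)
    qy[, t] <- sin(p)
    qz[, t] <- sin(w) * cos(p)
    qx[!vals[, t], t] <- NA; qy[!vals[, t], t] <- NA; qz[!vals[, t], t] <- NA
  }
  idx <- which(valid)
  axes <- array(NA_real_, c(d, 3))
  residual <- matrix(NA_real_, d[1], d[2])
  degenerate <- matrix(FALSE, d[1], d[2])
  if (length(idx)) {
    n_i <- nvalid[idx]
    msum <- function(m) rowSums(m[idx, , drop = FALSE], na.rm = TRUE) / n_i
    sxx <- msum(qx * qx); syy <- msum(qy * qy); szz <- msum(qz * qz)
    sxy <- msum(qx * qy); sxz <- msum(qx * qz); syz <- msum(qy * qz)
    ev <- eig3_smallest2(sxx, syy, szz, sxy, sxz, syz)
    degen <- (ev$l2 - ev$l1) / pmax(ev$l2, .Machine$double.xmin) <
      eigen_gap_tol | ev$l2 < 1e-14
    # init: cross product of the most orthogonal pair of valid tilts
    ax <- ay <- az <- rep(NA_real_, length(idx))
    bestn <- rep(-1, length(idx))
    for (t1 in seq_len(nt - 1)) for (t2 in (t1 + 1):nt) {
      cx <- qy[idx, t1] * qz[idx, t2] - qz[idx, t1] * qy[idx, t2]
      cy <- qz[idx, t1] * qx[idx, t2] - qx[idx, t1] * qz[idx, t2]
      cz <- qx[idx, t1] * qy[idx, t2] - qy[idx, t1] * qx[idx, t2]
      nn <- sqrt(cx^2 + cy^2 + cz^2)
      upd <- !is.na(nn) & nn > bestn
      bestn[upd] <- nn[upd]
      ax[upd] <- cx[upd] / nn[upd]; ay[upd] <- cy[upd] / nn[upd]
      az[upd] <- cz[upd] / nn[upd]
    }
    allpar <- is.na(ax) | bestn < 1e-12
    degen <- degen | allpar
    live <- which(!allpar)
    if (length(live)) {
      # fixed-point iteration a <- normalize(a - S a), vectorized over pixels
      for (it in seq_len(max_iter)) {
        bx <- ax - (sxx * ax + sxy * ay + sxz * az)
        by <- ay - (sxy * ax + syy * ay + syz * az)
        bz <- az - (sxz * ax + syz * ay + szz * az)
        nb <- sqrt(bx^2 + by^2 + bz^2)
        nb[nb < 1e-300] <- 1
        bx <- bx / nb; by <- by / nb; bz <- bz / nb
        step <- sqrt((bx - ax)^2 + (by - ay)^2 + (bz - az)^2)
        ax <- bx; ay <- by; az <- bz
        if (max(step, na.rm = TRUE) < tol) break
      }
      flip <- !is.na(az) & (az < 0 | (az == 0 & (ay < 0 | (ay == 0 & ax < 0))))
      ax[flip] <- -ax[flip]; ay[flip] <- -ay[flip]; az[flip] <- -az[flip]
    }
    ax[allpar] <- NA; ay[allpar] <- NA; az[allpar] <- NA
    res <- sqrt(pmax(0, sxx * ax^2 + syy * ay^2 + szz * az^2 +
                       2 * (sxy * ax * ay + sxz * ax * az + syz * ay * az)))
    A <- array(NA_real_, c(d, 3))
    lin <- function(k) idx + (k - 1) * np
    A[lin(1)] <- ax; A[lin(2)] <- ay; A[lin(3)] <- az
    axes <- A
    residual[idx] <- res
    degenerate[idx] <- degen
  }
  orientation_field(axes, residual, matrix(valid, d[1], d[2]), degenerate)
}

#' Export an orientation field as CSV
#'
#' @param field an [orientation_field()].
#' @param csv_path output path; columns row, col, ax, ay, az, residual,
#'   valid, degenerate.
#' @return invisibly, the path.
#' @export
write_orientation_csv <- function(field, csv_path) {
  d <- dim(field$valid)
  df <- data.frame(row = rep(seq_len(d[1]), d[2]),
                   col = rep(seq_len(d[2]), each = d[1]),
                   ax = as.vector(field$axes[, , 1]),
                   ay = as.vector(field$axes[, , 2]),
                   az = as.vector(field$axes[, , 3]),
                   residual = as.vector(field$residual),
                   valid = as.vector(field$valid),
                   degenerate = as.vector(field$degenerate))
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(csv_path)
}
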