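# Bringing per-tilt azimuth maps into the common zero-tilt pixel frame.
# A plane_transform is a 3x3 homogeneous projective matrix acting on column
# vectors (x, y, 1), x = column and y = row coordinate, mapping tilted-map
# pixels to zero-tilt pixels.

#' Construct / normalize a projective plane transform
#'
#' @param m 3x3 invertible matrix; normalized so the bottom-right element
#'   is 1.
#' @return an object of class `plane_transform`.
#' @export
plane_transform <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  if (abs(det(m)) < 1e-14)
    sed3d_error("transform is singular", "sed3d_geometry_error")
  if (abs(m[3, 3]) < 1e-14)
    sed3d_error("cannot normalize transform with zero corner element",
                "sed3d_geometry_error")
  structure(m / m[3, 3], class = "plane_transform")
}

#' Geometric foreshortening correction for a tilted scan
#'
#' Tilting the sample by `omega` about the vertical (y) axis compresses the
#' sample by `cos(omega)` along x in the recorded map; the correction
#' stretches x by `1/cos(omega)` about the map centre, leaving the tilt axis
#' untouched.
#'
#' @param omega_deg tilt angle in degrees, `|omega| < 90`.
#' @param shape map shape (rows, cols).
#' @return a [plane_transform()].
#' @export
foreshorten_transform <- function(omega_deg, shape) {
  if (abs(omega_deg) >= 90)
    sed3d_error("|omega| must be < 90 degrees", "sed3d_geometry_error")
  s <- 1 / cos(deg2rad(omega_deg))
  cx <- (shape[2] + 1) / 2
  plane_transform(matrix(c(s, 0, 0,
                           0, 1, 0,
                           cx * (1 - s), 0, 1), 3, 3))
}

# Apply a plane transform to points given as a 2 x n matrix (x; y).
apply_transform <- function(tm, xy) {
  p <- rbind(xy, 1)
  q <- unclass(tm) %*% p
  q[1:2, , drop = FALSE] / rep(q[3, ], each = 2)
}

# Warp a matrix into an output grid of shape out_shape through transform tm
# (input -> output coords). method "nn" keeps values unblended (angles),
# "bilinear" interpolates (intensity images). Outside-field -> NA.
warp_matrix <- function(values, tm, out_shape = dim(values),
                        method = c("nn", "bilinear")) {
  method <- match.arg(method)
  inv <- solve(unclass(tm))
  nro <- out_shape[1]; nco <- out_shape[2]
  nri <- nrow(values); nci <- ncol(values)
  xo <- rep(seq_len(nco), each = nro)
  yo <- rep(seq_len(nro), times = nco)
  src <- apply_transform(plane_transform(inv), rbind(xo, yo))
  xs <- src[1, ]; ys <- src[2, ]
  out <- rep(NA_real_, nro * nco)
  if (method == "nn") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= nci & yi >= 1 & yi <= nri
    out[ok] <- values[cbind(yi[ok], xi[ok])]
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    ok <- x0 >= 1 & x0 + 1 <= nci & y0 >= 1 & y0 + 1 <= nri
    fx <- xs[ok] - x0[ok]; fy <- ys[ok] - y0[ok]
    v00 <- values[cbind(y0[ok], x0[ok])]
    v10 <- values[cbind(y0[ok] + 1, x0[ok])]
    v01 <- values[cbind(y0[ok], x0[ok] + 1)]
    v11 <- values[cbind(y0[ok] + 1, x0[ok] + 1)]
    out[ok] <- v00 * (1 - fx) * (1 - fy) + v10 * (1 - fx) * fy +
      v01 * fx * (1 - fy) + v11 * fx * fy
  }
  matrix(out, nro, nco)
}

# Normalized cross-correlation of two maps over jointly finite pixels.
ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 9) return(NA_real_)
  av <- a[ok]; bv <- b[ok]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
  stats::cor(av, bv)
}

#' Refine a map-to-map projective alignment by correlation
#'
#' Starting from a geometric initial transform, searches integer
#' translations coarsely and then refines all eight projective degrees of
#' freedom by Nelder-Mead, maximizing the normalized cross-correlation of
#' the warped moving map against the reference. Intensity (virtual-image)
#' maps are the intended correlation channel; azimuth maps are unsuitable.
#'
#' @param reference,moving [scalar_map()]s or plain matrices.
#' @param init initial [plane_transform()] (default identity).
#' @param search_px half-width of the coarse translation search, pixels.
#' @param correlation_floor minimum acceptable final correlation; below it an
#'   alignment-failure error is signalled (carrying the best transform found
#'   in its `data` field).
#' @return a [plane_transform()] with attributes `correlation`.
#' @export
refine_alignment <- function(reference, moving, init = NULL, search_px = 8,
                             correlation_floor = 0.2) {
  ref <- if (inherits(reference, "scalar_map")) reference$values else reference
  mov <- if (inherits(moving, "scalar_map")) moving$values else moving
  if (is.null(init)) init <- plane_transform(diag(3))
  shape <- dim(ref)
  score <- function(tm) ncc(ref, warp_matrix(mov, tm, shape, "bilinear"))
  if (is.na(score(init)) || stats::sd(ref[is.finite(ref)]) == 0)
    sed3d_error("structureless maps cannot be aligned",
                "sed3d_alignment_error")
  # coarse integer translation search around init
  best <- c(0, 0); best_s <- -Inf
  for (tx in -search_px:search_px) for (ty in -search_px:search_px) {
    tm <- unclass(init); tm[1, 3] <- tm[1, 3] + tx; tm[2, 3] <- tm[2, 3] + ty
    s <- score(plane_transform(tm))
    if (!is.na(s) && s > best_s) { best_s <- s; best <- c(tx, ty) }
  }
  base <- unclass(init)
  base[1, 3] <- base[1, 3] + best[1]; base[2, 3] <- base[2, 3] + best[2]
  # full projective refinement: perturbation D(p) applied in the output frame
  cx <- (shape[2] + 1) / 2; cy <- (shape[1] + 1) / 2
  ctr <- matrix(c(1, 0, 0, 0, 1, 0, cx, cy, 1), 3, 3)
  make_tm <- function(p) {
    D <- matrix(c(1 + p[3], p[5], p[7] * 1e-3,
                  p[4], 1 + p[6], p[8] * 1e-3,
                  p[1], p[2], 1), 3, 3)
    plane_transform(ctr %*% D %*% solve(ctr) %*% base)
  }
  obj <- function(p) { s <- score(make_tm(p)); if (is.na(s)) 1 else -s }
  opt <- stats::optim(rep(0, 8), obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  tm <- make_tm(opt$par)
  corr <- -opt$value
  if (!is.finite(corr) || corr < correlation_floor) {
    cond <- structure(
      class = c("sed3d_alignment_error", "sed3d_error", "error", "condition"),
      list(message = sprintf("alignment correlation %.3f below floor %.3f",
                             corr, correlation_floor),
           call = sys.call(-1), data = tm))
    stop(cond)
  }
  attr(tm, "correlation") <- corr
  tm
}

#' Wrap already-aligned azimuth maps as a tilt series
#'
#' Use when the maps are known to share a common pixel frame (e.g. generated
#' on the zero-tilt grid, or aligned externally); all transforms are
#' identity.
#'
#' @param maps list of `azimuth_map`s with distinct tilts and equal shapes.
#' @return a `tilt_series`.
#' @export
tilt_series <- function(maps) {
  tilts <- vapply(maps, function(m) m$tilt_deg, numeric(1))
  if (anyDuplicated(tilts))
    sed3d_error("tilt angles must be distinct", "sed3d_config_error")
  shapes <- vapply(maps, function(m) dim(m$phi_deg), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    sed3d_error("maps must have equal shapes", "sed3d_config_error")
  structure(list(maps = maps,
                 transforms = replicate(length(maps),
                                        plane_transform(diag(3)),
                                        simplify = FALSE),
                 tilts_deg = tilts), class = "tilt_series")
}

#' Align a tilt series of azimuth maps into the zero-tilt frame
#'
#' Warps every per-tilt azimuth map into the pixel frame of the zero-tilt
#' map so that each pixel carries diffraction information from the same
#' sample position. Transforms are initialized from the tilt foreshortening
#' geometry and, when companion intensity images are supplied, refined by
#' correlation. Azimuth values are warped with nearest-neighbour sampling
#' (angles must never be blended between pixels); warped validity masks are
#' eroded by one pixel to suppress edge artifacts.
#'
#' @param maps list of `azimuth_map`s, one per tilt, including tilt 0.
#' @param images optional list of companion [scalar_map()]s (e.g. from
#'   [virtual_image()]) used as the correlation channel.
#' @param refine refine transforms by correlation (requires `images`).
#' @param correlation_floor passed to [refine_alignment()].
#' @return a `tilt_series`: list with `maps` (warped), `transforms`,
#'   `tilts_deg`.
#' @export
align_series <- function(maps, images = NULL, refine = !is.null(images),
                         correlation_floor = 0.2) {
  if (length(maps) < 1) sed3d_error("no maps", "sed3d_config_error")
  tilts <- vapply(maps, function(m) m$tilt_deg, numeric(1))
  if (anyDuplicated(tilts))
    sed3d_error("tilt angles must be distinct", "sed3d_config_error")
  iref <- which(tilts == 0)
  if (length(iref) != 1)
    sed3d_error("a zero-tilt reference map is required", "sed3d_config_error")
  shapes <- vapply(maps, function(m) dim(m$phi_deg), integer(2))
  common <- c(max(shapes[1, ]), max(shapes[2, ]))
  out_maps <- vector("list", length(maps))
  transforms <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    if (i == iref && identical(dim(m$phi_deg), as.integer(common))) {
      transforms[[i]] <- plane_transform(diag(3))
      out_maps[[i]] <- m
      next
    }
    tm <- if (i == iref) plane_transform(diag(3))
          else foreshorten_transform(tilts[i], dim(m$phi_deg))
    if (refine && i != iref) {
      if (is.null(images))
        sed3d_error("refine = TRUE needs companion images",
                    "sed3d_config_error")
      tm <- refine_alignment(images[[iref]], images[[i]], init = tm,
                             correlation_floor = correlation_floor)
    }
    phi <- warp_matrix(m$phi_deg, tm, common, "nn")
    qual <- warp_matrix(m$quality, tm, common, "nn")
    vnum <- warp_matrix(m$valid * 1, tm, common, "nn")
    valid <- !is.na(vnum) & vnum > 0
    valid <- erode3(valid)
    qual[is.na(qual)] <- 0
    out_maps[[i]] <- azimuth_map_obj(phi, qual, valid, tilts[i])
    transforms[[i]] <- tm
  }
  structure(list(maps = out_maps, transforms = transforms, tilts_deg = tilts),
            class = "tilt_series")
}
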