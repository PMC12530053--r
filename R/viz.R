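# Colour-wheel orientation maps, signed-component backgrounds and cylinder
# glyph export. Any RGB coding of a sign-ambiguous axis either collides or
# is discontinuous somewhere; the scheme here collides exactly on the
# documented ambiguity (a_y = 0) and nowhere else.

#' Colour-mapping specification for orientation fields
#'
#' Hue encodes the in-plane angle (period 180 degrees), saturation the
#' out-of-plane magnitude (`|theta| / 90`, so an axis along the beam is
#' grey), and lightness separates positive from negative y-components.
#'
#' @param hue_origin_deg in-plane angle mapped to hue 0.
#' @param lightness_pos,lightness_neg lightness for `a_y > 0` / `a_y < 0`
#'   (`a_y = 0` gets their midpoint).
#' @param invalid_rgb colour for invalid/degenerate pixels.
#' @return an object of class `colormap_spec`.
#' @export
colormap_spec <- function(hue_origin_deg = 0, lightness_pos = 0.65,
                          lightness_neg = 0.35, invalid_rgb = c(0, 0, 0)) {
  structure(list(hue_origin_deg = hue_origin_deg,
                 lightness_pos = lightness_pos,
                 lightness_neg = lightness_neg,
                 invalid_rgb = invalid_rgb), class = "colormap_spec")
}

# HSL -> RGB, vectorized, components in [0, 1].
hsl_to_rgb <- function(h, s, l) {
  c_ <- (1 - abs(2 * l - 1)) * s
  hp <- (h %% 1) * 6
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- l - c_ / 2
  r <- g <- b <- numeric(length(h))
  seg <- floor(hp) %% 6
  r <- ifelse(seg %in% c(0, 5), c_, ifelse(seg %in% c(1, 4), x, 0))
  g <- ifelse(seg %in% c(1, 2), c_, ifelse(seg %in% c(0, 3), x, 0))
  b <- ifelse(seg %in% c(3, 4), c_, ifelse(seg %in% c(2, 5), x, 0))
  cbind(r + m, g + m, b + m)
}

#' Colour-wheel rendering of an orientation field
#'
#' @param field an [orientation_field()].
#' @param spec a [colormap_spec()].
#' @param png_path optional output PNG path.
#' @return RGB array (ny, nx, 3) in `[0, 1]`, invisibly written to
#'   `png_path` when given.
#' @export
colorize <- function(field, spec = colormap_spec(), png_path = NULL) {
  d <- dim(field$valid)
  np <- prod(d)
  ok <- as.vector(field$valid & !field$degenerate)
  ax <- as.vector(field$axes[, , 1]); ay <- as.vector(field$axes[, , 2])
  az <- as.vector(field$axes[, , 3])
  ok <- ok & !is.na(ax)
  rgb <- matrix(rep(spec$invalid_rgb, each = np), np, 3)
  if (any(ok)) {
    phi <- mod180(rad2deg(atan2(ay[ok], ax[ok])) - spec$hue_origin_deg)
    theta_abs <- rad2deg(acos(pmax(-1, pmin(1, az[ok]))))
    h <- phi / 180
    s <- pmin(theta_abs / 90, 1)
    l <- ifelse(ay[ok] > 0, spec$lightness_pos,
                ifelse(ay[ok] < 0, spec$lightness_neg,
                       (spec$lightness_pos + spec$lightness_neg) / 2))
    rgb[ok, ] <- hsl_to_rgb(h, s, l)
  }
  img <- array(rgb, c(d[1], d[2], 3))
  if (!is.null(png_path)) png::writePNG(img, png_path)
  invisible(img)
}

#' Signed-component background map
#'
#' Per-pixel signed value of the chosen axis component (y or z), intended
#' for diverging-colormap rendering behind cylinder glyphs: the sign
#' separates the two helical handednesses, zero is neutral, and invalid
#' pixels are `NA`.
#'
#' @param field an [orientation_field()].
#' @param component `"y"` or `"z"`.
#' @return a [scalar_map()] with values in `[-1, 1]`.
#' @export
component_background <- function(field, component = c("y", "z")) {
  component <- match.arg(component)
  k <- if (component == "y") 2L else 3L
  d <- dim(field$valid)
  v <- matrix(field$axes[, , k], d[1], d[2])
  v[!(field$valid & !field$degenerate)] <- NA_real_
  scalar_map(v, units = "axis component")
}

#' Export cylinder-glyph table (and optional quiver preview)
#'
#' Writes one row per valid, non-degenerate pixel on a strided grid:
#' position in micrometres and the 3D unit axis, suitable for external 3D
#' glyph rendering. Optionally renders a 2D quiver-style preview (in-plane
#' projections of the axes) to PNG.
#'
#' @param field an [orientation_field()].
#' @param stride keep every `stride`-th pixel in both directions.
#' @param step_nm scan step, for pixel-to-micrometre conversion.
#' @param csv_path optional CSV output path.
#' @param preview_png optional PNG preview path.
#' @return data frame with columns `x_um`, `y_um`, `ax`, `ay`, `az`,
#'   `residual`.
#' @export
export_glyphs <- function(field, stride = 1L, step_nm = 100,
                          csv_path = NULL, preview_png = NULL) {
  if (stride < 1) sed3d_error("stride must be >= 1", "sed3d_value_error")
  d <- dim(field$valid)
  rows <- seq(1, d[1], by = stride)
  cols <- seq(1, d[2], by = stride)
  keep <- matrix(FALSE, d[1], d[2])
  keep[rows, cols] <- TRUE
  keep <- keep & field$valid & !field$degenerate & !is.na(field$axes[, , 1])
  idx <- which(keep)
  np <- prod(d)
  df <- data.frame(
    x_um = ((idx - 1) %/% d[1] + 1) * step_nm / 1000,
    y_um = ((idx - 1) %% d[1] + 1) * step_nm / 1000,
    ax = field$axes[idx], ay = field$axes[idx + np],
    az = field$axes[idx + 2 * np], residual = field$residual[idx])
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(preview_png)) {
    grDevices::png(preview_png, width = 800, height = 800)
    on.exit(grDevices::dev.off())
    graphics::plot(NA, xlim = c(0, d[2] * step_nm / 1000),
                   ylim = c(d[1] * step_nm / 1000, 0), asp = 1,
                   xlab = "x (um)", ylab = "y (um)")
    if (nrow(df)) {
      len <- stride * step_nm / 1000 * 0.45
      graphics::arrows(df$x_um - df$ax * len, df$y_um - df$ay * len,
                       df$x_um + df$ax * len, df$y_um + df$ay * len,
                       length = 0, col = grDevices::rgb(0.1, 0.3, 0.7))
    }
  }
  df
}
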