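# Small shared helpers: angle arithmetic, mask morphology, config hashing.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Reduce an angle in degrees to the half-turn interval [0, 180)
#'
#' Bragg azimuths and in-plane fibril angles are axial quantities (Friedel
#' pairs / sign-ambiguous axes), defined modulo 180 degrees.
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into `[0, 180)`.
#' @export
mod180 <- function(x) {
  out <- x %% 180
  # guard against 180 - eps rounding back to exactly 180
  fix <- which(out >= 180)
  out[fix] <- out[fix] - 180
  out
}

# Smallest absolute difference between two axial angles (period 180 deg).
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Binary erosion of a logical matrix with a 3x3 structuring element.
erode3 <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask
  pad <- function(mm, dr, dc) {
    nr <- nrow(mm); nc <- ncol(mm)
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- mm[rs[ok_r], cs[ok_c]]
    out
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    m <- m & pad(mask, dr, dc)
  }
  m
}

# Deterministic hash of an R object (canonical JSON -> md5 of a temp file).
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

# Error constructors with condition classes so callers can test failure modes.
sed3d_error <- function(msg, class) {
  stop(structure(class = c(class, "sed3d_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
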