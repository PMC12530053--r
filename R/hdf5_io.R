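# HDF5 layout: one group per tilt (e.g. "tilt_p45"), dataset "data" with dims
# (scan_y, scan_x, ky, kx), acquisition metadata as group attributes. A raw
# frame stream is accepted as a 3D dataset (frame, ky, kx) plus "scan_shape".

tilt_group_name <- function(tilt_deg) {
  sprintf("tilt_%s%02d", if (tilt_deg < 0) "m" else "p", abs(round(tilt_deg)))
}

meta_attr_names <- c("tilt_deg", "step_nm", "recip_pixel_inv_A",
                     "beam_current_pA", "dwell_ms", "beam_diameter_nm")

#' Write a diffraction stack to an HDF5 tilt-series file
#'
#' @param stack a [frame_stack()].
#' @param path HDF5 file (created if absent).
#' @param group group name; default derived from the tilt angle.
#' @return invisibly, the group name written.
#' @export
write_framestack <- function(stack, path, group = NULL) {
  if (is.null(group)) group <- tilt_group_name(stack$meta$tilt_deg)
  if (!file.exists(path)) rhdf5::h5createFile(path)
  if (group %in% rhdf5::h5ls(path)$name == FALSE)
    rhdf5::h5createGroup(path, group)
  rhdf5::h5write(stack$data, path, paste0(group, "/data"))
  rhdf5::h5write(stack$center, path, paste0(group, "/center"))
  rhdf5::h5write(stack$frame_valid * 1L, path, paste0(group, "/frame_valid"))
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, group)
  for (nm in meta_attr_names)
    rhdf5::h5writeAttribute(stack$meta[[nm]], gid, nm)
  rhdf5::h5writeAttribute(stack$meta$camera_shape, gid, "camera_shape")
  rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  invisible(group)
}

#' Load a diffraction stack from an HDF5 tilt-series file
#'
#' Reads the 4D dataset and acquisition attributes for one tilt group.
#' Optional metadata attributes that are absent fall back to the [acq_meta()]
#' defaults with a warning; a missing `data` dataset is a format error. A 3D
#' `(frame, ky, kx)` stream dataset is reshaped using the group's
#' `scan_shape` attribute (or the `scan_shape` argument).
#'
#' @param path HDF5 file.
#' @param group tilt group name; if `NULL` and the file holds exactly one
#'   tilt group, that group is used.
#' @param scan_shape rows x cols, used only for 3D stream datasets.
#' @return a [frame_stack()].
#' @export
load_framestack <- function(path, group = NULL, scan_shape = NULL) {
  if (!file.exists(path))
    sed3d_error(paste0("no such file: ", path), "sed3d_format_error")
  ls <- tryCatch(rhdf5::h5ls(path), error = function(e)
    sed3d_error(paste0("unreadable HDF5 file: ", path), "sed3d_format_error"))
  groups <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  if (is.null(group)) {
    tg <- grep("^tilt_", groups, value = TRUE)
    if (length(tg) != 1)
      sed3d_error("group not given and file does not hold exactly one tilt group",
                  "sed3d_format_error")
    group <- tg
  }
  dsets <- ls$name[ls$group == paste0("/", group)]
  if (!"data" %in% dsets)
    sed3d_error(sprintf("missing required dataset /%s/data", group),
                "sed3d_format_error")
  dat <- rhdf5::h5read(path, paste0(group, "/data"))
  att <- rhdf5::h5readAttributes(path, group)
  defaults <- acq_meta()
  margs <- list()
  for (nm in meta_attr_names) {
    if (!is.null(att[[nm]])) margs[[nm]] <- as.numeric(att[[nm]])
    else {
      warning(sprintf("attribute '%s' missing in %s; defaulting to %s",
                      nm, group, format(defaults[[nm]])))
      margs[[nm]] <- defaults[[nm]]
    }
  }
  if (length(dim(dat)) == 3) {
    ss <- if (!is.null(scan_shape)) scan_shape else att$scan_shape
    if (is.null(ss))
      sed3d_error("3D stream dataset needs a scan_shape", "sed3d_format_error")
    nf <- dim(dat)[1]
    if (nf != prod(ss))
      sed3d_error("stream length does not match scan_shape", "sed3d_size_error")
    dat4 <- array(0, c(ss[1], ss[2], dim(dat)[2], dim(dat)[3]))
    for (i in seq_len(nf))
      dat4[(i - 1) %/% ss[2] + 1, (i - 1) %% ss[2] + 1, , ] <- dat[i, , ]
    dat <- dat4
  }
  if (length(dim(dat)) != 4)
    sed3d_error("dataset 'data' is not 3D or 4D", "sed3d_format_error")
  margs$camera_shape <- as.integer(dim(dat)[3:4])
  meta <- do.call(acq_meta, margs)
  center <- if ("center" %in% dsets)
    rhdf5::h5read(path, paste0(group, "/center")) else NULL
  fv <- if ("frame_valid" %in% dsets)
    rhdf5::h5read(path, paste0(group, "/frame_valid")) > 0 else NULL
  frame_stack(dat, meta, center = center, frame_valid = fv)
}

#' @rdname write_framestack
#' @param field an `orientation_field` (see [reconstruct_field()]).
#' @export
write_orientation_field <- function(field, path, group = "reconstruction") {
  if (!file.exists(path)) rhdf5::h5createFile(path)
  if (!group %in% rhdf5::h5ls(path)$name) rhdf5::h5createGroup(path, group)
  rhdf5::h5write(field$axes, path, paste0(group, "/axis"))
  rhdf5::h5write(field$residual, path, paste0(group, "/residual"))
  rhdf5::h5write(field$valid * 1L, path, paste0(group, "/valid"))
  rhdf5::h5write(field$degenerate * 1L, path, paste0(group, "/degenerate"))
  invisible(group)
}

#' @rdname load_framestack
#' @export
read_orientation_field <- function(path, group = "reconstruction") {
  orientation_field(
    axes = rhdf5::h5read(path, paste0(group, "/axis")),
    residual = rhdf5::h5read(path, paste0(group, "/residual")),
    valid = rhdf5::h5read(path, paste0(group, "/valid")) > 0,
    degenerate = rhdf5::h5read(path, paste0(group, "/degenerate")) > 0)
}

# Alignment transforms: 3x3 matrices under group "alignment", one dataset per
# tilt, named like the tilt groups.
write_alignment <- function(transforms, tilts_deg, path) {
  if (!file.exists(path)) rhdf5::h5createFile(path)
  if (!"alignment" %in% rhdf5::h5ls(path)$name)
    rhdf5::h5createGroup(path, "alignment")
  for (i in seq_along(transforms))
    rhdf5::h5write(unclass(transforms[[i]]), path,
                   paste0("alignment/", tilt_group_name(tilts_deg[i])))
  invisible(NULL)
}
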