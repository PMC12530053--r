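# YAML-configured pipeline tying the stages together:
# simulate -> azimuth -> align -> reconstruct -> analyze -> render.
# Stages communicate through files in the output directory (HDF5 for stacks
# and reconstructions, CSV sidecars for maps and tables) so any suffix of
# the chain can be re-run; every artifact records the config hash and seed.

pipeline_stage_order <- c("simulate", "azimuth", "align", "reconstruct",
                          "analyze", "render")

default_config <- function() list(
  seed = 1L,
  output_dir = "sed3d_out",
  input_h5 = NULL,
  ring = list(radius_inv_A = 0.258, box_inv_A = 0.04, n_detectors = 360L,
              quality_threshold = 0.10),
  align = list(correlation_floor = 0.2, refine = FALSE),
  reconstruct = list(tol = 1e-10, max_iter = 1000L, eigen_gap_tol = 0.05),
  synth = list(mode = "azimuth", geometry = "annular",
               shape = c(64L, 64L), step_nm = 100,
               tilts = c(0, 45, -45), center_px = NULL, layers = NULL,
               detector = list(shape = c(64L, 64L),
                               recip_pixel_inv_A = 0.011),
               noise = list(azimuth_sigma_deg = 0, background_level = 1,
                            peak_snr = 30)),
  analysis = list(positive_theta = "left", erode_regions = 1L),
  viz = list(stride = 2L, hue_origin_deg = 0))

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      sed3d_error(sprintf("unknown config key '%s%s'", path, nm),
                  "sed3d_config_error")
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && nm != "layers")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    else base[nm] <- list(user[[nm]])
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), checks every key against the known
#' schema (unknown keys are rejected), and fills defaults. Every defaulted
#' parameter is logged once.
#'
#' @param config path to a YAML file, or a named list.
#' @param quiet suppress default-parameter logging.
#' @return validated config list with attribute `hash`.
#' @export
pipeline_config <- function(config = list(), quiet = FALSE) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  if (!quiet) {
    defaulted <- setdiff(names(default_config()), names(user))
    if (length(defaulted))
      message("config defaults used for: ", paste(defaulted, collapse = ", "))
  }
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

artifact_paths <- function(out) list(
  stacks = file.path(out, "stacks.h5"),
  azimuth = function(t) file.path(out, sprintf("azimuth_%s.csv",
                                               tilt_group_name(t))),
  vimage = function(t) file.path(out, sprintf("vimage_%s.csv",
                                              tilt_group_name(t))),
  aligned = function(t) file.path(out, sprintf("aligned_%s.csv",
                                               tilt_group_name(t))),
  recon_h5 = file.path(out, "reconstruction.h5"),
  recon_csv = file.path(out, "reconstruction.csv"),
  regions = file.path(out, "regions.csv"),
  truth = file.path(out, "phantom_axes.csv"),
  stats = file.path(out, "layer_stats.csv"),
  glyphs = file.path(out, "glyphs.csv"),
  color_png = file.path(out, "orientation.png"),
  manifest = file.path(out, "manifest.json"))

read_azimuth_csv <- function(path, tilt) {
  df <- utils::read.csv(path, comment.char = "#")
  d <- c(max(df$row), max(df$col))
  mk <- function(v) matrix(v[order(df$col, df$row)], d[1], d[2])
  azimuth_map_obj(mk(df$phi_deg), mk(df$quality), mk(df$valid > 0), tilt)
}

require_artifact <- function(path, stage, what) {
  if (!file.exists(path))
    sed3d_error(sprintf("stage '%s' needs missing artifact '%s' (%s)",
                        stage, path, what), "sed3d_precondition_error")
  path
}

#' Run the reconstruction pipeline
#'
#' Executes the requested stages in canonical order
#' (`simulate, azimuth, align, reconstruct, analyze, render`), reading and
#' writing the shared artifacts in the output directory. `simulate` builds
#' the configured phantom and either writes simulated azimuth maps directly
#' (`synth$mode = "azimuth"`) or renders full diffraction stacks to HDF5
#' (`synth$mode = "render"`); with real data, point `input_h5` at a tilt
#' series and start from `azimuth`. A missing precondition artifact raises
#' an error naming it. A manifest with the config hash, seed and package
#' version is written alongside the outputs; all randomness is governed by
#' `config$seed`.
#'
#' @param config a [pipeline_config()], YAML path, or list.
#' @param stages subset of the canonical stages.
#' @param output_dir overrides `config$output_dir`.
#' @param seed overrides `config$seed`.
#' @return invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(config = list(),
                         stages = pipeline_stage_order,
                         output_dir = NULL, seed = NULL) {
  cfg <- if (is.list(config) && !is.null(attr(config, "hash"))) config
         else pipeline_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- match.arg(stages, pipeline_stage_order, several.ok = TRUE)
  stages <- pipeline_stage_order[pipeline_stage_order %in% stages]
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ap <- artifact_paths(out)
  hash <- attr(cfg, "hash")
  if (is.null(hash)) hash <- config_hash(cfg)
  stamp <- sprintf("# config_hash=%s seed=%d", hash, cfg$seed)
  write_stamped_csv <- function(df, path) {
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  rcfg <- do.call(ring_config, cfg$ring)
  tilts <- cfg$synth$tilts
  written <- character(0)
  log <- function(...) message("[sed3d] ", sprintf(...))

  build_phantom <- function() {
    layers <- if (is.data.frame(cfg$synth$layers)) cfg$synth$layers
              else do.call(rbind, lapply(cfg$synth$layers, as.data.frame))
    if (is.null(layers))
      sed3d_error("synth$layers is required for stage 'simulate'",
                  "sed3d_config_error")
    make_phantom(layers, geometry = cfg$synth$geometry,
                 shape = as.integer(cfg$synth$shape),
                 step_nm = cfg$synth$step_nm,
                 center_px = cfg$synth$center_px)
  }

  if ("simulate" %in% stages) {
    log("simulate: building %s phantom", cfg$synth$geometry)
    ph <- build_phantom()
    nz <- do.call(noise_spec, c(cfg$synth$noise, list(seed = cfg$seed)))
    d <- dim(ph$labels)
    write_stamped_csv(data.frame(row = rep(seq_len(d[1]), d[2]),
                                 col = rep(seq_len(d[2]), each = d[1]),
                                 label = as.vector(ph$labels)), ap$regions)
    np <- prod(d)
    write_stamped_csv(data.frame(row = rep(seq_len(d[1]), d[2]),
                                 col = rep(seq_len(d[2]), each = d[1]),
                                 ax = as.vector(ph$axes[, , 1]),
                                 ay = as.vector(ph$axes[, , 2]),
                                 az = as.vector(ph$axes[, , 3])), ap$truth)
    if (identical(cfg$synth$mode, "render")) {
      unlink(ap$stacks)
      for (w in tilts) {
        st <- render_patterns(ph, w, rcfg,
                              detector = list(
                                shape = as.integer(cfg$synth$detector$shape),
                                recip_pixel_inv_A =
                                  cfg$synth$detector$recip_pixel_inv_A),
                              noise = nz)
        write_framestack(st, ap$stacks)
      }
      written <- c(written, ap$stacks)
    } else {
      maps <- simulate_azimuth_maps(ph, tilts, nz)
      for (i in seq_along(tilts)) {
        dd <- dim(maps[[i]]$phi_deg)
        write_stamped_csv(data.frame(
          row = rep(seq_len(dd[1]), dd[2]),
          col = rep(seq_len(dd[2]), each = dd[1]),
          phi_deg = as.vector(maps[[i]]$phi_deg),
          quality = as.vector(maps[[i]]$quality),
          valid = as.vector(maps[[i]]$valid) * 1),
          ap$azimuth(tilts[i]))
      }
    }
    written <- c(written, ap$regions, ap$truth)
  }

  if ("azimuth" %in% stages) {
    h5 <- if (!is.null(cfg$input_h5)) cfg$input_h5 else ap$stacks
    require_artifact(h5, "azimuth", "diffraction stacks (HDF5)")
    for (w in tilts) {
      st <- load_framestack(h5, tilt_group_name(w))
      am <- azimuth_map(st, rcfg)
      vi <- virtual_image(st)
      dd <- dim(am$phi_deg)
      write_stamped_csv(data.frame(
        row = rep(seq_len(dd[1]), dd[2]),
        col = rep(seq_len(dd[2]), each = dd[1]),
        phi_deg = as.vector(am$phi_deg), quality = as.vector(am$quality),
        valid = as.vector(am$valid) * 1), ap$azimuth(w))
      write_stamped_csv(as.data.frame(vi$values), ap$vimage(w))
      log("azimuth: tilt %+.0f, %.1f%% valid", w, 100 * mean(am$valid))
    }
    written <- c(written, vapply(tilts, function(w) ap$azimuth(w), ""))
  }

  if ("align" %in% stages) {
    maps <- lapply(tilts, function(w)
      read_azimuth_csv(require_artifact(ap$azimuth(w), "align",
                                        "azimuth maps"), w))
    images <- NULL
    if (isTRUE(cfg$align$refine) && all(file.exists(
          vapply(tilts, function(w) ap$vimage(w), ""))))
      images <- lapply(tilts, function(w) {
        v <- as.matrix(utils::read.csv(ap$vimage(w), comment.char = "#"))
        scalar_map(unname(v))
      })
    ser <- align_series(maps, images = images,
                        refine = isTRUE(cfg$align$refine) &&
                          !is.null(images),
                        correlation_floor = cfg$align$correlation_floor)
    for (i in seq_along(tilts)) {
      m <- ser$maps[[i]]
      dd <- dim(m$phi_deg)
      write_stamped_csv(data.frame(
        row = rep(seq_len(dd[1]), dd[2]),
        col = rep(seq_len(dd[2]), each = dd[1]),
        phi_deg = as.vector(m$phi_deg), quality = as.vector(m$quality),
        valid = as.vector(m$valid) * 1), ap$aligned(tilts[i]))
    }
    unlink(ap$recon_h5)
    write_alignment(ser$transforms, tilts, ap$recon_h5)
    written <- c(written, vapply(tilts, function(w) ap$aligned(w), ""))
  }

  if ("reconstruct" %in% stages) {
    maps <- lapply(tilts, function(w)
      read_azimuth_csv(require_artifact(ap$aligned(w), "reconstruct",
                                        "aligned azimuth maps"), w))
    ser <- structure(list(maps = maps,
                          transforms = replicate(length(tilts),
                                                 plane_transform(diag(3)),
                                                 simplify = FALSE),
                          tilts_deg = tilts), class = "tilt_series")
    fld <- reconstruct_field(ser, tol = cfg$reconstruct$tol,
                             max_iter = cfg$reconstruct$max_iter,
                             eigen_gap_tol = cfg$reconstruct$eigen_gap_tol)
    write_orientation_field(fld, ap$recon_h5)
    dd <- dim(fld$valid)
    write_stamped_csv(data.frame(
      row = rep(seq_len(dd[1]), dd[2]),
      col = rep(seq_len(dd[2]), each = dd[1]),
      ax = as.vector(fld$axes[, , 1]), ay = as.vector(fld$axes[, , 2]),
      az = as.vector(fld$axes[, , 3]),
      residual = as.vector(fld$residual),
      valid = as.vector(fld$valid) * 1,
      degenerate = as.vector(fld$degenerate) * 1), ap$recon_csv)
    log("reconstruct: %.1f%% valid, %.1f%% degenerate",
        100 * mean(fld$valid), 100 * mean(fld$degenerate))
    written <- c(written, ap$recon_csv)
  }

  if ("analyze" %in% stages) {
    require_artifact(ap$recon_csv, "analyze", "reconstructed field")
    fld <- read_field_csv(ap$recon_csv)
    require_artifact(ap$regions, "analyze", "region labels")
    reg <- utils::read.csv(ap$regions, comment.char = "#")
    d <- dim(fld$valid)
    regions <- matrix(0L, d[1], d[2])
    regions[cbind(reg$row, reg$col)] <- reg$label
    st <- layer_stats(fld, regions,
                      positive_theta = cfg$analysis$positive_theta,
                      erode = cfg$analysis$erode_regions)
    write_stamped_csv(st, ap$stats)
    written <- c(written, ap$stats)
  }

  if ("render" %in% stages) {
    require_artifact(ap$recon_csv, "render", "reconstructed field")
    fld <- read_field_csv(ap$recon_csv)
    colorize(fld, colormap_spec(hue_origin_deg = cfg$viz$hue_origin_deg),
             png_path = ap$color_png)
    gl <- export_glyphs(fld, stride = cfg$viz$stride,
                        step_nm = cfg$synth$step_nm)
    write_stamped_csv(gl, ap$glyphs)
    written <- c(written, ap$color_png, ap$glyphs)
  }

  manifest <- list(config_hash = hash, seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("sed3d")),
                   stages = stages, config = cfg)
  jsonlite::write_json(manifest, ap$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(c(written, ap$manifest))
}

# Read a reconstruction CSV (as written by the reconstruct stage) back into
# an orientation_field.
read_field_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  d <- c(max(df$row), max(df$col))
  o <- order(df$col, df$row)
  axes <- array(c(df$ax[o], df$ay[o], df$az[o]), c(d[1], d[2], 3))
  orientation_field(axes, matrix(df$residual[o], d[1], d[2]),
                    matrix(df$valid[o] > 0, d[1], d[2]),
                    matrix(df$degenerate[o] > 0, d[1], d[2]))
}
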