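test_that("HDF5 write/load round-trips data and metadata", {
  set.seed(1)
  dat <- array(runif(4 * 4 * 16 * 16), c(4, 4, 16, 16))
  meta <- acq_meta(tilt_deg = 45, step_nm = 40, recip_pixel_inv_A = 0.02,
                   camera_shape = c(16L, 16L), beam_current_pA = 2,
                   dwell_ms = 5, beam_diameter_nm = 8)
  st <- frame_stack(dat, meta)
  h5 <- withr::local_tempfile(fileext = ".h5")
  write_framestack(st, h5)
  back <- load_framestack(h5)
  expect_identical(back$data, st$data)
  for (nm in c("tilt_deg", "step_nm", "recip_pixel_inv_A", "beam_current_pA",
               "dwell_ms", "beam_diameter_nm"))
    expect_equal(back$meta[[nm]], st$meta[[nm]])
  expect_equal(back$center, st$center)
})

test_that("missing optional metadata defaults with a warning; missing data errors", {
  h5 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(h5)
  rhdf5::h5createGroup(h5, "tilt_p00")
  rhdf5::h5write(array(1, c(2, 2, 8, 8)), h5, "tilt_p00/data")
  fid <- rhdf5::H5Fopen(h5); gid <- rhdf5::H5Gopen(fid, "tilt_p00")
  for (nm in c("step_nm", "recip_pixel_inv_A", "beam_current_pA", "dwell_ms",
               "beam_diameter_nm"))
    rhdf5::h5writeAttribute(1, gid, nm)
  rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  expect_warning(st <- load_framestack(h5), "tilt_deg")
  expect_equal(st$meta$tilt_deg, 0)

  h5b <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(h5b)
  rhdf5::h5createGroup(h5b, "tilt_p00")
  expect_error(load_framestack(h5b, "tilt_p00"),
               class = "sed3d_format_error")
  # truncated / non-HDF5 file
  bad <- withr::local_tempfile(fileext = ".h5")
  writeLines("not hdf5", bad)
  expect_error(load_framestack(bad), class = "sed3d_format_error")
})

test_that("reassemble_stream inverts a known shuffle and checks sizes", {
  set.seed(7)
  for (shape in list(c(2L, 2L), c(3L, 5L), c(4L, 4L))) {
    nr <- shape[1]; nc <- shape[2]; nf <- nr * nc
    frames <- array(0, c(nf, 6, 6))
    raster <- lapply(seq_len(nf), function(i) matrix(runif(36) + i, 6, 6))
    # per-frame shift linear in scan position (the beam-tilt signature)
    sx <- rep(seq_len(nc), times = nr) * 0.3
    sy <- rep(seq_len(nr), each = nc) * 1.1
    shuf <- sample(nf)
    for (k in seq_len(nf)) frames[k, , ] <- raster[[shuf[k]]]
    dm <- data.frame(shift_x = sx[shuf], shift_y = sy[shuf])
    st <- reassemble_stream(frames, shape, dm,
                            acq_meta(camera_shape = c(6L, 6L)))
    for (i in seq_len(nf)) {
      r <- (i - 1) %/% nc + 1; c_ <- (i - 1) %% nc + 1
      expect_identical(st$data[r, c_, , ], raster[[i]])
    }
  }
  # already-ordered stream with zero shifts: identity
  frames <- array(seq_len(4 * 4 * 4), c(4, 4, 4))
  dm0 <- data.frame(shift_x = rep(1:2, 2), shift_y = rep(1:2, each = 2))
  st0 <- reassemble_stream(frames, c(2L, 2L), dm0,
                           acq_meta(camera_shape = c(4L, 4L)))
  expect_identical(attr(st0, "stream_order"), 1:4)
  expect_error(reassemble_stream(array(0, c(17, 4, 4)), c(4L, 4L),
                                 data.frame(shift_x = 1:17, shift_y = 1:17),
                                 acq_meta(camera_shape = c(4L, 4L))),
               class = "sed3d_size_error")
})

test_that("center_patterns moves the beam to the detector centre and is idempotent", {
  shape <- c(32L, 32L)
  ctr <- (shape + 1) / 2
  fr <- spot_frame(shape, ctr[1] + 3, ctr[2] - 3, A = 50, sigma = 2)
  dat <- array(0, c(1, 2, 32, 32))
  dat[1, 1, , ] <- fr
  dat[1, 2, , ] <- 0   # dead frame
  st <- frame_stack(dat, acq_meta(camera_shape = shape))
  cst <- center_patterns(st, window_radius = 12)
  com <- sed3d:::com_in_window(cst$data[1, 1, , ], 12)
  expect_lt(sqrt(sum((com - ctr)^2)), 0.1)
  expect_false(cst$frame_valid[1, 2])
  expect_identical(cst$data[1, 2, , ], dat[1, 2, , ])
  # idempotence: second pass shifts by < 0.05 px
  cst2 <- center_patterns(cst, window_radius = 12)
  com2 <- sed3d:::com_in_window(cst2$data[1, 1, , ], 12)
  expect_lt(sqrt(sum((com2 - com)^2)), 0.05)
})

test_that("virtual_image sums regions and is additive over disjoint masks", {
  set.seed(3)
  dat <- array(runif(2 * 3 * 8 * 8), c(2, 3, 8, 8))
  st <- frame_stack(dat, acq_meta(camera_shape = c(8L, 8L)))
  full <- virtual_image(st)
  expect_equal(full$values, apply(dat, c(1, 2), sum))
  left <- matrix(FALSE, 8, 8); left[, 1:4] <- TRUE
  right <- !left
  expect_equal(virtual_image(st, left)$values + virtual_image(st, right)$values,
               full$values)
  expect_error(virtual_image(st, matrix(FALSE, 8, 8)),
               class = "sed3d_value_error")
})

test_that("annular virtual image lights up exactly where the phantom has fibrils", {
  ph <- three_layer_phantom(shape = c(16L, 16L), step_nm = 400)
  st <- render_patterns(ph, 0, ring_config(),
                        detector = list(shape = c(64L, 64L),
                                        recip_pixel_inv_A = 0.011),
                        noise = noise_spec(azimuth_sigma_deg = 0,
                                           background_level = 0,
                                           peak_snr = 40, seed = 2))
  ann <- virtual_image(st, list(r_inner_inv_A = 0.22, r_outer_inv_A = 0.30))
  expect_true(all(ann$values[ph$labels > 0] > 0))
  expect_true(all(ann$values[ph$labels == 0] == 0))
})

test_that("dose estimate matches the acquisition parameters and scales linearly", {
  m <- acq_meta(beam_current_pA = 2, dwell_ms = 5, beam_diameter_nm = 8)
  expect_equal(estimate_dose(m), 12.417, tolerance = 1e-3)
  m2 <- m; m2$beam_current_pA <- 4
  expect_equal(estimate_dose(m2), 2 * estimate_dose(m))
  m3 <- m; m3$dwell_ms <- 0
  expect_error(estimate_dose(m3), class = "sed3d_value_error")
})
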