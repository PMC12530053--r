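test_that("phantom layers carry the specified orientations and labels", {
  # constant-axis layers reproduce their spec exactly
  ph <- three_layer_phantom(shape = c(48L, 48L), step_nm = 150)
  for (i in 1:3) {
    idx <- which(ph$labels == i)
    expect_gt(length(idx), 0)
    np <- 48 * 48
    a <- axis_from_angles(ph$layers$in_plane_deg[i],
                          ph$layers$out_of_plane_deg[i])
    expect_equal(max(abs(ph$axes[idx] - a[1])), 0)
    expect_equal(max(abs(ph$axes[idx + np] - a[2])), 0)
  }
  # lumen and background carry label 0 and no axes
  expect_true(all(is.na(ph$axes[, , 1][ph$labels == 0])))
  # helical layers have constant out-of-plane magnitude equal to the spec
  hp <- oat_helical_phantom(shape = c(64L, 64L), step_nm = 330)
  tab <- oat_layer_orientations("transverse")
  for (i in c(1, 2)) {
    idx <- which(hp$labels == i)
    th <- acos(pmin(1, hp$axes[, , 3][idx])) * 180 / pi
    expect_equal(max(abs(th - abs(tab$out_of_plane_deg[i]))), 0,
                 tolerance = 1e-9)
  }
  # overlapping layers are rejected
  bad <- data.frame(r_in_um = c(1, 1.5), r_out_um = c(2, 2.5),
                    in_plane_deg = c(0, 0), out_of_plane_deg = c(10, 10))
  expect_error(make_phantom(bad, "annular", c(16L, 16L), 100),
               class = "sed3d_spec_error")
})

test_that("banded phantoms stack constant-axis bands", {
  layers <- data.frame(y_in_um = c(0.2, 1, 2), y_out_um = c(1, 2, 2.6),
                       in_plane_deg = c(155, 54, 147),
                       out_of_plane_deg = c(-67, -51, -61))
  ph <- make_phantom(layers, "bands", shape = c(30L, 10L), step_nm = 100)
  expect_equal(sort(unique(as.vector(ph$labels))), 0:3)
  row_labels <- ph$labels[, 1]
  expect_true(all(diff(row_labels[row_labels > 0]) >= 0))
})

test_that("forward azimuth is adjoint to back-rotation", {
  set.seed(14)
  worst <- 0
  for (k in 1:10000) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    w <- runif(1, -80, 80)
    phi <- forward_azimuth(a, w)
    if (is.na(phi)) next
    worst <- max(worst, abs(sum(back_rotate(qvec_from_azimuth(phi), w) * a)))
  }
  expect_lt(worst, 1e-12)
})

test_that("zero-y axes give azimuth 90 at every tilt; beam-parallel axes none", {
  for (th in c(20, 50, 80)) {
    a <- axis_from_angles(0, th)   # a_y = 0 exactly
    for (w in c(0, 45, -45, 17.3))
      expect_identical(forward_azimuth(a, w), 90)
  }
  expect_true(is.na(forward_azimuth(c(0, 0, 1), 0)))
  expect_equal(forward_azimuth(c(1, 0, 0), 0), 90)
})

test_that("azimuth-map simulation is deterministic for a fixed seed", {
  ph <- three_layer_phantom()
  m1 <- simulate_azimuth_maps(ph, c(0, 45, -45),
                              noise_spec(azimuth_sigma_deg = 3, seed = 21))
  m2 <- simulate_azimuth_maps(ph, c(0, 45, -45),
                              noise_spec(azimuth_sigma_deg = 3, seed = 21))
  expect_identical(m1[[2]]$phi_deg, m2[[2]]$phi_deg)
  expect_identical(attr(m1, "seed"), 21)
  m3 <- simulate_azimuth_maps(ph, c(0, 45, -45),
                              noise_spec(azimuth_sigma_deg = 3, seed = 22))
  expect_false(identical(m1[[2]]$phi_deg, m3[[2]]$phi_deg))
})

test_that("noiseless simulation round-trips through the reconstruction", {
  ph <- oat_helical_phantom(shape = c(64L, 64L), step_nm = 330)
  maps <- simulate_azimuth_maps(ph, c(0, 45, -45),
                                noise_spec(azimuth_sigma_deg = 0, seed = 2),
                                foreshorten = FALSE)
  fld <- reconstruct_field(tilt_series(maps))
  err <- field_vs_phantom_err(fld, ph)
  expect_gte(mean(err < 0.5), 0.99)
})

test_that("rendered degenerate pixels give flat ring profiles below threshold", {
  # axis along the beam: whole ring excited, no defined azimuth
  layers <- data.frame(r_in_um = 0, r_out_um = 3, in_plane_deg = 0,
                       out_of_plane_deg = 0)
  ph <- make_phantom(layers, "annular", shape = c(4L, 4L), step_nm = 400)
  cfg <- ring_config()
  st <- render_patterns(ph, 0, cfg,
                        detector = list(shape = c(64L, 64L),
                                        recip_pixel_inv_A = 0.011),
                        noise = noise_spec(azimuth_sigma_deg = 0,
                                           background_level = 1,
                                           peak_snr = 30, seed = 4))
  am <- azimuth_map(st, cfg)
  expect_true(all(!am$valid))
})

test_that("rendered frames round-trip through azimuth extraction", {
  ph <- three_layer_phantom(shape = c(24L, 24L), step_nm = 280)
  cfg <- ring_config()
  st <- render_patterns(ph, 0, cfg,
                        detector = list(shape = c(64L, 64L),
                                        recip_pixel_inv_A = 0.011),
                        noise = noise_spec(azimuth_sigma_deg = 0,
                                           background_level = 1,
                                           peak_snr = 30, seed = 6))
  am <- azimuth_map(st, cfg)
  truth <- matrix(sed3d:::forward_azimuth_vec(
    as.vector(ph$axes[, , 1]), as.vector(ph$axes[, , 2]),
    as.vector(ph$axes[, , 3]), 0), 24, 24)
  cmp <- am$valid & !is.na(truth)
  d <- abs(am$phi_deg[cmp] - truth[cmp]) %% 180
  d <- pmin(d, 180 - d)
  expect_lt(stats::median(d), 1)
})
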