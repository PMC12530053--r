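test_that("axis/angle conversions follow the beam-referenced convention", {
  a <- angles_from_axis(c(0, 0, 1))
  expect_equal(a$out_of_plane_deg, 0)  # along the beam
  b <- angles_from_axis(c(1, 0, 0))
  expect_equal(b$in_plane_deg, 0)
  expect_equal(abs(b$out_of_plane_deg), 90)
  expect_true(b$zero_y)
  # published-layer worked example round-trips
  ax <- axis_from_angles(33, 56)
  r <- angles_from_axis(ax)
  expect_equal(r$in_plane_deg, 33)
  expect_equal(r$out_of_plane_deg, 56)
  # sign rule: negative theta means negative y-component
  ax2 <- axis_from_angles(47, -61)
  expect_lt(ax2[2], 0)
  expect_equal(ax2[3], cos(61 * pi / 180))
  expect_equal(axis_from_angles(0, 0), c(0, 0, 1))
})

test_that("angle round-trip is the identity off the zero-y set", {
  set.seed(12)
  for (k in 1:200) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    if (v[3] < 0) v <- -v
    if (abs(v[2]) < 1e-9) next
    ang <- angles_from_axis(v)
    expect_equal(axis_from_angles(ang$in_plane_deg, ang$out_of_plane_deg), v,
                 tolerance = 1e-9)
  }
})

test_that("orientation relationship is symmetric, bounded, sign-invariant", {
  set.seed(13)
  for (k in 1:50) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    b <- rnorm(3); b <- b / sqrt(sum(b^2))
    r <- orientation_relationship(a, b)
    expect_gte(r, 0); expect_lte(r, 90)
    expect_equal(orientation_relationship(b, a), r)
    expect_equal(orientation_relationship(-a, b), r)
    expect_equal(orientation_relationship(a, -b), r)
  }
  expect_equal(orientation_relationship(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(orientation_relationship(c(1, 0, 0), c(0, 0, 1)), 90)
})

test_that("interlayer relationships reproduce the published oat husk values", {
  # longitudinal section: three consecutive pairs average to 77 degrees
  t2 <- oat_layer_orientations("longitudinal")
  r2 <- interlayer_relationship(t2)
  expect_equal(round(r2$mean_deg), 77)
  # transverse section, opposite-handed pairs excluding the thin layer 5
  t1 <- oat_layer_orientations("transverse")
  r1 <- interlayer_relationship(t1, pairs = list(c(1, 2), c(2, 3), c(3, 4),
                                                 c(6, 7)))
  expect_equal(round(r1$mean_deg), 60)
})

test_that("layer_stats computes circular in-plane and arithmetic out-of-plane means", {
  # constant-orientation region
  axes <- array(NA_real_, c(1, 4, 3))
  a <- axis_from_angles(33, 56)
  for (j in 1:4) axes[1, j, ] <- a
  fld <- orientation_field(axes, matrix(0, 1, 4), matrix(TRUE, 1, 4),
                           matrix(FALSE, 1, 4))
  st <- layer_stats(fld, matrix(1L, 1, 4))
  expect_equal(st$in_plane_deg, 33, tolerance = 1e-9)
  expect_equal(st$out_of_plane_deg, 56, tolerance = 1e-9)
  expect_equal(st$in_plane_sd, 0, tolerance = 1e-6)
  expect_equal(st$handedness, "left")
  # wrap handling: {179, 1} averages to 0, not 90
  axes2 <- array(NA_real_, c(1, 2, 3))
  axes2[1, 1, ] <- axis_from_angles(179, 50)
  axes2[1, 2, ] <- axis_from_angles(1, 50)
  fld2 <- orientation_field(axes2, matrix(0, 1, 2), matrix(TRUE, 1, 2),
                            matrix(FALSE, 1, 2))
  st2 <- layer_stats(fld2, matrix(1L, 1, 2))
  expect_equal(st2$in_plane_deg, 0, tolerance = 1e-9)
  # a region with no usable pixels reports n = 0 and undefined means
  fld3 <- orientation_field(axes2, matrix(0, 1, 2),
                            matrix(c(TRUE, FALSE), 1, 2),
                            matrix(FALSE, 1, 2))
  st3 <- layer_stats(fld3, matrix(c(1L, 2L), 1, 2))
  expect_equal(st3$n_pixels[st3$label == 2], 0L)
  expect_true(is.na(st3$in_plane_deg[st3$label == 2]))
})

test_that("averaging the published left-handed layers gives the printed summary", {
  t1 <- oat_layer_orientations("transverse")
  lh <- which(t1$handedness == "left" & t1$layer != 5)
  rh <- which(t1$handedness == "right")
  axes <- array(NA_real_, c(1, 7, 3))
  for (i in 1:7) axes[1, i, ] <- axis_from_angles(t1$in_plane_deg[i],
                                                  t1$out_of_plane_deg[i])
  regions <- matrix(0L, 1, 7)
  regions[1, lh] <- 1L; regions[1, rh] <- 2L
  fld <- orientation_field(axes, matrix(0, 1, 7), matrix(TRUE, 1, 7),
                           matrix(FALSE, 1, 7))
  st <- layer_stats(fld, regions)
  expect_equal(round(st$in_plane_deg[st$label == 1]), 29)
  expect_equal(round(st$out_of_plane_deg[st$label == 1]), 60)
  expect_equal(round(st$in_plane_deg[st$label == 2]), 45)
  expect_equal(round(st$out_of_plane_deg[st$label == 2]), -63)
  expect_equal(st$handedness, c("left", "right"))
})

test_that("handedness classification is axis-sign invariant", {
  z <- c(0, 0, 1); r <- c(1, 0, 0)
  tangent <- c(0, 1, 0)  # z x r
  right <- (tangent + z) / sqrt(2)
  left <- (tangent - z) / sqrt(2)
  expect_equal(classify_handedness(right, z, r), "right")
  expect_equal(classify_handedness(left, z, r), "left")
  expect_equal(classify_handedness(tangent, z, r), "indeterminate")
  expect_equal(classify_handedness(-right, z, r), "right")
  expect_equal(classify_handedness(-left, z, r), "left")
  # simultaneous flip of the frame preserves the label
  expect_equal(classify_handedness(right, -z, r), "right")
  expect_error(classify_handedness(right, z, c(0.9, 0, 0.44)),
               class = "sed3d_geometry_error")
})

test_that("helix pitch follows from angle and circumference", {
  expect_equal(helix_pitch(45, 10), 10)
  expect_lt(helix_pitch(89.9, 10), 0.02)     # near-hoop winding
  expect_gt(helix_pitch(0.1, 10), 5000)      # near-axial winding
  expect_error(helix_pitch(90, 10), class = "sed3d_value_error")
  expect_error(helix_pitch(0, 10), class = "sed3d_value_error")
  expect_error(helix_pitch(45, 0), class = "sed3d_value_error")
})
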