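test_that("q-vector construction and back-rotation follow the tilt geometry", {
  expect_equal(qvec_from_azimuth(0), c(1, 0, 0))
  expect_equal(qvec_from_azimuth(90), c(0, 1, 0), tolerance = 1e-15)
  expect_equal(qvec_from_azimuth(30), -qvec_from_azimuth(210), tolerance = 1e-12)
  expect_equal(back_rotate(c(0.3, 0.8, 0.52), 0), c(0.3, 0.8, 0.52))
  # the tilt axis (y) is invariant
  for (w in c(-45, 10, 45)) expect_equal(back_rotate(c(0, 1, 0), w), c(0, 1, 0))
  # Ry(-45) applied to x-hat, evaluated from the rotation matrix
  expect_equal(back_rotate(c(1, 0, 0), 45),
               c(cos(pi / 4), 0, sin(pi / 4)), tolerance = 1e-12)
})

test_that("two orthogonal measurements solve exactly via the cross product", {
  est <- axis_from_two(c(1, 0, 0), c(0, 1, 0))
  expect_equal(est$a_hat, c(0, 0, 1))
  expect_equal(est$residual, 0)
  expect_true(axis_from_two(c(1, 0, 0), c(1, 0, 0))$degenerate)
  set.seed(3)
  for (k in 1:20) {
    q1 <- rnorm(3); q1 <- q1 / sqrt(sum(q1^2))
    q2 <- rnorm(3); q2 <- q2 / sqrt(sum(q2^2))
    est <- axis_from_two(q1, q2)
    if (est$degenerate) next
    expect_lt(abs(sum(est$a_hat * q1)), 1e-12)
    expect_lt(abs(sum(est$a_hat * q2)), 1e-12)
    expect_gte(est$a_hat[3], 0)
  }
})

test_that("averaged projections matches the cross product for N = 2", {
  set.seed(5)
  for (k in 1:20) {
    q1 <- rnorm(3); q1 <- q1 / sqrt(sum(q1^2))
    q2 <- rnorm(3); q2 <- q2 / sqrt(sum(q2^2))
    cp <- axis_from_two(q1, q2)
    if (cp$degenerate) next
    ap <- averaged_projections(rbind(q1, q2))
    expect_lt(min(sqrt(sum((ap$a_hat - cp$a_hat)^2)),
                  sqrt(sum((ap$a_hat + cp$a_hat)^2))), 1e-8)
  }
})

test_that("averaged projections equals the smallest scatter eigenvector", {
  set.seed(42)
  worst <- 0
  for (k in 1:100) {
    n <- sample(3:10, 1)
    Q <- matrix(rnorm(3 * n), n)
    Q <- Q / sqrt(rowSums(Q^2))
    ap <- averaged_projections(Q)
    if (ap$degenerate) next
    S <- crossprod(Q) / n
    v <- eigen(S, symmetric = TRUE)$vectors[, 3]
    worst <- max(worst, acos(min(1, abs(sum(ap$a_hat * v)))))
  }
  expect_lt(worst, 1e-6)
})

test_that("averaged projections recovers a known axis from its tilt azimuths", {
  a <- c(0.6, 0.64, 0.48); a <- a / sqrt(sum(a^2))
  Q <- t(sapply(c(0, 45, -45), function(w)
    back_rotate(qvec_from_azimuth(forward_azimuth(a, w)), w)))
  est <- averaged_projections(Q)
  expect_lt(acos(min(1, abs(sum(est$a_hat * a)))), 1e-6)
  expect_lt(est$residual, 1e-8)
})

test_that("the solution is invariant to flipping the sign of any q", {
  set.seed(8)
  Q <- matrix(rnorm(12), 4); Q <- Q / sqrt(rowSums(Q^2))
  base <- averaged_projections(Q)$a_hat
  for (i in 1:4) {
    Qf <- Q; Qf[i, ] <- -Qf[i, ]
    expect_lt(acos(min(1, abs(sum(averaged_projections(Qf)$a_hat * base)))),
              1e-8)
  }
  # the verbatim (absolute-value) projection form is NOT sign-invariant,
  # which is why the signed form is the default
  Qv <- Q; Qv[2, ] <- -Qv[2, ]
  v1 <- averaged_projections(Q, verbatim_projection = TRUE)
  expect_s3_class(v1, "axis_estimate")
})

test_that("reconstruct_field recovers a constant-axis phantom and flags zero-y pixels", {
  # constant-axis region plus a zero-y region in one field
  layers <- data.frame(r_in_um = c(0.2, 1.3), r_out_um = c(1.2, 2.3),
                       in_plane_deg = c(46.85, 0),
                       out_of_plane_deg = c(61.3, 80))
  ph <- make_phantom(layers, "annular", shape = c(48L, 48L), step_nm = 100)
  maps <- simulate_azimuth_maps(ph, c(0, 45, -45),
                                noise_spec(azimuth_sigma_deg = 0, seed = 3),
                                foreshorten = FALSE)
  fld <- reconstruct_field(tilt_series(maps))
  in1 <- ph$labels == 1
  in2 <- ph$labels == 2   # axis [sin80, 0, cos80]: a_y = 0 exactly
  expect_true(all(fld$valid[in1 | in2]))
  expect_true(all(!fld$degenerate[in1]))
  expect_true(all(fld$degenerate[in2]))
  # zero-y pixels show azimuth 90 at every tilt, exactly
  for (w in c(0, 45, -45))
    expect_true(all(maps[[1]]$phi_deg[in2] == 90))
  err <- field_vs_phantom_err(fld, ph)
  expect_true(all(err < 1e-4))
  # all returned axes are unit norm in the upper hemisphere
  np <- 48 * 48
  idx <- which(fld$valid & !fld$degenerate)
  nrm <- sqrt(fld$axes[idx]^2 + fld$axes[idx + np]^2 + fld$axes[idx + 2 * np]^2)
  expect_equal(max(abs(nrm - 1)), 0, tolerance = 1e-9)
  expect_true(all(fld$axes[idx + 2 * np] >= 0))
})

test_that("pixels observed at fewer than two tilts are invalid", {
  phi <- matrix(85, 4, 4)
  v1 <- matrix(TRUE, 4, 4)
  v2 <- matrix(TRUE, 4, 4); v2[1, 1] <- FALSE
  v3 <- matrix(FALSE, 4, 4); v3[2, 2] <- TRUE
  maps <- list(azimuth_map_obj(phi, phi, v1, 0),
               azimuth_map_obj(phi + 3, phi, v2, 45),
               azimuth_map_obj(phi - 3, phi, v3, -45))
  fld <- reconstruct_field(tilt_series(maps))
  expect_true(fld$valid[2, 2])   # three tilts
  expect_true(fld$valid[1, 2])   # two tilts
  expect_false(fld$valid[1, 1])  # only the zero-tilt measurement remains
})
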