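test_that("a stress-free film rasterizes at full length in every frame", {
  sp <- default_spec()
  px <- sp$free_length_L / 500
  tr <- make_stress_trace(1, 0, 0, 2, 100)      # zero stress throughout
  mv <- render_cantilever_movie(tr, sp,
                                rows = 10, cols = 520, pixel_size = px,
                                noise_sd = 0, seed = 1)
  extents <- apply(mv$frames, 3, function(f) sum(colSums(f) > 0))
  expect_true(all(extents == round(sp$free_length_L / px)))
  expect_equal(mv$kind, "binary_mask")
})

test_that("cantilever rendering is deterministic under a fixed seed", {
  sp <- default_spec()
  tr <- make_stress_trace(1, 1e3, 5e3, 3, 100)
  a <- render_cantilever_movie(tr, sp, 12, 516, sp$free_length_L / 500,
                               noise_sd = 0.1, seed = 99)
  b <- render_cantilever_movie(tr, sp, 12, 516, sp$free_length_L / 500,
                               noise_sd = 0.1, seed = 99)
  expect_identical(a$frames, b$frames)
})

test_that("over-curled or under-resolved films are rejected", {
  sp <- default_spec()
  # 10 kPa -> kappa*L > pi with the default mechanics
  tr <- make_stress_trace(1, 1e3, 9e3, 2, 100)
  expect_error(
    render_cantilever_movie(tr, sp, 10, 520, sp$free_length_L / 500,
                            noise_sd = 0, seed = 1),
    "over-curl")
  tr2 <- make_stress_trace(1, 1e3, 5e3, 2, 100)
  expect_error(
    render_cantilever_movie(tr2, sp, 10, 4, sp$free_length_L,
                            noise_sd = 0, seed = 1),
    "2 pixels")
  expect_error(
    render_cantilever_movie(tr2, sp, 10, 100, sp$free_length_L / 500,
                            noise_sd = 0, seed = 1),
    "field of view")
})

test_that("noise-free render/analyze round trip recovers the stress to 2% RMS", {
  sp <- default_spec()
  px <- sp$free_length_L / 500
  tr <- make_stress_trace(0.7, 1e3, 6e3, 10, 100)   # kappa*L in [0.32, 2.27]
  mv <- render_cantilever_movie(tr, sp, 12, 516, px, noise_sd = 0, seed = 1)
  rec <- extract_stress_trace(mv, sp)
  rms_rel <- sqrt(mean((rec$stress - tr$stress)^2)) / sqrt(mean(tr$stress^2))
  expect_lt(rms_rel, 0.02)
})

test_that("edge activation field is planar with the prescribed speed", {
  f <- make_activation_field(20, 40, 1e-4, "edge", c(1, 1), 0.042)
  # T(x, y) = x / v, x measured in m from the source edge
  expect_equal(f$T[7, 11], 10 * 1e-4 / 0.042)
  expect_equal(f$T[, 1], rep(0, 20))
  expect_true(all(diff(t(f$T)[, 3]) > 0))
  # doubling the speed halves every activation time
  f2 <- make_activation_field(20, 40, 1e-4, "edge", c(1, 1), 0.084)
  expect_equal(f2$T, f$T / 2)
})

test_that("point activation field is radial and zero at the source", {
  f <- make_activation_field(21, 41, 1e-4, "point", c(11, 21), 0.04)
  expect_equal(f$T[11, 21], 0)
  expect_equal(f$T[11, 31], 10 * 1e-4 / 0.04)      # 10 px along the axis
  # symmetric about the source
  expect_equal(f$T[11, 21 + 7], f$T[11, 21 - 7])
  expect_equal(f$T[11 + 5, 21], f$T[11 - 5, 21])
  expect_error(make_activation_field(10, 10, 1e-4, "point", c(5, 5), 0),
               "speed")
  expect_error(make_activation_field(10, 10, 1e-4, "edge", c(4, 5), 1))
})

test_that("activation fields satisfy |grad T| = 1/v off the source", {
  px <- 1e-4
  for (kind in c("edge", "point")) {
    loc <- if (kind == "edge") c(1, 1) else c(15, 25)
    f <- make_activation_field(30, 50, px, kind, loc, 0.042)
    gx <- (f$T[, 3:50] - f$T[, 1:48]) / (2 * px)
    gy <- (f$T[3:30, ] - f$T[1:28, ]) / (2 * px)
    gmag <- sqrt(gx[2:29, ]^2 + gy[, 2:49]^2)
    # keep interior pixels at least 5 px from a point source
    if (kind == "point") {
      d <- sqrt((row(gmag) + 1 - loc[1])^2 + (col(gmag) + 1 - loc[2])^2)
      gmag <- gmag[d > 5]
    }
    expect_lt(max(abs(gmag - 1 / 0.042) * 0.042), 0.01)
  }
})

test_that("calcium rendering peaks at F0 + dF and respects activation order", {
  f <- make_activation_field(5, 20, 1e-4, "edge", c(1, 1), 0.02)
  mv <- render_calcium_movie(f, frame_rate = 100, n_beats = 1,
                             beat_period = 1, rise_time = 0.02,
                             decay_tau = 0.1, baseline_F0 = 100,
                             amplitude_dF = 50, noise_sd = 0, seed = 1)
  # source pixel activates at t = 0; rise_time = 2 frames lands on the grid
  expect_equal(max(mv$frames[1, 1, ]), 150)
  expect_equal(min(mv$frames), 100)
  # upstroke midpoints are ordered like the ground-truth activation times
  half_cross <- apply(mv$frames[3, , ], 1, function(y) which(y >= 125)[1])
  expect_true(all(diff(half_cross) >= 0))
  expect_equal(order(half_cross), order(f$T[3, ]))
})

test_that("calcium rendering is deterministic and warns on heavy clipping", {
  f <- make_activation_field(6, 8, 1e-4, "edge", c(1, 1), 0.02)
  a <- render_calcium_movie(f, frame_rate = 200, n_beats = 1, noise_sd = 2,
                            seed = 5)
  b <- render_calcium_movie(f, frame_rate = 200, n_beats = 1, noise_sd = 2,
                            seed = 5)
  expect_identical(a$frames, b$frames)
  expect_warning(
    render_calcium_movie(f, frame_rate = 200, n_beats = 1, baseline_F0 = 1,
                         amplitude_dF = 1, noise_sd = 2, seed = 5),
    "clipped")
})

test_that("orientation sampler hits degenerate limits and is seeded", {
  # enormous concentration: all angles collapse onto the mean
  os <- sample_orientations(50, 20, 1e7, seed = 3)
  expect_lt(max(abs(os$angles - 20)), 0.5)
  # zero concentration: uniform axial -> tiny resultant length at large n
  os0 <- sample_orientations(20000, 0, 0, seed = 4)
  expect_lt(circular_summary(os0)$resultant_length, 0.05)
  expect_identical(sample_orientations(100, 8.89, 11.5, seed = 7)$angles,
                   sample_orientations(100, 8.89, 11.5, seed = 7)$angles)
  expect_true(all(os0$angles >= -90 & os0$angles < 90))
})
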