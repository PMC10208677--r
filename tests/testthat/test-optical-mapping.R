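test_that("3x3 mean filter preserves constants and spreads an impulse", {
  const <- movie(array(7, c(6, 9, 2)), 400, 1e-4, "fluorescence")
  expect_equal(spatial_filter(const)$frames, const$frames)

  imp <- array(0, c(9, 9, 2)); imp[5, 5, ] <- 1
  sf <- spatial_filter(movie(imp, 400, 1e-4, "fluorescence"))
  expect_equal(sf$frames[4:6, 4:6, 1], matrix(1 / 9, 3, 3))
  expect_equal(sum(sf$frames[, , 1]), 1)   # interior impulse conserves mass

  tiny <- movie(array(1, c(2, 5, 2)), 400, 1e-4, "fluorescence")
  expect_error(spatial_filter(tiny), "3 x 3")
})

test_that("filter output matches a direct reflect-padded summation oracle", {
  set.seed(31)
  fr <- matrix(runif(64), 8, 8)
  sf <- spatial_filter(movie(array(rep(fr, 2), c(8, 8, 2)), 400, 1e-4,
                             "fluorescence"))
  refl <- function(i, n) pmin(pmax(i, 1), n)  # edge reflection index
  oracle <- matrix(0, 8, 8)
  for (r in 1:8) for (c in 1:8) {
    acc <- 0
    for (dr in -1:1) for (dc in -1:1) {
      acc <- acc + fr[refl(r + dr, 8), refl(c + dc, 8)]
    }
    oracle[r, c] <- acc / 9
  }
  expect_equal(sf$frames[, , 1], oracle)
})

test_that("dF/F normalization is exact, scale-free and baseline-safe", {
  fr <- array(100, c(4, 4, 10)); fr[2, 3, 6] <- 150
  mv <- movie(fr, 400, 1e-4, "fluorescence")
  dff <- normalize_dff(mv)
  expect_equal(max(dff$frames), 0.5)
  expect_equal(dff$frames[1, 1, ], rep(0, 10))   # constant pixel -> zeros
  # multiplying the movie by 3 leaves dF/F unchanged
  dff3 <- normalize_dff(movie(3 * fr, 400, 1e-4, "fluorescence"))
  expect_equal(dff3$frames, dff$frames)
  # zero-baseline pixel is masked with a warning
  fr0 <- fr; fr0[1, 2, ] <- 0
  expect_warning(d0 <- normalize_dff(movie(fr0, 400, 1e-4, "fluorescence")),
                 "baseline")
  expect_true(attr(d0, "baseline_masked")[1, 2])
  expect_equal(d0$frames[1, 2, ], rep(0, 10))
})

test_that("beat segmentation returns one disjoint ordered window per beat", {
  fx <- calcium_fixture("edge", 0.042, seed = 12, rows = 8, cols = 20,
                        noise_frac = 0)
  dff <- normalize_dff(spatial_filter(fx$movie))
  w <- segment_beats(dff)
  expect_length(w, 3)
  lens <- vapply(w, function(x) x[2] - x[1] + 1L, integer(1))
  expect_true(all(abs(lens - 400) <= 210))   # ~400 frames per 1 Hz beat
  starts <- vapply(w, `[`, integer(1), 1)
  ends <- vapply(w, `[`, integer(1), 2)
  expect_true(all(starts[-1] > ends[-3]))    # disjoint, ordered
  # snapped windows are exactly one period long away from the edges
  ws <- segment_beats(dff, pacing_frequency = 1)
  expect_length(ws, 3)
  expect_equal(ws[[2]][2] - ws[[2]][1] + 1L, 400L)
})

test_that("single-beat movies yield one window spanning the movie", {
  fx <- calcium_fixture("edge", 0.042, seed = 13, rows = 8, cols = 20,
                        noise_frac = 0, n_beats = 1)
  dff <- normalize_dff(fx$movie)
  w <- segment_beats(dff)
  expect_length(w, 1)
  expect_equal(w[[1]], c(1L, 400L))
})

test_that("activation times hit analytic markers for steps and ramps", {
  # step 0 -> 1 at frame 11 (t0 = 0.025 s at 400 fps)
  fr <- array(0, c(4, 4, 40)); fr[, , 11:40] <- 1
  mv <- movie(fr, 400, 1e-4, "dff")
  am <- activation_times(mv, c(1, 40))
  expect_lte(max(abs(am$T - 10 / 400)), 0.501 / 400)  # within half a frame
  amd <- activation_times(mv, c(1, 40), method = "max_derivative")
  expect_lt(max(abs(amd$T - 10 / 400)), 1.01 / 400)
  # linear ramp over frames 11..21 -> half-amplitude at the midpoint
  ramp <- array(0, c(4, 4, 40))
  for (j in 11:21) ramp[, , j] <- (j - 11) / 10
  ramp[, , 22:40] <- 1
  am2 <- activation_times(movie(ramp, 400, 1e-4, "dff"), c(1, 40))
  expect_equal(am2$T, matrix(15 / 400, 4, 4), tolerance = 1e-10)
  expect_error(activation_times(mv, c(10, 10)), "empty")
})

test_that("low-amplitude pixels are invalidated", {
  fr <- array(0, c(3, 3, 20)); fr[, , 11:20] <- 1
  fr[2, 2, ] <- 0.01 * fr[2, 2, ]       # 1% of the median amplitude
  am <- activation_times(movie(fr, 400, 1e-4, "dff"), c(1, 20))
  expect_false(am$valid[2, 2])
  expect_true(all(am$valid[-5]))
})

test_that("activation map shifts exactly with a time shift of the movie", {
  fx <- calcium_fixture("edge", 0.042, seed = 14, rows = 8, cols = 20,
                        noise_frac = 0, n_beats = 1)
  k <- 30
  d <- dim(fx$movie$frames)
  shifted <- array(fx$movie$frames[, , 1], c(d[1], d[2], d[3] + k))
  shifted[, , (k + 1):(d[3] + k)] <- fx$movie$frames
  mv2 <- movie(shifted, 400, 1e-4, "fluorescence")
  a1 <- activation_times(normalize_dff(spatial_filter(fx$movie)), c(1, 200))
  a2 <- activation_times(normalize_dff(spatial_filter(mv2)), c(1 + k, 200 + k))
  expect_equal(a2$T, a1$T + k / 400, tolerance = 1e-8)
})

test_that("conduction velocity recovers analytic plane and radial waves", {
  px <- 1e-4
  # plane wave along +x at 4.2 cm/s
  T <- matrix(rep((0:29) * px / 0.042, each = 20), 20, 30)
  vf <- conduction_velocity(as_activation_map(T, px))
  expect_equal(vf$mean_speed, 0.042, tolerance = 0.01)
  expect_true(all(vf$vx[vf$valid] > 0))
  # radial wave: speed = v everywhere off the source disc
  f <- make_activation_field(31, 51, px, "point", c(16, 26), 0.04)
  vr <- conduction_velocity(as_activation_map(f$T, px))
  d <- sqrt((row(f$T) - 16)^2 + (col(f$T) - 26)^2)
  far <- vr$valid & d > 4
  expect_equal(unname(stats::median(vr$speed[far])), 0.04, tolerance = 0.01)
  # constant map: no propagating front
  expect_error(conduction_velocity(as_activation_map(T * 0 + 1, px)),
               "no propagating front")
})

test_that("speed is invariant to time offsets and 90-degree rotation", {
  px <- 1e-4
  f <- make_activation_field(20, 30, px, "edge", c(1, 1), 0.03)
  v1 <- conduction_velocity(as_activation_map(f$T, px))
  v2 <- conduction_velocity(as_activation_map(f$T + 5, px))
  expect_equal(v1$speed, v2$speed)
  rot <- t(f$T)[ncol(f$T):1, ]            # rotate the map 90 degrees
  v3 <- conduction_velocity(as_activation_map(rot, px))
  expect_equal(v3$median_speed, v1$median_speed, tolerance = 1e-10)
})

test_that("plane-wave oracle: random angles and speeds recovered to 1%", {
  set.seed(77)
  px <- 1e-4
  for (i in 1:50) {
    ang <- runif(1, 0, 2 * pi)
    v <- runif(1, 0.01, 0.10)
    X <- (col(matrix(0, 20, 30)) - 1) * px
    Y <- (row(matrix(0, 20, 30)) - 1) * px
    T <- (cos(ang) * X + sin(ang) * Y) / v + 0.3
    vf <- conduction_velocity(as_activation_map(T, px))
    expect_equal(vf$mean_speed, v, tolerance = 0.01)
    dir <- atan2(mean(vf$vy[vf$valid]), mean(vf$vx[vf$valid]))
    err <- abs(atan2(sin(dir - ang), cos(dir - ang))) * 180 / pi
    expect_lt(err, 2)
  }
})

test_that("wavefront counting distinguishes edge, point and double sources", {
  px <- 1e-4
  edge <- make_activation_field(20, 60, px, "edge", c(1, 1), 0.042)
  we <- count_wavefronts(as_activation_map(edge$T, px))
  expect_equal(we$n_origins, 1)
  expect_equal(we$n_fronts, 1L)
  expect_equal(we$classification, "edge wave")
  expect_lte(we$origin_positions, 3)

  pt <- make_activation_field(20, 60, px, "point", c(10, 30), 0.039)
  wp <- count_wavefronts(as_activation_map(pt$T, px))
  expect_equal(wp$n_origins, 1)
  expect_equal(wp$n_fronts, 2L)
  expect_equal(wp$classification, "point-source double wave")
  expect_equal(wp$origin_positions, 30, tolerance = 2)

  # two synchronized sources at 1/4 and 3/4 of the axis
  p1 <- make_activation_field(20, 60, px, "point", c(10, 15), 0.04)
  p2 <- make_activation_field(20, 60, px, "point", c(10, 45), 0.04)
  both <- pmin(p1$T, p2$T)
  wb <- count_wavefronts(as_activation_map(both, px))
  expect_equal(wb$n_origins, 2)
  expect_equal(wb$classification, "multiple sources")
})

test_that("full pipeline stays within 5% at 10% dF noise", {
  fx <- calcium_fixture("edge", 0.042, seed = 15, noise_frac = 0.10)
  res <- analyze_calcium_movie(fx$movie, pacing_frequency = 1)
  expect_equal(res$velocity$median_speed, 0.042, tolerance = 0.05)
  expect_equal(res$n_beats, 3)
  expect_equal(res$wavefronts$classification, "edge wave")
})
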