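# pad a matrix by one pixel with edge reflection
pad_reflect1 <- function(a) {
  nr <- nrow(a); nc <- ncol(a)
  a2 <- a[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  a2
}

#' 3 x 3 spatial mean filter
#'
#' Per-frame 3 x 3 uniform mean filter to improve the signal-to-noise ratio
#' of fluorescence movies before activation detection. Borders are handled
#' by edge reflection, so a constant image is exactly preserved.
#'
#' @param m A fluorescence [movie()], at least 3 x 3 pixels.
#' @return A filtered [movie()] with the same frame count.
#' @export
spatial_filter <- function(m) {
  stopifnot(inherits(m, "movie"))
  d <- dim(m$frames)
  if (d[1] < 3 || d[2] < 3) stop("movie smaller than the 3 x 3 filter")
  out <- array(0, d)
  ri <- seq_len(d[1]) + 1L; ci <- seq_len(d[2]) + 1L
  for (j in seq_len(d[3])) {
    p <- pad_reflect1(m$frames[, , j])
    acc <- matrix(0, d[1], d[2])
    for (dr in -1:1) for (dc in -1:1) {
      acc <- acc + p[ri + dr, ci + dc]
    }
    out[, , j] <- acc / 9
  }
  movie(out, m$frame_rate, m$pixel_size, m$kind)
}

#' Normalize a fluorescence movie to per-pixel Delta F / F0
#'
#' Each pixel's baseline `F0` is a low percentile of its own trace
#' (default 10th); the output trace is `(F - F0) / F0`. Pixels whose
#' baseline is non-positive cannot be normalized and are set to zero with a
#' warning.
#'
#' @param m A fluorescence [movie()].
#' @param baseline_percentile Percentile (0-100) used for `F0`.
#' @return A [movie()] of kind `"dff"` (signed: noise dips below baseline).
#'   Pixels with a non-positive baseline carry no usable signal; they are
#'   zeroed, recorded in the `baseline_masked` attribute, and excluded from
#'   downstream activation maps.
#' @export
normalize_dff <- function(m, baseline_percentile = 10) {
  stopifnot(inherits(m, "movie"))
  d <- dim(m$frames)
  fmat <- matrix(aperm(m$frames, c(3, 1, 2)), d[3], d[1] * d[2])
  f0 <- apply(fmat, 2, stats::quantile, probs = baseline_percentile / 100,
              names = FALSE)
  bad <- f0 <= 0
  if (any(bad)) {
    warning(sprintf("%d pixel(s) with non-positive baseline masked out",
                    sum(bad)))
    f0[bad] <- 1
  }
  dff <- sweep(sweep(fmat, 2, f0, "-"), 2, f0, "/")
  dff[, bad] <- 0
  out <- movie(aperm(array(dff, c(d[3], d[1], d[2])), c(2, 3, 1)),
               m$frame_rate, m$pixel_size, "dff")
  attr(out, "baseline_masked") <- matrix(bad, d[1], d[2])
  out
}

#' Split a calcium movie into per-beat frame windows
#'
#' Beats are located as peaks of the spatially averaged trace (topographic
#' prominence at least 20% of its range). Window boundaries are the
#' midpoints between consecutive peaks, extended to the movie ends. If the
#' pacing frequency is known, windows are instead snapped to one stimulus
#' period centred on each detected peak.
#'
#' @param m A (Delta F / F) fluorescence [movie()].
#' @param pacing_frequency Pacing rate in Hz, or `NULL` for free-running.
#' @return A list of integer vectors `c(first_frame, last_frame)` (1-based,
#'   inclusive), disjoint and ordered.
#' @export
segment_beats <- function(m, pacing_frequency = NULL) {
  stopifnot(inherits(m, "movie"))
  nf <- n_frames(m)
  gtrace <- apply(m$frames, 3, mean)
  rng <- max(gtrace) - min(gtrace)
  if (rng <= 0) stop("no beats found: spatially averaged trace is flat")
  pk <- find_peaks(gtrace, 0.2 * rng)
  if (!nrow(pk)) stop("no beats found in the spatially averaged trace")
  p <- pk$index
  if (is.null(pacing_frequency)) {
    bounds <- c(1L, as.integer(floor((p[-1] + p[-length(p)]) / 2)), nf)
    windows <- lapply(seq_along(p), function(k) {
      c(if (k == 1) 1L else bounds[k] + 1L, bounds[k + 1L])
    })
  } else {
    period <- round(m$frame_rate / pacing_frequency)
    windows <- list()
    last_end <- 0L
    for (k in seq_along(p)) {
      a <- max(last_end + 1L, p[k] - period %/% 2L)
      b <- min(nf, a + period - 1L)
      if (b > a) {
        windows[[length(windows) + 1L]] <- c(as.integer(a), as.integer(b))
        last_end <- b
      }
    }
  }
  windows
}

#' Per-pixel activation times for one beat
#'
#' For every pixel, the activation time within the window: either the first
#' upward crossing of 50% of the pixel's in-window amplitude, with linear
#' interpolation between frames (sub-frame resolution; the default), or the
#' time of maximal upstroke slope (centred first difference). Pixels whose
#' in-window amplitude is below 20% of the frame-wide median amplitude carry
#' no usable upstroke and are marked invalid.
#'
#' @param m A Delta F / F [movie()] (see [normalize_dff()]).
#' @param window Integer `c(first_frame, last_frame)` (1-based, inclusive),
#'   e.g. one element of [segment_beats()].
#' @param method `"half_amplitude"` or `"max_derivative"`.
#' @return An object of class `activation_map`: matrix `T` of absolute
#'   activation times (s), logical matrix `valid`, `method`, `frame_rate`,
#'   `pixel_size`, `window`.
#' @export
activation_times <- function(m, window,
                             method = c("half_amplitude", "max_derivative")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "movie"), length(window) == 2,
            window[1] >= 1, window[2] <= n_frames(m))
  if (window[2] <= window[1]) stop("empty activation window")
  d <- dim(m$frames)
  jj <- window[1]:window[2]
  fmat <- matrix(aperm(m$frames[, , jj, drop = FALSE], c(3, 1, 2)),
                 length(jj), d[1] * d[2])
  lo <- apply(fmat, 2, min)
  amp <- apply(fmat, 2, max) - lo
  valid <- amp >= 0.2 * stats::median(amp)
  masked <- attr(m, "baseline_masked")
  if (!is.null(masked)) valid <- valid & !as.vector(masked)
  if (!any(valid)) stop("all pixels invalid in this window")
  thr <- lo + 0.5 * amp
  tv <- rep(NA_real_, d[1] * d[2])
  t0 <- (window[1] - 1) / m$frame_rate
  for (p in which(valid)) {
    y <- fmat[, p]
    if (method == "half_amplitude") {
      above <- y >= thr[p]
      k <- which(above & !c(TRUE, above[-length(above)]))[1]
      if (is.na(k)) { k <- which(above)[1]; frac <- 0 } else {
        frac <- (thr[p] - y[k - 1]) / (y[k] - y[k - 1])
        k <- k - 1L
      }
      tv[p] <- t0 + (k - 1 + frac) / m$frame_rate
    } else {
      dy <- diff(y, lag = 2) / 2      # centred first difference
      k <- which.max(dy) + 1L
      tv[p] <- t0 + (k - 1) / m$frame_rate
    }
  }
  structure(
    list(T = matrix(tv, d[1], d[2]),
         valid = matrix(valid, d[1], d[2]),
         method = method,
         frame_rate = m$frame_rate,
         pixel_size = m$pixel_size,
         window = as.integer(window)),
    class = "activation_map"
  )
}

#' Median-combine per-beat activation maps
#'
#' Rebases each beat's map to its window start and takes the per-pixel
#' median across beats; a pixel stays valid where it is valid in a majority
#' of beats. Combining before differentiation suppresses beat-to-beat
#' timing noise.
#'
#' @param maps List of `activation_map`s of identical geometry.
#' @return A single `activation_map` (window of the first beat, times
#'   rebased to window start).
#' @export
combine_activation_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  if (length(maps) == 1) {
    m <- maps[[1]]
    m$T <- m$T - (m$window[1] - 1) / m$frame_rate
    return(m)
  }
  d <- dim(maps[[1]]$T)
  rebased <- lapply(maps, function(m) m$T - (m$window[1] - 1) / m$frame_rate)
  vstack <- sapply(maps, function(m) as.vector(m$valid))
  tstack <- sapply(rebased, as.vector)
  tstack[!vstack] <- NA
  valid <- rowSums(vstack) > length(maps) / 2
  tv <- apply(tstack, 1, stats::median, na.rm = TRUE)
  tv[!valid] <- NA
  out <- maps[[1]]
  out$T <- matrix(tv, d[1], d[2])
  out$valid <- matrix(valid, d[1], d[2])
  out
}

# one-sided/central finite differences of T over valid pixels, along one
# dimension; returns gradient in s/m (NA where no valid neighbour)
grad_1d <- function(T, valid, h, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") { T <- t(T); valid <- t(valid) }
  nr <- nrow(T); nc <- ncol(T)
  Tm <- cbind(NA, T[, -nc, drop = FALSE])   # value one column to the left
  Tp <- cbind(T[, -1, drop = FALSE], NA)
  Vm <- cbind(FALSE, valid[, -nc, drop = FALSE])
  Vp <- cbind(valid[, -1, drop = FALSE], FALSE)
  g <- matrix(NA_real_, nr, nc)
  both <- valid & Vm & Vp
  g[both] <- (Tp[both] - Tm[both]) / (2 * h)
  left <- valid & Vm & !Vp
  g[left] <- (T[left] - Tm[left]) / h
  right <- valid & !Vm & Vp
  g[right] <- (Tp[right] - T[right]) / h
  if (along == "row") g <- t(g)
  g
}

#' Conduction velocity field from an activation map
#'
#' The activation-time gradient `g = (dT/dx, dT/dy)` is estimated by central
#' differences on valid pixels (one-sided at valid-region borders); the
#' local conduction velocity is `v = g / |g|^2`, pointing along propagation
#' with speed `1 / |g|`. Pixels whose gradient magnitude falls below
#' `0.5 / v_max` (near-simultaneous activation: plateau or wave-collision
#' pixels) or implies a speed below `v_min` are invalidated before the
#' summary statistics.
#'
#' @param map An `activation_map` (see [activation_times()]).
#' @param pixel_size Pixel size in m (default: taken from the map).
#' @param v_min,v_max Physiological speed bounds in m/s (defaults 0.001 and
#'   1) used to reject plateau and stalled pixels.
#' @return An object of class `velocity_field`: matrices `vx`, `vy`,
#'   `speed` (m/s), logical `valid`, and scalars `mean_speed`,
#'   `median_speed` over valid pixels.
#' @export
conduction_velocity <- function(map, pixel_size = map$pixel_size,
                                v_min = 1e-3, v_max = 1) {
  stopifnot(inherits(map, "activation_map"))
  if (sum(map$valid) < 9) stop("fewer than 9 valid pixels")
  gx <- grad_1d(map$T, map$valid, pixel_size, "col")
  gy <- grad_1d(map$T, map$valid, pixel_size, "row")
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0   # missing component: no info along it
  g2 <- gx^2 + gy^2
  gmag <- sqrt(g2)
  ok <- map$valid & gmag >= 0.5 / v_max & gmag <= 1 / v_min
  if (!any(ok)) stop("no propagating front: activation is simultaneous everywhere")
  vx <- matrix(NA_real_, nrow(gx), ncol(gx)); vy <- vx; sp <- vx
  vx[ok] <- gx[ok] / g2[ok]
  vy[ok] <- gy[ok] / g2[ok]
  sp[ok] <- 1 / gmag[ok]
  structure(
    list(vx = vx, vy = vy, speed = sp, valid = ok,
         mean_speed = mean(sp[ok]), median_speed = stats::median(sp[ok])),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "velocity_field: %d valid px; mean %.2f cm/s, median %.2f cm/s\n",
    sum(x$valid), 100 * x$mean_speed, 100 * x$median_speed))
  invisible(x)
}

#' Count wavefront origins along the long axis
#'
#' Projects the activation map onto the long axis (per-column minimum over
#' valid rows), smooths the profile with a 5-column moving average, and
#' counts its strict local minima (minima closer than 2 columns are merged).
#' Each minimum is a wavefront origin. Classification: a single minimum at
#' an axis boundary is an `"edge wave"` (one front); a single interior
#' minimum is a `"point-source double wave"` (two counter-propagating
#' fronts); two or more separated minima are `"multiple sources"`.
#'
#' @param map An `activation_map`.
#' @param long_axis `"x"` (columns, default) or `"y"` (rows).
#' @param smooth_window Moving-average window in columns (default 5).
#' @param boundary_margin Columns from an axis end still counted as the
#'   boundary (default 2).
#' @return A list: `n_origins`, `n_fronts`, `origin_positions` (1-based
#'   column indices on the long axis), `classification`.
#' @export
count_wavefronts <- function(map, long_axis = c("x", "y"),
                             smooth_window = 5, boundary_margin = 2) {
  long_axis <- match.arg(long_axis)
  stopifnot(inherits(map, "activation_map"))
  T <- map$T; valid <- map$valid
  if (long_axis == "y") { T <- t(T); valid <- t(valid) }
  Tm <- T; Tm[!valid] <- NA
  prof <- suppressWarnings(apply(Tm, 2, min, na.rm = TRUE))
  keep <- is.finite(prof)
  prof <- prof[keep]
  cols <- which(keep)
  if (length(prof) < smooth_window) {
    stop("valid region narrower than the smoothing window")
  }
  sm <- stats::filter(prof, rep(1 / smooth_window, smooth_window),
                      sides = 2)
  sm <- as.numeric(sm)
  # moving average is undefined at the ends: fall back to the raw profile
  sm[is.na(sm)] <- prof[is.na(sm)]
  # local minima of the smoothed profile, boundaries included
  n <- length(sm)
  mins <- find_peaks(-c(Inf, sm, Inf))$index - 1L
  if (length(mins) > 1) {       # merge minima closer than 2 columns
    mins <- mins[c(TRUE, diff(mins) > 2)]
  }
  origins <- cols[mins]
  at_boundary <- origins <= boundary_margin + cols[1] - 1 |
    origins >= cols[length(cols)] - boundary_margin
  if (length(origins) == 1 && at_boundary) {
    cls <- "edge wave"; fronts <- 1L
  } else if (length(origins) == 1) {
    cls <- "point-source double wave"; fronts <- 2L
  } else {
    cls <- "multiple sources"
    fronts <- sum(at_boundary) + 2L * sum(!at_boundary)
  }
  list(n_origins = length(origins), n_fronts = as.integer(fronts),
       origin_positions = origins, classification = cls)
}

#' Run the whole optical-mapping pipeline on a calcium movie
#'
#' [spatial_filter()], [normalize_dff()], [segment_beats()], per-beat
#' [activation_times()], [combine_activation_maps()], then
#' [conduction_velocity()] and [count_wavefronts()].
#'
#' @param m A raw fluorescence [movie()].
#' @param pacing_frequency Optional pacing rate in Hz for beat snapping.
#' @param method Activation criterion, see [activation_times()].
#' @param ... Passed to [conduction_velocity()].
#' @return A list: `activation` (combined `activation_map`), `velocity`
#'   (`velocity_field`), `wavefronts`, `n_beats`.
#' @export
analyze_calcium_movie <- function(m, pacing_frequency = NULL,
                                  method = "half_amplitude", ...) {
  filt <- spatial_filter(m)
  dff <- normalize_dff(filt)
  windows <- segment_beats(dff, pacing_frequency)
  maps <- lapply(windows, function(w) activation_times(dff, w, method))
  comb <- combine_activation_maps(maps)
  list(activation = comb,
       velocity = conduction_velocity(comb, ...),
       wavefronts = count_wavefronts(comb),
       n_beats = length(windows))
}
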