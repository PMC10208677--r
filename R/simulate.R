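#' Render a cantilever bending movie from a stress trace
#'
#' Forward model of the muscular-thin-film contractility assay. Per frame,
#' the film stress is converted to an arc curvature by inverting the Stoney
#' relation, the curled cantilever's horizontal extent
#' \eqn{x = L \sin(\kappa L)/(\kappa L)} is computed, and a binary rectangle
#' of that extent is rasterized from a fixed base column. Optional Gaussian
#' intensity noise is added and re-binarized at 0.5, so the output is always
#' a clean mask.
#'
#' @param trace A [stress_trace()] (film stress in Pa per frame).
#' @param spec A [mechanical_spec()].
#' @param rows,cols Frame size in pixels.
#' @param pixel_size Physical pixel size in m; the free length plus a small
#'   base margin must fit inside `cols * pixel_size`.
#' @param noise_sd Gaussian intensity noise s.d. (mask amplitude is 1).
#' @param seed Integer seed; every stochastic renderer requires one.
#' @param base_col Column (1-based) of the cantilever base (default 3).
#' @param band_rows Rows occupied by the cantilever (default: middle half).
#' @return A binary-mask [movie()] with the trace's frame rate.
#' @export
render_cantilever_movie <- function(trace, spec, rows, cols, pixel_size,
                                    noise_sd = 0, seed,
                                    base_col = 3L,
                                    band_rows = NULL) {
  stopifnot(inherits(trace, "stress_trace"), inherits(spec, "mechanical_spec"))
  if (missing(seed)) stop("an explicit integer seed is required")
  L <- spec$free_length_L
  if (base_col - 1 + ceiling(L / pixel_size) > cols) {
    stop("free length does not fit in the field of view: increase cols or pixel_size")
  }
  kappa <- stoney_curvature(trace$stress, spec)
  if (any(kappa * L >= pi)) {
    stop(sprintf(
      "over-curl: kappa*L = %.3f >= pi; the x-projection is no longer injective",
      max(kappa * L)))
  }
  x <- projection_from_curvature(kappa, L)
  n_px <- round(x / pixel_size)
  if (any(n_px < 2)) stop("projected extent below 2 pixels: resolution failure")
  if (is.null(band_rows)) {
    band_rows <- seq.int(max(1L, floor(rows / 4)), ceiling(3 * rows / 4))
  }
  nf <- length(n_px)
  frames <- array(0, c(rows, cols, nf))
  for (j in seq_len(nf)) {
    frames[band_rows, base_col:(base_col + n_px[j] - 1L), j] <- 1
  }
  if (noise_sd > 0) {
    set.seed(seed)
    frames <- frames + array(stats::rnorm(length(frames), 0, noise_sd),
                             dim(frames))
    frames <- (frames > 0.5) * 1
  }
  movie(frames, trace$frame_rate, pixel_size, "binary_mask")
}

#' Build a ground-truth activation-time field
#'
#' Per-pixel activation time for a single propagating calcium wave moving at
#' constant speed: `T(p) = dist(source, p) / speed`. An edge source produces
#' a planar wave sweeping in from one boundary of the frame (a spontaneous
#' wave starting at a cantilever edge); an interior point source produces a
#' radial field, i.e. two counter-propagating fronts along the long axis (a
#' light-spot-triggered wave).
#'
#' @param rows,cols Field size in pixels.
#' @param pixel_size Physical pixel size in m.
#' @param source_kind `"edge"` or `"point"`.
#' @param source_location Pixel `c(row, col)` (1-based). For an edge source
#'   it must lie on a frame boundary; the wave is planar from that boundary
#'   (vertical edges are preferred at corners, the long axis being x).
#' @param speed_v Wave speed in m/s (> 0).
#' @return An object of class `activation_field` with per-pixel times `T`
#'   (s), a validity `mask`, and the ground-truth parameters.
#' @examples
#' f <- make_activation_field(20, 40, 1e-4, "edge", c(1, 1), 0.042)
#' f$T[1, 11]  # 10 pixels in: 1e-3 / 0.042 s
#' @export
make_activation_field <- function(rows, cols, pixel_size,
                                  source_kind = c("edge", "point"),
                                  source_location, speed_v) {
  source_kind <- match.arg(source_kind)
  if (speed_v <= 0) stop("speed_v must be positive")
  r0 <- source_location[1]; c0 <- source_location[2]
  stopifnot(r0 >= 1, r0 <= rows, c0 >= 1, c0 <= cols)
  cx <- (col(matrix(0, rows, cols)) - 1) * pixel_size
  cy <- (row(matrix(0, rows, cols)) - 1) * pixel_size
  if (source_kind == "edge") {
    if (c0 == 1) {
      d <- cx
    } else if (c0 == cols) {
      d <- max(cx) - cx
    } else if (r0 == 1) {
      d <- cy
    } else if (r0 == rows) {
      d <- max(cy) - cy
    } else {
      stop("an edge source must lie on a frame boundary")
    }
  } else {
    d <- sqrt((cx - (c0 - 1) * pixel_size)^2 + (cy - (r0 - 1) * pixel_size)^2)
  }
  structure(
    list(T = d / speed_v,
         mask = matrix(TRUE, rows, cols),
         source_kind = source_kind,
         source_location = c(r0, c0),
         speed_v = speed_v,
         pixel_size = pixel_size),
    class = "activation_field"
  )
}

# Calcium transient kernel: linear rise to 1 over `rise`, then exponential
# decay with time constant `tau`; 0 before activation.
calcium_kernel <- function(u, rise, tau) {
  k <- numeric(length(u))
  up <- u >= 0 & u <= rise
  k[up] <- u[up] / rise
  down <- u > rise
  k[down] <- exp(-(u[down] - rise) / tau)
  k
}

#' Render a calcium fluorescence movie from an activation field
#'
#' Each pixel fires at its activation time in every beat: its trace is
#' `F0 + dF * K(t - T(p) - k * beat_period)` summed over beats, where `K`
#' is a linear-rise / exponential-decay transient kernel, plus seeded
#' Gaussian noise. Negative intensities after noise are clipped to zero;
#' if more than 1% of samples clip, a warning reports the fraction.
#'
#' @param field An [make_activation_field()] result.
#' @param frame_rate Frames per second (400 is typical for calcium mapping).
#' @param n_beats Number of beats rendered.
#' @param beat_period Beat period in s.
#' @param rise_time Upstroke duration in s (must be < `beat_period`).
#' @param decay_tau Decay time constant in s.
#' @param baseline_F0,amplitude_dF Baseline and peak-minus-baseline
#'   intensities (arbitrary units).
#' @param noise_sd Gaussian noise s.d. in the same intensity units.
#' @param seed Integer seed.
#' @return A fluorescence [movie()].
#' @export
render_calcium_movie <- function(field, frame_rate = 400, n_beats = 3,
                                 beat_period = 1, rise_time = 0.02,
                                 decay_tau = 0.15,
                                 baseline_F0 = 100, amplitude_dF = 50,
                                 noise_sd = 0, seed) {
  stopifnot(inherits(field, "activation_field"))
  if (missing(seed)) stop("an explicit integer seed is required")
  if (rise_time >= beat_period) stop("rise_time must be shorter than the beat period")
  d <- dim(field$T)
  nf <- round(n_beats * beat_period * frame_rate)
  t <- (seq_len(nf) - 1) / frame_rate
  Tvec <- as.vector(field$T)
  frames <- array(baseline_F0, c(d[1], d[2], nf))
  # outer(time, pixel) per beat keeps this fully vectorized
  fmat <- matrix(0, nf, length(Tvec))
  for (k in seq_len(n_beats) - 1) {
    u <- outer(t - k * beat_period, Tvec, "-")
    fmat <- fmat + calcium_kernel(u, rise_time, decay_tau)
  }
  frames <- frames + amplitude_dF *
    aperm(array(fmat, c(nf, d[1], d[2])), c(2, 3, 1))
  if (noise_sd > 0) {
    set.seed(seed)
    frames <- frames + array(stats::rnorm(length(frames), 0, noise_sd),
                             dim(frames))
    n_clip <- sum(frames < 0)
    if (n_clip > 0.01 * length(frames)) {
      warning(sprintf("%.2f%% of samples clipped at zero intensity",
                      100 * n_clip / length(frames)))
    }
    frames[frames < 0] <- 0
  }
  movie(frames, frame_rate, field$pixel_size, "fluorescence")
}

# von Mises sampler (Best & Fisher 1979 wrapping rejection scheme);
# kappa = 0 falls back to the circular uniform. Angles in radians.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("concentration must be non-negative")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}

# fold axial angles (degrees) into [-90, 90)
canonicalize_axial <- function(angles_deg) {
  a <- (angles_deg + 90) %% 180 - 90
  a[a >= 90] <- a[a >= 90] - 180
  a
}

#' Sample axial nuclear orientations
#'
#' Draws axial (180-degree-periodic) angles emulating nuclear orientations
#' in an anisotropic engineered tissue: doubled angles `2 * theta` are drawn
#' from a von Mises law with mean `2 * mean_angle` and the given
#' concentration, halved, and canonicalized to `[-90, 90)` degrees relative
#' to the pattern direction.
#'
#' @param n Sample size (>= 1).
#' @param mean_angle Mean axial angle in degrees (relative to the pattern).
#' @param concentration von Mises concentration of the doubled angles
#'   (>= 0; 0 = uniform axial).
#' @param pattern_direction Reference direction in degrees (default 0).
#' @param seed Integer seed.
#' @return An object of class `orientation_set` with fields `angles`
#'   (degrees in `[-90, 90)`), `pattern_direction` and `n`.
#' @export
sample_orientations <- function(n, mean_angle, concentration,
                                pattern_direction = 0, seed) {
  stopifnot(n >= 1, concentration >= 0)
  if (missing(seed)) stop("an explicit integer seed is required")
  set.seed(seed)
  doubled <- rvonmises(n, 2 * mean_angle * pi / 180, concentration)
  orientation_set(canonicalize_axial(doubled * 90 / pi), pattern_direction)
}

#' Construct an orientation set
#'
#' @param angles Axial angles in degrees; canonicalized to `[-90, 90)`.
#' @param pattern_direction Reference direction in degrees.
#' @return An object of class `orientation_set`.
#' @export
orientation_set <- function(angles, pattern_direction = 0) {
  stopifnot(length(angles) >= 1, all(is.finite(angles)))
  structure(
    list(angles = canonicalize_axial(angles),
         pattern_direction = pattern_direction,
         n = length(angles)),
    class = "orientation_set"
  )
}
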