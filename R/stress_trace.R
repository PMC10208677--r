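#' Construct a film stress trace
#'
#' A `stress_trace` is the central product of the contractility pipeline and
#' the central input of the cantilever simulator: film stress (Pa) sampled on
#' a uniform time grid at a fixed frame rate.
#'
#' @param stress Numeric vector of film stresses in Pa (finite, >= 0,
#'   length >= 2).
#' @param frame_rate Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `stress_trace` with fields `times`, `stress`
#'   and `frame_rate`.
#' @export
stress_trace <- function(stress, frame_rate, t0 = 0) {
  stopifnot(is.numeric(stress), length(stress) >= 2,
            is.numeric(frame_rate), length(frame_rate) == 1, frame_rate > 0)
  if (any(!is.finite(stress)) || any(stress < 0)) {
    stop("stress values must be finite and non-negative")
  }
  structure(
    list(
      times = t0 + (seq_along(stress) - 1) / frame_rate,
      stress = as.numeric(stress),
      frame_rate = frame_rate
    ),
    class = "stress_trace"
  )
}

#' @export
print.stress_trace <- function(x, ...) {
  cat(sprintf(
    "stress_trace: %d samples at %g Hz (%.2f s), stress %.1f-%.1f Pa\n",
    length(x$stress), x$frame_rate, length(x$stress) / x$frame_rate,
    min(x$stress), max(x$stress)
  ))
  invisible(x)
}

# Twitch shape: linear rise over the upstroke, then a half-cosine relaxation
# back to baseline over twice the rise time (capped so it ends before the
# next beat), then quiescence. Unit peak; the peak is attained exactly at
# the end of the rise.
twitch_kernel <- function(u, rise, decay) {
  k <- numeric(length(u))
  up <- u >= 0 & u < rise
  k[up] <- u[up] / rise
  k[u == rise] <- 1
  down <- u > rise & u < rise + decay
  k[down] <- 0.5 * (1 + cos(pi * (u[down] - rise) / decay))
  k
}

#' Generate a periodic twitch stress trace
#'
#' Forward model of the contractile activity of a paced cardiac film: a flat
#' diastolic baseline with one twitch per beat, each twitch a fast linear
#' rise to `diastolic + twitch_amplitude` followed by a slower half-cosine
#' relaxation to baseline. Beat onsets sit at `k / frequency` for every onset
#' inside `duration`.
#'
#' @param frequency Beat rate in Hz.
#' @param diastolic Baseline (relaxed) stress in Pa.
#' @param twitch_amplitude Peak-minus-baseline stress in Pa (>= 0).
#' @param duration Trace duration in seconds.
#' @param frame_rate Sampling rate in Hz; must be at least 10 x `frequency`
#'   so the twitch upstroke is resolved.
#' @param upstroke_fraction Fraction of the beat period occupied by the
#'   rising phase (default 0.2); the relaxation takes twice as long, capped
#'   at 90% of the remaining period.
#' @return A [stress_trace()].
#' @examples
#' tr <- make_stress_trace(1, 1e3, 5.4e3, 30, 100)
#' max(tr$stress)  # 6400 Pa
#' @export
make_stress_trace <- function(frequency, diastolic, twitch_amplitude,
                              duration, frame_rate,
                              upstroke_fraction = 0.2) {
  stopifnot(frequency > 0, twitch_amplitude >= 0, diastolic >= 0)
  if (duration <= 0) stop("duration must be positive")
  if (frame_rate < 10 * frequency) {
    stop(sprintf(paste0(
      "frame_rate %g Hz cannot resolve a %g Hz twitch: ",
      "need >= 10 x frequency (Nyquist-safe sampling of the upstroke)"),
      frame_rate, frequency))
  }
  stopifnot(upstroke_fraction > 0, upstroke_fraction < 0.5)
  period <- 1 / frequency
  rise <- upstroke_fraction * period
  decay <- min(2 * rise, 0.9 * (period - rise))
  t <- seq(0, duration - 1 / frame_rate + 1e-12, by = 1 / frame_rate)
  onsets <- make_stimulus_train(frequency, 0.5, duration)$pulse_onsets
  s <- rep(diastolic, length(t))
  for (on in onsets) {
    s <- s + twitch_amplitude * twitch_kernel(t - on, rise, decay)
  }
  stress_trace(s, frame_rate)
}
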