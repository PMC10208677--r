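#' Build a periodic light-pulse stimulus train
#'
#' A pacing protocol is a square-wave light train described by its frequency
#' and duty cycle: the pulse width is `duty_cycle / frequency`, so at 1 Hz a
#' 50% duty cycle gives a 500 ms pulse and a 15% duty cycle a 150 ms pulse,
#' without changing the pacing rate.
#'
#' @param frequency Pacing frequency in Hz (> 0).
#' @param duty_cycle Fraction of each period the light is on, in (0, 1).
#' @param duration Total train duration in seconds (> 0).
#' @param irradiance Light intensity in mW/cm^2 (default 60, the standard
#'   photopacing irradiance).
#'
#' @return An object of class `stimulus_train` with fields `frequency`,
#'   `duty_cycle`, `duration`, `pulse_onsets` (seconds, one per delivered
#'   pulse), `pulse_width` (seconds) and `irradiance`.
#' @examples
#' tr <- make_stimulus_train(1, 0.5, 10)
#' tr$pulse_width  # 0.5 s
#' @export
make_stimulus_train <- function(frequency, duty_cycle, duration,
                                irradiance = 60) {
  stopifnot(is.numeric(frequency), length(frequency) == 1, frequency > 0)
  if (!is.numeric(duty_cycle) || length(duty_cycle) != 1 ||
      duty_cycle <= 0 || duty_cycle >= 1) {
    stop("duty_cycle must lie strictly in (0, 1); continuous light is not a pulse train")
  }
  stopifnot(is.numeric(duration), length(duration) == 1, duration > 0)
  # guard floor() against floating-point representation of duration * f
  n_pulses <- floor(duration * frequency * (1 + 1e-12))
  onsets <- if (n_pulses >= 1) (seq_len(n_pulses) - 1) / frequency else numeric(0)
  structure(
    list(
      frequency = frequency,
      duty_cycle = duty_cycle,
      duration = duration,
      pulse_onsets = onsets,
      pulse_width = duty_cycle / frequency,
      irradiance = irradiance
    ),
    class = "stimulus_train"
  )
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf(
    "stimulus_train: %g Hz, duty %g%% -> %g ms pulses, %d pulses over %g s, %g mW/cm^2\n",
    x$frequency, 100 * x$duty_cycle, 1000 * x$pulse_width,
    length(x$pulse_onsets), x$duration, x$irradiance
  ))
  invisible(x)
}
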