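#' Build a stimulate/record protocol schedule
#'
#' The standard photopacing session alternates a pulsed-light stimulation
#' block with a short video recording made without photostimulation (so the
#' pacing light cannot interfere with the acquisition): `cycles` repetitions
#' of (stimulate `stim_minutes`, record `record_seconds`). Cumulative
#' stimulation time is `cycles * stim_minutes`.
#'
#' @param stim_minutes Stimulation block length in minutes (default 3).
#' @param record_seconds Recording block length in seconds (default 30).
#' @param cycles Number of stimulate/record cycles (>= 1).
#' @param train A [make_stimulus_train()] describing the light pulses; its
#'   duration must not exceed the stimulation block.
#' @return An object of class `protocol_schedule`: `blocks` (data.frame of
#'   kind, duration_s, with the train attached to stimulate blocks),
#'   `total_duration` (s), `cumulative_stimulation` (s), `train`.
#' @examples
#' tr <- make_stimulus_train(1, 0.5, 180)
#' build_protocol(cycles = 2, train = tr)$cumulative_stimulation / 60  # 6 min
#' @export
build_protocol <- function(stim_minutes = 3, record_seconds = 30, cycles,
                           train) {
  stopifnot(cycles >= 1, stim_minutes > 0, record_seconds > 0,
            inherits(train, "stimulus_train"))
  stim_s <- 60 * stim_minutes
  if (train$duration > stim_s + 1e-9) {
    stop("stimulus train outlasts the stimulation block: light would overlap the recording")
  }
  blocks <- data.frame(
    kind = rep(c("stimulate", "record"), cycles),
    duration_s = rep(c(stim_s, record_seconds), cycles),
    stringsAsFactors = FALSE
  )
  structure(
    list(blocks = blocks,
         total_duration = sum(blocks$duration_s),
         cumulative_stimulation = cycles * stim_s,
         train = train),
    class = "protocol_schedule"
  )
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf(
    "protocol_schedule: %d blocks, %g s total, %g min cumulative stimulation\n",
    nrow(x$blocks), x$total_duration, x$cumulative_stimulation / 60))
  invisible(x)
}

#' Background-correct and per-nucleus normalize a ROS intensity
#'
#' Oxidative-stress readouts (e.g. CellROX) are reported per cell:
#' `normalized = (raw_intensity - background) / n_nuclei`, with the
#' background a per-plate (or per-condition) scalar and `n_nuclei` the
#' Hoechst-positive count. A negative normalized value (background exceeds
#' signal) is kept but flagged.
#'
#' @param raw_intensity Raw integrated intensity (a.u., >= 0).
#' @param background Background intensity (a.u.).
#' @param n_nuclei Hoechst-positive nucleus count (>= 1).
#' @param condition Optional condition label.
#' @return An object of class `ros_result`: `condition`, `raw_intensity`,
#'   `background`, `n_nuclei`, `normalized`, `flagged_negative`.
#' @export
ros_normalize <- function(raw_intensity, background, n_nuclei,
                          condition = NA_character_) {
  stopifnot(raw_intensity >= 0)
  if (!is.numeric(n_nuclei) || n_nuclei < 1) {
    stop("n_nuclei must be at least 1")
  }
  normalized <- (raw_intensity - background) / n_nuclei
  structure(
    list(condition = condition, raw_intensity = raw_intensity,
         background = background, n_nuclei = n_nuclei,
         normalized = normalized,
         flagged_negative = normalized < 0),
    class = "ros_result"
  )
}

#' Assemble a per-condition experiment report
#'
#' Collects twitch summaries and velocity summaries per condition into a
#' single deterministic report: per-condition means +/- s.e.m., pairwise
#' comparisons with star annotations, and provenance (seeds, package
#' version, config hash). Rendering the same inputs twice yields
#' byte-identical JSON.
#'
#' @param twitch_summaries Named list (one element per condition) of lists
#'   of `twitch_summary` objects, or `NULL`.
#' @param velocity_summaries Named list per condition of lists of
#'   `velocity_field` objects, or `NULL`.
#' @param comparisons Named list of `comparison_result` objects, or `NULL`.
#' @param seeds Integer vector of seeds used for the run (provenance).
#' @param config Arbitrary (JSON-serializable) configuration list; hashed
#'   into the provenance block.
#' @return An object of class `experiment_report`; see [format_report()]
#'   and [write_report()].
#' @export
experiment_report <- function(twitch_summaries = NULL,
                              velocity_summaries = NULL,
                              comparisons = NULL,
                              seeds = integer(0),
                              config = list()) {
  if (is.null(twitch_summaries) && is.null(velocity_summaries)) {
    stop("at least one condition is required")
  }
  summarize <- function(vals) {
    list(mean = mean(vals),
         sem = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0,
         n = length(vals))
  }
  twitch_block <- lapply(twitch_summaries, function(cond) {
    list(
      contraction_frequency_Hz = summarize(
        vapply(cond, `[[`, numeric(1), "contraction_frequency")),
      twitch_stress_kPa = summarize(
        1e-3 * vapply(cond, `[[`, numeric(1), "twitch_stress")),
      diastolic_stress_kPa = summarize(
        1e-3 * vapply(cond, `[[`, numeric(1), "diastolic_stress")),
      systolic_stress_kPa = summarize(
        1e-3 * vapply(cond, `[[`, numeric(1), "systolic_stress"))
    )
  })
  velocity_block <- lapply(velocity_summaries, function(cond) {
    list(median_speed_cm_s = summarize(
      100 * vapply(cond, `[[`, numeric(1), "median_speed")))
  })
  comparison_block <- lapply(comparisons, function(cmp) {
    list(mean_a = cmp$mean_a, sem_a = cmp$sem_a, n_a = cmp$n_a,
         mean_b = cmp$mean_b, sem_b = cmp$sem_b, n_b = cmp$n_b,
         t = cmp$t_statistic, p = cmp$p_value, stars = cmp$stars,
         variant = cmp$variant)
  })
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_file <- tempfile()
  writeLines(cfg_json, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  structure(
    list(conditions = list(twitch = twitch_block, velocity = velocity_block),
         comparisons = comparison_block,
         provenance = list(
           seeds = as.integer(seeds),
           package_version = as.character(utils::packageVersion("photopace")),
           config_hash = cfg_hash)),
    class = "experiment_report"
  )
}

#' Render an experiment report as canonical JSON
#'
#' @param report An [experiment_report()].
#' @return A single JSON string (byte-stable for identical inputs).
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE))
}

#' Write an experiment report to disk
#'
#' Writes `<stem>.json` (machine-readable) and `<stem>.txt` (human-readable
#' summary with star annotations).
#'
#' @param report An [experiment_report()].
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_report <- function(report, stem) {
  writeLines(format_report(report), paste0(stem, ".json"))
  lines <- c("photopace experiment report", "")
  for (cond in names(report$conditions$twitch)) {
    b <- report$conditions$twitch[[cond]]
    lines <- c(lines, sprintf(
      "%s: frequency %.3f +/- %.3f Hz, twitch %.2f +/- %.2f kPa (n = %d)",
      cond, b$contraction_frequency_Hz$mean, b$contraction_frequency_Hz$sem,
      b$twitch_stress_kPa$mean, b$twitch_stress_kPa$sem,
      b$contraction_frequency_Hz$n))
  }
  for (cond in names(report$conditions$velocity)) {
    b <- report$conditions$velocity[[cond]]
    lines <- c(lines, sprintf(
      "%s: conduction speed %.2f +/- %.2f cm/s (n = %d)",
      cond, b$median_speed_cm_s$mean, b$median_speed_cm_s$sem,
      b$median_speed_cm_s$n))
  }
  for (nm in names(report$comparisons)) {
    cmp <- report$comparisons[[nm]]
    lines <- c(lines, sprintf("%s: t = %.3f, p = %.4g %s",
                              nm, cmp$t, cmp$p, cmp$stars))
  }
  writeLines(lines, paste0(stem, ".txt"))
  invisible(stem)
}
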