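#' Threshold a grayscale movie into a cantilever mask movie
#'
#' Binarizes every frame at a single level: either Otsu's threshold computed
#' on the first frame and reused for the whole movie (so threshold jitter
#' cannot masquerade as contraction), or a user-fixed level. After
#' binarization only the largest connected foreground component of each
#' frame is kept. Already-binary movies are returned unchanged.
#'
#' @param m A [movie()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_level Threshold intensity, required iff `method = "fixed"`.
#' @return A binary-mask [movie()].
#' @export
threshold_movie <- function(m, method = c("otsu", "fixed"),
                            fixed_level = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(m, "movie"))
  if (m$kind == "binary_mask") return(m)
  if (method == "fixed") {
    if (is.null(fixed_level)) stop("fixed_level is required for method = 'fixed'")
    level <- fixed_level
  } else {
    f1 <- m$frames[, , 1]
    lo <- min(f1); hi <- max(f1)
    if (hi <= lo) stop("frame 1 is constant: empty or full foreground")
    level <- lo + (hi - lo) * EBImage::otsu((f1 - lo) / (hi - lo),
                                            range = c(0, 1))
  }
  nf <- n_frames(m)
  out <- array(0, dim(m$frames))
  for (j in seq_len(nf)) {
    b <- (m$frames[, , j] > level) * 1
    if (all(b == 0) || all(b == 1)) {
      stop(sprintf("frame %d: empty or full foreground after thresholding", j))
    }
    lab <- EBImage::bwlabel(b)
    sizes <- tabulate(lab[lab > 0])
    out[, , j] <- (lab == which.max(sizes)) * 1
  }
  movie(out, m$frame_rate, m$pixel_size, "binary_mask")
}

#' Per-frame x-projection of a cantilever mask movie
#'
#' The horizontal extent of the curled cantilever seen from above, measured
#' along the bending (column) axis from a fixed base column to the farthest
#' foreground column: `x = (max_col - base_col + 1) * pixel_size`.
#'
#' @param m A binary-mask [movie()].
#' @param base_col Base column (1-based); by default the leftmost column of
#'   maximal temporal occupancy (the cantilever base is foreground in every
#'   frame, the tip only in relaxed ones).
#' @return Numeric vector of projected lengths in m, one per frame.
#' @export
x_projection <- function(m, base_col = NULL) {
  stopifnot(inherits(m, "movie"))
  if (m$kind != "binary_mask") stop("x_projection needs a binary-mask movie")
  d <- dim(m$frames)
  col_occ <- apply(m$frames, 2, sum)
  if (is.null(base_col)) base_col <- which.max(col_occ)
  x <- numeric(d[3])
  for (j in seq_len(d[3])) {
    fg_cols <- which(colSums(m$frames[, , j]) > 0)
    if (!length(fg_cols)) stop(sprintf("frame %d: empty foreground", j))
    tip <- max(fg_cols)
    if (tip == d[2]) {
      stop(sprintf(
        "frame %d: foreground touches the image border; projection censored (field of view too small)",
        j))
    }
    x[j] <- (tip - base_col + 1) * m$pixel_size
  }
  x
}

#' Extract a film stress trace from a cantilever movie
#'
#' The full inverse pipeline: threshold, per-frame x-projection, arc
#' curvature by bisection on the sinc projection relation, and the Stoney
#' stress. Projections that exceed the free length by less than one pixel
#' (rasterization round-off of a flat film) are clamped to the free length.
#'
#' @param m A [movie()] (binary or grayscale).
#' @param spec A [mechanical_spec()].
#' @param threshold_method Passed to [threshold_movie()].
#' @param fixed_level Passed to [threshold_movie()].
#' @param base_col Passed to [x_projection()].
#' @return A [stress_trace()] aligned to the movie frames.
#' @export
extract_stress_trace <- function(m, spec, threshold_method = "otsu",
                                 fixed_level = NULL, base_col = NULL) {
  stopifnot(inherits(m, "movie"), inherits(spec, "mechanical_spec"))
  mask <- threshold_movie(m, threshold_method, fixed_level)
  x <- x_projection(mask, base_col)
  L <- spec$free_length_L
  over <- x > L
  if (any(x > L + m$pixel_size)) {
    stop(sprintf("frame %d: projection exceeds the free length by more than one pixel",
                 which(x > L + m$pixel_size)[1]))
  }
  x[over] <- L
  kappa <- curvature_from_projection(x, L)
  stress_trace(stoney_stress(kappa, spec), m$frame_rate)
}

# Local maxima of a numeric vector with topographic prominence.
# Plateaus contribute their (rounded) middle sample. Returns a data.frame
# with index, height, prominence.
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(0), height = numeric(0),
                               prominence = numeric(0)))
  # candidate peaks: strictly above the nearest differing neighbours
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L   # walk the plateau
      if (j < n && y[j + 1L] < y[j]) {
        idx <- c(idx, as.integer(round((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(idx)) return(data.frame(index = integer(0), height = numeric(0),
                                      prominence = numeric(0)))
  prom <- vapply(idx, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1L)]
    hl <- which(left > h)
    lmin <- if (length(hl)) min(y[(max(hl) + 1L):(p - 1L)]) else min(left)
    right <- y[(p + 1L):n]
    hr <- which(right > h)
    rmin <- if (length(hr)) min(right[seq_len(min(hr) - 1L)]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = idx[keep], height = y[idx[keep]], prominence = prom[keep])
}

#' Twitch statistics from a stress trace
#'
#' Detects beats as stress peaks whose topographic prominence is at least
#' `min_prominence_fraction` of the trace's dynamic range. Per beat, the
#' diastolic baseline is the 5th percentile of the inter-peak segment
#' preceding the peak (robust to slow drift). Diastolic stress is the mean
#' baseline, systolic stress the mean peak, twitch stress their difference,
#' and the contraction frequency the reciprocal of the median inter-peak
#' interval (robust to a single missed beat); fewer than two peaks give
#' frequency 0. A flat trace yields zero beats, not an error.
#'
#' @param trace A [stress_trace()] of duration >= 2 s.
#' @param min_prominence_fraction Prominence floor as a fraction of
#'   (max - min) stress (default 0.2).
#' @param analysis_window Seconds of trace analyzed from the start
#'   (default 30, the standard acquisition length; traces shorter than the
#'   window are used whole).
#' @return An object of class `twitch_summary`: `diastolic_stress`,
#'   `systolic_stress`, `twitch_stress` (Pa), `contraction_frequency` (Hz),
#'   `n_beats`, and `per_beat_table` (peak_time, peak_stress, baseline).
#' @export
detect_twitches <- function(trace, min_prominence_fraction = 0.2,
                            analysis_window = 30) {
  stopifnot(inherits(trace, "stress_trace"))
  if (length(trace$stress) / trace$frame_rate < 2) {
    stop("trace must be at least 2 s long")
  }
  n_use <- min(length(trace$stress),
               floor(analysis_window * trace$frame_rate))
  y <- trace$stress[seq_len(n_use)]
  t <- trace$times[seq_len(n_use)]
  rng <- max(y) - min(y)
  peaks <- if (rng > 0) find_peaks(y, min_prominence_fraction * rng) else
    data.frame(index = integer(0), height = numeric(0),
               prominence = numeric(0))
  nb <- nrow(peaks)
  if (nb == 0) {
    tab <- data.frame(peak_time = numeric(0), peak_stress = numeric(0),
                      baseline = numeric(0))
    return(structure(
      list(diastolic_stress = mean(y), systolic_stress = mean(y),
           twitch_stress = 0, contraction_frequency = 0, n_beats = 0L,
           per_beat_table = tab),
      class = "twitch_summary"))
  }
  starts <- c(1L, peaks$index[-nb] + 1L)
  baselines <- vapply(seq_len(nb), function(k) {
    seg <- y[starts[k]:peaks$index[k]]
    as.numeric(stats::quantile(seg, 0.05, names = FALSE))
  }, numeric(1))
  freq <- if (nb >= 2) 1 / stats::median(diff(t[peaks$index])) else 0
  structure(
    list(diastolic_stress = mean(baselines),
         systolic_stress = mean(peaks$height),
         twitch_stress = mean(peaks$height) - mean(baselines),
         contraction_frequency = freq,
         n_beats = as.integer(nb),
         per_beat_table = data.frame(peak_time = t[peaks$index],
                                     peak_stress = peaks$height,
                                     baseline = baselines)),
    class = "twitch_summary"
  )
}

#' @export
print.twitch_summary <- function(x, ...) {
  cat(sprintf(
    paste0("twitch_summary: %d beats at %.3f Hz; diastolic %.2f kPa, ",
           "systolic %.2f kPa, twitch %.2f kPa\n"),
    x$n_beats, x$contraction_frequency, 1e-3 * x$diastolic_stress,
    1e-3 * x$systolic_stress, 1e-3 * x$twitch_stress
  ))
  invisible(x)
}

#' Run the whole contractility pipeline on a cantilever movie
#'
#' Convenience wrapper: [extract_stress_trace()] then [detect_twitches()].
#'
#' @inheritParams extract_stress_trace
#' @inheritParams detect_twitches
#' @return A list with `trace` (the [stress_trace()]) and `summary`
#'   (the `twitch_summary`).
#' @export
analyze_cantilever_movie <- function(m, spec, threshold_method = "otsu",
                                     fixed_level = NULL, base_col = NULL,
                                     min_prominence_fraction = 0.2,
                                     analysis_window = 30) {
  tr <- extract_stress_trace(m, spec, threshold_method, fixed_level, base_col)
  list(trace = tr,
       summary = detect_twitches(tr, min_prominence_fraction, analysis_window))
}
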