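#' Nuclear orientations from a labeled mask
#'
#' For every labeled region of sufficient area, the orientation of the major
#' axis from second-order image moments, as an axial angle in `[-90, 90)`
#' degrees. Angles are measured counter-clockwise from the +x (column) axis
#' in the physical frame (i.e. with the row axis pointing up), so a nucleus
#' drawn at +30 degrees reads +30 degrees. Nearly isotropic regions (a
#' circle's principal moments are equal, so its axis is undefined) are
#' excluded with a warning.
#'
#' @param label_image Integer matrix; 0 = background, k = pixels of
#'   nucleus k.
#' @param min_area Minimum region area in pixels (default 20).
#' @param pattern_direction Reference direction in degrees subtracted from
#'   every angle (default 0).
#' @param isotropy_tol Regions with moment anisotropy
#'   `(l1 - l2)/(l1 + l2)` below this are treated as axis-free
#'   (default 1e-3).
#' @return An [orientation_set()].
#' @export
fit_nucleus_orientations <- function(label_image, min_area = 20,
                                     pattern_direction = 0,
                                     isotropy_tol = 1e-3) {
  stopifnot(is.matrix(label_image))
  labs <- sort(unique(label_image[label_image > 0]))
  angles <- numeric(0)
  n_round <- 0L
  for (lb in labs) {
    px <- which(label_image == lb, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    x <- px[, 2]
    y <- -px[, 1]               # row axis points down in storage; flip
    mu20 <- stats::var(x)
    mu02 <- stats::var(y)
    mu11 <- stats::cov(x, y)
    spread <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
    if (spread / (mu20 + mu02) < isotropy_tol) {
      n_round <- n_round + 1L
      next
    }
    angles <- c(angles, 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi)
  }
  if (n_round > 0) {
    warning(sprintf("%d nearly circular region(s) with undefined axis excluded",
                    n_round))
  }
  if (!length(angles)) stop("no labeled regions survive the area filter")
  orientation_set(angles - pattern_direction, pattern_direction)
}

#' Axial circular summary of an orientation set
#'
#' Doubled-angle circular statistics for axial (180-degree-periodic) data:
#' with \eqn{z = \sum e^{i 2\theta} / n}, the mean axis is
#' \eqn{\bar\theta = \arg(z) / 2}, the resultant length is \eqn{r_2 = |z|},
#' the axial circular standard deviation is
#' \eqn{\sqrt{-2 \ln r_2} / 2} (in radians, halved to undo the angle
#' doubling) and the standard error of the mean axis is that s.d. divided by
#' \eqn{\sqrt n}. The nematic order parameter
#' \eqn{S = 2 \langle \cos^2(\theta - \bar\theta) \rangle - 1} is reported
#' alongside (1 = perfect alignment, 0 = isotropic). A 10-degree-bin
#' histogram over `[-90, 90)` is attached.
#'
#' If `r2` is numerically zero (perfectly balanced axes) the mean is
#' undefined and the summary is flagged, with `NA` angle.
#'
#' @param os An [orientation_set()].
#' @return An object of class `orientation_summary`: `mean_angle` (deg),
#'   `sem` (deg), `resultant_length`, `order_parameter`, `n`,
#'   `undefined_mean`, `histogram` (data.frame of bin edges and counts).
#' @examples
#' circular_summary(orientation_set(c(10, 10, 10)))
#' @export
circular_summary <- function(os) {
  stopifnot(inherits(os, "orientation_set"))
  th2 <- 2 * os$angles * pi / 180
  zc <- mean(cos(th2)); zs <- mean(sin(th2))
  r2 <- sqrt(zc^2 + zs^2)
  edges <- seq(-90, 90, by = 10)
  counts <- as.vector(table(cut(os$angles, edges, right = FALSE,
                                include.lowest = FALSE)))
  hist_df <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                        count = counts)
  if (r2 < 1e-12) {
    return(structure(
      list(mean_angle = NA_real_, sem = NA_real_, resultant_length = 0,
           order_parameter = NA_real_, n = os$n, undefined_mean = TRUE,
           histogram = hist_df),
      class = "orientation_summary"))
  }
  mean_angle <- canonicalize_axial(0.5 * atan2(zs, zc) * 180 / pi)
  circ_sd_deg <- sqrt(pmax(0, -2 * log(r2))) / 2 * 180 / pi
  dth <- (os$angles - mean_angle) * pi / 180
  structure(
    list(mean_angle = mean_angle,
         sem = circ_sd_deg / sqrt(os$n),
         resultant_length = r2,
         order_parameter = 2 * mean(cos(dth)^2) - 1,
         n = os$n,
         undefined_mean = FALSE,
         histogram = hist_df),
    class = "orientation_summary"
  )
}

#' @export
print.orientation_summary <- function(x, ...) {
  if (x$undefined_mean) {
    cat(sprintf("orientation_summary: n = %d, mean axis undefined (r2 = 0)\n",
                x$n))
  } else {
    cat(sprintf(
      "orientation_summary: n = %d, mean %.2f deg +/- %.2f deg (s.e.m.), r2 = %.3f, OOP = %.3f\n",
      x$n, x$mean_angle, x$sem, x$resultant_length, x$order_parameter))
  }
  invisible(x)
}
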