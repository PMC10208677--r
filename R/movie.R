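#' Construct a time-lapse movie
#'
#' A `movie` is a 3-D intensity stack (row x col x frame) with its frame
#' rate and physical pixel size attached. Cantilever contractility movies are
#' binary masks (nominally 100 frames/s); calcium optical-mapping movies are
#' graded fluorescence (nominally 400 frames/s).
#'
#' @param frames Numeric array, dim = c(rows, cols, n_frames), values >= 0.
#'   Binary-mask movies must contain only 0 and 1.
#' @param frame_rate Frames per second.
#' @param pixel_size Physical size of one pixel in m.
#' @param kind `"binary_mask"`, `"fluorescence"`, or `"dff"` (a normalized
#'   Delta F / F stack, the only kind allowed to hold negative values).
#' @return An object of class `movie`.
#' @export
movie <- function(frames, frame_rate, pixel_size,
                  kind = c("fluorescence", "binary_mask", "dff")) {
  kind <- match.arg(kind)
  stopifnot(is.array(frames), length(dim(frames)) == 3,
            dim(frames)[3] >= 2,
            frame_rate > 0, pixel_size > 0)
  if (kind != "dff" && any(frames < 0)) {
    stop("intensities must be non-negative")
  }
  if (kind == "binary_mask" && !all(frames %in% c(0, 1))) {
    stop("binary_mask frames must contain only 0 and 1")
  }
  structure(
    list(frames = frames, frame_rate = frame_rate,
         pixel_size = pixel_size, kind = kind),
    class = "movie"
  )
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "movie (%s): %d x %d px, %d frames at %g fps, pixel %g um\n",
    x$kind, d[1], d[2], d[3], x$frame_rate, 1e6 * x$pixel_size
  ))
  invisible(x)
}

n_frames <- function(m) dim(m$frames)[3]

frame_times <- function(m) (seq_len(n_frames(m)) - 1) / m$frame_rate

#' Write a movie as a multi-page TIFF with a JSON metadata sidecar
#'
#' One TIFF page per frame: 8-bit for binary masks, 16-bit for fluorescence
#' (linearly rescaled to use the full range; the scale is recorded in the
#' sidecar so [read_movie()] restores original intensities).
#'
#' @param m A [movie()].
#' @param path Output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "movie"))
  if (m$kind == "dff") {
    stop("dff movies are in-memory intermediates; write the raw fluorescence movie")
  }
  bits <- if (m$kind == "binary_mask") 8L else 16L
  top <- max(m$frames)
  scale <- if (m$kind == "binary_mask" || top == 0) 1 else top
  pages <- lapply(seq_len(n_frames(m)),
                  function(j) m$frames[, , j] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- list(frame_rate = m$frame_rate, pixel_size = m$pixel_size,
               kind = m$kind, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path with a `<path>.json` sidecar.
#' @return A [movie()].
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- dim(pages[[1]])
  frames <- array(0, c(d[1], d[2], length(pages)))
  for (j in seq_along(pages)) frames[, , j] <- pages[[j]] * meta$intensity_scale
  if (meta$kind == "binary_mask") frames <- round(frames)
  movie(frames, meta$frame_rate, meta$pixel_size, meta$kind)
}
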