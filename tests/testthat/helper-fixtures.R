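# shared fixture builders; everything is generated in code, seeded

default_spec <- function() mechanical_spec()

# render a full cantilever fixture with known ground truth
cantilever_fixture <- function(frequency, twitch_kpa, seed,
                               duration = 30, diastolic_kpa = 1,
                               noise_sd = 0.02, rows = 16) {
  sp <- default_spec()
  px <- sp$free_length_L / 500
  tr <- make_stress_trace(frequency, diastolic_kpa * 1e3, twitch_kpa * 1e3,
                          duration, 100)
  mv <- render_cantilever_movie(tr, sp, rows = rows, cols = 516,
                                pixel_size = px, noise_sd = noise_sd,
                                seed = seed)
  list(movie = mv, trace = tr, spec = sp,
       truth = list(frequency = frequency, twitch_Pa = twitch_kpa * 1e3))
}

# calcium fixture from an edge or point source at known speed (m/s)
calcium_fixture <- function(source_kind, speed, seed,
                            rows = 40, cols = 80, pixel_size = 5e-5,
                            noise_frac = 0.05, n_beats = 3) {
  loc <- if (source_kind == "edge") c(1, 1) else c(rows %/% 2, cols %/% 2)
  field <- make_activation_field(rows, cols, pixel_size, source_kind,
                                 loc, speed)
  mv <- render_calcium_movie(field, frame_rate = 400, n_beats = n_beats,
                             beat_period = 1, noise_sd = noise_frac * 50,
                             seed = seed)
  list(movie = mv, field = field)
}

# wrap a plain activation-time matrix as an activation_map (for analytic
# fields that never went through a movie)
as_activation_map <- function(T, pixel_size, valid = NULL, frame_rate = 400) {
  structure(
    list(T = T,
         valid = if (is.null(valid)) matrix(TRUE, nrow(T), ncol(T)) else valid,
         method = "half_amplitude",
         frame_rate = frame_rate,
         pixel_size = pixel_size,
         window = c(1L, 2L)),
    class = "activation_map"
  )
}

# rasterize a filled ellipse into a label matrix (angle in degrees,
# measured CCW from the +column axis with the row axis pointing up)
rasterize_ellipse <- function(nr, nc, r0, c0, a, b, angle_deg, label = 1L) {
  th <- angle_deg * pi / 180
  m <- matrix(0L, nr, nc)
  dx <- col(m) - c0
  dy <- -(row(m) - r0)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  m[(u / a)^2 + (v / b)^2 <= 1] <- label
  m
}
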