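#' Drifting-grating stimulus specification
#'
#' Describes the sinusoidal grating used in the motion-discrimination task:
#' a drifting sinusoid windowed by a spatial Gaussian envelope, displayed on
#' a mid-grey background.  Defaults follow the study conditions: 1 cycle per
#' degree of visual angle, drifting at 4 degrees/s, 0.42 Michelson contrast,
#' on a 32 cd/m^2 background.  The spatial envelope SD is 0.5 degrees for the
#' small grating and 2 degrees for the large one.
#'
#' @param spatial_frequency Cycles per degree of visual angle (> 0).
#' @param drift_speed Drift speed in degrees of visual angle per second.
#' @param michelson_contrast Peak Michelson contrast, in `[0, 1]`.
#' @param spatial_envelope_sd SD of the spatial Gaussian envelope, degrees.
#' @param background_luminance Background luminance in cd/m^2 (> 0).
#' @param initial_phase Initial spatial phase in degrees, in `[0, 360)`.
#'
#' @return An object of class `grating_spec`.
#' @examples
#' small <- grating_spec(spatial_envelope_sd = 0.5)
#' large <- grating_spec(spatial_envelope_sd = 2)
#' @export
grating_spec <- function(spatial_frequency = 1,
                         drift_speed = 4,
                         michelson_contrast = 0.42,
                         spatial_envelope_sd = 0.5,
                         background_luminance = 32,
                         initial_phase = 0) {
  if (!is.numeric(spatial_frequency) || spatial_frequency <= 0) {
    stop_invalid("`spatial_frequency` must be a positive number.")
  }
  if (michelson_contrast < 0 || michelson_contrast > 1) {
    stop_invalid("`michelson_contrast` must lie in [0, 1].")
  }
  if (spatial_envelope_sd <= 0) {
    stop_invalid("`spatial_envelope_sd` must be positive.")
  }
  if (background_luminance <= 0) {
    stop_invalid("`background_luminance` must be positive.")
  }
  if (initial_phase < 0 || initial_phase >= 360) {
    stop_invalid("`initial_phase` must lie in [0, 360) degrees.")
  }
  structure(
    list(
      spatial_frequency = spatial_frequency,
      drift_speed = drift_speed,
      michelson_contrast = michelson_contrast,
      spatial_envelope_sd = spatial_envelope_sd,
      background_luminance = background_luminance,
      initial_phase = initial_phase
    ),
    class = "grating_spec"
  )
}

#' Temporal parameters of a briefly displayed stimulus
#'
#' The nominal duration of the stimulus is defined as twice the SD of the
#' Gaussian temporal contrast envelope, so `envelope_sd = nominal_duration/2`.
#' `peak_offset` displaces the envelope peak relative to the display's frame
#' sample times, in frame periods: 0 aligns the peak with a frame and 0.5 is
#' the half-frame displacement used to obtain two visible frames on a 60 Hz
#' display for the shortest stimulus.
#'
#' @param nominal_duration Nominal stimulus duration in seconds (> 0),
#'   equal to 2 envelope SDs.
#' @param refresh_rate Display refresh rate in Hz (> 0).
#' @param peak_offset Peak displacement in frame periods, in `[0, 1)`.
#'
#' @return An object of class `stimulus_timing` with fields
#'   `nominal_duration`, `envelope_sd`, `refresh_rate` and `peak_offset`.
#' @examples
#' stimulus_timing(0.01, refresh_rate = 120)
#' stimulus_timing(0.01, refresh_rate = 60, peak_offset = 0.5)
#' @export
stimulus_timing <- function(nominal_duration, refresh_rate, peak_offset = 0) {
  if (!is.numeric(nominal_duration) || length(nominal_duration) != 1 ||
      nominal_duration <= 0) {
    stop_invalid("`nominal_duration` must be a positive number of seconds.")
  }
  if (!is.numeric(refresh_rate) || length(refresh_rate) != 1 ||
      refresh_rate <= 0) {
    stop_invalid("`refresh_rate` must be a positive frequency in Hz.")
  }
  if (peak_offset < 0 || peak_offset >= 1) {
    stop_invalid("`peak_offset` must lie in [0, 1) frame periods.")
  }
  structure(
    list(
      nominal_duration = nominal_duration,
      envelope_sd = nominal_duration / 2,
      refresh_rate = refresh_rate,
      peak_offset = peak_offset
    ),
    class = "stimulus_timing"
  )
}

#' Logarithmically spaced duration grid
#'
#' Builds the geometric grid of stimulus durations used by the method of
#' constant stimuli.  The default reproduces the study grid: 7 durations
#' from 0.01 s to 0.2 s.
#'
#' @param n_durations Number of durations (>= 2).
#' @param d_min,d_max Shortest and longest duration in seconds,
#'   `0 < d_min < d_max`.
#'
#' @return Numeric vector of durations in seconds; the ratio between
#'   consecutive elements is constant.
#' @examples
#' make_duration_grid()          # 0.01 ... 0.2 s, 7 steps
#' make_duration_grid(2, 1, 10)  # just the endpoints
#' @export
make_duration_grid <- function(n_durations = 7, d_min = 0.01, d_max = 0.2) {
  if (!is.numeric(n_durations) || n_durations < 2 ||
      n_durations != round(n_durations)) {
    stop_invalid("`n_durations` must be an integer >= 2.")
  }
  if (!is.numeric(d_min) || !is.numeric(d_max) || d_min <= 0 ||
      d_max <= d_min) {
    stop_invalid("Durations must satisfy 0 < d_min < d_max.")
  }
  grid <- 10^seq(log10(d_min), log10(d_max), length.out = n_durations)
  grid[1] <- d_min
  grid[n_durations] <- d_max
  grid
}

#' Quantize the Gaussian contrast envelope to display frames
#'
#' A display realizes the continuous Gaussian temporal contrast envelope as a
#' discrete sequence of frames.  Each frame takes the contrast of the
#' envelope sampled at its vsync time; frame times sit on the display's frame
#' grid, displaced by `peak_offset` frame periods relative to the envelope
#' peak.  The envelope is truncated at two temporal SDs on either side of the
#' peak (the stimulus duration is defined as 2 SDs), so frames beyond
#' `|t| > 2 * envelope_sd` carry exactly zero contrast and are omitted.
#'
#' With this rule the shortest study stimulus (0.01 s) spans 3 frames at
#' 120 Hz, a single frame at 60 Hz, and 2 equal-contrast frames at 60 Hz
#' when the peak is displaced by half a frame.
#'
#' @param timing A [stimulus_timing()] object.
#' @param peak_contrast Peak Michelson contrast of the envelope, in `(0, 1]`.
#'
#' @return A tibble of class `frame_schedule` with columns `frame_index`,
#'   `time_s` (frame time relative to the envelope peak) and `contrast`;
#'   attributes `refresh_rate` and `peak_offset`.
#' @examples
#' frame_schedule(stimulus_timing(0.01, 120))            # 3 frames
#' frame_schedule(stimulus_timing(0.01, 60))             # 1 frame
#' frame_schedule(stimulus_timing(0.01, 60, peak_offset = 0.5))  # 2 frames
#' @export
frame_schedule <- function(timing, peak_contrast = 0.42) {
  if (!inherits(timing, "stimulus_timing")) {
    stop_invalid("`timing` must be a `stimulus_timing` object.")
  }
  if (peak_contrast <= 0 || peak_contrast > 1) {
    stop_invalid("`peak_contrast` must lie in (0, 1].")
  }
  period <- 1 / timing$refresh_rate
  sigma <- timing$envelope_sd
  t_max <- 2 * sigma
  tol <- 1e-9 * period  # boundary-inclusive truncation despite fp rounding
  k_lo <- ceiling(-t_max / period - timing$peak_offset - 1e-9)
  k_hi <- floor(t_max / period - timing$peak_offset + 1e-9)
  k <- seq.int(k_lo, k_hi)
  t <- (k + timing$peak_offset) * period
  keep <- abs(t) <= t_max + tol
  t <- t[keep]
  contrast <- peak_contrast * exp(-t^2 / (2 * sigma^2))
  out <- tibble(
    frame_index = seq_along(t),
    time_s = t,
    contrast = contrast
  )
  attr(out, "refresh_rate") <- timing$refresh_rate
  attr(out, "peak_offset") <- timing$peak_offset
  class(out) <- c("frame_schedule", class(out))
  out
}

#' Number of displayed (nonzero-contrast) frames in a schedule
#'
#' @param schedule A [frame_schedule()] tibble.
#' @return Integer count of frames with contrast strictly greater than zero.
#' @examples
#' effective_frame_count(frame_schedule(stimulus_timing(0.01, 120)))
#' @export
effective_frame_count <- function(schedule) {
  if (!is.data.frame(schedule) || !"contrast" %in% names(schedule)) {
    stop_invalid("`schedule` must be a frame schedule with a `contrast` column.")
  }
  sum(schedule$contrast > 0)
}

#' Luminance profile of one grating frame
#'
#' Computes the luminance of a drifting grating at time `t` along a spatial
#' axis (degrees of visual angle, centered on the patch):
#' `L(x, t) = L_b * (1 + c * g(x) * sin(2 * pi * f * (x - v * t) + phi))`,
#' with `g` the unit-peak spatial Gaussian envelope.  Values are bounded by
#' `L_b * (1 - c)` and `L_b * (1 + c)`.
#'
#' @param spec A [grating_spec()].
#' @param contrast Contrast of this frame (the temporal envelope value),
#'   in `[0, 1]`.
#' @param t Time in seconds.
#' @param x_grid Positions in degrees of visual angle.
#' @return Numeric vector of luminances (cd/m^2), one per position.
#' @export
render_frame <- function(spec, contrast, t, x_grid) {
  if (!inherits(spec, "grating_spec")) {
    stop_invalid("`spec` must be a `grating_spec` object.")
  }
  if (!is.numeric(contrast) || contrast < 0 || contrast > 1) {
    stop_invalid("`contrast` must lie in [0, 1].")
  }
  if (any(!is.finite(x_grid))) {
    stop_invalid("`x_grid` must be finite.")
  }
  g <- exp(-x_grid^2 / (2 * spec$spatial_envelope_sd^2))
  phase <- spec$initial_phase * pi / 180
  carrier <- sin(2 * pi * spec$spatial_frequency *
                   (x_grid - spec$drift_speed * t) + phase)
  spec$background_luminance * (1 + contrast * g * carrier)
}
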