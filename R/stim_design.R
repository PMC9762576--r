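#' Enumerate the factorial stimulus design
#'
#' Builds the full Cartesian product of the four stimulus feature grids used
#' throughout the package: probe size (radius, mm), ramp amplitude (maximum
#' indentation depth, mm), ramp-up time (s), and the frequency of the
#' sinusoidal vibration superimposed during the hold (Hz). The full design
#' has \eqn{4 \times 4 \times 5 \times 10 = 800} distinct conditions.
#'
#' The order is deterministic: size-major, frequency-minor, i.e. frequency
#' cycles fastest, then ramp time, then ramp amplitude, then size.
#'
#' @param size_mm Probe radii in mm.
#' @param ramp_amplitude_mm Maximum indentation depths in mm.
#' @param ramp_time_s Ramp-up durations in s.
#' @param frequency_hz Vibration frequencies in Hz (0 = no vibration).
#'
#' @return A tibble with one row per condition and columns `condition_id`,
#'   `size_mm`, `ramp_amplitude_mm`, `ramp_time_s`, `frequency_hz`.
#' @examples
#' design <- build_design()
#' nrow(design) # 800
#' @export
build_design <- function(size_mm = 1:4,
                         ramp_amplitude_mm = c(0.3, 0.6, 0.9, 1.2),
                         ramp_time_s = seq(0.01, 0.05, by = 0.01),
                         frequency_hz = c(0, 10, 20, 40, 60, 80, 100, 130, 160, 200)) {
  grid <- tidyr::expand_grid(
    size_mm = size_mm,
    ramp_amplitude_mm = ramp_amplitude_mm,
    ramp_time_s = ramp_time_s,
    frequency_hz = frequency_hz
  )
  dplyr::mutate(grid, condition_id = dplyr::row_number(), .before = 1)
}

#' Motor-noise specification for trial rendering
#'
#' Half-widths of the uniform trial-to-trial jitters emulating motor noise
#' during active touch: the probe location along the afferent line, the
#' amplitude of the superimposed sinusoid, and the ramp amplitude.
#'
#' @param location_jitter_mm Half-width of probe-location jitter (mm).
#' @param sine_amplitude_jitter_mm Half-width of sine-amplitude jitter (mm).
#' @param ramp_amplitude_jitter_mm Half-width of ramp-amplitude jitter (mm).
#' @return A list of class `motor_noise`.
#' @export
motor_noise <- function(location_jitter_mm = 0.3,
                        sine_amplitude_jitter_mm = 0.05,
                        ramp_amplitude_jitter_mm = 0.1) {
  hw <- c(location_jitter_mm, sine_amplitude_jitter_mm, ramp_amplitude_jitter_mm)
  if (any(!is.finite(hw)) || any(hw < 0)) {
    rlang::abort("motor-noise half-widths must be finite and non-negative")
  }
  structure(
    list(
      location_jitter_mm = location_jitter_mm,
      sine_amplitude_jitter_mm = sine_amplitude_jitter_mm,
      ramp_amplitude_jitter_mm = ramp_amplitude_jitter_mm
    ),
    class = "motor_noise"
  )
}

#' Zero motor noise (noiseless rendering)
#' @return A `motor_noise` object with all half-widths zero.
#' @export
no_motor_noise <- function() motor_noise(0, 0, 0)

#' Render one trial's probe-indentation time series
#'
#' Renders a ramp-and-hold indentation: a linear ramp up over `ramp_time_s`
#' to the (jittered) ramp amplitude, a hold with a superimposed sinusoid
#' that starts once the plateau is reached, and a linear ramp down (mirroring
#' the ramp-up duration) at the end of the trial. Per-trial motor noise
#' jitters the probe location, the sine amplitude, and the ramp amplitude,
#' each drawn uniformly within the half-widths of `noise` from the seeded
#' RNG, so an identical seed reproduces the trace exactly.
#'
#' Depth is clipped at zero: the sinusoid rides on the plateau with onset
#' phase 0 and can never drive the trace negative. A jittered sine amplitude
#' that would be negative is clamped at zero and recorded in the
#' `clamped_sine` field.
#'
#' @param features One row of [build_design()] (or any list with fields
#'   `size_mm`, `ramp_amplitude_mm`, `ramp_time_s`, `frequency_hz`).
#' @param noise A [motor_noise()] specification.
#' @param duration_s Total trial duration in s; must exceed twice the ramp
#'   time so that a hold phase exists.
#' @param dt_s Sample interval in s; must resolve the highest stimulus
#'   frequency (dt <= 1/(10 * 200 Hz) = 0.5 ms).
#' @param seed Integer seed for the jitter draws.
#' @param probe_center_cm Nominal probe-center position along the afferent
#'   line, in cm (jittered by the location noise).
#' @param sine_amplitude_mm Base amplitude of the superimposed sinusoid (mm).
#'
#' @return A list of class `stim_trace` with fields `dt_s`, `depth_mm`
#'   (numeric vector, one sample per time step), `time_s`, `probe_center_cm`,
#'   `probe_size_mm`, `trial_duration_s`, `features`, `clamped_sine`.
#' @examples
#' f <- build_design()[1, ]
#' tr <- render_trial(f, no_motor_noise(), seed = 1)
#' max(tr$depth_mm) # equals the ramp amplitude when frequency is 0
#' @export
render_trial <- function(features, noise = motor_noise(), duration_s = 0.5,
                         dt_s = 1e-4, seed = 1L, probe_center_cm = 0,
                         sine_amplitude_mm = 0.1) {
  stopifnot(inherits(noise, "motor_noise"))
  if (!is.finite(duration_s) || duration_s <= 0 || !is.finite(dt_s) || dt_s <= 0) {
    rlang::abort("duration_s and dt_s must be positive")
  }
  if (dt_s > 1 / (10 * 200)) {
    rlang::abort("dt_s too coarse: must be <= 0.5 ms to resolve 200 Hz")
  }
  ramp_time <- features$ramp_time_s
  if (duration_s <= 2 * ramp_time) {
    rlang::abort("duration_s must exceed twice the ramp time")
  }

  jit <- withr::with_seed(seed, {
    stats::runif(3, -1, 1)
  })
  center_cm <- probe_center_cm + jit[1] * noise$location_jitter_mm / 10
  amp_sine <- sine_amplitude_mm + jit[2] * noise$sine_amplitude_jitter_mm
  clamped <- amp_sine < 0
  amp_sine <- max(amp_sine, 0)
  amp_ramp <- max(features$ramp_amplitude_mm + jit[3] * noise$ramp_amplitude_jitter_mm, 0)

  n <- round(duration_s / dt_s)
  t <- (seq_len(n) - 1) * dt_s
  ramp_down_start <- duration_s - ramp_time

  depth <- rep(amp_ramp, n)
  up <- t < ramp_time
  depth[up] <- amp_ramp * t[up] / ramp_time
  down <- t >= ramp_down_start
  depth[down] <- amp_ramp * (duration_s - t[down]) / ramp_time
  # depth[n] corresponds to t = duration - dt, so the trace ends within one
  # sample of zero; force the last sample to 0 so traces start and end at rest
  depth[n] <- 0

  f_hz <- features$frequency_hz
  if (f_hz > 0 && amp_sine > 0) {
    hold <- t >= ramp_time & t < ramp_down_start
    depth[hold] <- depth[hold] + amp_sine * sin(2 * pi * f_hz * (t[hold] - ramp_time))
  }
  depth <- pmax(depth, 0)

  structure(
    list(
      dt_s = dt_s,
      time_s = t,
      depth_mm = depth,
      probe_center_cm = center_cm,
      probe_size_mm = features$size_mm,
      trial_duration_s = duration_s,
      features = tibble::as_tibble(features[c(
        "size_mm", "ramp_amplitude_mm", "ramp_time_s", "frequency_hz"
      )]),
      clamped_sine = clamped
    ),
    class = "stim_trace"
  )
}

#' @export
print.stim_trace <- function(x, ...) {
  cat(sprintf(
    "<stim_trace> %.2g s @ %.2g ms, size %g mm, ramp %g mm / %g s, %g Hz, center %.3f cm\n",
    x$trial_duration_s, x$dt_s * 1e3, x$probe_size_mm,
    x$features$ramp_amplitude_mm, x$features$ramp_time_s,
    x$features$frequency_hz, x$probe_center_cm
  ))
  invisible(x)
}

#' Plot an indentation trace
#' @param object A `stim_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.stim_trace <- function(object, ...) {
  df <- tibble::tibble(time_s = object$time_s, depth_mm = object$depth_mm)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$depth_mm)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (s)", y = "Indentation depth (mm)",
      title = sprintf(
        "%g mm probe, %g mm ramp, %g Hz",
        object$probe_size_mm, object$features$ramp_amplitude_mm,
        object$features$frequency_hz
      )
    )
}
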