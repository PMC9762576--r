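#' @useDynLib tactilepop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

# Hierarchical seed derivation: folds any number of non-negative integers
# into one 32-bit-safe seed. Multipliers kept below sqrt(2^53) so the
# modular arithmetic is exact in double precision.
derive_seed <- function(...) {
  parts <- c(...)
  s <- 17
  for (p in parts) {
    s <- ((s %% 94906265) * 94906249 + as.numeric(p) + 1) %% 2147483647
  }
  as.integer(s)
}

#' Phenomenological response parameters for an afferent class
#'
#' Returns the default parameter set for one of the three mechanoreceptive
#' afferent classes of the glabrous skin. The model is deliberately
#' phenomenological: each afferent's input drive is a rectified weighted sum
#' of indentation depth, unsigned indentation velocity, and signed
#' indentation acceleration, attenuated exponentially with the distance
#' between the afferent and the probe, and converted to spikes by a leaky
#' integrate-and-fire unit with Gaussian threshold noise and an absolute
#' refractory period.
#'
#' Class signatures, in the qualitative sense the model must reproduce:
#' * `SA1`: small receptive fields (short length constant), positive static
#'   gain, so it fires throughout a sustained indentation, with spikes also
#'   aligned to a superimposed vibration; sensitive to the probe edge, hence
#'   to probe size.
#' * `RA`: medium receptive fields, velocity gain only, so it fires at ramp
#'   on/offsets and phase-locks in the flutter range but is silent during a
#'   static hold.
#' * `PC`: very large receptive fields, acceleration gain only, so it is
#'   silent during static indentation, phase-locks at high frequencies, and
#'   its drive is computed from the probe centre — independent of probe size
#'   and static depth by construction.
#'
#' The numeric values are calibration constants chosen so that the
#' qualitative invariants above hold at physiologically plausible firing
#' rates; they are not fitted claims about real afferents.
#'
#' @param class_label One of `"SA1"`, `"RA"`, `"PC"`.
#' @return A list of class `afferent_params` with fields `class_label`,
#'   `rf_length_constant_cm`, `static_gain`, `velocity_gain`,
#'   `acceleration_gain`, `bandpass_hz`, `threshold`, `threshold_noise_sd`,
#'   `refractory_s`, `membrane_tau_s`, `size_sensitive`.
#' @export
afferent_params <- function(class_label = c("SA1", "RA", "PC")) {
  class_label <- match.arg(class_label)
  p <- switch(class_label,
    SA1 = list(
      rf_length_constant_cm = 0.15,
      static_gain = 2.0, velocity_gain = 0.02, acceleration_gain = 0,
      bandpass_hz = c(0, 100),
      threshold = 1, threshold_noise_sd = 0.1,
      refractory_s = 0.005, membrane_tau_s = 0.010,
      size_sensitive = TRUE
    ),
    RA = list(
      rf_length_constant_cm = 0.7,
      static_gain = 0, velocity_gain = 0.06, acceleration_gain = 0,
      bandpass_hz = c(5, 120),
      threshold = 1, threshold_noise_sd = 0.1,
      refractory_s = 0.005, membrane_tau_s = 0.005,
      size_sensitive = TRUE
    ),
    PC = list(
      rf_length_constant_cm = 3,
      static_gain = 0, velocity_gain = 0, acceleration_gain = 2.5e-4,
      bandpass_hz = c(40, 400),
      threshold = 1, threshold_noise_sd = 0.1,
      refractory_s = 0.003, membrane_tau_s = 0.001,
      size_sensitive = FALSE
    )
  )
  structure(c(list(class_label = class_label), p), class = "afferent_params")
}

#' Place an afferent population along a line
#'
#' Afferents terminate along a line radiating outward from the stimulation
#' site (position 0): 1 cm for SA1 and RA, 5 cm for PC, whose receptive
#' fields extend much further. Areal innervation density (afferents per
#' square cm) is mapped to a line count through a 1-cm-wide strip, so the
#' population holds `round(density * line_length)` afferents. Afferents are
#' evenly spaced with a small seeded positional dither (less than a quarter
#' of the spacing).
#'
#' @param class_label `"SA1"`, `"RA"` or `"PC"`.
#' @param density_per_cm2 Innervation density in afferents per square cm,
#'   within the simulated range `[1, 140]`.
#' @param line_length_cm Line length in cm; defaults to 1 for SA1/RA and 5
#'   for PC.
#' @param seed Integer seed for the positional dither.
#' @return A tibble of class `afferent_population` with columns `afferent`,
#'   `position_cm`, and attributes `class_label`, `density_per_cm2`,
#'   `line_length_cm`.
#' @examples
#' pop <- place_population("SA1", 30)
#' nrow(pop) # 30
#' @export
place_population <- function(class_label = c("SA1", "RA", "PC"),
                             density_per_cm2, line_length_cm = NULL,
                             seed = 1L) {
  class_label <- match.arg(class_label)
  if (!is.finite(density_per_cm2) || density_per_cm2 < 1 || density_per_cm2 > 140) {
    rlang::abort("density_per_cm2 must lie in [1, 140]")
  }
  if (is.null(line_length_cm)) {
    line_length_cm <- if (class_label == "PC") 5 else 1
  }
  n <- max(1L, round(density_per_cm2 * line_length_cm))
  spacing <- line_length_cm / n
  dither <- withr::with_seed(
    derive_seed(seed, 211L),
    stats::runif(n, -spacing / 4, spacing / 4)
  )
  pos <- pmin(pmax((seq_len(n) - 0.5) * spacing + dither, 0), line_length_cm)
  structure(
    tibble::tibble(afferent = seq_len(n), position_cm = pos),
    class_label = class_label,
    density_per_cm2 = density_per_cm2,
    line_length_cm = line_length_cm,
    class = c("afferent_population", class(tibble::tibble()))
  )
}

# Shared drive time course g(t) for one class and one trace, before the
# per-afferent receptive-field weight. Velocity enters unsigned (RA-type
# afferents respond at both ramp onset and offset); acceleration enters
# signed and is rectified with the rest, which gives 1:1 phase locking of
# PC-type afferents to a sinusoid rather than frequency-doubled locking.
class_drive_profile <- function(params, trace) {
  dt <- trace$dt_s
  depth <- trace$depth_mm
  vel <- c(diff(depth), 0) / dt
  acc <- c(diff(vel), 0) / dt
  pmax(
    params$static_gain * depth +
      params$velocity_gain * abs(vel) +
      params$acceleration_gain * acc,
    0
  )
}

# Receptive-field weight of each afferent for a given trace: exponential
# attenuation with distance to the probe edge (SA1/RA) or probe centre (PC;
# size-independent by construction).
rf_weights <- function(pop, params, trace) {
  radius_cm <- trace$probe_size_mm / 10
  if (isTRUE(params$size_sensitive)) {
    dist <- pmax(abs(pop$position_cm - trace$probe_center_cm) - radius_cm, 0)
  } else {
    dist <- abs(pop$position_cm - trace$probe_center_cm)
  }
  exp(-dist / params$rf_length_constant_cm)
}

#' Compute per-afferent drive time series for a stimulus trace
#'
#' The drive of afferent \eqn{i} is
#' \deqn{d_i(t) = w(x_i)\,\max(0,\; g_s z(t) + g_v |z'(t)| + g_a z''(t))}
#' where \eqn{z(t)} is the indentation depth, \eqn{w(x) = e^{-x/\lambda}}
#' attenuates with the distance \eqn{x_i} from the afferent to the probe
#' edge (SA1/RA) or probe centre (PC), and \eqn{g_s, g_v, g_a} are the
#' class gains. PC drive is independent of probe size and of static depth
#' by construction.
#'
#' @param pop An [place_population()] result.
#' @param params An [afferent_params()] list.
#' @param trace A [render_trial()] trace.
#' @return A matrix (afferents x time samples) of non-negative drives.
#' @export
drive <- function(pop, params, trace) {
  g <- class_drive_profile(params, trace)
  w <- rf_weights(pop, params, trace)
  out <- outer(w, g)
  rownames(out) <- NULL
  out
}

#' Generate spikes from a drive time series
#'
#' Noisy-threshold leaky integrate-and-fire: the membrane state integrates
#' the drive with time constant `membrane_tau_s`; a spike is emitted when it
#' crosses a threshold redrawn after every spike as
#' `threshold + threshold_noise_sd * N(0,1)`, followed by an absolute
#' refractory period with the state clamped at reset. The same seed yields
#' identical spikes; an all-zero drive yields none.
#'
#' @param drive_series Numeric vector (one afferent) or matrix
#'   (afferents x time) of non-negative drive values.
#' @param params An [afferent_params()] list.
#' @param dt_s Sample interval of the drive in s.
#' @param seed Integer seed (one per afferent row, recycled from a single
#'   integer by hierarchical derivation).
#' @return A list of numeric vectors of spike times (s), one per afferent.
#' @export
generate_spikes <- function(drive_series, params, dt_s = 1e-4, seed = 1L) {
  if (is.null(dim(drive_series))) {
    drive_series <- matrix(drive_series, nrow = 1)
  }
  if (any(drive_series < 0)) rlang::abort("drive must be non-negative")
  n_aff <- nrow(drive_series)
  seeds <- vapply(seq_len(n_aff), function(a) derive_seed(seed, a), integer(1))
  # the population kernel shares one drive profile; here each row may differ,
  # so call it row-wise with unit weight
  out <- vector("list", n_aff)
  for (a in seq_len(n_aff)) {
    out[[a]] <- lif_population(
      drive_series[a, ], 1.0, dt_s, params$membrane_tau_s, params$threshold,
      params$threshold_noise_sd, params$refractory_s, seeds[a]
    )[[1]]
  }
  out
}

#' Simulate a spike dataset over a stimulus design
#'
#' For every condition and trial, renders a motor-noise-jittered indentation
#' trace and simulates every afferent of every requested population
#' responding to it. All randomness (jitters, threshold noise) derives
#' deterministically from `master_seed` through a hierarchical scheme
#' indexed by condition, trial and afferent, so reruns are bitwise
#' identical and, e.g., PC responses to two probe sizes that are otherwise
#' matched differ only through the condition-indexed seeds.
#'
#' @param design A tibble from [build_design()] (or a subset of its rows).
#' @param populations A single [place_population()] result or a list of them
#'   (one per class).
#' @param n_trials Trials per condition.
#' @param noise A [motor_noise()] specification.
#' @param master_seed Integer master seed.
#' @param duration_s,dt_s Trial duration and simulation step (s).
#' @param sine_amplitude_mm Base amplitude of the superimposed sinusoid.
#' @return A list of class `spike_dataset` with elements
#'   `spikes` (tibble: `trial`, `class`, `afferent`, `time`),
#'   `trials` (tibble: `trial`, `condition_id`, the four feature columns,
#'   `trial_rep`, `seed`), `populations` (named list), `duration_s`, `dt_s`.
#' @export
simulate_dataset <- function(design, populations, n_trials = 40,
                             noise = motor_noise(), master_seed = 1L,
                             duration_s = 0.5, dt_s = 1e-4,
                             sine_amplitude_mm = 0.1) {
  if (n_trials < 1) rlang::abort("n_trials must be >= 1")
  if (inherits(populations, "afferent_population")) {
    populations <- list(populations)
  }
  labels <- vapply(populations, function(p) attr(p, "class_label"), character(1))
  if (anyDuplicated(labels)) rlang::abort("one population per class at most")
  names(populations) <- labels
  params <- lapply(labels, afferent_params)
  names(params) <- labels

  trial_tbl <- tidyr::expand_grid(
    condition_id = design$condition_id,
    trial_rep = seq_len(n_trials)
  )
  trial_tbl <- dplyr::left_join(trial_tbl, design, by = "condition_id")
  trial_tbl <- dplyr::mutate(
    trial_tbl,
    trial = dplyr::row_number(),
    seed = purrr::map2_int(
      .data$condition_id, .data$trial_rep,
      function(c, r) derive_seed(master_seed, c, r)
    ),
    .before = 1
  )

  spike_rows <- vector("list", nrow(trial_tbl))
  for (m in seq_len(nrow(trial_tbl))) {
    row <- trial_tbl[m, ]
    trace <- tryCatch(
      render_trial(row, noise, duration_s, dt_s, seed = row$seed,
                   sine_amplitude_mm = sine_amplitude_mm),
      error = function(e) {
        rlang::abort(sprintf(
          "rendering failed at condition %d, trial %d: %s",
          row$condition_id, row$trial_rep, conditionMessage(e)
        ))
      }
    )
    per_class <- vector("list", length(labels))
    for (ci in seq_along(labels)) {
      cl <- labels[ci]
      pop <- populations[[cl]]
      pr <- params[[cl]]
      g <- class_drive_profile(pr, trace)
      w <- rf_weights(pop, pr, trace)
      seeds <- vapply(
        seq_len(nrow(pop)),
        function(a) derive_seed(row$seed, ci, a),
        integer(1)
      )
      sp <- lif_population(
        g, w, dt_s, pr$membrane_tau_s, pr$threshold,
        pr$threshold_noise_sd, pr$refractory_s, seeds
      )
      n_sp <- lengths(sp)
      per_class[[ci]] <- tibble::tibble(
        trial = row$trial,
        class = cl,
        afferent = rep.int(seq_len(nrow(pop)), n_sp),
        time = unlist(sp, use.names = FALSE)
      )
    }
    spike_rows[[m]] <- dplyr::bind_rows(per_class)
  }

  structure(
    list(
      spikes = dplyr::bind_rows(spike_rows),
      trials = trial_tbl,
      populations = populations,
      duration_s = duration_s,
      dt_s = dt_s
    ),
    class = "spike_dataset"
  )
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf(
    "<spike_dataset> %d trials x {%s}, %d spikes, %.2g s trials\n",
    nrow(x$trials),
    paste(sprintf(
      "%s: %d", names(x$populations),
      vapply(x$populations, nrow, integer(1))
    ), collapse = ", "),
    nrow(x$spikes), x$duration_s
  ))
  invisible(x)
}

#' Keep a single afferent class of a dataset
#' @param dataset A `spike_dataset`.
#' @param class_label Class to keep.
#' @return A `spike_dataset` restricted to that class.
#' @export
filter_class <- function(dataset, class_label) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (!class_label %in% names(dataset$populations)) {
    rlang::abort(sprintf("class %s not present in dataset", class_label))
  }
  dataset$spikes <- dplyr::filter(dataset$spikes, .data$class == class_label)
  dataset$populations <- dataset$populations[class_label]
  dataset
}

#' Raster plot of a spike dataset
#'
#' @param dataset A `spike_dataset`.
#' @param trials Which trial indices to show (default: first 10).
#' @return A ggplot object, one facet per class, afferents on the y axis.
#' @export
plot_raster <- function(dataset, trials = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (is.null(trials)) trials <- utils::head(dataset$trials$trial, 10)
  df <- dplyr::filter(dataset$spikes, .data$trial %in% trials)
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$time, .data$afferent, colour = factor(.data$trial))
  ) +
    ggplot2::geom_point(shape = "|", size = 2, show.legend = FALSE) +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Afferent")
}

#' Vector strength of phase locking
#'
#' Resultant length of spike phases relative to a reference frequency:
#' 1 for perfect locking, ~0 for phases uniform over the cycle.
#'
#' @param spike_times Numeric vector of spike times (s).
#' @param frequency_hz Reference frequency.
#' @param t0 Phase origin (s).
#' @return Vector strength in `[0, 1]` (`NA` if no spikes).
#' @export
vector_strength <- function(spike_times, frequency_hz, t0 = 0) {
  if (length(spike_times) == 0) return(NA_real_)
  ph <- 2 * pi * frequency_hz * (spike_times - t0)
  sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
}
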