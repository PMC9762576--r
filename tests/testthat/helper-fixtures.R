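# Independent plugin mutual-information oracle: direct double loop over the
# joint distribution, kept deliberately separate from the package's
# vectorized implementation.
oracle_mi <- function(cm) {
  total <- sum(cm)
  p <- cm / total
  ps <- rowSums(p)
  psh <- colSums(p)
  I <- 0
  for (i in seq_len(nrow(cm))) {
    for (j in seq_len(ncol(cm))) {
      if (p[i, j] > 0) {
        I <- I + p[i, j] * log2(p[i, j] / (ps[i] * psh[j]))
      }
    }
  }
  I
}

one_condition <- function(size = 2, amp = 0.6, rt = 0.02, fr = 0) {
  tibble::tibble(
    condition_id = 1L, size_mm = size, ramp_amplitude_mm = amp,
    ramp_time_s = rt, frequency_hz = fr
  )
}

# hand-built single-class spike dataset for binning/perturbation tests
manual_dataset <- function(spikes, n_trials, n_afferents, duration_s = 0.5,
                           class_label = "SA1", condition_id = NULL) {
  if (is.null(condition_id)) condition_id <- rep(1L, n_trials)
  pop <- structure(
    tibble::tibble(
      afferent = seq_len(n_afferents),
      position_cm = seq(0.05, 0.95, length.out = n_afferents)
    ),
    class_label = class_label, density_per_cm2 = n_afferents,
    line_length_cm = 1,
    class = c("afferent_population", class(tibble::tibble()))
  )
  pops <- stats::setNames(list(pop), class_label)
  trials <- tibble::tibble(
    trial = seq_len(n_trials), condition_id = condition_id,
    size_mm = 2, ramp_amplitude_mm = 0.6, ramp_time_s = 0.02,
    frequency_hz = 0, trial_rep = seq_len(n_trials),
    seed = seq_len(n_trials)
  )
  structure(
    list(
      spikes = spikes, trials = trials, populations = pops,
      duration_s = duration_s, dt_s = 1e-4
    ),
    class = "spike_dataset"
  )
}

random_response <- function(M = 12, n_aff = 5, n_t = 20, seed = 1) {
  sp <- withr::with_seed(seed, {
    n_sp <- 30 * M
    tibble::tibble(
      trial = sample.int(M, n_sp, replace = TRUE),
      class = "SA1",
      afferent = sample.int(n_aff, n_sp, replace = TRUE),
      time = runif(n_sp, 0, n_t * 0.002 - 1e-6)
    )
  })
  sp <- dplyr::arrange(sp, trial, class, afferent, time)
  ds <- manual_dataset(sp, M, n_aff, duration_s = n_t * 0.002)
  list(ds = ds, R = bin_raster(ds, 0.002))
}

# ---- shared heavy fixtures (computed once per test run) --------------------

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

desk_size_design <- function() {
  build_design(
    size_mm = 1:4, ramp_amplitude_mm = 0.6, ramp_time_s = 0.02,
    frequency_hz = c(0, 60)
  )
}

desk_freq_design <- function() {
  build_design(
    size_mm = 2, ramp_amplitude_mm = 0.6, ramp_time_s = 0.02,
    frequency_hz = c(0, 10, 20, 40, 60, 80, 100, 130, 160, 200)
  )
}

# desk-scale profile: 2 densities, ~8-10 conditions per decoded feature,
# 20 trials/condition, 5 NMF instantiations
desk_size_results <- function() {
  memoize("desk_size", {
    cfg <- experiment_config(
      features = "size_mm", designs = desk_size_design(),
      classes = c("SA1", "RA", "PC"), densities = c(5, 20),
      n_trials = 20, n_instantiations = 5, K_max = 8,
      perturbations = c("spatial_shuffle", "temporal_jitter_2"),
      master_seed = 42
    )
    suppressWarnings(run_experiment(cfg))
  })
}

desk_freq_results <- function() {
  memoize("desk_freq", {
    cfg <- experiment_config(
      features = "frequency_hz", designs = desk_freq_design(),
      classes = c("SA1", "RA", "PC"), densities = c(5, 20),
      n_trials = 20, n_instantiations = 5, K_max = 8,
      perturbations = c(
        "spatial_shuffle", "temporal_jitter_2",
        "temporal_jitter_5", "temporal_jitter_10"
      ),
      master_seed = 42
    )
    suppressWarnings(run_experiment(cfg))
  })
}

# small combined-class run used for the information-algebra checks
combined_results <- function() {
  memoize("combined", {
    cfg <- experiment_config(
      features = "size_mm",
      designs = build_design(
        size_mm = 1:4, ramp_amplitude_mm = 0.6,
        ramp_time_s = 0.02, frequency_hz = 60
      ),
      classes = c("SA1", "RA", "PC"), densities = c(8),
      n_trials = 16, n_instantiations = 2, K_max = 6,
      combine_classes = TRUE, master_seed = 11
    )
    suppressWarnings(run_experiment(cfg))
  })
}
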