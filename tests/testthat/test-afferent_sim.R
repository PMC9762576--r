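test_that("populations have round(density x line length) afferents on the line", {
  expect_equal(nrow(place_population("SA1", 30)), 30)
  expect_equal(nrow(place_population("PC", 10)), 50) # 5-cm line
  expect_equal(nrow(place_population("RA", 1)), 1)
  pop <- place_population("RA", 25, seed = 3)
  expect_true(all(pop$position_cm >= 0 & pop$position_cm <= 1))
  # even spacing with dither below a quarter of the spacing
  even <- (seq_len(25) - 0.5) / 25
  expect_true(all(abs(pop$position_cm - even) < (1 / 25) / 4 + 1e-12))
  expect_identical(
    place_population("SA1", 7, seed = 5)$position_cm,
    place_population("SA1", 7, seed = 5)$position_cm
  )
  expect_error(place_population("SA1", 0.5), "density")
  expect_error(place_population("SA1", 141), "density")
})

test_that("class drives follow the class signatures", {
  f <- one_condition(fr = 0, amp = 0.9, rt = 0.02)
  tr <- render_trial(f, no_motor_noise(), seed = 1)
  hold <- tr$time_s > 0.05 & tr$time_s < 0.4
  pop <- place_population("SA1", 5, line_length_cm = 1, seed = 1)

  d_sa1 <- drive(pop, afferent_params("SA1"), tr)
  d_ra <- drive(pop, afferent_params("RA"), tr)
  d_pc <- drive(pop, afferent_params("PC"), tr)
  # static hold: SA1 sustained, RA and PC silent
  expect_gt(min(d_sa1[1, hold]), 0.5)
  expect_equal(max(d_ra[, hold]), 0)
  expect_equal(max(d_pc[, hold]), 0)
  # RA drive concentrates at ramp on/offset
  onset <- tr$time_s < 0.02
  expect_gt(max(d_ra[1, onset]), 1)
  # receptive-field attenuation: drive decays with distance from the probe
  peaks <- apply(d_sa1, 1, max)
  expect_true(all(diff(peaks) < 0))
})

test_that("PC drive is independent of probe size, SA1 drive is not", {
  tr1 <- render_trial(one_condition(size = 1, fr = 60), no_motor_noise(), seed = 7)
  tr4 <- render_trial(one_condition(size = 4, fr = 60), no_motor_noise(), seed = 7)
  pop_pc <- place_population("PC", 4, seed = 2)
  expect_identical(
    drive(pop_pc, afferent_params("PC"), tr1),
    drive(pop_pc, afferent_params("PC"), tr4)
  )
  # consequently matched-seed PC spike trains are identical across sizes
  sp1 <- generate_spikes(drive(pop_pc, afferent_params("PC"), tr1),
                         afferent_params("PC"), seed = 9)
  sp4 <- generate_spikes(drive(pop_pc, afferent_params("PC"), tr4),
                         afferent_params("PC"), seed = 9)
  expect_identical(sp1, sp4)
  pop_sa <- place_population("SA1", 10, seed = 2)
  expect_false(identical(
    drive(pop_sa, afferent_params("SA1"), tr1),
    drive(pop_sa, afferent_params("SA1"), tr4)
  ))
})

test_that("spike generation is deterministic, refractory, and silent for zero drive", {
  p <- afferent_params("RA")
  expect_identical(generate_spikes(rep(0, 5000), p, seed = 1)[[1]], numeric(0))
  dr <- rep(3, 5000)
  s1 <- generate_spikes(dr, p, seed = 12)[[1]]
  s2 <- generate_spikes(dr, p, seed = 12)[[1]]
  expect_identical(s1, s2)
  expect_false(identical(s1, generate_spikes(dr, p, seed = 13)[[1]]))
  expect_true(all(diff(s1) >= p$refractory_s - 1e-12))
  expect_true(all(diff(s1) > 0))
  expect_error(generate_spikes(rep(-1, 100), p), "non-negative")
})

test_that("PC units phase-lock to strong 200 Hz drive and SA1 fires regularly under constant drive", {
  dt <- 1e-4
  t <- seq(0, 0.5 - dt, by = dt)
  pc <- afferent_params("PC")
  dr <- 40 * pmax(sin(2 * pi * 200 * t), 0)
  sp <- generate_spikes(dr, pc, dt_s = dt, seed = 3)[[1]]
  expect_gt(vector_strength(sp[sp > 0.05], 200), 0.8)

  sa <- afferent_params("SA1")
  sp2 <- generate_spikes(rep(2, length(t)), sa, dt_s = dt, seed = 4)[[1]]
  # sustained firing across the window with sub-Poisson regularity
  expect_gt(length(sp2), 20)
  expect_lt(min(sp2), 0.05)
  expect_gt(max(sp2), 0.45)
  isi <- diff(sp2)
  expect_lt(stats::sd(isi) / mean(isi), 1)
})

test_that("simulated datasets carry labels, are reproducible, and respect spike bounds", {
  des <- build_design(
    size_mm = 2, ramp_amplitude_mm = 0.6, ramp_time_s = 0.02,
    frequency_hz = c(0, 130)
  )
  pops <- list(place_population("SA1", 5, seed = 1),
               place_population("PC", 2, seed = 1))
  ds <- simulate_dataset(des, pops, n_trials = 3, noise = motor_noise(),
                         master_seed = 21)
  expect_equal(nrow(ds$trials), nrow(des) * 3)
  expect_true(all(c("condition_id", "frequency_hz", "seed") %in% names(ds$trials)))
  expect_true(all(ds$spikes$time >= 0 & ds$spikes$time < ds$duration_s))
  # per-afferent spike times are strictly increasing
  ok <- dplyr::summarise(
    dplyr::group_by(ds$spikes, trial, class, afferent),
    inc = all(diff(time) > 0), .groups = "drop"
  )
  expect_true(all(ok$inc))
  ds2 <- simulate_dataset(des, pops, n_trials = 3, noise = motor_noise(),
                          master_seed = 21)
  expect_identical(ds$spikes, ds2$spikes)
  ds3 <- simulate_dataset(des, pops, n_trials = 3, noise = motor_noise(),
                          master_seed = 22)
  expect_false(identical(ds$spikes, ds3$spikes))
})

test_that("PC population rate grows from 0 Hz to high-frequency stimulation", {
  des <- build_design(
    size_mm = 2, ramp_amplitude_mm = 0.6, ramp_time_s = 0.02,
    frequency_hz = c(0, 130)
  )
  ds <- simulate_dataset(des, place_population("PC", 4, seed = 1),
                         n_trials = 4, noise = motor_noise(), master_seed = 5)
  counts <- dplyr::count(
    dplyr::left_join(ds$spikes, ds$trials[, c("trial", "frequency_hz")], by = "trial"),
    frequency_hz
  )
  n0 <- counts$n[counts$frequency_hz == 0]
  n130 <- counts$n[counts$frequency_hz == 130]
  expect_gt(n130, 5 * n0)
})

test_that("hierarchical seeds stay in 32-bit range and separate branches", {
  s <- replicate(500, derive_seed(sample.int(1e6, 1), sample.int(1e6, 1)))
  expect_true(all(s >= 0 & s < 2^31))
  expect_false(derive_seed(1, 2) == derive_seed(2, 1))
  expect_false(derive_seed(1) == derive_seed(1, 0))
})
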