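# Synthetic-data generator: determinism, spatial coupling of the
# superficial field, spectral content, the neural component and the
# layered-truth bookkeeping.

test_that("montage invariants hold for the built-in layouts", {
  m <- montage_default()
  expect_length(long_channels(m), 14)
  expect_length(short_channels(m), 8)
  expect_setequal(names(m$pairing), long_channels(m))
  expect_true(all(m$pairing %in% short_channels(m)))
  sep <- m$channels$separation_mm
  expect_true(min(sep[m$channels$role == "long"]) >
                max(sep[m$channels$role == "short"]))
  expect_equal(nrow(measurement_index(m)), 44)

  m2 <- montage_frontal20()
  expect_length(long_channels(m2), 20)
  expect_length(short_channels(m2), 8)
  expect_equal(sum(measurement_index(m2)$role == "long"), 40)
})

test_that("identical configs and seeds give bit-identical recordings", {
  cfg <- tiny_config(seed = 7)
  r1 <- synthesize_recording(cfg, 2)
  r2 <- synthesize_recording(cfg, 2)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$truth, r2$truth)
  r3 <- synthesize_recording(cfg, 3)
  expect_false(identical(r1$data, r3$data))
})

test_that("perfect phase coupling makes paired sites identical (r = 1)", {
  cfg <- tiny_config(phase_coupling = 1, noise_sd = 0, drift_amp = 0,
                     neural_gain = 0)
  field <- generate_superficial_field(cfg, rng_seed = 1)
  expect_equal(field[, "S1"], field[, "SD1"])
  expect_equal(cor(field[, "S1"], field[, "SD1"]), 1)
})

test_that("with zero coupling, distant sites are decorrelated", {
  cfg <- tiny_config(duration_s = 360, phase_coupling = 0,
                     oscillators = default_oscillators(0))
  rs <- vapply(1:200, function(s) {
    f <- generate_superficial_field(cfg, rng_seed = s)
    cor(f[, "S1"], f[, "S2"])  # sites 200 mm apart
  }, numeric(1))
  expect_gt(mean(abs(rs) < 0.3), 0.95)
})

test_that("superficial spectrum peaks at the configured frequency", {
  osc <- list(oscillator_spec(0.1, freq_jitter_hz = 0, amplitude = 1e-3,
                              phase_coupling = 0.95))
  cfg <- tiny_config(duration_s = 360, oscillators = osc, background_sd = 0)
  f <- generate_superficial_field(cfg, rng_seed = 3)
  x <- f[, "S1"]
  n <- length(x)
  spec <- Mod(fft(x - mean(x))[2:(n / 2)])^2
  fgrid <- (1:(n / 2 - 1)) * cfg$fs_hz / n
  expect_lte(abs(fgrid[which.max(spec)] - 0.1), cfg$fs_hz / n)
})

test_that("averaged periodograms peak at every default oscillator", {
  oscs <- default_oscillators(0.95)
  oscs <- lapply(oscs, function(o) { o$freq_jitter_hz <- 0; o })
  cfg <- tiny_config(duration_s = 360, oscillators = oscs, background_sd = 0)
  f <- generate_superficial_field(cfg, rng_seed = 5)
  n <- nrow(f)
  fgrid <- (1:(n / 2 - 1)) * cfg$fs_hz / n
  spec <- rowMeans(vapply(seq_len(ncol(f)), function(j) {
    Mod(fft(f[, j] - mean(f[, j]))[2:(n / 2)])^2
  }, numeric(n / 2 - 1)))
  for (o in oscs) {
    near <- which(abs(fgrid - o$center_freq_hz) <= cfg$fs_hz / n)
    wide <- which(abs(fgrid - o$center_freq_hz) <= 0.05)
    expect_equal(wide[which.max(spec[wide])] %in% near, TRUE)
  }
})

test_that("sampling below the oscillator Nyquist rate is rejected", {
  expect_error(synthetic_config(fs_hz = 1.5), "Nyquist")
  cfg <- tiny_config()
  cfg$fs_hz <- 1.5
  expect_error(generate_superficial_field(cfg, rng_seed = 1), "Nyquist")
})

test_that("neural component follows the event schedule and HRF", {
  hrf <- c(peak_delay_s = 6, undershoot_delay_s = 16, ratio = 1 / 6)
  zero <- generate_neural_component(empty_events(), hrf, 60, 7)
  expect_true(all(zero == 0))
  expect_equal(dim(zero), c(420L, 2L))

  ev <- tibble::tibble(onset_s = 10, duration_s = 1 / 7, label = "tap")
  one <- generate_neural_component(ev, hrf, 60, 7, amplitude_mM = 2e-4)
  peak_t <- (which.max(one[, "850"]) - 1) / 7
  expect_lte(abs(peak_t - (10 + 6)), 1 / 7 + 1e-9)

  two <- generate_neural_component(ev, hrf, 60, 7, amplitude_mM = 4e-4)
  expect_equal(two, 2 * one)

  # conversion back to concentrations gives O2Hb up, HHb down
  conc <- od_to_concentration(one, mbll_params())
  expect_gt(max(conc[, "o2hb"]), 0)
  expect_lt(min(conc[, "hhb"]), -1e-9)
  expect_gt(max(conc[, "o2hb"]), max(abs(conc[, "hhb"])))

  bad <- tibble::tibble(onset_s = 59, duration_s = 5, label = "tap")
  expect_error(generate_neural_component(bad, hrf, 60, 7), "within")
})

test_that("noise-free fully-coupled recording is an exact gain of its pair", {
  cfg <- tiny_config(noise_sd = 0, drift_amp = 0, neural_gain = 0,
                     phase_coupling = 1,
                     oscillators = default_oscillators(1))
  rec <- synthesize_recording(cfg, 1)
  for (w in c(760, 850)) {
    expect_equal(rec$data[, paste0("L01@", w)],
                 cfg$superficial_gain_long * rec$data[, paste0("S01@", w)],
                 tolerance = 1e-12)
  }
})

test_that("stored truth reproduces the data and supports oracle denoising", {
  cfg <- tiny_config(duration_s = 360, phase_coupling = 1,
                     oscillators = default_oscillators(1), seed = 21)
  rec <- synthesize_recording(cfg, 1)
  recon <- rec$truth$superficial + rec$truth$neural + rec$truth$drift +
    rec$truth$noise
  expect_equal(unname(recon), unname(rec$data), tolerance = 1e-12)

  # regressing each long channel on its paired short channel removes the
  # superficial component down to the non-superficial floor
  for (col in c("L01@850", "L02@760")) {
    ch <- sub("@.*", "", col); wl <- sub(".*@", "", col)
    short_col <- paste0(rec$montage$pairing[[ch]], "@", wl)
    fit <- lm(rec$data[, col] ~ rec$data[, short_col])
    resid_var <- var(residuals(fit))
    floor_var <- var(rec$truth$neural[, col] + rec$truth$drift[, col] +
                       rec$truth$noise[, col])
    expect_lte(resid_var - floor_var, 0.01 * var(rec$data[, col]))
  }
})

test_that("cohorts are reproducible, sized correctly, and empty at n = 0", {
  cfg <- tiny_config(n_subjects = 3, duration_s = 60)
  co1 <- synthesize_cohort(cfg)
  co2 <- synthesize_cohort(cfg)
  expect_length(co1, 3)
  expect_identical(lapply(co1, `[[`, "data"), lapply(co2, `[[`, "data"))
  cfg0 <- tiny_config(n_subjects = 0)
  expect_identical(synthesize_cohort(cfg0), list())
})

test_that("intensity representation round-trips to OD", {
  cfg <- tiny_config(duration_s = 60)
  rec <- synthesize_recording(cfg, 1)
  back <- intensity_to_od(intensity_of(rec))
  expect_lt(max(abs(back$data - rec$data)), 1e-10)
  expect_true(all(intensity_of(rec)$data > 0))
})
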