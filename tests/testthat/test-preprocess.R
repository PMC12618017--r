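# Intensity-to-OD conversion, anti-aliased resampling and the
# wavelet-coherence quality control.

make_intensity_rec <- function(data_long1 = NULL, fs = 7, n = 700) {
  m <- tiny_montage()
  mi <- measurement_index(m)
  dat <- matrix(rep(1 + 0.1 * sin(2 * pi * 0.2 * (0:(n - 1)) / fs),
                    nrow(mi)), n, nrow(mi))
  colnames(dat) <- mi$column
  if (!is.null(data_long1)) dat[, 1] <- data_long1
  new_recording(dat, "intensity", fs, m)
}

test_that("OD conversion matches -ln(I/mean) and its closed-form values", {
  rec <- make_intensity_rec(rep(c(1, 2), 350))
  od <- intensity_to_od(rec)
  expect_equal(round(od$data[1:4, 1], 4), c(0.4055, -0.2877, 0.4055, -0.2877))

  const <- make_intensity_rec(rep(3.7, 700))
  expect_true(all(abs(intensity_to_od(const)$data[, 1]) < 1e-12))

  scaled <- rec
  scaled$data <- rec$data * 7
  expect_equal(intensity_to_od(scaled)$data, od$data)
})

test_that("nonpositive intensity is rejected with channel and sample", {
  rec <- make_intensity_rec()
  rec$data[13, 2] <- 0
  expect_error(new_recording(rec$data, "intensity", 7, rec$montage),
               "positive")
  err <- tryCatch(intensity_to_od(rec), error = function(e) conditionMessage(e))
  expect_match(err, "L01@850")
  expect_match(err, "13")
})

test_that("resampling preserves the passband and kills aliases", {
  m <- tiny_montage()
  mi <- measurement_index(m)
  fs <- 8.719
  n <- round(360 * fs)
  t <- (0:(n - 1)) / fs
  dat <- matrix(0, n, nrow(mi), dimnames = list(NULL, mi$column))
  dat[, 1] <- sin(2 * pi * 0.1 * t)
  dat[, 2] <- sin(2 * pi * 4 * t)
  rec <- new_recording(dat, "od", fs, m)

  expect_identical(resample_recording(rec, fs), rec)
  expect_error(resample_recording(rec, 10), "upsampling")

  rs <- resample_recording(rec, 7)
  expect_equal(rs$fs_hz, 7)
  expect_equal(nrow(rs$data), floor((n - 1) * 7 / fs) + 1)
  tn <- (seq_len(nrow(rs$data)) - 1) / 7
  fit <- lm(rs$data[, 1] ~ sin(2 * pi * 0.1 * tn) + cos(2 * pi * 0.1 * tn))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(abs(amp - 1), 0.01)
  expect_lt(sd(rs$data[, 2]) / sd(dat[, 2]), 0.01)
})

test_that("median wavelet coherence is 1 for identical signals and behaves", {
  set.seed(31)
  x <- rnorm(2520)
  expect_lt(abs(wavelet_coherence_median(x, x, 7) - 1), 1e-6)

  y <- rnorm(2520)
  c_xy <- wavelet_coherence_median(x, y, 7)
  expect_equal(wavelet_coherence_median(y, x, 7), c_xy)           # symmetry
  expect_equal(wavelet_coherence_median(3 * x, 0.2 * y, 7), c_xy) # scaling
  expect_true(c_xy >= 0 && c_xy <= 1)

  expect_error(wavelet_coherence_median(x, y[-1], 7), "equal length")
  expect_error(
    wavelet_coherence_median(x, y, 7, coherence_qc_config(freq_band_hz = c(0.01, 5))),
    "fs/2")
})

test_that("a shared oscillation raises coherence above the noise floor", {
  set.seed(32)
  t <- (0:2519) / 7
  sh <- sin(2 * pi * 0.1 * t)
  nz <- sqrt(0.5 / 5)  # SNR 5 against a unit-amplitude sinusoid
  a <- sh + rnorm(2520, sd = nz)
  b <- sh + rnorm(2520, sd = nz)
  qc <- coherence_qc_config(freq_band_hz = c(0.05, 0.2))
  shared <- wavelet_coherence_median(a, b, 7, qc)
  indep <- wavelet_coherence_median(rnorm(2520, sd = nz),
                                    rnorm(2520, sd = nz), 7, qc)
  expect_gt(shared, indep)
  expect_gt(shared, 0.8)
})

test_that("pair rejection drops exactly the decoupled channels", {
  cfg <- tiny_config(duration_s = 360, seed = 77,
                     decoupled_long_channels = 2L)
  rec <- synthesize_recording(cfg, 1)

  res <- reject_pairs(rec)
  expect_setequal(
    unique(res$report$long_channel[!res$report$retained]), "L02")
  expect_equal(attr(res$report, "n_rejected"), 1L)
  expect_false("L02@760" %in% colnames(res$recording$data))
  expect_true("L01@760" %in% colnames(res$recording$data))
  # invariant: retained <-> min over wavelengths >= threshold
  per_ch <- tapply(res$report$median_coherence, res$report$long_channel, min)
  expect_equal(res$report$retained,
               per_ch[res$report$long_channel] >= 0.39,
               ignore_attr = TRUE)

  # near-zero threshold keeps everything; near-one rejects everything
  keep_all <- reject_pairs(rec, qc = coherence_qc_config(threshold = 1e-6))
  expect_equal(attr(keep_all$report, "n_rejected"), 0L)
  drop_all <- reject_pairs(rec, qc = coherence_qc_config(threshold = 0.999))
  expect_equal(attr(drop_all$report, "n_rejected"), 2L)

  # idempotence: a second pass on the filtered recording rejects nothing
  again <- reject_pairs(res$recording)
  expect_equal(attr(again$report, "n_rejected"), 0L)
  expect_identical(again$recording$data, res$recording$data)
})
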