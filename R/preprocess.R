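#' Convert raw light intensity to optical density
#'
#' `OD_c(t) = -ln(I_c(t) / ref_c)` per measurement column.  The reference
#' is the column's temporal mean (the conventional choice, which makes OD
#' invariant to per-channel intensity gain), unless the intensity was
#' produced by [intensity_of()], in which case the recorded baseline `I0`
#' is used and the conversion is an exact inverse.
#'
#' @param rec An intensity [new_recording()].
#' @return An OD `nirs_recording`.
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (rec$kind != "intensity") stop("intensity_to_od() expects an intensity recording")
  bad <- which(rec$data <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("nonpositive intensity in channel %s at sample %d",
                 colnames(rec$data)[bad[1, 2]], bad[1, 1]))
  }
  ref <- attr(rec$data, "i0") %||% colMeans(rec$data)
  out <- rec
  out$data <- -log(sweep(rec$data, 2, ref, `/`))
  attr(out$data, "i0") <- NULL
  out$kind <- "od"
  out
}

#' Resample a recording to a common rate
#'
#' Anti-aliased downsampling for the non-integer rate ratios of
#' continuous-wave fNIRS systems (e.g. 8.719 Hz or 7.812 Hz native to the
#' common 7 Hz): a zero-phase Chebyshev type-II low-pass (stopband from
#' just below the new Nyquist, >= 40 dB) followed by cubic-spline
#' interpolation onto the uniform target grid.  Output length is
#' `floor((n - 1) * target / native) + 1`, i.e. `floor(n * target /
#' native) +- 1`.  Requesting a rate above the native rate is an error;
#' requesting the native rate returns the input unchanged.
#'
#' @param rec A [new_recording()] (intensity or OD).
#' @param target_fs_hz Target sampling rate (default 7 Hz).
#' @return The resampled `nirs_recording`.
#' @export
resample_recording <- function(rec, target_fs_hz = 7) {
  stopifnot(inherits(rec, "nirs_recording"))
  fs <- rec$fs_hz
  if (target_fs_hz > fs + 1e-9) stop("upsampling is not supported")
  if (abs(target_fs_hz - fs) < 1e-9) return(rec)
  n <- nrow(rec$data)
  cf <- signal::cheby2(6, 45, 0.95 * target_fs_hz / fs)  # W relative to fs/2
  t_old <- (seq_len(n) - 1) / fs
  t_new <- seq(0, t_old[n], by = 1 / target_fs_hz)
  newdat <- apply(rec$data, 2, function(v) {
    vf <- signal::filtfilt(cf, v)
    spline(t_old, vf, xout = t_new)$y
  })
  colnames(newdat) <- colnames(rec$data)
  out <- rec
  out$data <- newdat
  out$fs_hz <- target_fs_hz
  if (!is.null(rec$truth)) {
    out$truth <- lapply(rec$truth, function(m) {
      mm <- apply(m, 2, function(v) spline(t_old, v, xout = t_new)$y)
      colnames(mm) <- colnames(m)
      mm
    })
  }
  out
}

#' Wavelet-coherence quality-control configuration
#'
#' Channel pairs are screened by the median magnitude-squared wavelet
#' coherence between each long channel and its paired short channel.  The
#' analytic Morlet wavelet (centre frequency `omega0 = 6`) is used with
#' `voices` scales per octave; the cross- and auto-spectra are smoothed in
#' time (Gaussian with a scale-proportional footprint) and across scales
#' (moving average over two octaves of voices), and the
#' coherence matrix is reduced to a scalar by the median over all
#' time-frequency cells inside `freq_band_hz`, excluding the
#' cone-of-influence.  The default band 0.01-1.5 Hz spans the
#' Mayer-to-cardiac physiology the regression targets; the default
#' retention threshold is 0.39.
#'
#' @param threshold Median-coherence retention threshold in (0, 1).
#' @param freq_band_hz Length-2 band `(low, high)` over which the median
#'   is taken.
#' @param omega0 Morlet centre frequency (rad/s equivalent).
#' @param voices Scales per octave.
#' @return List of class `coherence_qc_config`.
#' @export
coherence_qc_config <- function(threshold = 0.39,
                                freq_band_hz = c(0.01, 1.5),
                                omega0 = 6, voices = 12) {
  stopifnot(threshold > 0, threshold < 1,
            length(freq_band_hz) == 2, freq_band_hz[1] > 0,
            freq_band_hz[2] > freq_band_hz[1])
  structure(list(threshold = threshold, freq_band_hz = freq_band_hz,
                 omega0 = omega0, voices = voices),
            class = "coherence_qc_config")
}

# Shared FFT-domain machinery for one coherence computation: Morlet
# daughter wavelets and the scale-dependent Gaussian time-smoothing
# kernels on a common padded grid.
cwt_plan <- function(n, fs, freqs, omega0) {
  npad <- 2^ceiling(log2(1.5 * n))
  dt <- 1 / fs
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))  # Fourier factor: period = ff*s
  scales <- 1 / (ff * freqs)                    # seconds
  k <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) * (2 * pi / (npad * dt))
  pos <- k > 0
  daught <- vapply(scales, function(s) {
    psi <- numeric(npad)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-0.5 * (s * k[pos] - omega0)^2)
    psi
  }, numeric(npad))
  # time smoothing: Gaussian of sd 2*sqrt(2)*s seconds, unit DC gain
  G <- vapply(scales, function(s) exp(-(2 * s * k)^2), numeric(npad))
  list(n = n, npad = npad, scales = scales, daught = daught, G = G,
       coi_s = scales * sqrt(2))
}

# analytic Morlet CWT of x under a precomputed plan: n x nscales complex
morlet_cwt <- function(x, plan) {
  xh <- fft(c(x - mean(x), rep(0, plan$npad - plan$n)))
  mvfft(plan$daught * xh, inverse = TRUE)[seq_len(plan$n), ,
                                          drop = FALSE] / plan$npad
}

# smoothing operator S: scale-dependent Gaussian in time (via the plan's
# kernels), then a boxcar across scales (two octaves of voices, truncated
# and renormalised at the edges)
smooth_field <- function(Z, plan, voices) {
  n <- plan$n
  Zp <- rbind(Z, matrix(0, plan$npad - n, ncol(Z)))
  sm <- mvfft(mvfft(Zp) * plan$G, inverse = TRUE)[seq_len(n), ,
                                                  drop = FALSE] / plan$npad
  if (!is.complex(Z)) sm <- Re(sm)
  win <- max(1L, round(2 * voices))
  if (win > 1L) {
    half <- floor(win / 2)
    ns <- ncol(sm)
    out <- sm
    for (j in seq_len(ns)) {
      jj <- max(1, j - half):min(ns, j + half)
      out[, j] <- rowMeans(sm[, jj, drop = FALSE])
    }
    sm <- out
  }
  sm
}

#' Median wavelet coherence between two series
#'
#' Magnitude-squared wavelet coherence
#' `|S(W_x W_y* / s)|^2 / (S(|W_x|^2 / s) * S(|W_y|^2 / s))` with
#' smoothing operator `S` in time and scale, reduced to its median over
#' the configured frequency band with cone-of-influence cells excluded.
#' Symmetric in `(x, y)` and invariant to positive rescaling of either
#' input; identical (non-constant) inputs give exactly 1.
#'
#' @param x,y Equal-length numeric series.
#' @param fs_hz Sampling rate (Hz).
#' @param qc A [coherence_qc_config()].
#' @return Scalar median coherence in `[0, 1]`.
#' @export
wavelet_coherence_median <- function(x, y, fs_hz,
                                     qc = coherence_qc_config()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  band <- qc$freq_band_hz
  if (band[2] > fs_hz / 2 + 1e-9) {
    stop("frequency band must lie within (0, fs/2]")
  }
  n <- length(x)
  f_hi <- min(band[2], fs_hz / 2)
  # analyse only periods that fit at least 10 times into the record
  f_lo <- max(band[1], 10 * fs_hz / n)
  if (f_lo >= f_hi) stop("series too short for the requested band")
  freqs <- 2^seq(log2(f_hi), log2(f_lo), by = -1 / qc$voices)
  plan <- cwt_plan(n, fs_hz, freqs, qc$omega0)
  Wx <- morlet_cwt(x, plan)
  Wy <- morlet_cwt(y, plan)
  inv_s <- matrix(1 / plan$scales, n, length(freqs), byrow = TRUE)
  Sxy <- smooth_field(Wx * Conj(Wy) * inv_s, plan, qc$voices)
  Sxx <- smooth_field(Mod(Wx)^2 * inv_s, plan, qc$voices)
  Syy <- smooth_field(Mod(Wy)^2 * inv_s, plan, qc$voices)
  C <- Mod(Sxy)^2 / pmax(Sxx * Syy, 1e-300)
  C <- pmin(pmax(C, 0), 1)
  # cone of influence: within sqrt(2)*s of either record edge
  t_edge <- (pmin(seq_len(n) - 1, n - seq_len(n))) / fs_hz
  keep_t <- outer(t_edge, plan$coi_s, `>=`)
  keep_f <- matrix(freqs >= band[1] & freqs <= band[2],
                   n, length(freqs), byrow = TRUE)
  vals <- C[keep_t & keep_f]
  if (!length(vals)) stop("no usable time-frequency cells in the band")
  median(vals)
}

#' Reject unreliable long-short channel pairs by wavelet coherence
#'
#' Computes the median wavelet coherence between every long channel and
#' its paired short channel at each wavelength, and drops a long channel
#' (both wavelengths) whenever the median coherence falls below the
#' threshold at either wavelength.  Long channels lacking strong coherence
#' with their proximal short channel are likely artifact-contaminated and
#' would teach the predictor inconsistent input-output relationships.
#'
#' @param rec An OD [new_recording()].
#' @param pairing Long-to-short pairing (default: the montage's).
#' @param qc A [coherence_qc_config()].
#' @return List with `recording` (retained long channels only; short
#'   channels untouched) and `report`, a tibble `(long_channel,
#'   wavelength, median_coherence, retained)` with attribute `n_rejected`.
#' @export
reject_pairs <- function(rec, pairing = rec$montage$pairing,
                         qc = coherence_qc_config()) {
  stopifnot(inherits(rec, "nirs_recording"), rec$kind == "od")
  long_ids <- long_channels(rec$montage)
  if (!all(long_ids %in% names(pairing))) {
    stop("pairing must cover all long channels")
  }
  wl <- rec$montage$wavelengths
  rows <- list()
  for (l in long_ids) {
    for (w in wl) {
      co <- wavelet_coherence_median(rec$data[, paste0(l, "@", w)],
                                     rec$data[, paste0(pairing[[l]], "@", w)],
                                     rec$fs_hz, qc)
      rows[[length(rows) + 1]] <-
        tibble::tibble(long_channel = l, wavelength = w,
                       median_coherence = co)
    }
  }
  report <- dplyr::bind_rows(rows)
  per_ch <- tapply(report$median_coherence, report$long_channel, min)
  keep <- names(per_ch)[per_ch >= qc$threshold]
  report$retained <- report$long_channel %in% keep
  attr(report, "n_rejected") <- length(long_ids) - length(keep)

  out <- rec
  drop_ids <- setdiff(long_ids, keep)
  if (length(drop_ids)) {
    keep_cols <- !(sub("@.*$", "", colnames(rec$data)) %in% drop_ids)
    out$data <- rec$data[, keep_cols, drop = FALSE]
    out$montage$channels <-
      rec$montage$channels[!(rec$montage$channels$channel_id %in% drop_ids), ]
    out$montage$pairing <- rec$montage$pairing[keep]
    if (!is.null(rec$truth)) {
      out$truth <- lapply(rec$truth, function(m) m[, keep_cols, drop = FALSE])
    }
  }
  list(recording = out, report = report)
}
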