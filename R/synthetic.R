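#' Superficial oscillator specification
#'
#' One quasi-periodic component of scalp physiology.  The defaults model
#' the three rhythms that dominate superficial fNIRS signals: cardiac
#' (~1 Hz), respiratory (~0.25 Hz) and Mayer waves (~0.1 Hz).  The centre
#' frequency is slowly modulated by a bounded random walk
#' (`freq_jitter_hz`) shared across sites, so that long-short coherence is
#' high but below 1, as in real recordings.  `phase_coupling` in [0, 1]
#' controls how similar the oscillation is across scalp sites: 1 means an
#' identical waveform everywhere; towards 0, sites acquire independent,
#' slowly wandering phase offsets and amplitude differences whose spatial
#' correlation decays with optode distance.
#'
#' @param center_freq_hz Positive centre frequency in Hz.
#' @param freq_jitter_hz Bound of the slow frequency modulation, Hz.
#' @param amplitude Oscillation amplitude in OD units (at the
#'   short-channel scale, reference wavelength).
#' @param phase_coupling Spatial phase coupling in `[0, 1]`.
#' @return A list of class `oscillator_spec`.
#' @export
oscillator_spec <- function(center_freq_hz, freq_jitter_hz = 0.02,
                            amplitude = 1e-3, phase_coupling = 0.95) {
  stopifnot(center_freq_hz > 0, freq_jitter_hz >= 0, amplitude >= 0,
            phase_coupling >= 0, phase_coupling <= 1)
  structure(list(center_freq_hz = center_freq_hz,
                 freq_jitter_hz = freq_jitter_hz,
                 amplitude = amplitude,
                 phase_coupling = phase_coupling),
            class = "oscillator_spec")
}

#' @rdname oscillator_spec
#' @export
default_oscillators <- function(phase_coupling = 0.95) {
  list(
    cardiac     = oscillator_spec(1.00, 0.05, 6e-3, phase_coupling),
    respiratory = oscillator_spec(0.25, 0.02, 5e-3, phase_coupling),
    mayer       = oscillator_spec(0.10, 0.01, 8e-3, phase_coupling)
  )
}

#' Configuration of the synthetic fNIRS cohort generator
#'
#' Defines the study conditions emulated by the simulator: 6-minute
#' resting recordings at 7 Hz on the default 14-long + 8-short montage,
#' with shared superficial oscillations (cardiac / respiratory / Mayer), a
#' broadband low-frequency systemic background, spatially heterogeneous
#' scalp coupling, optional 20 s-on / 20 s-off task blocks driving a
#' double-gamma hemodynamic response in the long channels, slow instrument
#' drift and white sensor noise.  Amplitudes are in OD units at the
#' short-channel scale; long channels receive the superficial signal
#' amplified by `superficial_gain_long` (the longer photon path through
#' the scalp).  All signal components are reproducible from `seed`.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param duration_s Recording duration in seconds (default 360).
#' @param fs_hz Sampling rate in Hz (default 7; must exceed twice the
#'   fastest oscillator frequency).
#' @param oscillators List of [oscillator_spec()]s.
#' @param superficial_gain_long Coupling gain of the superficial signal
#'   into long channels (default 3, the approximate scalp-path ratio).
#' @param neural_gain Gain on the cortical (task) component in long
#'   channels; 0 disables it.
#' @param hrf_params Named vector `(peak_delay_s, undershoot_delay_s,
#'   ratio)` of the double-gamma hemodynamic response.
#' @param drift_amp Standard deviation of the slow per-measurement drift
#'   (OD units).
#' @param noise_sd White sensor-noise standard deviation (OD units).
#' @param background_sd Standard deviation of the shared broadband
#'   low-frequency systemic background (OD units).
#' @param task_blocks `NULL` for resting state, or `list(on_s, off_s)`
#'   for a block design (tapping-style 20/20 by default when enabled).
#' @param montage A [nirs_montage()] (default [montage_default()]).
#' @param phase_coupling Default spatial phase coupling for oscillators
#'   and background (see [oscillator_spec()]).
#' @param spatial_decay_mm Length scale of the exponential spatial
#'   correlation of scalp physiology across optode sites.
#' @param spectral_weights Named vector of per-wavelength scaling of the
#'   superficial OD signal (hemoglobin absorption differs across
#'   wavelengths).
#' @param hrf_amplitude_mM Peak task-evoked oxygenated-hemoglobin change
#'   in mM (scaled into OD through the modified Beer-Lambert forward
#'   model).
#' @param spontaneous_mM Standard deviation (mM O2Hb) of the spontaneous
#'   resting-state cortical fluctuations present in every long channel
#'   (pink spectrum, channel-specific, absent from short channels); they
#'   are what lets a model learn that channel-idiosyncratic content must
#'   not be mapped into the superficial prediction.
#' @param neural_channels Integer indices (into the long-channel list)
#'   of the channels that receive the cortical component.  Task
#'   responses are spatially localised: the default is the third
#'   quadrant of the long-channel list (the left temporo-parietal /
#'   motor group on the built-in montages), not the whole array.
#' @param decoupled_long_channels Integer indices (into the long-channel
#'   list) whose superficial driver is replaced by an independent
#'   realisation; used to construct known-bad pairs for QC fixtures.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 30, duration_s = 360, fs_hz = 7,
                             oscillators = NULL,
                             superficial_gain_long = 3,
                             neural_gain = 1,
                             hrf_params = c(peak_delay_s = 6,
                                            undershoot_delay_s = 16,
                                            ratio = 1 / 6),
                             drift_amp = 5e-4, noise_sd = 5e-4,
                             background_sd = 1e-2,
                             task_blocks = NULL,
                             montage = montage_default(),
                             phase_coupling = 0.95,
                             spatial_decay_mm = 60,
                             spectral_weights = c("760" = 0.75, "850" = 1),
                             hrf_amplitude_mM = 3e-4,
                             spontaneous_mM = 3e-4,
                             neural_channels = NULL,
                             decoupled_long_channels = integer(0),
                             seed = 1L) {
  if (is.null(oscillators)) oscillators <- default_oscillators(phase_coupling)
  stopifnot(n_subjects >= 0, duration_s > 0, fs_hz > 0,
            superficial_gain_long >= 0, neural_gain >= 0,
            drift_amp >= 0, noise_sd >= 0, background_sd >= 0)
  fmax <- max(vapply(oscillators, `[[`, numeric(1), "center_freq_hz"))
  if (fs_hz <= 2 * fmax) {
    stop(sprintf(
      "fs_hz = %g is at or below the Nyquist rate of the fastest oscillator (%g Hz)",
      fs_hz, fmax))
  }
  if (!all(as.character(montage$wavelengths) %in% names(spectral_weights))) {
    stop("spectral_weights must name every montage wavelength")
  }
  n_long <- sum(montage$channels$role == "long")
  if (is.null(neural_channels)) {
    # third quadrant of the long-channel list: L07-L10 on the default
    # montage, covering the left temporo-parietal (motor) group
    neural_channels <- seq(max(1, floor(n_long / 2)),
                           length.out = max(1, ceiling(n_long / 4)))
  }
  if (length(neural_channels) && (min(neural_channels) < 1 ||
                                  max(neural_channels) > n_long)) {
    stop("neural_channels out of range")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), duration_s = duration_s,
         fs_hz = fs_hz, oscillators = oscillators,
         superficial_gain_long = superficial_gain_long,
         neural_gain = neural_gain, hrf_params = hrf_params,
         drift_amp = drift_amp, noise_sd = noise_sd,
         background_sd = background_sd, task_blocks = task_blocks,
         montage = montage, phase_coupling = phase_coupling,
         spatial_decay_mm = spatial_decay_mm,
         spectral_weights = spectral_weights,
         hrf_amplitude_mM = hrf_amplitude_mM,
         spontaneous_mM = spontaneous_mM,
         neural_channels = as.integer(neural_channels),
         decoupled_long_channels = as.integer(decoupled_long_channels),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# 1/f ("pink") noise in [f0, fs/2], unit variance, via spectral shaping.
pink_noise <- function(n, fs, f0 = 0.01) {
  w <- rnorm(n)
  W <- fft(w)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  g <- 1 / sqrt(pmax(f, f0))
  g[1] <- 0                                 # no DC
  x <- Re(fft(W * g, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# AR(1) (discretised Ornstein-Uhlenbeck) smoother of white input, unit
# stationary variance.
ou_filter <- function(innov, rho) {
  out <- stats::filter(innov * sqrt(1 - rho^2), rho, method = "recursive",
                       init = innov[1])
  as.numeric(out)
}

#' Generate the superficial (scalp) signal field over optode sites
#'
#' Returns one superficial OD series per optode site.  All sites share the
#' oscillator centre frequencies and the shared frequency random walk;
#' site-specific amplitude factors and slowly wandering phase offsets are
#' drawn with spatial correlation `exp(-distance / spatial_decay_mm)` and
#' magnitude scaled by `1 - phase_coupling`, so that nearby sites (a long
#' channel and its bundled short channel) receive highly similar series
#' while distant sites decorrelate as coupling drops.  A broadband pink
#' systemic background is mixed from a shared master series and spatially
#' correlated site-specific series with weight `phase_coupling`.
#'
#' @param config A [synthetic_config()].
#' @param montage A [nirs_montage()]; defaults to the config's montage.
#' @param rng_seed Integer seed for this field realisation.
#' @return Numeric matrix `n_samples x n_sites` with optode ids as column
#'   names and the sampling rate as attribute `fs_hz`.
#' @export
generate_superficial_field <- function(config, montage = config$montage,
                                       rng_seed = config$seed) {
  fmax <- max(vapply(config$oscillators, `[[`, numeric(1), "center_freq_hz"))
  if (config$fs_hz <= 2 * fmax) {
    stop("sampling rate below the Nyquist rate of the fastest oscillator")
  }
  fs <- config$fs_hz
  n <- round(config$duration_s * fs)
  sites <- montage$optodes
  ns <- nrow(sites)
  d <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  K <- exp(-d / config$spatial_decay_mm)
  R <- chol(K + diag(1e-8, ns))
  dt <- 1 / fs

  with_seed(rng_seed, {
    field <- matrix(0, n, ns)
    for (osc in config$oscillators) {
      cpl <- osc$phase_coupling
      # shared slow frequency modulation, bounded by freq_jitter_hz
      df <- ou_filter(rnorm(n), exp(-dt / 10)) * osc$freq_jitter_hz / 2
      df <- pmin(pmax(df, -osc$freq_jitter_hz), osc$freq_jitter_hz)
      phase_shared <- 2 * pi * cumsum(osc$center_freq_hz + df) * dt
      # site-specific static phase offsets and amplitudes, spatially correlated
      theta <- (1 - cpl) * pi * drop(rnorm(ns) %*% R)
      amp <- osc$amplitude *
        exp(0.5 * (1 - cpl) * drop(rnorm(ns) %*% R) -
              0.125 * (1 - cpl)^2)
      # slowly wandering site phase (spatially correlated OU innovations)
      sd_ou <- 4 * (1 - cpl)
      if (sd_ou > 0) {
        innov <- matrix(rnorm(n * ns), n, ns) %*% R
        psi <- apply(innov, 2, ou_filter, rho = exp(-dt / 20)) * sd_ou
      } else {
        psi <- matrix(0, n, ns)
      }
      arg <- outer(phase_shared, theta, `+`) + psi
      field <- field + sweep(sin(arg), 2, amp, `*`)
    }
    if (config$background_sd > 0) {
      cpl <- config$phase_coupling
      b0 <- pink_noise(n, fs)
      eb <- (matrix(vapply(seq_len(ns), function(i) pink_noise(n, fs),
                           numeric(n)), n, ns)) %*% R
      bg <- (cpl * b0 + sqrt(max(0, 1 - cpl^2)) * eb) * config$background_sd
      field <- field + bg
    }
    colnames(field) <- sites$optode_id
    attr(field, "fs_hz") <- fs
    field
  })
}

#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; peak) - ratio * g(t; undershoot)` with unit-rate gamma
#' densities whose modes sit at the requested delays; scaled to unit peak.
#'
#' @param t Time grid in seconds.
#' @param peak_delay_s,undershoot_delay_s,ratio Shape parameters
#'   (community defaults 6 s, 16 s, 1/6).
#' @return Numeric vector `h(t)` with `max(h) = 1`.
#' @export
double_gamma_hrf <- function(t, peak_delay_s = 6, undershoot_delay_s = 16,
                             ratio = 1 / 6) {
  h <- dgamma(t, shape = peak_delay_s + 1, rate = 1) -
    ratio * dgamma(t, shape = undershoot_delay_s + 1, rate = 1)
  m <- max(h)
  if (m > 0) h <- h / m
  h
}

#' Alternating task-block event schedule
#'
#' Blocks of `on_s` seconds of task alternating with `off_s` seconds of
#' rest, starting with rest, for the whole recording.
#'
#' @param duration_s Recording duration (s).
#' @param on_s,off_s Task and rest durations (s).
#' @param label Event label.
#' @return Events tibble as used by [new_recording()].
#' @export
task_events <- function(duration_s, on_s = 20, off_s = 20, label = "task") {
  onsets <- seq(off_s, duration_s - on_s, by = on_s + off_s)
  tibble::tibble(onset_s = onsets, duration_s = on_s, label = label)
}

#' Generate the cortical (neural) OD component for a long channel
#'
#' A boxcar over the event schedule is convolved with the double-gamma
#' hemodynamic response, normalised to unit peak, and converted to OD per
#' wavelength through the modified Beer-Lambert forward model with an
#' oxygenated-hemoglobin increase of `amplitude_mM` and a deoxygenated
#' change of `hhb_ratio * amplitude_mM` (opposite-signed), so that
#' converting the simulated OD back to concentrations recovers the
#' canonical O2Hb-up / HHb-down task response.
#'
#' @param events Events tibble (`onset_s`, `duration_s`); may be empty.
#' @param hrf_params Named vector as in [synthetic_config()].
#' @param duration_s,fs_hz Time axis of the output.
#' @param wavelengths Wavelengths (nm) of the output columns.
#' @param amplitude_mM Peak O2Hb concentration change in mM.
#' @param hhb_ratio HHb/O2Hb amplitude ratio (negative).
#' @param separation_mm,dpf Long-channel geometry for the Beer-Lambert
#'   forward model.
#' @return Matrix `n_samples x length(wavelengths)` of OD.
#' @export
generate_neural_component <- function(events, hrf_params, duration_s, fs_hz,
                                      wavelengths = c(760, 850),
                                      amplitude_mM = 3e-4, hhb_ratio = -1 / 3,
                                      separation_mm = 30, dpf = 6) {
  n <- round(duration_s * fs_hz)
  out <- matrix(0, n, length(wavelengths),
                dimnames = list(NULL, as.character(wavelengths)))
  if (is.null(events) || nrow(events) == 0) return(out)
  if (any(events$onset_s < 0) ||
      any(events$onset_s + events$duration_s > duration_s + 1e-9)) {
    stop("events must lie within [0, duration_s]")
  }
  box <- numeric(n)
  for (i in seq_len(nrow(events))) {
    i0 <- floor(events$onset_s[i] * fs_hz) + 1
    i1 <- min(n, ceiling((events$onset_s[i] + events$duration_s[i]) * fs_hz))
    box[i0:i1] <- 1
  }
  th <- seq(0, min(32, duration_s), by = 1 / fs_hz)
  h <- double_gamma_hrf(th, hrf_params[["peak_delay_s"]],
                        hrf_params[["undershoot_delay_s"]],
                        hrf_params[["ratio"]])
  reg <- stats::convolve(box, rev(h), type = "open")[seq_len(n)]
  m <- max(abs(reg))
  if (m > 0) reg <- reg / m
  eps_tab <- extinction_coefficients(wavelengths)
  dhbo <- amplitude_mM * reg
  dhhb <- hhb_ratio * dhbo
  for (j in seq_along(wavelengths)) {
    out[, j] <- (eps_tab[j, "o2hb"] * dhbo + eps_tab[j, "hhb"] * dhhb) *
      separation_mm * dpf
  }
  out
}

#' Synthesize one multichannel fNIRS recording
#'
#' Long-channel OD is `neural_gain * neural + superficial_gain_long *
#' superficial(site) + drift + noise`; short-channel OD is
#' `superficial(site) + drift + noise` (no neural term).  The superficial
#' series of a channel is the mean of the field at its source and detector
#' sites, scaled per wavelength by `spectral_weights`.  The exact layered
#' decomposition is stored in `$truth`.  Fully reproducible from
#' `(config$seed, subject_index)`.
#'
#' @param config A [synthetic_config()].
#' @param subject_index Positive integer identifying the subject.
#' @return An OD [new_recording()] with a `truth` decomposition.
#' @export
synthesize_recording <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"), subject_index >= 1)
  montage <- config$montage
  fs <- config$fs_hz
  n <- round(config$duration_s * fs)
  mi <- measurement_index(montage)
  ch <- montage$channels
  subj_seed <- derive_seed(config$seed, subject_index)

  field <- generate_superficial_field(config, montage, rng_seed = subj_seed)
  # per-channel superficial series: mean of source and detector site fields
  ch_sup <- sapply(seq_len(nrow(ch)), function(i) {
    0.5 * (field[, ch$source[i]] + field[, ch$detector[i]])
  })
  colnames(ch_sup) <- ch$channel_id

  long_ids <- long_channels(montage)
  if (length(config$decoupled_long_channels)) {
    alt <- generate_superficial_field(config, montage,
                                      rng_seed = derive_seed(subj_seed, 7L))
    for (k in config$decoupled_long_channels) {
      id <- long_ids[k]
      i <- which(ch$channel_id == id)
      ch_sup[, id] <- 0.5 * (alt[, ch$source[i]] + alt[, ch$detector[i]])
    }
  }

  events <- if (!is.null(config$task_blocks)) {
    task_events(config$duration_s, config$task_blocks$on_s,
                config$task_blocks$off_s)
  } else {
    empty_events()
  }
  neural_wl <- generate_neural_component(
    events, config$hrf_params, config$duration_s, fs,
    wavelengths = montage$wavelengths,
    amplitude_mM = config$hrf_amplitude_mM,
    separation_mm = max(ch$separation_mm), dpf = 6
  )

  # spontaneous cortical hemodynamics: slow fluctuations present in every
  # long channel but absent from the short channels -- the contrast the
  # virtual-short-channel method relies on.  Correlated within cortical
  # neighbourhoods (resting-state networks), never globally.
  eps_tab <- extinction_coefficients(montage$wavelengths)
  sep_long <- max(ch$separation_mm)
  spont_hbo <- with_seed(derive_seed(subj_seed, 17L), {
    mids <- channel_midpoints(montage)
    mids <- mids[match(long_ids, mids$channel_id), ]
    Kc <- exp(-as.matrix(stats::dist(cbind(mids$x, mids$y))) / 40)
    Rc <- chol(Kc + diag(1e-8, length(long_ids)))
    base <- vapply(long_ids, function(id) pink_noise(n, fs), numeric(n))
    out <- config$spontaneous_mM * (base %*% Rc)
    colnames(out) <- long_ids
    out
  })

  nm <- nrow(mi)
  sup <- matrix(0, n, nm, dimnames = list(NULL, mi$column))
  neu <- matrix(0, n, nm, dimnames = list(NULL, mi$column))
  for (j in seq_len(nm)) {
    gain <- if (mi$role[j] == "long") config$superficial_gain_long else 1
    w <- config$spectral_weights[[as.character(mi$wavelength[j])]]
    sup[, j] <- gain * w * ch_sup[, mi$channel_id[j]]
    if (mi$role[j] == "long") {
      wi <- which(montage$wavelengths == mi$wavelength[j])
      emix <- eps_tab[wi, "o2hb"] - eps_tab[wi, "hhb"] / 3
      neu[, j] <- config$neural_gain * emix * sep_long * 6 *
        spont_hbo[, mi$channel_id[j]]
      if (match(mi$channel_id[j], long_ids) %in% config$neural_channels) {
        neu[, j] <- neu[, j] + config$neural_gain *
          neural_wl[, as.character(mi$wavelength[j])]
      }
    }
  }

  with_seed(derive_seed(subj_seed, 13L), {
    drift <- apply(matrix(rnorm(n * nm), n, nm), 2, function(z) {
      rw <- cumsum(z)
      config$drift_amp * (rw - mean(rw)) / max(sd(rw), 1e-12)
    })
    noise <- matrix(rnorm(n * nm, sd = config$noise_sd), n, nm)
    colnames(drift) <- colnames(noise) <- mi$column
    data <- sup + neu + drift + noise
    new_recording(data, kind = "od", fs_hz = fs, montage = montage,
                  events = events,
                  truth = list(superficial = sup, neural = neu,
                               drift = drift, noise = noise))
  })
}

#' Synthesize a cohort of recordings
#'
#' `n_subjects` independent recordings whose per-subject seeds are derived
#' deterministically from the master seed: two cohorts generated from the
#' same config are identical.
#'
#' @param config A [synthetic_config()].
#' @return List of [new_recording()]s (empty when `n_subjects = 0`).
#' @export
synthesize_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lapply(seq_len(config$n_subjects), function(i) {
    synthesize_recording(config, subject_index = i)
  })
}
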