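#' Hemoglobin extinction coefficients
#'
#' Molar extinction coefficients of oxygenated and deoxygenated hemoglobin
#' in 1/(mM*mm), compiled from the standard literature tabulation of
#' hemoglobin absorption spectra (Gratzer/Kollias compilation, as shipped
#' with the common fNIRS processing toolboxes).  Values are provided for
#' the usual continuous-wave wavelengths and can be overridden by passing
#' an explicit table to [mbll_params()].
#'
#' @param wavelengths Wavelengths in nm (760 and 850 supported built-in).
#' @return Matrix `length(wavelengths) x 2` with columns `o2hb`, `hhb`.
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  tab <- rbind(
    "760" = c(o2hb = 0.14866, hhb = 0.38437),
    "850" = c(o2hb = 0.25264, hhb = 0.17986)
  )
  keys <- as.character(wavelengths)
  if (!all(keys %in% rownames(tab))) {
    stop("no built-in extinction coefficients for wavelengths: ",
         paste(setdiff(keys, rownames(tab)), collapse = ", "))
  }
  out <- tab[keys, , drop = FALSE]
  rownames(out) <- keys
  out
}

#' Modified Beer-Lambert conversion parameters
#'
#' @param separation_mm Source-detector separation of the channel (mm).
#' @param dpf Differential pathlength factor (default 6).
#' @param extinction 2 x 2 extinction matrix (rows = wavelengths, columns
#'   `o2hb`, `hhb`) in 1/(mM*mm); defaults to
#'   [extinction_coefficients()] for `wavelengths`.
#' @param wavelengths Wavelengths in nm matching the OD column order.
#' @return List of class `mbll_params`.
#' @export
mbll_params <- function(separation_mm = 30, dpf = 6, extinction = NULL,
                        wavelengths = c(760, 850)) {
  if (is.null(extinction)) extinction <- extinction_coefficients(wavelengths)
  stopifnot(nrow(extinction) == length(wavelengths), ncol(extinction) == 2)
  if (abs(det(extinction)) < 1e-12) stop("extinction matrix is singular")
  structure(list(separation_mm = separation_mm, dpf = dpf,
                 extinction = extinction, wavelengths = wavelengths),
            class = "mbll_params")
}

# Processing-stage bookkeeping: the pipeline order is fixed as
# SCR (OD) -> band-pass (OD) -> Beer-Lambert conversion, and the stage tag
# carried on each series lets the functions refuse a silently reordered
# pipeline.
stage_of <- function(x) attr(x, "nirs_stage") %||% "od"
`%||%` <- function(a, b) if (is.null(a)) b else a
set_stage <- function(x, stage) {
  attr(x, "nirs_stage") <- stage
  x
}

#' Short-channel regression (SCR)
#'
#' Removes the superficial component from a long-channel OD series by
#' ordinary least squares on `[1, regressor]`, where the regressor is the
#' paired short-channel series (measured or virtual) at the same
#' wavelength: `residual = long - (a + b * regressor)`.  The residual is
#' uncorrelated with the regressor and its variance never exceeds the
#' input variance.
#'
#' @param long_od Numeric long-channel OD series.
#' @param regressor_od Numeric short-channel OD series of equal length.
#' @return Residual series (stage-tagged `"scr"`), with attributes
#'   `intercept` and `slope`.
#' @export
scr <- function(long_od, regressor_od) {
  if (length(long_od) != length(regressor_od)) {
    stop("long and regressor series must have equal length")
  }
  if (stage_of(long_od) %in% c("bandpass", "conc")) {
    stop("SCR must precede band-pass filtering and concentration conversion")
  }
  vr <- var(regressor_od)
  if (!is.finite(vr) || vr < 1e-24) {
    warning("zero-variance regressor; returning mean-centered long channel")
    out <- long_od - mean(long_od)
    a <- mean(long_od); b <- 0
  } else {
    b <- cov(long_od, regressor_od) / vr
    a <- mean(long_od) - b * mean(regressor_od)
    out <- long_od - (a + b * regressor_od)
  }
  out <- set_stage(out, "scr")
  attr(out, "intercept") <- a
  attr(out, "slope") <- b
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' 3rd-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), isolating the hemodynamic band (default
#' 0.01-0.2 Hz): passband amplitude is preserved within a few percent and
#' cardiac-band content (~1 Hz) is suppressed by orders of magnitude.
#' Accepts a vector or a column matrix.
#'
#' @param x Numeric vector or matrix (columns filtered independently).
#' @param fs_hz Sampling rate (Hz); must exceed `2 * high`.
#' @param low,high Band edges in Hz.
#' @return Filtered series, stage-tagged `"bandpass"`.
#' @export
bandpass <- function(x, fs_hz, low = 0.01, high = 0.2) {
  if (!(low > 0 && high > low && fs_hz > 2 * high)) {
    stop("invalid band: need 0 < low < high < fs/2")
  }
  if (stage_of(x) == "conc") {
    stop("band-pass operates on OD series, before concentration conversion")
  }
  bf <- signal::butter(3, c(low, high) / (fs_hz / 2), type = "pass")
  f1 <- function(v) signal::filtfilt(bf, v)
  out <- if (is.matrix(x)) apply(x, 2, f1) else f1(as.numeric(x))
  if (is.matrix(x)) dimnames(out) <- dimnames(x)
  set_stage(out, "bandpass")
}

#' Modified Beer-Lambert conversion of dual-wavelength OD
#'
#' Solves `extinction %*% dc = dOD / (separation * DPF)` per sample via
#' the 2 x 2 inverse and appends total hemoglobin
#' `tHb = O2Hb + HHb`.  Concentration changes are in mM.
#'
#' @param od_pair Matrix `n x 2` of OD, columns ordered as
#'   `params$wavelengths`.
#' @param params An [mbll_params()].
#' @return Matrix `n x 3` with columns `o2hb`, `hhb`, `thb` (class
#'   `nirs_conc`, stage-tagged `"conc"`).
#' @export
od_to_concentration <- function(od_pair, params = mbll_params()) {
  stopifnot(inherits(params, "mbll_params"))
  od_pair <- as.matrix(od_pair)
  if (ncol(od_pair) != length(params$wavelengths)) {
    stop("od_pair must have one column per wavelength")
  }
  einv <- solve(params$extinction)
  dc <- od_pair %*% t(einv) / (params$separation_mm * params$dpf)
  out <- cbind(dc, rowSums(dc))
  colnames(out) <- c("o2hb", "hhb", "thb")
  class(out) <- c("nirs_conc", class(out))
  set_stage(out, "conc")
}

#' Block average of event-related responses
#'
#' Epochs a series over `[-pre_s, post_s]` around each event onset,
#' subtracts the per-trial baseline (the mean over `[-pre_s, 0)`), and
#' returns the mean and across-trial standard deviation.  Epochs that are
#' not fully inside the recording are dropped with a warning.
#'
#' @param x Numeric vector, or matrix whose columns are epoch-averaged
#'   independently (e.g. the chromophore columns of
#'   [od_to_concentration()]).
#' @param events Events tibble (`onset_s`).
#' @param fs_hz Sampling rate (Hz).
#' @param pre_s,post_s Epoch extent in seconds before/after onset.
#' @return Tibble with columns `time_s`, `series`, `mean`, `sd` and
#'   attribute `n_trials`.
#' @export
block_average <- function(x, events, fs_hz, pre_s = 5, post_s = 30) {
  xm <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1,
                                        dimnames = list(NULL, "x"))
  if (is.null(colnames(xm))) colnames(xm) <- paste0("V", seq_len(ncol(xm)))
  n <- nrow(xm)
  npre <- round(pre_s * fs_hz)
  grid <- seq(-npre, round(post_s * fs_hz))   # round((pre+post)*fs)+1 samples
  time_s <- grid / fs_hz
  onset_idx <- round(events$onset_s * fs_hz) + 1
  keep <- onset_idx + min(grid) >= 1 & onset_idx + max(grid) <= n
  if (any(!keep)) warning(sum(!keep), " partial epoch(s) dropped")
  onset_idx <- onset_idx[keep]
  if (!length(onset_idx)) stop("no usable trials")
  base_rows <- which(time_s < 0)
  res <- lapply(colnames(xm), function(cn) {
    ep <- vapply(onset_idx, function(i0) {
      e <- xm[i0 + grid, cn]
      e - mean(e[base_rows])
    }, numeric(length(grid)))
    tibble::tibble(time_s = time_s, series = cn,
                   mean = rowMeans(ep),
                   sd = apply(ep, 1, sd))
  })
  out <- dplyr::bind_rows(res)
  attr(out, "n_trials") <- length(onset_idx)
  out
}

#' Denoise the long channels of a recording by SCR
#'
#' Applies [scr()] to every retained long-channel measurement using either
#' the measured paired short channel or a supplied matrix of virtual short
#' channels with the long-channel feature layout (see
#' [build_target_matrix()]), then band-pass filters the residuals.
#'
#' @param rec An OD [new_recording()].
#' @param regressors `"measured"`, or a numeric matrix `n_samples x
#'   n_long_features` of regressor series in long-feature layout.
#' @param low,high Band edges for [bandpass()]; `NULL` skips filtering.
#' @return Matrix of denoised long-channel OD (stage-tagged), same feature
#'   layout as [long_matrix()].
#' @export
denoise_long_channels <- function(rec, regressors = "measured",
                                  low = 0.01, high = 0.2) {
  x <- long_matrix(rec)
  reg <- if (is.character(regressors) && identical(regressors, "measured")) {
    build_target_matrix(rec)$data
  } else {
    as.matrix(regressors)
  }
  if (!all(dim(reg) == dim(x))) {
    stop("regressor matrix must match the long-channel feature layout")
  }
  res <- x
  for (j in seq_len(ncol(x))) res[, j] <- scr(x[, j], reg[, j])
  res <- set_stage(res, "scr")
  if (!is.null(low)) res <- bandpass(res, rec$fs_hz, low, high)
  res
}

#' Convert a long-feature OD matrix to per-channel concentrations
#'
#' Pairs the two wavelength columns of each channel and applies
#' [od_to_concentration()].
#'
#' @param od Matrix in (channel, wavelength) feature layout with
#'   `"<channel>@<wavelength>"` column names.
#' @param separation_mm,dpf,wavelengths Beer-Lambert parameters.
#' @return Named list of `nirs_conc` matrices, one per channel.
#' @export
concentration_by_channel <- function(od, separation_mm = 30, dpf = 6,
                                     wavelengths = c(760, 850)) {
  cols <- colnames(od)
  chans <- unique(sub("@.*$", "", cols))
  params <- mbll_params(separation_mm, dpf, wavelengths = wavelengths)
  out <- lapply(chans, function(ch) {
    sel <- paste0(ch, "@", wavelengths)
    od_to_concentration(od[, sel, drop = FALSE], params)
  })
  names(out) <- chans
  out
}
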