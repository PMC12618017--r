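#' Multichannel fNIRS recording container
#'
#' Holds an `n_samples x n_measurements` matrix of either raw light
#' intensity or optical density (OD), the sampling rate, the montage, the
#' stimulus events and (for simulated data) the ground-truth signal
#' decomposition.  Measurement columns follow [measurement_index()] order.
#'
#' @param data Numeric matrix `n_samples x n_measurements`; column names
#'   must match the montage's measurement layout.
#' @param kind `"intensity"` or `"od"`.
#' @param fs_hz Sampling rate in Hz.
#' @param montage A [nirs_montage()].
#' @param events Tibble with columns `onset_s`, `duration_s`, `label`
#'   (may be empty).
#' @param truth Optional named list of matrices (same shape as `data`) with
#'   components `superficial`, `neural`, `drift`, `noise`.
#' @return An object of class `nirs_recording`.
#' @export
new_recording <- function(data, kind = c("od", "intensity"), fs_hz, montage,
                          events = empty_events(), truth = NULL) {
  kind <- match.arg(kind)
  mi <- measurement_index(montage)
  if (!identical(colnames(data), mi$column)) {
    stop("data columns must follow the montage measurement layout (",
         "see measurement_index())")
  }
  if (kind == "intensity" && any(data <= 0)) {
    stop("intensity values must be strictly positive")
  }
  structure(
    list(data = data, kind = kind, fs_hz = fs_hz, montage = montage,
         events = tibble::as_tibble(events), truth = truth),
    class = "nirs_recording"
  )
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf(
    "<nirs_recording> %s, %d samples x %d measurements @ %.3f Hz (%.1f s)%s%s\n",
    x$kind, nrow(x$data), ncol(x$data), x$fs_hz, nrow(x$data) / x$fs_hz,
    if (nrow(x$events)) sprintf(", %d events", nrow(x$events)) else "",
    if (!is.null(x$truth)) ", with truth decomposition" else ""
  ))
  invisible(x)
}

#' @rdname new_recording
#' @export
empty_events <- function() {
  tibble::tibble(onset_s = numeric(), duration_s = numeric(),
                 label = character())
}

#' @rdname new_recording
#' @param rec A `nirs_recording`.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Convert an OD recording to light intensity
#'
#' Simulated recordings are generated in OD; `intensity_of()` produces the
#' corresponding raw intensity as `I(t) = I0 * exp(-OD(t))`.  The baseline
#' intensity `I0` is unidentifiable from OD (the conversion is
#' ratio-based), so `I0 = 1` is used and recorded per column so that
#' [intensity_to_od()] can invert the conversion exactly.
#'
#' @param rec An OD [new_recording()].
#' @param i0 Baseline intensity (scalar or per-column vector).
#' @return An intensity `nirs_recording` carrying an `i0` attribute.
#' @export
intensity_of <- function(rec, i0 = 1) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (rec$kind != "od") stop("intensity_of() expects an OD recording")
  i0v <- rep_len(i0, ncol(rec$data))
  out <- rec
  out$data <- sweep(exp(-rec$data), 2, i0v, `*`)
  out$kind <- "intensity"
  attr(out$data, "i0") <- i0v
  out
}

#' Extract submatrices by channel role
#'
#' `long_matrix()` returns the long-channel measurement columns,
#' `short_matrix()` the short-channel columns, in layout order.
#'
#' @param rec A [new_recording()].
#' @return Numeric matrix with the selected measurement columns.
#' @export
long_matrix <- function(rec) {
  mi <- measurement_index(rec$montage)
  rec$data[, mi$column[mi$role == "long"], drop = FALSE]
}

#' @rdname long_matrix
#' @export
short_matrix <- function(rec) {
  mi <- measurement_index(rec$montage)
  rec$data[, mi$column[mi$role == "short"], drop = FALSE]
}
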