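#' Build the short-channel target matrix in long-channel layout
#'
#' Returns a measurement matrix with the same feature layout as the
#' long-channel predictor matrix: the column for long channel `l` at
#' wavelength `w` holds the OD series of `l`'s paired short channel at
#' `w`.  Short channels serving several long channels are duplicated, so
#' the target dimensionally matches the predictors (28 features on the
#' default montage).
#'
#' @param rec An OD [new_recording()].
#' @param pairing Long-to-short pairing (default: the montage's).
#' @return List with `data` (matrix, long-feature column names) and
#'   `feature_map` ([measurement_index()] rows for the long features).
#' @export
build_target_matrix <- function(rec, pairing = rec$montage$pairing) {
  mi <- measurement_index(rec$montage)
  mi_long <- mi[mi$role == "long", ]
  missing <- setdiff(mi_long$channel_id, names(pairing))
  if (length(missing)) {
    stop("missing pairing entry for long channel(s): ",
         paste(unique(missing), collapse = ", "))
  }
  src_cols <- paste0(pairing[mi_long$channel_id], "@", mi_long$wavelength)
  out <- rec$data[, src_cols, drop = FALSE]
  colnames(out) <- mi_long$column
  list(data = out, feature_map = mi_long)
}

#' Segment a series matrix into non-overlapping windows
#'
#' Splits an `n_samples x n_features` matrix into
#' `floor(n_samples / window_len)` consecutive, non-overlapping windows of
#' `window_len` samples; the trailing remainder is discarded.  A 6-minute
#' recording at 7 Hz (2520 samples) yields 19 windows of 128.
#'
#' @param x Numeric matrix (or a [new_recording()], whose long-channel
#'   matrix is used).
#' @param window_len Window length in samples (default 128).
#' @param subject Subject identifier attached to every window.
#' @return A `nirs_windows` object: `tensor` (`n_windows x window_len x
#'   n_features` array), `feature_map` (column names), `subjects`.
#' @export
segment_windows <- function(x, window_len = 128, subject = 1L) {
  stopifnot(window_len >= 1)
  if (inherits(x, "nirs_recording")) x <- long_matrix(x)
  x <- as.matrix(x)
  nw <- floor(nrow(x) / window_len)
  if (nw == 0) warning("fewer samples than window_len: zero windows")
  tensor <- array(0, dim = c(nw, window_len, ncol(x)))
  for (w in seq_len(nw)) {
    tensor[w, , ] <- x[((w - 1) * window_len + 1):(w * window_len), ]
  }
  new_windows(tensor, feature_map = colnames(x),
              subjects = rep(subject, nw))
}

new_windows <- function(tensor, feature_map, subjects, stats = NULL) {
  structure(list(tensor = tensor, window_len = dim(tensor)[2],
                 feature_map = feature_map, subjects = subjects,
                 stats = stats),
            class = "nirs_windows")
}

#' @export
print.nirs_windows <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<nirs_windows> %d windows x %d samples x %d features, %d subject(s)%s\n",
              d[1], d[2], d[3], length(unique(x$subjects)),
              if (!is.null(x$stats)) ", normalized" else ""))
  invisible(x)
}

#' Bind window sets from several subjects
#'
#' @param ws_list List of `nirs_windows` with identical window length and
#'   feature maps.
#' @return A single `nirs_windows`.
#' @export
bind_windows <- function(ws_list) {
  ws_list <- ws_list[vapply(ws_list, function(w) dim(w$tensor)[1] > 0,
                            logical(1))]
  stopifnot(length(ws_list) >= 1)
  fm <- ws_list[[1]]$feature_map
  for (w in ws_list) stopifnot(identical(w$feature_map, fm))
  tensor <- do.call(abind1, lapply(ws_list, `[[`, "tensor"))
  new_windows(tensor, fm, unlist(lapply(ws_list, `[[`, "subjects")))
}

# rbind along the first (window) axis of 3-D arrays
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0
  for (p in parts) {
    np <- dim(p)[1]
    if (np) out[at + seq_len(np), , ] <- p
    at <- at + np
  }
  out
}

#' Segment predictor and target windows for a whole cohort
#'
#' For each recording, builds the long-channel predictor matrix `X` and
#' the paired-short-channel target matrix `Y` ([build_target_matrix()]),
#' and segments both with the same windows.
#'
#' @param cohort List of OD [new_recording()]s.
#' @param window_len Window length in samples.
#' @return List `(x, y)` of `nirs_windows` over all subjects.
#' @export
cohort_windows <- function(cohort, window_len = 128) {
  xs <- list(); ys <- list()
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    xs[[i]] <- segment_windows(long_matrix(rec), window_len, subject = i)
    ys[[i]] <- segment_windows(build_target_matrix(rec)$data, window_len,
                               subject = i)
  }
  list(x = bind_windows(xs), y = bind_windows(ys))
}

#' Merge windows back into continuous per-subject series
#'
#' Concatenates each subject's windows in time order, inverting
#' [segment_windows()] up to the discarded trailing remainder:
#' `merge(segment(x))` equals `x` truncated to
#' `n_windows * window_len` samples.
#'
#' @param ws A `nirs_windows`.
#' @return Named list of matrices, one per subject.
#' @export
merge_windows <- function(ws) {
  stopifnot(inherits(ws, "nirs_windows"))
  subj <- ws$subjects
  if (length(subj) > 1 && any(diff(match(subj, unique(subj))) < 0)) {
    stop("windows out of order: each subject's windows must be contiguous")
  }
  out <- lapply(unique(subj), function(s) {
    idx <- which(subj == s)
    L <- ws$window_len
    m <- matrix(0, length(idx) * L, dim(ws$tensor)[3])
    for (k in seq_along(idx)) {
      m[((k - 1) * L + 1):(k * L), ] <- ws$tensor[idx[k], , ]
    }
    colnames(m) <- ws$feature_map
    m
  })
  names(out) <- as.character(unique(subj))
  out
}

#' Min-max normalisation of windows to [-1, 1]
#'
#' Per-feature affine map to `[-1, 1]`, with the extrema computed on the
#' training windows only (no leakage from validation or test windows).
#' Constant features map to 0 and are flagged.  The returned stats are
#' stored with the window set and reused by [denormalize_windows()]; the
#' same stats should be applied to the target windows so that inputs and
#' outputs share the feature space.
#'
#' @param ws A `nirs_windows`.
#' @param train_idx Window indices used to fit the extrema (default: all).
#' @param stats Optional precomputed stats tibble to apply instead.
#' @return The normalised `nirs_windows` (stats in `$stats`).
#' @export
normalize_windows <- function(ws, train_idx = NULL, stats = NULL) {
  stopifnot(inherits(ws, "nirs_windows"))
  nf <- dim(ws$tensor)[3]
  if (is.null(stats)) {
    if (is.null(train_idx)) train_idx <- seq_len(dim(ws$tensor)[1])
    sub <- ws$tensor[train_idx, , , drop = FALSE]
    mins <- apply(sub, 3, min)
    maxs <- apply(sub, 3, max)
    stats <- tibble::tibble(
      feature = if (!is.null(ws$feature_map)) ws$feature_map else
        as.character(seq_len(nf)),
      min = mins, max = maxs, degenerate = (maxs - mins) < 1e-300
    )
  }
  out <- ws
  for (j in seq_len(nf)) {
    if (stats$degenerate[j]) {
      out$tensor[, , j] <- 0
    } else {
      out$tensor[, , j] <-
        2 * (ws$tensor[, , j] - stats$min[j]) / (stats$max[j] - stats$min[j]) - 1
    }
  }
  out$stats <- stats
  out
}

#' @rdname normalize_windows
#' @export
denormalize_windows <- function(ws, stats = ws$stats) {
  stopifnot(inherits(ws, "nirs_windows"), !is.null(stats))
  out <- ws
  for (j in seq_len(dim(ws$tensor)[3])) {
    if (!stats$degenerate[j]) {
      out$tensor[, , j] <-
        (ws$tensor[, , j] + 1) / 2 * (stats$max[j] - stats$min[j]) + stats$min[j]
    } else {
      out$tensor[, , j] <- stats$min[j]
    }
  }
  out$stats <- NULL
  out
}

#' Random train/validation/test split of window indices
#'
#' Seeded shuffle of `1:n_windows` partitioned with floor rounding on the
#' train and validation counts and the remainder assigned to test: 1311
#' windows at (0.8, 0.1, 0.1) give 1048 / 131 / 132.  A window-level split
#' mirrors the training protocol; `by_subject = TRUE` splits whole
#' subjects instead (the stricter generalisation test).
#'
#' @param n_windows Number of windows (>= 3).
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed for the shuffle.
#' @param subjects Optional subject id per window (required for
#'   `by_subject`).
#' @param by_subject Split at the subject level instead of window level.
#' @return List of disjoint, exhaustive index vectors `train`, `val`,
#'   `test`.
#' @export
split_windows <- function(n_windows, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          subjects = NULL, by_subject = FALSE) {
  stopifnot(n_windows >= 3, length(fractions) == 3,
            abs(sum(fractions) - 1) < 1e-9)
  if (by_subject) {
    stopifnot(!is.null(subjects), length(subjects) == n_windows)
    us <- unique(subjects)
    ns <- length(us)
    sh <- with_seed(seed, sample(us))
    ntr <- floor(fractions[1] * ns); nva <- floor(fractions[2] * ns)
    gr <- list(train = sh[seq_len(ntr)],
               val = sh[ntr + seq_len(nva)],
               test = sh[setdiff(seq_len(ns), seq_len(ntr + nva))])
    lapply(gr, function(s) which(subjects %in% s))
  } else {
    sh <- with_seed(seed, sample.int(n_windows))
    ntr <- floor(fractions[1] * n_windows)
    nva <- floor(fractions[2] * n_windows)
    list(train = sort(sh[seq_len(ntr)]),
         val = sort(sh[ntr + seq_len(nva)]),
         test = sort(sh[(ntr + nva + 1):n_windows]))
  }
}
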