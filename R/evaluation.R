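#' Signal similarity metrics
#'
#' Pointwise and shape metrics between a predicted and a reference
#' series: `mse()` is the mean squared pointwise difference; `nmse()`
#' divides the MSE by the squared dynamic range (max - min) of the
#' reference, making errors comparable across amplitude scales; `mae()`
#' is the mean absolute difference; `pearson_r()` the sample correlation
#' over time; `r_squared()` is `1 - SS_res / SS_tot` of the prediction
#' against the reference.
#'
#' @param pred,truth Equal-length numeric series.
#' @return Scalar metric.  `nmse()` and `pearson_r()` return `NA` with an
#'   `"undefined"` attribute when the reference (or either series, for
#'   correlation) is constant.
#' @export
mse <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  mean((pred - truth)^2)
}

#' @rdname mse
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  mean(abs(pred - truth))
}

#' @rdname mse
#' @export
nmse <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  rng <- max(truth) - min(truth)
  if (rng <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  mse(pred, truth) / rng^2
}

#' @rdname mse
#' @export
pearson_r <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (sd(pred) == 0 || sd(truth) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cor(pred, truth)
}

#' @rdname mse
#' @export
r_squared <- function(pred, truth) {
  sst <- sum((truth - mean(truth))^2)
  if (sst <= 0) return(NA_real_)
  1 - sum((truth - pred)^2) / sst
}

#' Residual variance of denoised channels
#'
#' Sample variance per channel/chromophore of a series after
#' short-channel regression; lower residual variance means more
#' superficial noise removed.  Warns when the input does not carry a
#' post-SCR stage tag.
#'
#' @param x Numeric vector or matrix (columns = channels).
#' @return Named numeric vector of variances.
#' @export
residual_variance <- function(x) {
  if (!stage_of(x) %in% c("scr", "bandpass", "conc")) {
    warning("input is not tagged as post-SCR; variance is of the raw series")
  }
  if (is.matrix(x)) apply(x, 2, var) else var(as.numeric(x))
}

#' Per-channel metrics report with median aggregation
#'
#' Computes MSE, NMSE, Pearson r and MAE per (subject, channel) series
#' and aggregates by the median across channels, then across subjects.
#' Undefined metrics (constant reference) are excluded from the medians
#' and counted.
#'
#' @param pred,truth Matrices `n_samples x n_features` with identical
#'   column names, or lists of such matrices (one per subject).
#' @param domain Label for the signal domain (`"od"`, `"o2hb"`, ...).
#' @return Tibble of per-channel rows; attributes `summary` (tibble of
#'   medians) and `n_undefined`.
#' @export
metrics_report <- function(pred, truth, domain = "od") {
  if (is.matrix(pred)) { pred <- list(pred); truth <- list(truth) }
  rows <- list()
  for (s in seq_along(pred)) {
    p <- pred[[s]]; y <- truth[[s]]
    stopifnot(identical(dim(p), dim(y)))
    for (j in seq_len(ncol(p))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = s,
        channel = colnames(p)[j] %||% as.character(j),
        domain = domain,
        mse = mse(p[, j], y[, j]),
        nmse = as.numeric(nmse(p[, j], y[, j])),
        mae = mae(p[, j], y[, j]),
        pearson_r = as.numeric(pearson_r(p[, j], y[, j]))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  per_subj <- dplyr::summarise(
    dplyr::group_by(out, .data$subject),
    dplyr::across(c("mse", "nmse", "mae", "pearson_r"),
                  ~ median(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  summary <- dplyr::summarise(
    per_subj,
    dplyr::across(c("mse", "nmse", "mae", "pearson_r"),
                  ~ median(.x, na.rm = TRUE))
  )
  attr(out, "summary") <- summary
  attr(out, "n_undefined") <- sum(is.na(out$nmse)) + sum(is.na(out$pearson_r))
  out
}

#' Coherence-threshold sweep
#'
#' Evaluates the wavelet-coherence rejection threshold over a grid: for
#' each threshold the long-short pairs below it are masked out (their
#' input and target features zeroed and excluded from metrics), the
#' model is retrained from scratch at a reduced epoch budget, and mean
#' MAE, mean Pearson r, mean R-squared over retained held-out channel
#' series plus the mean number of rejected channels per subject are
#' reported.  Coherence is computed once per pair and reused across
#' thresholds, so the rejection count is non-decreasing in the threshold
#' by construction.
#'
#' @param cohort List of OD [new_recording()]s.
#' @param thresholds Ascending threshold grid.
#' @param epochs Reduced retraining budget per threshold.
#' @param window_len,fractions,seed Windowing/split/protocol seeds.
#' @param qc Base [coherence_qc_config()] (its threshold field is swept).
#' @return `SweepResult` tibble: `threshold`, `mean_mae`, `mean_r`,
#'   `mean_r2`, `mean_rejected_per_subject`.
#' @export
threshold_sweep <- function(cohort, thresholds = c(0.20, 0.30, 0.39, 0.45, 0.50),
                            epochs = 6, window_len = 128,
                            fractions = c(0.8, 0.1, 0.1), seed = 1L,
                            qc = coherence_qc_config()) {
  thresholds <- sort(thresholds)
  # per-subject, per-pair median coherence (threshold-independent)
  coh <- lapply(cohort, function(rec) {
    rep <- reject_pairs(rec, qc = coherence_qc_config(
      threshold = 0.5, freq_band_hz = qc$freq_band_hz,
      omega0 = qc$omega0, voices = qc$voices))$report
    tapply(rep$median_coherence, rep$long_channel, min)
  })
  ws <- cohort_windows(cohort, window_len)
  nwin <- dim(ws$x$tensor)[1]
  split <- split_windows(nwin, fractions, seed = derive_seed(seed, 1L))
  feat_ch <- sub("@.*$", "", ws$x$feature_map)

  rows <- lapply(thresholds, function(th) {
    drop_by_subj <- lapply(coh, function(v) names(v)[v < th])
    n_rej <- mean(vapply(drop_by_subj, length, integer(1)))
    xs <- ws$x; ys <- ws$y
    for (s in seq_along(cohort)) {
      sel <- which(xs$subjects == s)
      mask <- feat_ch %in% drop_by_subj[[s]]
      if (any(mask)) {
        xs$tensor[sel, , mask] <- 0
        ys$tensor[sel, , mask] <- 0
      }
    }
    xs <- normalize_windows(xs, train_idx = split$train)
    ys <- normalize_windows(ys, train_idx = split$train)
    cfg <- transformer_config(n_features_in = dim(xs$tensor)[3],
                              n_features_out = dim(ys$tensor)[3],
                              window_len = window_len)
    mdl <- init_transformer(cfg, seed = derive_seed(seed, 2L))
    mdl <- train_transformer(mdl, xs$tensor, ys$tensor, split,
                             train_config(epochs = epochs,
                                          seed = derive_seed(seed, 3L)))
    pred <- transformer_forward(mdl, xs$tensor[split$test, , , drop = FALSE],
                                precision = "single")
    targ <- ys$tensor[split$test, , , drop = FALSE]
    maes <- c(); rsv <- c(); r2v <- c()
    for (k in seq_along(split$test)) {
      w <- split$test[k]
      s <- xs$subjects[w]
      keep_f <- which(!(feat_ch %in% drop_by_subj[[s]]))
      for (f in keep_f) {
        p <- pred[k, , f]; yy <- targ[k, , f]
        maes <- c(maes, mae(p, yy))
        r <- suppressWarnings(pearson_r(p, yy))
        if (!is.na(r)) rsv <- c(rsv, r)
        r2 <- r_squared(p, yy)
        if (!is.na(r2)) r2v <- c(r2v, r2)
      }
    }
    tibble::tibble(threshold = th, mean_mae = mean(maes),
                   mean_r = mean(rsv), mean_r2 = mean(r2v),
                   mean_rejected_per_subject = n_rej)
  })
  dplyr::bind_rows(rows)
}
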