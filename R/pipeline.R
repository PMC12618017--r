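#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations: simulation, optional coherence
#' QC, windowing, training, test-time augmentation and post-processing.
#' `strict_paper_mode` disables the optional extras of the training
#' recipe: positional encoding, training-time augmentation and gradient
#' clipping.  Every stage's configuration is validated on
#' construction, before any stage runs.
#'
#' @param synthetic A [synthetic_config()].
#' @param qc A [coherence_qc_config()], or `NULL` to skip channel
#'   rejection.
#' @param window_len Window length in samples.
#' @param fractions Train/val/test fractions.
#' @param model A [transformer_config()]; feature counts are taken from
#'   the montage when `NULL`.
#' @param train A [train_config()].
#' @param tta A [tta_config()], or `NULL` for plain forward prediction.
#' @param alpha Hybrid-loss weight.
#' @param bandpass_hz Post-SCR band edges.
#' @param strict_paper_mode Disable non-protocol extras.
#' @param seed Master seed; stage seeds derive from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            qc = NULL, window_len = 128,
                            fractions = c(0.8, 0.1, 0.1),
                            model = NULL, train = train_config(),
                            tta = tta_config(), alpha = 0.3,
                            bandpass_hz = c(0.01, 0.2),
                            strict_paper_mode = FALSE, seed = 1L) {
  stopifnot(inherits(synthetic, "synthetic_config"),
            is.null(qc) || inherits(qc, "coherence_qc_config"),
            inherits(train, "train_config"),
            is.null(tta) || inherits(tta, "tta_config"),
            abs(sum(fractions) - 1) < 1e-9)
  if (is.null(model)) {
    nf <- length(long_channels(synthetic$montage)) *
      length(synthetic$montage$wavelengths)
    model <- transformer_config(n_features_in = nf, n_features_out = nf,
                                window_len = window_len)
  }
  if (strict_paper_mode) {
    model$positional_encoding <- "none"
    train$augment <- FALSE
    train$clip_norm <- NULL
  }
  structure(list(synthetic = synthetic, qc = qc, window_len = window_len,
                 fractions = fractions, model = model, train = train,
                 tta = tta, alpha = alpha, bandpass_hz = bandpass_hz,
                 strict_paper_mode = strict_paper_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full virtual-short-channel pipeline
#'
#' simulate -> (QC) -> window -> normalise -> train -> predict (TTA) ->
#' merge -> SCR -> band-pass -> Beer-Lambert -> metrics, with the stage
#' order SCR -> band-pass -> conversion enforced by the stage tags.  All
#' artifacts are returned in memory; when `out_dir` is given, the metric
#' tables, training history and a JSON manifest (config hash, seeds,
#' package version, stage order) are also written as text files.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return List: `cohort`, `qc_reports`, `model`, `metrics` (OD-domain
#'   [metrics_report()]), `residual_variance` (tibble), `block_averages`
#'   (when the config has task blocks), `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  say("simulate: %d subjects", cfg$synthetic$n_subjects)
  cohort <- synthesize_cohort(cfg$synthetic)

  qc_reports <- NULL
  if (!is.null(cfg$qc)) {
    say("qc: coherence threshold %.2f", cfg$qc$threshold)
    res <- lapply(cohort, reject_pairs, qc = cfg$qc)
    cohort <- lapply(res, `[[`, "recording")
    qc_reports <- lapply(res, `[[`, "report")
  }

  say("windows: L = %d", cfg$window_len)
  ws <- cohort_windows(cohort, cfg$window_len)
  nwin <- dim(ws$x$tensor)[1]
  split <- split_windows(nwin, cfg$fractions, seed = derive_seed(cfg$seed, 1L))
  xs <- normalize_windows(ws$x, train_idx = split$train)
  ys <- normalize_windows(ws$y, train_idx = split$train)

  say("train: %d epochs", cfg$train$epochs)
  model <- init_transformer(cfg$model, seed = derive_seed(cfg$seed, 2L))
  model <- train_transformer(model, xs$tensor, ys$tensor, split, cfg$train,
                             alpha = cfg$alpha, quiet = quiet)
  model$norm_stats <- list(input = xs$stats, target = ys$stats)

  say("predict: %s", if (is.null(cfg$tta)) "plain" else
    sprintf("TTA x %d", cfg$tta$n_augment))
  pred_n <- if (is.null(cfg$tta)) {
    transformer_forward(model, xs$tensor, precision = "single")
  } else {
    tta_predict(model, xs$tensor, cfg$tta)
  }
  predws <- xs; predws$tensor <- pred_n
  pred <- denormalize_windows(predws, ys$stats)
  pred$subjects <- xs$subjects

  # held-out OD metrics, per test-window channel series merged by subject
  test_ws <- function(w, idx) {
    out <- w; out$tensor <- w$tensor[idx, , , drop = FALSE]
    out$subjects <- w$subjects[idx]; out
  }
  ord <- order(xs$subjects[split$test])
  tidx <- split$test[ord]
  pm <- merge_windows(test_ws(pred, tidx))
  ym <- merge_windows(test_ws(ws$y, tidx))
  metrics <- metrics_report(pm, ym, domain = "od")

  # denoising: SCR on each subject's long channels with virtual regressors
  say("denoise: SCR -> bandpass(%g-%g Hz) -> MBLL",
      cfg$bandpass_hz[1], cfg$bandpass_hz[2])
  pred_full <- merge_windows(pred)
  rv <- list(); bas <- list()
  for (s in seq_along(cohort)) {
    rec <- cohort[[s]]
    L <- cfg$window_len
    ncov <- nrow(pred_full[[as.character(s)]])
    rec_cov <- rec
    rec_cov$data <- rec$data[seq_len(ncov), , drop = FALSE]
    den_virtual <- denoise_long_channels(rec_cov, pred_full[[as.character(s)]],
                                         cfg$bandpass_hz[1], cfg$bandpass_hz[2])
    den_measured <- denoise_long_channels(rec_cov, "measured",
                                          cfg$bandpass_hz[1], cfg$bandpass_hz[2])
    raw_bp <- bandpass(long_matrix(rec_cov), rec$fs_hz,
                       cfg$bandpass_hz[1], cfg$bandpass_hz[2])
    rv[[s]] <- tibble::tibble(
      subject = s, channel = colnames(den_virtual),
      var_raw = apply(raw_bp, 2, var),
      var_scr_virtual = residual_variance(den_virtual),
      var_scr_measured = residual_variance(den_measured)
    )
    if (nrow(rec$events)) {
      conc <- concentration_by_channel(den_virtual)
      ba <- lapply(names(conc), function(ch) {
        out <- block_average(unclass(conc[[ch]]), rec$events, rec$fs_hz)
        out$channel <- ch; out$subject <- s; out
      })
      bas[[length(bas) + 1]] <- dplyr::bind_rows(ba)
    }
  }
  rv <- dplyr::bind_rows(rv)
  bas <- if (length(bas)) dplyr::bind_rows(bas) else NULL

  manifest <- list(
    package = "vshortr",
    version = as.character(utils::packageVersion("vshortr")),
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    strict_paper_mode = cfg$strict_paper_mode,
    stage_order = c("simulate", if (!is.null(cfg$qc)) "qc", "windows",
                    "train", "predict", "scr", "bandpass", "mbll",
                    "metrics"),
    n_subjects = length(cohort), n_windows = nwin,
    split = vapply(split, length, integer(1))
  )
  out <- list(cohort = cohort, qc_reports = qc_reports, model = model,
              split = split, windows = ws, predictions = pred_full,
              metrics = metrics, residual_variance = rv,
              block_averages = bas, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(metrics, file.path(out_dir, "metrics_od.csv"),
              row.names = FALSE)
    write.csv(rv, file.path(out_dir, "residual_variance.csv"),
              row.names = FALSE)
    write.csv(model$history, file.path(out_dir, "train_history.csv"),
              row.names = FALSE)
    if (!is.null(bas)) {
      write.csv(bas, file.path(out_dir, "block_averages.csv"),
                row.names = FALSE)
    }
    write_model(model, file.path(out_dir, "model.json"))
  }
  out
}
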