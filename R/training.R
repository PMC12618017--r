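#' Training configuration
#'
#' AdamW (decoupled weight decay) with a cosine-annealed learning rate,
#' mirroring the training protocol of the predictor: batch 128, 180
#' epochs, initial learning rate 8e-4, weight decay 1e-4.  The best
#' model by validation loss is kept.  Gradient clipping at global norm
#' `clip_norm` is a divergence guard; set it to `NULL` (as
#' `strict_paper_mode` does) to disable.
#'
#' @param batch_size Windows per optimisation step.
#' @param epochs Training epochs.
#' @param lr0 Initial learning rate.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param eta_min Final learning rate of the cosine schedule.
#' @param seed Seed for shuffling, dropout and augmentation.
#' @param clip_norm Global gradient-norm clip, or `NULL`.
#' @param augment Apply the augmentation magnitudes of `tta` to training
#'   batches as well (the default; augmentation is used across both
#'   training and inference, and is the main guard against mapping
#'   channel-idiosyncratic content into the predictions; strict mode
#'   turns it off).
#' @param tta A [tta_config()] supplying training-augmentation magnitudes
#'   when `augment = TRUE`.
#' @return List of class `train_config`.
#' @export
train_config <- function(batch_size = 128, epochs = 180, lr0 = 8e-4,
                         weight_decay = 1e-4, eta_min = 0, seed = 1L,
                         clip_norm = 1, augment = TRUE, tta = tta_config()) {
  stopifnot(lr0 > 0, epochs >= 1, batch_size >= 1, weight_decay >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0,
                 weight_decay = weight_decay, eta_min = eta_min,
                 seed = as.integer(seed), clip_norm = clip_norm,
                 augment = augment, tta = tta),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `eta_min + 0.5 * (lr0 - eta_min) * (1 + cos(pi * epoch / total))`,
#' stepped once per epoch: `lr0` at epoch 0, `(lr0 + eta_min)/2` at
#' mid-training, `eta_min` at the end; monotonically non-increasing.
#'
#' @param epoch Epoch index in `0:total_epochs`.
#' @param total_epochs Schedule length.
#' @param lr0 Initial learning rate.
#' @param eta_min Floor learning rate.
#' @return Learning rate.
#' @export
cosine_lr <- function(epoch, total_epochs, lr0 = 8e-4, eta_min = 0) {
  stopifnot(epoch >= 0, epoch <= total_epochs)
  eta_min + 0.5 * (lr0 - eta_min) * (1 + cos(pi * epoch / total_epochs))
}

# One AdamW step over a named parameter list (state updated in place
# semantics via returned list).
adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       trainable = names(params)) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    gg <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gg
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gg^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (upd + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

global_grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

#' Train the transformer on normalised windows
#'
#' Minimises the hybrid loss ([hybrid_loss()]) with AdamW and a
#' per-epoch cosine learning-rate schedule.  Windows must already be
#' normalised to `[-1, 1]`; the normalisation stats travel with the
#' returned model so predictions can be mapped back.  Per-epoch train and
#' validation losses are logged and the checkpoint with the best
#' validation loss is returned.  Fully seeded: identical configs and
#' seeds give identical results on a fixed BLAS.
#'
#' @param model A `nirs_model` from [init_transformer()].
#' @param x,y Normalised window arrays `[n, T, F]` (e.g.
#'   `nirs_windows$tensor`).
#' @param split Index partition from [split_windows()].
#' @param tc A [train_config()].
#' @param alpha,epsilon Hybrid-loss parameters.
#' @param trainable Parameter names to update (default all); used by
#'   montage adaptation to freeze the encoder core.
#' @param precision Arithmetic of the forward/backward passes;
#'   single precision (the default, standard for this model class) halves
#'   the cost on one CPU while the AdamW accumulators stay in double.
#' @param quiet Suppress progress messages.
#' @return The trained `nirs_model` with `$history` (tibble: epoch, lr,
#'   train_loss, val_loss).
#' @export
train_transformer <- function(model, x, y, split, tc = train_config(),
                              alpha = 0.3, epsilon = 1e-8,
                              trainable = names(model$params),
                              precision = c("single", "double"),
                              quiet = TRUE) {
  precision <- match.arg(precision)
  stopifnot(inherits(model, "nirs_model"), inherits(tc, "train_config"))
  if (length(intersect(split$train, split$val)) ||
      length(intersect(split$train, split$test))) {
    stop("splits must be disjoint")
  }
  params <- model$params
  state <- list(t = 0,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  xv <- x[split$val, , , drop = FALSE]
  yv <- y[split$val, , , drop = FALSE]
  hist <- vector("list", tc$epochs)
  best <- list(val = Inf, params = params)
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      lr <- cosine_lr(ep - 1, tc$epochs, tc$lr0, tc$eta_min)
      idx <- sample(split$train)
      nb <- ceiling(length(idx) / tc$batch_size)
      tr_loss <- 0
      diverged <- FALSE
      for (bi in seq_len(nb)) {
        take <- idx[((bi - 1) * tc$batch_size + 1):
                      min(bi * tc$batch_size, length(idx))]
        xb <- x[take, , , drop = FALSE]
        yb <- y[take, , , drop = FALSE]
        if (tc$augment) xb <- augment_batch(xb, tc$tta)
        mdl <- list(params = params, cfg = model$cfg)
        class(mdl) <- "nirs_model"
        res <- transformer_loss_grad(mdl, xb, yb, alpha, epsilon,
                                     train_mode = TRUE,
                                     precision = precision)
        if (!is.finite(res$loss)) {
          warning("divergent loss; aborting with last good checkpoint")
          diverged <- TRUE
          break
        }
        grads <- res$grads
        if (!is.null(tc$clip_norm)) {
          gn <- global_grad_norm(grads)
          if (gn > tc$clip_norm) {
            grads <- lapply(grads, function(g) g * tc$clip_norm / gn)
          }
        }
        stp <- adamw_step(params, grads, state, lr, tc$weight_decay,
                          trainable = trainable)
        params <- stp$params
        state <- stp$state
        tr_loss <- tr_loss + res$loss * length(take)
      }
      if (diverged) break
      tr_loss <- tr_loss / length(idx)
      mdl <- list(params = params, cfg = model$cfg)
      class(mdl) <- "nirs_model"
      pv <- transformer_forward(mdl, xv, train_mode = FALSE,
                                precision = precision)
      val_loss <- hybrid_loss(pv, yv, alpha, epsilon)
      if (val_loss < best$val) best <- list(val = val_loss, params = params)
      hist[[ep]] <- tibble::tibble(epoch = ep, lr = lr,
                                   train_loss = tr_loss, val_loss = val_loss)
      if (!quiet) {
        message(sprintf("epoch %3d  lr %.2e  train %.5f  val %.5f",
                        ep, lr, tr_loss, val_loss))
      }
    }
  })
  out <- model
  out$params <- best$params
  out$history <- dplyr::bind_rows(hist)
  out
}

#' Test-time augmentation configuration
#'
#' Magnitudes of the inference-time perturbation ensemble: additive
#' Gaussian noise (sigma 0.01 in normalised units), temporal jitter of up
#' to +-10 samples (edge-replicated, with the prediction shifted back),
#' amplitude scaling of +-5%, and a per-window additive baseline offset
#' (sigma 0.01, the same order as the noise).
#'
#' @param n_augment Number of perturbed copies averaged.
#' @param noise_sd Gaussian noise sigma.
#' @param jitter_samples Maximum absolute shift.
#' @param amp_scale Half-width of the multiplicative factor range.
#' @param baseline_shift_sd Baseline offset sigma.
#' @param seed Seed for the perturbation draws.
#' @return List of class `tta_config`.
#' @export
tta_config <- function(n_augment = 5, noise_sd = 0.01, jitter_samples = 10,
                       amp_scale = 0.05, baseline_shift_sd = 0.01,
                       seed = 1L) {
  stopifnot(n_augment >= 1, noise_sd >= 0, jitter_samples >= 0,
            amp_scale >= 0, baseline_shift_sd >= 0)
  structure(list(n_augment = as.integer(n_augment), noise_sd = noise_sd,
                 jitter_samples = as.integer(jitter_samples),
                 amp_scale = amp_scale,
                 baseline_shift_sd = baseline_shift_sd,
                 seed = as.integer(seed)),
            class = "tta_config")
}

# shift a [T, F] window by k samples with edge replication (k > 0: delay)
shift_window <- function(w, k) {
  T <- nrow(w)
  if (k == 0) return(w)
  if (k > 0) {
    rbind(w[rep(1, k), , drop = FALSE], w[1:(T - k), , drop = FALSE])
  } else {
    k <- -k
    rbind(w[(k + 1):T, , drop = FALSE], w[rep(T, k), , drop = FALSE])
  }
}

# draw one perturbation per window of a [B, T, F] batch; returns the
# perturbed batch and the shifts used (so predictions can be unshifted)
perturb_batch <- function(x, ttc) {
  d <- dim(x)
  shifts <- if (ttc$jitter_samples > 0) {
    sample(seq(-ttc$jitter_samples, ttc$jitter_samples), d[1], replace = TRUE)
  } else {
    rep(0L, d[1])
  }
  facs <- if (ttc$amp_scale > 0) {
    runif(d[1], 1 - ttc$amp_scale, 1 + ttc$amp_scale)
  } else {
    rep(1, d[1])
  }
  offs <- rnorm(d[1], 0, ttc$baseline_shift_sd)
  for (b in seq_len(d[1])) {
    w <- x[b, , ]
    if (shifts[b] != 0) w <- shift_window(w, shifts[b])
    w <- w * facs[b] + offs[b]
    if (ttc$noise_sd > 0) w <- w + rnorm(length(w), 0, ttc$noise_sd)
    x[b, , ] <- w
  }
  list(x = x, shifts = shifts)
}

augment_batch <- function(x, ttc) perturb_batch(x, ttc)$x

#' Predict with test-time augmentation
#'
#' Builds `n_augment` perturbed copies of each input window (noise,
#' temporal jitter, amplitude scaling, baseline shift), predicts each,
#' inverse-shifts the jittered predictions, and averages.  The ensemble
#' average reduces prediction variance relative to any single perturbed
#' pass; with all magnitudes zero it equals the plain forward pass
#' exactly.
#'
#' @param model A trained `nirs_model`.
#' @param x Window array `[B, T, F]` or single `[T, F]` matrix.
#' @param ttc A [tta_config()].
#' @return Averaged predictions, same shape semantics as
#'   [transformer_forward()].
#' @export
tta_predict <- function(model, x, ttc = tta_config(),
                        precision = c("single", "double")) {
  precision <- match.arg(precision)
  single <- is.matrix(x)
  if (single) x <- array(x, c(1, nrow(x), ncol(x)))
  d <- dim(x)
  if (ttc$noise_sd == 0 && ttc$jitter_samples == 0 && ttc$amp_scale == 0 &&
      ttc$baseline_shift_sd == 0) {
    # every augmented copy is the input itself: exact identity wrapper
    out <- transformer_forward(model, x, train_mode = FALSE,
                               precision = precision)
    return(if (single) out[1, , ] else out)
  }
  acc <- array(0, c(d[1], d[2], model$cfg$n_features_out))
  with_seed(ttc$seed, {
    for (a in seq_len(ttc$n_augment)) {
      pb <- perturb_batch(x, ttc)
      pred <- transformer_forward(model, pb$x, train_mode = FALSE,
                                  precision = precision)
      for (b in seq_len(d[1])) {
        if (pb$shifts[b] != 0) {
          pred[b, , ] <- shift_window(pred[b, , ], -pb$shifts[b])
        }
      }
      acc <- acc + pred
    }
  })
  out <- acc / ttc$n_augment
  if (single) out[1, , ] else out
}

#' Predict virtual short channels for a whole recording
#'
#' Segments the recording's long channels into model windows, normalises
#' them with the training statistics, predicts the paired short-channel
#' windows (optionally with test-time augmentation), maps the
#' predictions back to OD units and merges them into a continuous
#' matrix in long-feature layout, ready to be used as SCR regressors
#' (see [denoise_long_channels()]).
#'
#' @param model A trained `nirs_model` whose `norm_stats` (a list with
#'   elements `input` and `target`) were fitted during training, or pass
#'   `stats` explicitly.
#' @param rec An OD [new_recording()] on a montage matching the model's
#'   feature count.
#' @param stats List of normalisation stats tibbles (`input`, `target`).
#' @param tta Optional [tta_config()].
#' @return Matrix `n_covered_samples x n_long_features` of predicted
#'   short-channel OD; `n_covered = floor(n / window_len) * window_len`.
#' @export
predict_short_channels <- function(model, rec, stats = model$norm_stats,
                                   tta = NULL) {
  stopifnot(inherits(model, "nirs_model"))
  if (is.null(stats) || is.null(stats$input) || is.null(stats$target)) {
    stop("normalisation stats are required (model$norm_stats$input/target)")
  }
  ws <- segment_windows(long_matrix(rec), model$cfg$window_len)
  wsn <- normalize_windows(ws, stats = stats$input)
  pred <- if (is.null(tta)) {
    transformer_forward(model, wsn$tensor, precision = "single")
  } else {
    tta_predict(model, wsn$tensor, tta)
  }
  out <- wsn
  out$tensor <- pred
  out <- denormalize_windows(out, stats$target)
  merge_windows(out)[[1]]
}

#' Adapt a trained model to a new montage
#'
#' Enlarges the input and output projections to a new feature count,
#' copies the pre-trained projection rows/columns for the features named
#' in `overlap_map`, freshly initialises the new ones, and optionally
#' fine-tunes on windows from the new montage.  With `frozen_core = TRUE`
#' (default) only the projections are updated, minimally altering the
#' encoder representations learned on the original montage.
#'
#' @param model A trained `nirs_model`.
#' @param new_cfg A [transformer_config()] for the new feature counts
#'   (other architecture fields must match the original).
#' @param overlap_map Named integer vector: `new_index = old_index`
#'   given as `old -> new`, i.e. `overlap_map[old_feature] = new_feature`;
#'   must be injective.
#' @param x,y,split Optional fine-tuning windows (normalised) and split.
#' @param tc Fine-tuning [train_config()] (e.g. few epochs, smaller lr).
#' @param frozen_core Freeze everything except the input/output
#'   projections during fine-tuning.
#' @param init_seed Seed for the freshly initialised weights.
#' @return The adapted `nirs_model`.
#' @export
adapt_to_montage <- function(model, new_cfg, overlap_map,
                             x = NULL, y = NULL, split = NULL,
                             tc = train_config(epochs = 10),
                             frozen_core = TRUE, init_seed = 1L) {
  stopifnot(inherits(model, "nirs_model"), inherits(new_cfg, "transformer_config"))
  old_cfg <- model$cfg
  same <- c("embed_dim", "n_heads", "n_blocks", "ff_dim", "window_len")
  for (f in same) stopifnot(identical(old_cfg[[f]], new_cfg[[f]]))
  if (anyDuplicated(overlap_map)) stop("overlap_map must be injective")
  old_idx <- as.integer(names(overlap_map) %||% seq_along(overlap_map))
  new_idx <- as.integer(overlap_map)
  if (max(old_idx) > old_cfg$n_features_in ||
      max(new_idx) > new_cfg$n_features_in) {
    stop("overlap_map references absent features")
  }
  new_model <- init_transformer(new_cfg, seed = init_seed)
  p <- new_model$params
  core <- setdiff(names(model$params), c("W_in", "W_out", "b_out"))
  for (nm in intersect(core, names(p))) p[[nm]] <- model$params[[nm]]
  p$W_in[new_idx, ] <- model$params$W_in[old_idx, ]
  p$W_out[, new_idx] <- model$params$W_out[, old_idx]
  p$b_out[new_idx] <- model$params$b_out[old_idx]
  new_model$params <- p
  if (!is.null(x) && tc$epochs > 0) {
    trainable <- if (frozen_core) c("W_in", "b_in", "W_out", "b_out") else
      names(p)
    new_model <- train_transformer(new_model, x, y, split, tc,
                                   trainable = trainable)
  }
  new_model
}
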