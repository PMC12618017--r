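#' Transformer encoder configuration
#'
#' Architecture of the window-to-window regressor: a learned affine
#' projection of each 28-feature time step into a 128-dimensional
#' embedding, optional positional encoding, two identical encoder blocks
#' (4-head self-attention and a 128 -> 256 -> 128 GELU feed-forward, each
#' wrapped in dropout + residual add + layer normalisation), and an affine
#' decoder back to the 28 output features.
#'
#' @param n_features_in,n_features_out Input/output features per time step.
#' @param embed_dim Embedding width (divisible by `n_heads`).
#' @param n_heads Attention heads.
#' @param n_blocks Encoder blocks.
#' @param ff_dim Feed-forward hidden width (2 x embedding by default).
#' @param dropout Dropout probability (train mode only).
#' @param positional_encoding `"none"` (default: the mapping is
#'   time-stationary and injecting a position code measurably hurts it),
#'   `"sinusoidal"` or `"learned"`.
#' @param window_len Window length in samples.
#' @return List of class `transformer_config`.
#' @export
transformer_config <- function(n_features_in = 28, n_features_out = 28,
                               embed_dim = 128, n_heads = 4, n_blocks = 2,
                               ff_dim = 256, dropout = 0.1,
                               positional_encoding = c("none", "sinusoidal",
                                                       "learned"),
                               window_len = 128) {
  positional_encoding <- match.arg(positional_encoding)
  stopifnot(embed_dim %% n_heads == 0, n_blocks >= 1, ff_dim >= 1,
            dropout >= 0, dropout < 1)
  structure(
    list(n_features_in = as.integer(n_features_in),
         n_features_out = as.integer(n_features_out),
         embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads),
         n_blocks = as.integer(n_blocks), ff_dim = as.integer(ff_dim),
         dropout = dropout, positional_encoding = positional_encoding,
         window_len = as.integer(window_len)),
    class = "transformer_config"
  )
}

# uniform fan-in initialisation, the standard scheme for affine layers
init_affine <- function(fan_in, fan_out) {
  bound <- 1 / sqrt(fan_in)
  list(W = matrix(runif(fan_in * fan_out, -bound, bound), fan_in, fan_out),
       b = runif(fan_out, -bound, bound))
}

#' Initialise a transformer model
#'
#' Weights use the standard uniform fan-in scheme; layer-norm gains start
#' at 1 and shifts at 0; a learned positional encoding starts at 0.  The
#' seed is recorded in the model.
#'
#' @param cfg A [transformer_config()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `nirs_model` with elements `params`, `cfg`,
#'   `seed`, and after training `history`, `norm_stats`.
#' @export
init_transformer <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "transformer_config"))
  D <- cfg$embed_dim
  with_seed(seed, {
    p <- list()
    a <- init_affine(cfg$n_features_in, D)
    p$W_in <- a$W; p$b_in <- a$b
    for (l in seq_len(cfg$n_blocks) - 1L) {
      for (nm in c("q", "k", "v", "o")) {
        a <- init_affine(D, D)
        p[[paste0("W", nm, l)]] <- a$W
        p[[paste0("b", nm, l)]] <- a$b
      }
      p[[paste0("ln1g", l)]] <- rep(1, D)
      p[[paste0("ln1b", l)]] <- rep(0, D)
      a <- init_affine(D, cfg$ff_dim)
      p[[paste0("W1", l)]] <- a$W; p[[paste0("b1", l)]] <- a$b
      a <- init_affine(cfg$ff_dim, D)
      p[[paste0("W2", l)]] <- a$W; p[[paste0("b2", l)]] <- a$b
      p[[paste0("ln2g", l)]] <- rep(1, D)
      p[[paste0("ln2b", l)]] <- rep(0, D)
    }
    a <- init_affine(D, cfg$n_features_out)
    p$W_out <- a$W; p$b_out <- a$b
    if (cfg$positional_encoding == "learned") {
      p$P_pos <- matrix(0, cfg$window_len, D)
    }
    structure(list(params = p, cfg = cfg, seed = as.integer(seed),
                   history = NULL, norm_stats = NULL),
              class = "nirs_model")
  })
}

#' @export
print.nirs_model <- function(x, ...) {
  cat(sprintf(
    "<nirs_model> transformer %d->%d features, embed %d, %d heads, %d blocks (%s params)%s\n",
    x$cfg$n_features_in, x$cfg$n_features_out, x$cfg$embed_dim,
    x$cfg$n_heads, x$cfg$n_blocks,
    format(n_parameters(x), big.mark = ","),
    if (!is.null(x$history)) sprintf(", trained %d epochs",
                                     max(x$history$epoch)) else ""
  ))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model A `nirs_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# flatten [B, T, F] (or [T, F]) to the (B*T) x F layout the C++ core uses
flatten_windows <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(1, nrow(x), ncol(x)))
  d <- dim(x)
  xf <- aperm(x, c(2, 1, 3))
  dim(xf) <- c(d[1] * d[2], d[3])
  xf
}
unflatten_windows <- function(xf, B, T) {
  a <- array(xf, dim = c(T, B, ncol(xf)))
  aperm(a, c(2, 1, 3))
}

#' Transformer forward pass
#'
#' Maps a batch of long-channel windows to predicted short-channel
#' windows.  Dropout is active only when `train_mode = TRUE`; in
#' evaluation mode repeated calls are bit-identical.
#'
#' @param model A `nirs_model`.
#' @param x Array `[B, window_len, n_features_in]` or a single
#'   `[window_len, n_features_in]` matrix.
#' @param train_mode Enable dropout.
#' @param precision `"double"` for strict accuracy (gradient checks,
#'   small analyses) or `"single"`, the standard arithmetic for this
#'   model class and about twice as fast.
#' @return Array `[B, window_len, n_features_out]` (or matrix for matrix
#'   input).
#' @export
transformer_forward <- function(model, x, train_mode = FALSE,
                                precision = c("double", "single")) {
  precision <- match.arg(precision)
  single_in <- is.matrix(x)
  xf <- flatten_windows(x)
  T <- model$cfg$window_len
  if (nrow(xf) %% T != 0) stop("window length does not match config")
  yf <- cpp_transformer_forward(model$params, xf, unclass(model$cfg),
                                train_mode, precision == "single")
  B <- nrow(xf) / T
  y <- unflatten_windows(yf, B, T)
  if (single_in) y[1, , ] else y
}

#' Hybrid training loss: MSE plus Pearson shape penalty
#'
#' `L = MSE(pred, target) + alpha * (1 - r(pred, target))`, where the MSE
#' averages over every time point and feature and `r` is the Pearson
#' correlation computed over time separately for each (window, feature)
#' series and then averaged.  The MSE term drives amplitude accuracy and
#' the correlation term preserves the temporal shape; `alpha = 0.3`
#' balances the two.  A small `epsilon` guards the correlation
#' denominator, and zero-variance series contribute `r = 0` rather than
#' `NaN`.
#'
#' @param pred,target Equal-shaped arrays `[B, T, F]`, matrices `[T, F]`
#'   or vectors (treated as one series).
#' @param alpha Weight of the correlation term (default 0.3).
#' @param epsilon Denominator guard.
#' @return Non-negative scalar loss.
#' @export
hybrid_loss <- function(pred, target, alpha = 0.3, epsilon = 1e-8) {
  if (is.null(dim(pred))) {
    pred <- matrix(pred, ncol = 1)
    target <- matrix(target, ncol = 1)
  }
  if (!identical(dim(pred), dim(target))) stop("shape mismatch")
  if (is.matrix(pred)) {
    d <- dim(pred)
    pred <- array(pred, c(1, d[1], d[2]))
    target <- array(target, c(1, d[1], d[2]))
  }
  d <- dim(pred)
  if (d[2] < 2) stop("need at least 2 time points")
  mse <- mean((pred - target)^2)
  rs <- vapply(seq_len(d[1]), function(b) {
    vapply(seq_len(d[3]), function(f) {
      p <- pred[b, , f]; y <- target[b, , f]
      pc <- p - mean(p); yc <- y - mean(y)
      den <- sqrt(sum(pc^2)) * sqrt(sum(yc^2)) + epsilon
      sum(pc * yc) / den
    }, numeric(1))
  }, numeric(d[3]))
  mse + alpha * (1 - mean(rs))
}

#' Loss and analytic gradient for one batch
#'
#' Thin wrapper over the compiled forward + backward pass; used by
#' [train_transformer()] and by gradient-checking tests.
#'
#' @inheritParams transformer_forward
#' @param y Target array matching `x`'s window layout.
#' @param alpha,epsilon As in [hybrid_loss()].
#' @return List `loss`, `grads` (named like `model$params`), `pred`.
#' @export
transformer_loss_grad <- function(model, x, y, alpha = 0.3, epsilon = 1e-8,
                                  train_mode = TRUE,
                                  precision = c("double", "single")) {
  precision <- match.arg(precision)
  xf <- flatten_windows(x)
  yf <- flatten_windows(y)
  cpp_transformer_loss_grad(model$params, xf, yf, unclass(model$cfg),
                            alpha, epsilon, train_mode,
                            precision == "single")
}

#' @export
glance.nirs_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_parameters = n_parameters(x),
    epochs = if (is.null(h)) 0L else max(h$epoch),
    best_val_loss = if (is.null(h)) NA_real_ else min(h$val_loss),
    final_train_loss = if (is.null(h)) NA_real_ else
      h$train_loss[which.max(h$epoch)]
  )
}

#' @export
tidy.nirs_model <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble(epoch = integer(),
                                                lr = numeric(),
                                                train_loss = numeric(),
                                                val_loss = numeric()))
  x$history
}
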