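# Shared fixtures: a tiny 2-long + 2-short montage for cheap generation,
# small synthetic configs, and a memoised briefly-trained model so several
# test files can reuse one training run.

tiny_montage <- function(far = 200) {
  sq2 <- 8 / sqrt(2)
  optodes <- tibble::tibble(
    optode_id = c("S1", "D1", "S2", "D2", "SD1", "SD2"),
    x = c(0, 30, far, far + 30, sq2, far + sq2),
    y = c(0, 0, 0, 0, sq2, sq2)
  )
  channels <- tibble::tibble(
    channel_id = c("L01", "L02", "S01", "S02"),
    source = c("S1", "S2", "S1", "S2"),
    detector = c("D1", "D2", "SD1", "SD2"),
    separation_mm = c(30, 30, 8, 8),
    role = c("long", "long", "short", "short")
  )
  nirs_montage(channels, optodes)
}

tiny_config <- function(..., n_subjects = 1, duration_s = 120, seed = 101) {
  synthetic_config(n_subjects = n_subjects, duration_s = duration_s,
                   montage = tiny_montage(), seed = seed, ...)
}

small_tf_config <- function(n_features = 4, window_len = 32) {
  transformer_config(n_features_in = n_features, n_features_out = n_features,
                     embed_dim = 16, n_heads = 2, n_blocks = 2, ff_dim = 32,
                     dropout = 0.1, window_len = window_len)
}

# a briefly trained small model on the tiny montage, cached per session
.fixture_cache <- new.env(parent = emptyenv())

tiny_trained_model <- function() {
  if (!is.null(.fixture_cache$model)) return(.fixture_cache$model)
  cfg <- tiny_config(n_subjects = 6, duration_s = 160, seed = 55)
  cohort <- synthesize_cohort(cfg)
  ws <- cohort_windows(cohort, window_len = 32)
  split <- split_windows(dim(ws$x$tensor)[1], seed = 9)
  xs <- normalize_windows(ws$x, split$train)
  ys <- normalize_windows(ws$y, split$train)
  mdl <- init_transformer(small_tf_config(), seed = 3)
  mdl <- train_transformer(mdl, xs$tensor, ys$tensor, split,
                           train_config(epochs = 5, seed = 4))
  mdl$norm_stats <- list(input = xs$stats, target = ys$stats)
  .fixture_cache$model <- list(model = mdl, split = split, xs = xs, ys = ys,
                               cohort = cohort, windows = ws)
  .fixture_cache$model
}
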