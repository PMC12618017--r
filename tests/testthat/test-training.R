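# Optimisation loop, schedule, test-time augmentation and montage
# adaptation.

test_that("cosine schedule hits its endpoints and never increases", {
  expect_equal(cosine_lr(0, 180), 8e-4)
  expect_equal(cosine_lr(180, 180), 0)
  expect_equal(cosine_lr(90, 180), 4e-4)
  expect_equal(cosine_lr(50, 100, lr0 = 1e-3, eta_min = 2e-4), 6e-4)
  lrs <- vapply(0:180, cosine_lr, numeric(1), total_epochs = 180)
  expect_true(all(diff(lrs) <= 1e-15))
})

test_that("one epoch on a toy set logs exactly one train and val entry", {
  fix <- tiny_trained_model()
  mdl <- init_transformer(small_tf_config(), seed = 1)
  sp <- list(train = 1:4, val = 5, test = 6)
  out <- train_transformer(mdl, fix$xs$tensor[1:6, , , drop = FALSE],
                           fix$ys$tensor[1:6, , , drop = FALSE], sp,
                           train_config(epochs = 1, batch_size = 2, seed = 2))
  expect_equal(nrow(out$history), 1)
  expect_true(all(c("epoch", "lr", "train_loss", "val_loss") %in%
                    names(out$history)))
})

test_that("training is reproducible and rejects overlapping splits", {
  fix <- tiny_trained_model()
  run <- function() {
    mdl <- init_transformer(small_tf_config(), seed = 3)
    train_transformer(mdl, fix$xs$tensor, fix$ys$tensor, fix$split,
                      train_config(epochs = 2, seed = 11))
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
  bad <- fix$split; bad$val <- bad$train[1:2]
  mdl <- init_transformer(small_tf_config(), seed = 3)
  expect_error(train_transformer(mdl, fix$xs$tensor, fix$ys$tensor, bad,
                                 train_config(epochs = 1)), "disjoint")
})

test_that("training loss decreases over the first epochs on synthetic data", {
  fix <- tiny_trained_model()
  h <- fix$model$history
  expect_gte(nrow(h), 5)
  expect_lt(h$train_loss[5], h$train_loss[1])
  # and the best-validation checkpoint is at least as good as the last
  expect_lte(min(h$val_loss), h$val_loss[nrow(h)])
})

test_that("TTA with zero magnitudes is an exact identity wrapper", {
  fix <- tiny_trained_model()
  x <- fix$xs$tensor[1:3, , , drop = FALSE]
  plain <- transformer_forward(fix$model, x, precision = "single")
  zero <- tta_predict(fix$model, x,
                      tta_config(n_augment = 4, noise_sd = 0,
                                 jitter_samples = 0, amp_scale = 0,
                                 baseline_shift_sd = 0))
  expect_identical(zero, plain)
})

test_that("TTA is seeded and its averaging reduces prediction variance", {
  fix <- tiny_trained_model()
  x <- fix$xs$tensor[1, , ]
  a <- tta_predict(fix$model, x, tta_config(seed = 5))
  b <- tta_predict(fix$model, x, tta_config(seed = 5))
  expect_identical(a, b)

  probe <- function(n_aug, seed) {
    tta_predict(fix$model, x, tta_config(n_augment = n_aug, seed = seed))[16, 2]
  }
  many <- vapply(1:50, function(s) probe(5, s), numeric(1))
  single <- vapply(101:150, function(s) probe(1, s), numeric(1))
  expect_lte(var(many), var(single))
})

test_that("montage adaptation transfers overlapping projections exactly", {
  fix <- tiny_trained_model()
  mdl <- fix$model
  cfg6 <- transformer_config(n_features_in = 6, n_features_out = 6,
                             embed_dim = 16, n_heads = 2, n_blocks = 2,
                             ff_dim = 32, dropout = 0.1, window_len = 32)
  ad <- adapt_to_montage(mdl, cfg6, overlap_map = setNames(1:4, 1:4))
  expect_equal(dim(ad$params$W_in), c(6L, 16L))
  expect_equal(dim(ad$params$W_out), c(16L, 6L))
  x <- fix$xs$tensor[1:2, , , drop = FALSE]
  x6 <- array(0, c(2, 32, 6)); x6[, , 1:4] <- x
  p6 <- transformer_forward(ad, x6)
  expect_equal(p6[, , 1:4], transformer_forward(mdl, x))

  expect_error(adapt_to_montage(mdl, cfg6, setNames(c(2, 2), 1:2)),
               "injective")
  expect_error(adapt_to_montage(mdl, cfg6, setNames(7, 1)), "absent")
})

test_that("fine-tuning on an expanded montage improves held-out loss", {
  fix <- tiny_trained_model()
  # 6-feature synthetic cohort: tiny montage plus one extra long channel
  m3 <- {
    sq2 <- 8 / sqrt(2)
    optodes <- tibble::tibble(
      optode_id = c("S1", "D1", "S2", "D2", "S3", "D3", "SD1", "SD2", "SD3"),
      x = c(0, 30, 200, 230, 100, 130, sq2, 200 + sq2, 100 + sq2),
      y = c(0, 0, 0, 0, 60, 60, sq2, sq2, 60 + sq2)
    )
    channels <- tibble::tibble(
      channel_id = c("L01", "L02", "L03", "S01", "S02", "S03"),
      source = c("S1", "S2", "S3", "S1", "S2", "S3"),
      detector = c("D1", "D2", "D3", "SD1", "SD2", "SD3"),
      separation_mm = c(30, 30, 30, 8, 8, 8),
      role = c(rep("long", 3), rep("short", 3))
    )
    nirs_montage(channels, optodes)
  }
  cfg6 <- transformer_config(n_features_in = 6, n_features_out = 6,
                             embed_dim = 16, n_heads = 2, n_blocks = 2,
                             ff_dim = 32, dropout = 0.1, window_len = 32)
  sc <- synthetic_config(n_subjects = 10, duration_s = 160, montage = m3,
                         seed = 91)
  co <- synthesize_cohort(sc)
  ws <- cohort_windows(co, 32)
  sp <- split_windows(dim(ws$x$tensor)[1], seed = 13)
  xs <- normalize_windows(ws$x, sp$train)
  ys <- normalize_windows(ws$y, sp$train)
  heldout_loss <- function(m) {
    hybrid_loss(transformer_forward(m, xs$tensor[sp$test, , , drop = FALSE]),
                ys$tensor[sp$test, , , drop = FALSE])
  }
  # L01/L02 of the tiny montage match L01/L02 of the expanded one, so
  # old features 1:4 map onto new features 1:4
  om <- setNames(1:4, 1:4)
  wins <- 0
  for (s in 1:3) {
    plain <- adapt_to_montage(fix$model, cfg6, om, init_seed = s)
    tuned <- adapt_to_montage(fix$model, cfg6, om, x = xs$tensor,
                              y = ys$tensor, split = sp,
                              tc = train_config(epochs = 10, seed = s),
                              init_seed = s)
    wins <- wins + (heldout_loss(tuned) < heldout_loss(plain))
  }
  expect_gte(wins, 2)
})

test_that("frozen-core fine-tuning leaves the encoder untouched", {
  fix <- tiny_trained_model()
  cfg <- small_tf_config()
  sp <- list(train = 1:8, val = 9:10, test = 11:12)
  tuned <- adapt_to_montage(fix$model, cfg, setNames(1:4, 1:4),
                            x = fix$xs$tensor[1:12, , , drop = FALSE],
                            y = fix$ys$tensor[1:12, , , drop = FALSE],
                            split = sp, tc = train_config(epochs = 2, seed = 1),
                            frozen_core = TRUE)
  expect_identical(tuned$params$Wq0, fix$model$params$Wq0)
  expect_identical(tuned$params$W10, fix$model$params$W10)
  expect_false(identical(tuned$params$W_in, fix$model$params$W_in))
})
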