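# Transformer encoder: shapes, determinism, parameter bookkeeping, the
# hybrid loss, and agreement between the analytic backward pass and
# finite differences.

test_that("forward pass produces the documented shapes deterministically", {
  cfg <- small_tf_config()
  mdl <- init_transformer(cfg, seed = 1)
  set.seed(2)
  x <- array(rnorm(3 * 32 * 4), c(3, 32, 4))
  y1 <- transformer_forward(mdl, x)
  y2 <- transformer_forward(mdl, x)
  expect_identical(y1, y2)            # eval mode: no stochastic elements
  expect_equal(dim(y1), c(3, 32, 4))
  ym <- transformer_forward(mdl, x[1, , ])
  expect_equal(dim(ym), c(32, 4))
  expect_equal(ym, y1[1, , ])

  expect_error(transformer_forward(mdl, x[, 1:10, ]), "window length")
  bad <- x; bad[1] <- NaN
  expect_error(transformer_forward(mdl, bad), "finite")
})

test_that("batch-128 default forward has the standard [128, 128, 28] shape", {
  mdl <- init_transformer(transformer_config(), seed = 1)
  x <- array(rnorm(128 * 128 * 28), c(128, 128, 28))
  y <- transformer_forward(mdl, x, precision = "single")
  expect_equal(dim(y), c(128, 128, 28))
})

test_that("parameter count equals the closed-form sum of layer shapes", {
  count_for <- function(fin, fout, d, dff, blocks, pe_rows = 0) {
    inp <- fin * d + d
    attn <- 4 * (d * d + d)
    ff <- d * dff + dff + dff * d + d
    ln <- 2 * (2 * d)
    out <- d * fout + fout
    inp + blocks * (attn + ff + ln) + out + pe_rows * d
  }
  mdl <- init_transformer(transformer_config(), seed = 1)
  expect_equal(n_parameters(mdl), count_for(28, 28, 128, 256, 2))
  small <- init_transformer(small_tf_config(), seed = 1)
  expect_equal(n_parameters(small), count_for(4, 4, 16, 32, 2))
  learned <- init_transformer(
    transformer_config(positional_encoding = "learned"), seed = 1)
  expect_equal(n_parameters(learned), count_for(28, 28, 128, 256, 2, 128))
})

test_that("hybrid loss reproduces its closed-form cases", {
  y <- c(1, -1)
  expect_equal(hybrid_loss(-y, y), 4.6)
  expect_equal(hybrid_loss(y + 0.5, y), 0.25)
  set.seed(3)
  t <- matrix(rnorm(64), 32, 2)
  expect_equal(hybrid_loss(t, t), 0)
  # constant target: no NaN, correlation term treated as r = 0
  const <- matrix(1, 32, 2)
  l <- hybrid_loss(t, const)
  expect_true(is.finite(l))
  expect_equal(l, mean((t - 1)^2) + 0.3)
})

test_that("hybrid loss is non-negative and zero only at equality", {
  set.seed(4)
  for (i in 1:20) {
    p <- array(rnorm(2 * 16 * 3), c(2, 16, 3))
    y <- array(rnorm(2 * 16 * 3), c(2, 16, 3))
    expect_gte(hybrid_loss(p, y), 0)
  }
  y <- array(rnorm(2 * 16 * 3), c(2, 16, 3))
  # the epsilon guard in the correlation denominator leaves a ~1e-10 floor
  expect_lt(hybrid_loss(y + 1e-9, y), 1e-8)
})

test_that("compiled loss matches the reference implementation", {
  cfg <- small_tf_config()
  mdl <- init_transformer(cfg, seed = 5)
  set.seed(6)
  x <- array(rnorm(4 * 32 * 4), c(4, 32, 4))
  y <- array(rnorm(4 * 32 * 4), c(4, 32, 4))
  res <- transformer_loss_grad(mdl, x, y, train_mode = FALSE)
  pred <- transformer_forward(mdl, x)
  expect_equal(res$loss, hybrid_loss(pred, y), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  cfg <- transformer_config(n_features_in = 3, n_features_out = 3,
                            embed_dim = 8, n_heads = 2, n_blocks = 2,
                            ff_dim = 16, dropout = 0, window_len = 6)
  mdl <- init_transformer(cfg, seed = 2)
  set.seed(7)
  x <- array(rnorm(2 * 6 * 3), c(2, 6, 3))
  y <- array(rnorm(2 * 6 * 3), c(2, 6, 3))
  res <- transformer_loss_grad(mdl, x, y, train_mode = FALSE)
  h <- 1e-5
  set.seed(8)
  for (nm in names(mdl$params)) {
    for (k in sample(seq_along(mdl$params[[nm]]),
                     min(3, length(mdl$params[[nm]])))) {
      up <- mdl; up$params[[nm]][k] <- up$params[[nm]][k] + h
      dn <- mdl; dn$params[[nm]][k] <- dn$params[[nm]][k] - h
      fd <- (transformer_loss_grad(up, x, y, train_mode = FALSE)$loss -
               transformer_loss_grad(dn, x, y, train_mode = FALSE)$loss) / (2 * h)
      an <- res$grads[[nm]][k]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
    }
  }
})

test_that("loss is invariant under consistent feature permutation", {
  cfg <- small_tf_config()
  mdl <- init_transformer(cfg, seed = 9)
  set.seed(10)
  x <- array(rnorm(3 * 32 * 4), c(3, 32, 4))
  y <- array(rnorm(3 * 32 * 4), c(3, 32, 4))
  l0 <- transformer_loss_grad(mdl, x, y, train_mode = FALSE)$loss
  perm <- c(3, 1, 4, 2)
  mdl2 <- mdl
  mdl2$params$W_in <- mdl$params$W_in[perm, ]
  mdl2$params$W_out <- mdl$params$W_out[, perm]
  mdl2$params$b_out <- mdl$params$b_out[perm]
  l1 <- transformer_loss_grad(mdl2, x[, , perm], y[, , perm],
                              train_mode = FALSE)$loss
  expect_equal(l1, l0, tolerance = 1e-12)
})

test_that("single-precision path agrees with double to float accuracy", {
  cfg <- small_tf_config()
  mdl <- init_transformer(cfg, seed = 11)
  set.seed(12)
  x <- array(rnorm(4 * 32 * 4), c(4, 32, 4))
  y <- array(rnorm(4 * 32 * 4), c(4, 32, 4))
  rs <- transformer_loss_grad(mdl, x, y, train_mode = FALSE,
                              precision = "single")
  rd <- transformer_loss_grad(mdl, x, y, train_mode = FALSE,
                              precision = "double")
  expect_equal(rs$loss, rd$loss, tolerance = 1e-5)
  expect_equal(rs$grads$W_in, rd$grads$W_in, tolerance = 1e-4)
})

test_that("model JSON archive round-trips", {
  fix <- tiny_trained_model()
  path <- tempfile(fileext = ".json")
  write_model(fix$model, path)
  back <- read_model(path)
  expect_equal(back$params, fix$model$params, tolerance = 1e-12)
  expect_equal(unclass(back$cfg), unclass(fix$model$cfg))
  set.seed(13)
  x <- array(rnorm(2 * 32 * 4), c(2, 32, 4))
  expect_equal(transformer_forward(back, x), transformer_forward(fix$model, x))
})
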