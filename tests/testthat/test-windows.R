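# Windowing: target construction, segmentation/merging identities,
# normalisation, and the split bookkeeping.

test_that("target matrix mirrors the long-channel feature layout", {
  cfg <- synthetic_config(n_subjects = 1, duration_s = 60)
  rec <- synthesize_recording(cfg, 1)
  tm <- build_target_matrix(rec)
  expect_equal(ncol(tm$data), 28)
  expect_identical(colnames(tm$data),
                   measurement_index(rec$montage)$column[
                     measurement_index(rec$montage)$role == "long"])
  # two long channels sharing one short get identical target columns
  p <- rec$montage$pairing
  shared <- names(p)[duplicated(p) | duplicated(p, fromLast = TRUE)]
  expect_gt(length(shared), 1)
  l1 <- shared[p[shared] == p[shared[1]]][1:2]
  expect_identical(tm$data[, paste0(l1[1], "@760")],
                   tm$data[, paste0(l1[2], "@760")])
  # and every target column is the paired short channel's series
  expect_identical(tm$data[, "L01@850"], rec$data[, paste0(p[["L01"]], "@850")])

  bad <- p[-1]
  expect_error(build_target_matrix(rec, bad), "missing pairing")
})

test_that("segmentation counts follow the floor rule", {
  x <- matrix(rnorm(2520 * 2), ncol = 2)
  expect_equal(dim(segment_windows(x, 128)$tensor)[1], 19)
  expect_equal(dim(segment_windows(x[1:128, ], 128)$tensor)[1], 1)
  expect_warning(w0 <- segment_windows(x[1:127, ], 128), "zero windows")
  expect_equal(dim(w0$tensor)[1], 0)
})

test_that("merge inverts segment on the covered prefix", {
  set.seed(5)
  x <- matrix(rnorm(2520 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  ws <- segment_windows(x, 128)
  m <- merge_windows(ws)[[1]]
  expect_equal(nrow(m), 2432)  # 19 x 128
  expect_equal(unname(m), unname(x[1:2432, ]))
  one <- segment_windows(x[1:128, ], 128)
  expect_equal(unname(merge_windows(one)[[1]]), unname(x[1:128, ]))
})

test_that("normalisation maps to [-1, 1], inverts, and flags constants", {
  set.seed(6)
  ws <- segment_windows(cbind(runif(256, -3, 3), rnorm(256), rep(2, 256)), 32)
  n <- normalize_windows(ws)
  expect_equal(range(n$tensor[, , 1]), c(-1, 1))
  expect_equal(range(n$tensor[, , 2]), c(-1, 1))
  expect_true(all(n$tensor[, , 3] == 0))
  expect_true(n$stats$degenerate[3])
  back <- denormalize_windows(n)
  expect_equal(back$tensor[, , 1:2], ws$tensor[, , 1:2], tolerance = 1e-10)
  expect_equal(back$tensor[, , 3], ws$tensor[, , 3])

  # symmetric range [-a, a] maps exactly onto [-1, 1]
  sym <- segment_windows(matrix(seq(-2, 2, length.out = 64), ncol = 1), 64)
  ns <- normalize_windows(sym)
  expect_equal(min(ns$tensor), -1)
  expect_equal(max(ns$tensor), 1)

  # stats fitted on the training windows only
  tr <- normalize_windows(ws, train_idx = 1:4)
  sub <- ws$tensor[1:4, , 1]
  expect_equal(tr$stats$min[1], min(sub))
  expect_equal(tr$stats$max[1], max(sub))
})

test_that("splits are disjoint, exhaustive and follow the floor rule", {
  s <- split_windows(1311, seed = 1)
  expect_equal(lengths(s), c(train = 1048L, val = 131L, test = 132L))
  expect_equal(lengths(split_windows(10, seed = 2)),
               c(train = 8L, val = 1L, test = 1L))
  expect_identical(split_windows(100, seed = 3), split_windows(100, seed = 3))
  expect_false(identical(split_windows(100, seed = 3),
                         split_windows(100, seed = 4)))
  for (k in 1:20) {
    n <- sample(3:500, 1)
    sp <- split_windows(n, seed = k)
    all_idx <- sort(unname(unlist(sp)))
    expect_identical(all_idx, seq_len(n))
    expect_equal(length(sp$train), floor(0.8 * n))
    expect_equal(length(sp$val), floor(0.1 * n))
  }
})

test_that("subject-level splits keep whole subjects together", {
  subjects <- rep(1:10, each = 19)
  sp <- split_windows(190, seed = 5, subjects = subjects, by_subject = TRUE)
  expect_identical(sort(unname(unlist(sp))), seq_len(190))
  for (part in sp) {
    expect_true(all(table(subjects[part]) == 19))
  }
  inter <- intersect(unique(subjects[sp$train]), unique(subjects[sp$test]))
  expect_length(inter, 0)
})

test_that("cohort windowing aligns predictors and targets", {
  cfg <- tiny_config(n_subjects = 2, duration_s = 64 / 7 * 3 + 1)
  co <- synthesize_cohort(cfg)
  ws <- cohort_windows(co, window_len = 64)
  expect_identical(ws$x$feature_map, ws$y$feature_map)
  expect_identical(ws$x$subjects, ws$y$subjects)
  expect_equal(dim(ws$x$tensor), dim(ws$y$tensor))
  # a target window is the paired short channel over the same samples
  p <- co[[1]]$montage$pairing
  expect_equal(ws$y$tensor[1, , 1],
               unname(co[[1]]$data[1:64, paste0(p[["L01"]], "@760")]))
})
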