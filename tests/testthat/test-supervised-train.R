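test_that("the variant table has the study's 10 rows per fold", {
  v <- enumerate_variants(3)
  expect_equal(nrow(v), 10L)
  expect_equal(sum(v$init == "RandInit"), 2L)
  expect_equal(sum(v$scheme == "FTL"), 4L)
  expect_equal(sum(v$scheme == "FTA"), 4L)
  expect_true(all(v$fold == 3L))
  # RandInit <=> no fine-tuning scheme
  expect_true(all((v$init == "RandInit") == (v$scheme == "none")))
  # 5 variants per training set
  expect_equal(as.integer(table(v$train_set)), c(5L, 5L))
  expect_false(anyDuplicated(v$variant_id) > 0)
})

test_that("binary cross-entropy matches hand values and a loop oracle", {
  expect_equal(bce_loss(1, 1 - 1e-12), 0, tolerance = 1e-5)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c("high", "low"), c(0.5, 0.5)), log(2),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    y <- rbinom(50, 1, 0.4)
    p <- runif(50, 0.01, 0.99)
    oracle <- 0
    for (j in 1:50)
      oracle <- oracle - (y[j] * log(p[j]) + (1 - y[j]) * log(1 - p[j]))
    expect_equal(bce_loss(y, p), oracle / 50, tolerance = 1e-12)
  }
  expect_error(bce_loss(c(1, 0), 0.5), "lengths")
})

test_that("training a variant respects datasets, transfer and freeze semantics", {
  segs <- separable_segment_set(n_groups = 10, segs_per_group = 4)
  splits <- make_splits(segs, split_config(K = 2, seed = 1))
  fs <- splits[[1]]
  cfg <- tiny_config(seed = 4)
  tcfg <- train_config(epochs_all = 2, epochs_head = 2, batch_size = 16,
                       seed = 5)

  pw <- pretrain(subset_segments(segs, split_segment_idx(segs, fs, "trn_pd")),
                 subset_segments(segs, split_segment_idx(segs, fs, "val_pd")),
                 tiny_config("reconstruction", seed = 4), mask_spec(),
                 pretrain_config(epochs = 2, batch_size = 16, seed = 6),
                 tag = "W_PD(1)")

  v <- enumerate_variants(1)
  ftl <- v[v$train_set == "PD" & v$init == "W_PD" & v$scheme == "FTL", ]
  fit <- train_variant(ftl, fs, segs, list(W_PD = pw), cfg, tcfg)
  expect_s3_class(fit$model, "xt_model")
  expect_identical(fit$model$tags$variant_id, ftl$variant_id)
  expect_setequal(unique(fit$log$phase), c("head", "all"))

  # a transfer variant without its weights errors with the missing tag
  expect_error(train_variant(ftl, fs, segs, list(), cfg, tcfg), "W_PD")
})

test_that("FTL phase one leaves every backbone parameter untouched", {
  segs <- separable_segment_set(n_groups = 8, segs_per_group = 3)
  cfg <- tiny_config(seed = 9)
  model <- build_model(cfg)
  bn <- asNamespace("bradynet")
  bb_names <- Filter(bn$is_backbone_param, names(model$params))
  hash_before <- bn$param_hash(model$params, bb_names)
  x <- bn$segments_to_input(segs)
  y <- as.numeric(segs$meta$label == "high")
  set.seed(1)
  out <- bn$supervised_phase(model, x, y, x, y, epochs = 3,
                             train_config(epochs_all = 3, batch_size = 12),
                             head_only = TRUE)
  expect_identical(bn$param_hash(out$model$params, bb_names), hash_before)
  # and the head did move
  expect_false(identical(out$model$params[["head.fc1.W"]],
                         model$params[["head.fc1.W"]]))
})

test_that("a separable problem is learned to high training accuracy", {
  segs <- separable_segment_set(n_groups = 12, segs_per_group = 4)
  cfg <- tiny_config(seed = 2, filters = 3)
  bn <- asNamespace("bradynet")
  model <- build_model(cfg)
  x <- bn$segments_to_input(segs)
  y <- as.numeric(segs$meta$label == "high")
  set.seed(3)
  out <- bn$supervised_phase(model, x, y, x, y, epochs = 40,
                             train_config(epochs_all = 40, batch_size = 16,
                                          max_learning_rate = 3e-3))
  p <- model_forward(out$model, x)
  expect_gte(mean((p >= 0.5) == y), 0.95)
})

test_that("supervised runs are reproducible under fixed seeds", {
  segs <- separable_segment_set(n_groups = 6, segs_per_group = 3)
  splits <- make_splits(segs, split_config(K = 2, seed = 3))
  v <- enumerate_variants(1)
  rand <- v[v$init == "RandInit" & v$train_set == "PD", ]
  cfg <- tiny_config(seed = 1)
  tcfg <- train_config(epochs_all = 2, batch_size = 8, seed = 13)
  f1 <- train_variant(rand, splits[[1]], segs, NULL, cfg, tcfg)
  f2 <- train_variant(rand, splits[[1]], segs, NULL, cfg, tcfg)
  expect_equal(f1$log, f2$log, tolerance = 1e-12)
  expect_identical(f1$model$params, f2$model$params)
})
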