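make_group_df <- function(n_low, n_high) {
  data.frame(
    group_id = sprintf("g%03d", seq_len(n_low + n_high)),
    cohort = "PD",
    label = c(rep("low", n_low), rep("high", n_high)),
    stringsAsFactors = FALSE)
}

test_that("HOA split honours the 80-20 fraction, determinism and empty input", {
  ids <- sprintf("h%02d", 1:10)
  s <- split_hoa(ids, 0.8, seed = 4)
  expect_length(s$trn_hoa, 8L)
  expect_length(s$val_hoa, 2L)
  expect_setequal(c(s$trn_hoa, s$val_hoa), ids)
  expect_identical(split_hoa(ids, 0.8, seed = 4), s)
  expect_false(identical(split_hoa(ids, 0.8, seed = 5)$trn_hoa, s$trn_hoa))

  empty <- split_hoa(character(), 0.8)
  expect_length(empty$trn_hoa, 0L)
  expect_length(empty$val_hoa, 0L)
})

test_that("stratified k-fold balances sizes and label proportions", {
  g <- make_group_df(10, 10)
  folds <- stratified_group_kfold(g, K = 5, seed = 1)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(f, 4L)
    expect_equal(sum(grepl("^g0(0[1-9]|10)$", f)), 2L)  # exactly 2 low
  }
  expect_setequal(unlist(folds), g$group_id)

  # uneven classes: per-fold class counts within 1 of n_c / K
  g <- make_group_df(7, 8)
  folds <- stratified_group_kfold(g, K = 5, seed = 2)
  expect_setequal(unlist(folds), g$group_id)
  sizes <- lengths(folds)
  expect_lte(max(sizes) - min(sizes), 1L)
  for (f in folds) {
    n_low <- sum(g$label[match(f, g$group_id)] == "low")
    n_high <- length(f) - n_low
    expect_lte(abs(n_low - 7 / 5), 1)
    expect_lte(abs(n_high - 8 / 5), 1)
  }

  expect_error(stratified_group_kfold(make_group_df(3, 10), K = 5),
               "class 'low'")
})

test_that("fold assembly is leakage-free with exact test coverage", {
  g <- make_group_df(10, 10)
  folds <- stratified_group_kfold(g, K = 5, seed = 3)
  hoa <- split_hoa(sprintf("h%02d", 1:5), 0.8, seed = 3)
  cfg <- split_config(K = 5)
  tested <- character()
  for (i in 1:5) {
    fs <- make_fold_split(folds, i, hoa, cfg, seed = i)
    expect_identical(fs$tst_pd, sort(folds[[i]]))
    expect_length(intersect(fs$trn_pd, fs$tst_pd), 0L)
    expect_length(intersect(fs$val_pd, fs$tst_pd), 0L)
    expect_setequal(c(fs$trn_pd, fs$val_pd, fs$tst_pd), g$group_id)
    tested <- c(tested, fs$tst_pd)
  }
  # every PD group is tested exactly once across the K folds
  expect_setequal(tested, g$group_id)
  expect_false(anyDuplicated(tested) > 0)

  # 70-30 arithmetic on the 16 non-test groups
  fs <- make_fold_split(folds, 1, hoa, cfg, seed = 9)
  expect_length(fs$trn_pd, 11L)  # round-half-up of 0.7 * 16
  expect_length(fs$val_pd, 5L)
  expect_error(make_fold_split(folds, 6, hoa, cfg), "outside")
})

test_that("segment-level leakage is impossible across full splits", {
  spec <- cohort_spec(n_pd = 12, n_hoa = 4, retest_fraction = 0.5,
                      tasks = c("FT", "HM"), duration = 10, seed = 17)
  segs <- preprocess_cohort(generate_cohort(spec))
  splits <- make_splits(segs, split_config(K = 3, seed = 2))
  for (fs in splits) {
    tst_ids <- segs$meta$segment_id[split_segment_idx(segs, fs, "tst_pd")]
    other <- unlist(lapply(c("trn_pd", "val_pd", "trn_hoa", "val_hoa"),
                           function(r) segs$meta$segment_id[
                             split_segment_idx(segs, fs, r)]))
    expect_length(intersect(tst_ids, other), 0L)
    # test sets are PD-only
    expect_true(all(segs$meta$cohort[split_segment_idx(segs, fs, "tst_pd")]
                    == "PD"))
  }
  # determinism under the config seed, variation across seeds
  splits2 <- make_splits(segs, split_config(K = 3, seed = 2))
  expect_identical(splits, splits2)
  splits3 <- make_splits(segs, split_config(K = 3, seed = 99))
  expect_false(identical(splits, splits3))
})

test_that("split manifests round-trip the group roles", {
  g <- make_group_df(5, 5)
  folds <- stratified_group_kfold(g, K = 2, seed = 1)
  fs <- make_fold_split(folds, 1, split_hoa(character()), split_config(K = 2),
                        seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(fs, g, path, seed = 1)
  lines <- readLines(path)
  expect_match(lines[1], "^# fold 1 seed 1$")
  df <- read.csv(path, comment.char = "#")
  expect_setequal(df$group_id, g$group_id)
  expect_setequal(unique(df$fold_role), c("trn_pd", "val_pd", "tst_pd"))
})
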