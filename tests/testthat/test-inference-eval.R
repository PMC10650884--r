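fake_predictions <- function(p_high, group_id, truth = NULL) {
  data.frame(segment_id = sprintf("s%03d", seq_along(p_high)),
             group_id = group_id,
             truth = truth %||% rep("low", length(p_high)),
             p_high = p_high,
             predicted = ifelse(p_high >= 0.5, "high", "low"),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("segment predictions apply the 0.5-maps-to-high convention", {
  segs <- random_segment_set(n_groups = 3, segs_per_group = 2)
  m <- build_model(tiny_config(seed = 8))
  pred <- predict_segments(m, segs)
  expect_equal(nrow(pred), 6L)
  expect_identical(pred$predicted, ifelse(pred$p_high >= 0.5, "high", "low"))
  # boundary: p_high exactly 0.5 is high
  expect_identical(ifelse(0.5 >= 0.5, "high", "low"), "high")
})

test_that("max-vote takes the mode with mean-probability tie-breaks", {
  p <- fake_predictions(c(0.1, 0.2, 0.9), rep("g1", 3), rep("low", 3))
  expect_identical(maxvote(p)$predicted, "low")

  # unanimity passes through
  p <- fake_predictions(c(0.9, 0.8), rep("g1", 2), rep("high", 2))
  expect_identical(maxvote(p)$predicted, "high")

  # 1-1 tie with mean p_high = 0.6 -> high; 0.4 -> low
  p <- fake_predictions(c(0.3, 0.9), rep("g1", 2))
  expect_identical(maxvote(p)$predicted, "high")
  p <- fake_predictions(c(0.1, 0.7), rep("g1", 2))
  expect_identical(maxvote(p)$predicted, "low")

  expect_error(maxvote(fake_predictions(numeric(), character())),
               "no predictions")
})

test_that("accuracy and F1 match hand arithmetic and a confusion oracle", {
  m <- compute_metrics(c("high", "high", "low", "low"),
                       c("high", "high", "low", "low"))
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)

  # TP=2 FP=1 FN=1 -> precision = recall = 2/3 -> F1 = 2/3
  m <- compute_metrics(c("high", "high", "high", "low", "low"),
                       c("high", "high", "low", "high", "low"))
  expect_equal(m$f1, 2 / 3, tolerance = 1e-12)
  expect_equal(m$accuracy, 3 / 5)

  # all-low degenerate case: F1 = 0 by convention
  m <- compute_metrics(c("low", "low"), c("low", "low"))
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 0)

  set.seed(11)
  for (i in 1:50) {
    pred <- sample(c("low", "high"), 40, replace = TRUE)
    truth <- sample(c("low", "high"), 40, replace = TRUE)
    cm <- table(factor(pred, c("low", "high")), factor(truth, c("low", "high")))
    tp <- cm["high", "high"]; fp <- cm["high", "low"]; fn <- cm["low", "high"]
    f1_oracle <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    got <- compute_metrics(pred, truth)
    expect_equal(got$accuracy, mean(pred == truth))
    expect_equal(got$f1, f1_oracle)
  }
  expect_error(compute_metrics("high", c("high", "low")), "lengths differ")
})

test_that("test-time Gaussian noise has the stated moments and is reproducible", {
  segs <- random_segment_set(n_groups = 4, segs_per_group = 4, n_time = 100)
  spec <- noise_spec(mu = 0, sigma = 0.05, seed = 21)
  noisy <- add_gaussian_noise(segs, spec)
  delta <- noisy$windows - segs$windows
  n <- length(delta)
  expect_lt(abs(mean(delta)), 3 * 0.05 / sqrt(n))
  expect_lt(abs(sd(delta) - 0.05), 3 * 0.05 / sqrt(2 * n))
  expect_identical(add_gaussian_noise(segs, spec)$windows, noisy$windows)
  # sigma 0 is the identity; the input object is never modified
  expect_identical(add_gaussian_noise(segs, noise_spec(sigma = 0)), segs)
  expect_error(noise_spec(sigma = -1), "non-negative")
})

test_that("attribute aggregation pools model-by-fold rows correctly", {
  report <- expand.grid(fold = 1:2, variant = 1:10)
  v <- do.call(rbind, lapply(1:2, enumerate_variants))
  report <- v
  set.seed(3)
  report$mv_acc <- runif(nrow(report), 0.5, 1)
  report$seg_acc <- runif(nrow(report), 0.5, 1)

  by_train <- aggregate_by_attribute(report, "train_set")
  expect_equal(nrow(by_train), 2L)
  expect_setequal(by_train$value, c("PD", "PD_HOA"))
  pd_rows <- report[report$train_set == "PD", ]
  expect_equal(by_train$mv_acc_mean[by_train$value == "PD"],
               mean(pd_rows$mv_acc), tolerance = 1e-12)

  by_init <- aggregate_by_attribute(report, "init")
  expect_equal(nrow(by_init), 3L)
  expect_setequal(by_init$value, c("RandInit", "W_PD", "W_PD_HOA"))

  single <- report[1, ]
  warns <- capture_warnings(agg <- aggregate_by_attribute(single, "init"))
  expect_length(warns, 2L)  # both pre-trained-init groups are empty
  expect_match(warns, "omitted", all = TRUE)
  expect_equal(agg$mv_acc_sd, 0)
})
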