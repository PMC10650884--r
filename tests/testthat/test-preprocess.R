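test_that("resultant matches the elementwise magnitude and is rotation invariant", {
  samples <- list(matrix(c(1, 2, 2), 1, 3), matrix(c(0, 0, 0), 1, 3))
  attr(samples, "sampling_rate") <- 80
  res <- compute_resultant(samples)
  expect_equal(res$values[1, 1], 3)
  expect_equal(res$values[1, 2], 0)

  set.seed(4)
  n <- 200
  s1 <- matrix(rnorm(3 * n), n, 3)
  s2 <- matrix(rnorm(3 * n), n, 3)
  samples <- list(s1, s2)
  oracle <- sapply(list(s1, s2), function(m)
    sapply(seq_len(n), function(i) sqrt(sum(m[i, ]^2))))
  got <- compute_resultant(samples)$values
  expect_equal(got, oracle, tolerance = 1e-12)

  # any 3-D rotation of the axes leaves the resultant unchanged
  for (k in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    rotated <- list(s1 %*% q, s2 %*% q)
    expect_equal(compute_resultant(rotated)$values, got, tolerance = 1e-9)
  }

  bad <- list(s1, s2[-1, ])
  expect_error(compute_resultant(bad), "different lengths")
})

test_that("jerk is the fs-scaled forward difference", {
  expect_equal(as.numeric(compute_jerk(matrix(c(0, 1, 3), ncol = 1), fs = 1)),
               c(1, 2))
  expect_equal(as.numeric(compute_jerk(matrix(rep(5, 10), ncol = 1), fs = 80)),
               rep(0, 9))
  # linear ramp of slope m recovers m at any sampling rate
  m <- 0.37
  t <- seq(0, 1, by = 1 / 80)
  jerk <- compute_jerk(matrix(m * t, ncol = 1), fs = 80)
  expect_equal(as.numeric(jerk), rep(m, length(t) - 1), tolerance = 1e-10)
  expect_error(compute_jerk(matrix(1, 1, 1), fs = 80), "at least 2")
})

test_that("windowed RMS agrees with a brute-force oracle", {
  expect_equal(rms_window(rep(-3, 200), fs = 80), rep(3, 121))
  expect_equal(rms_window(rep(0, 100), fs = 80), rep(0, 21))

  set.seed(8)
  x <- rnorm(300)
  for (stride in c(1L, 7L, 80L)) {
    got <- rms_window(x, fs = 80, window = 1, stride = stride)
    w <- 80L
    starts <- seq(1L, length(x) - w + 1L, by = stride)
    oracle <- sapply(starts, function(s) sqrt(mean(x[s:(s + w - 1L)]^2)))
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_length(got, floor((length(x) - w) / stride) + 1L)
  }
  expect_error(rms_window(rnorm(10), fs = 80), "shorter than")
})

test_that("segmentation yields the closed-form window count", {
  s <- matrix(rnorm(400 * 2), 400, 2)
  expect_length(segment_sequence(s, 400L, 80L), 1L)
  expect_length(segment_sequence(matrix(rnorm(480 * 2), 480, 2), 400L, 80L),
                2L)
  expect_warning(w <- segment_sequence(matrix(rnorm(399 * 2), 399, 2),
                                       400L, 80L),
                 "skipped")
  expect_length(w, 0L)

  # property: count formula holds across random lengths and strides
  set.seed(12)
  for (i in 1:1000) {
    n <- sample(50:600, 1)
    len <- sample(20:80, 1)
    stride <- sample(1:60, 1)
    if (n < len) next
    got <- segment_sequence(matrix(0, n, 2), len, stride)
    expect_length(got, floor((n - len) / stride) + 1L)
  }
})

test_that("per-channel standardization is exact, guarded, and idempotent", {
  set.seed(3)
  w <- matrix(rnorm(800, 5, 3), 400, 2)
  z <- standardize_segment(w)
  expect_equal(colMeans(z), c(0, 0), tolerance = 1e-9)
  expect_equal(apply(z, 2, sd), c(1, 1), tolerance = 1e-9)
  expect_equal(standardize_segment(z), z, tolerance = 1e-9)

  w[, 2] <- 7  # constant channel -> zeros, never NaN
  z <- standardize_segment(w)
  expect_true(all(z[, 2] == 0))
  expect_false(anyNA(z))
})

test_that("severity binarization follows the low/high/drop rule", {
  expect_identical(binarize_severity(c(0, 1)), c("low", "low"))
  expect_identical(binarize_severity(c(3, 4)), c("high", "high"))
  expect_true(is.na(binarize_severity(2)))
  expect_error(binarize_severity(7), "0\\.\\.4")
})

test_that("recording preprocessing chains the stage length formulas", {
  spec <- cohort_spec(n_pd = 1, n_hoa = 0, retest_fraction = 0, tasks = "FT",
                      duration = 20, seed = 21)
  cohort <- generate_cohort(spec)
  rec <- cohort$recordings[[1L]]
  segs <- preprocess_recording(rec)
  n <- 20 * 80
  n_jerk <- n - 1
  n_rms <- n_jerk - 80 + 1
  expect_length(segs, floor((n_rms - 400) / 80) + 1)
  expect_true(all(vapply(segs, function(s) nrow(s$window), integer(1)) == 400L))

  # severity 2 recordings are dropped entirely
  rec2 <- rec
  rec2$severity <- 2L
  expect_length(preprocess_recording(rec2), 0L)

  # HOA recordings are all low
  rec$cohort <- "HOA"
  rec$severity <- 0L
  segs <- preprocess_recording(rec)
  expect_true(all(vapply(segs, `[[`, character(1), "label") == "low"))
})

test_that("segments never mix recordings and inherit one group id", {
  spec <- cohort_spec(n_pd = 3, n_hoa = 1, retest_fraction = 0,
                      tasks = c("FT", "HM"), duration = 10, seed = 31)
  segs <- preprocess_cohort(generate_cohort(spec))
  g <- segment_groups(segs)
  expect_true(all(table(segs$meta$group_id) == g$n_segments[
    match(names(table(segs$meta$group_id)), g$group_id)]))
  # one group_id per recording (session x task), consistent cohort/label
  per_group <- split(segs$meta, segs$meta$group_id)
  for (pg in per_group) {
    expect_length(unique(pg$label), 1L)
    expect_length(unique(pg$cohort), 1L)
  }
})
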