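test_that("severity-to-parameter maps anchor severity 0 and stay monotone", {
  p0 <- severity_to_params(0, "HOA", "FT", seed = 1)
  expect_identical(p0$tremor_amplitude, 0)
  expect_identical(p0$hesitation_rate, 0)

  # same seed = same heterogeneity draws, so monotonicity is exact
  for (task in c("FT", "PS", "LA")) {
    p1 <- severity_to_params(1, "PD", task, seed = 42)
    p4 <- severity_to_params(4, "PD", task, seed = 42)
    expect_lte(p4$amplitude, p1$amplitude)
    expect_gte(p4$tremor_amplitude, p1$tremor_amplitude)
    expect_gte(p4$decrement_rate, p1$decrement_rate)
    expect_gte(p4$hesitation_rate, p1$hesitation_rate)
    expect_gte(p4$phase_jitter_sd, p1$phase_jitter_sd)
  }

  expect_identical(severity_to_params(2, "PD", "HM", seed = 5),
                   severity_to_params(2, "PD", "HM", seed = 5))
  expect_error(severity_to_params(5, "PD"), "0\\.\\.4")
  expect_error(severity_to_params(-1, "PD"), "0\\.\\.4")
  expect_error(severity_to_params(3, "HOA"), "severity 0")
})

test_that("noise-free sinusoid simulation has the expected spectrum and length", {
  params <- movement_params(base_frequency = 2.5, amplitude = 1,
                            sensor_axis_directions = list(c(1, 0, 0),
                                                          c(0, 1, 0)))
  rec <- simulate_recording(params, duration = 10, sampling_rate = 80,
                            seed = 1)
  expect_equal(nrow(rec[[1L]]), 800L)
  expect_equal(nrow(rec[[2L]]), 800L)
  # axis-projected signal peaks at the movement frequency
  expect_equal(peak_frequency(rec[[1L]][, "ax"], 80), 2.5, tolerance = 1e-6)
  # the resultant rectifies the cosine, so its dominant line sits at 2f
  res <- sqrt(rowSums(rec[[1L]]^2))
  expect_equal(peak_frequency(res, 80), 5.0, tolerance = 1e-6)

  # 5 s at 80 Hz = exactly 400 samples per sensor
  rec5 <- simulate_recording(params, duration = 5, sampling_rate = 80)
  expect_equal(nrow(rec5[[1L]]), 400L)

  zero <- simulate_recording(movement_params(amplitude = 0), duration = 5,
                             sampling_rate = 80)
  expect_true(all(zero[[1L]] == 0) && all(zero[[2L]] == 0))

  expect_error(simulate_recording(params, duration = -1), "positive")
  expect_error(simulate_recording(params, duration = 2, sampling_rate = 80),
               "400")
})

test_that("cohort generation is deterministic and matches the requested shape", {
  spec <- cohort_spec(n_pd = 4, n_hoa = 2, retest_fraction = 0.5,
                      tasks = c("FT", "HM"), duration = 5, seed = 3)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$recordings[[1L]]$samples, c2$recordings[[1L]]$samples)

  # every session yields one recording per task; HOA severities are all 0
  m <- c1$manifest
  expect_true(all(table(m$session_id) == 2L))
  expect_true(all(m$severity[m$cohort == "HOA"] == 0L))
  expect_true(all(m$severity %in% 0:4))

  # no HOA participants -> PD-only cohort
  pd_only <- generate_cohort(cohort_spec(n_pd = 2, n_hoa = 0, tasks = "FT",
                                         duration = 5, seed = 1))
  expect_true(all(pd_only$manifest$cohort == "PD"))

  expect_error(cohort_spec(tasks = character()), "at least one task")
  expect_error(cohort_spec(severity_distribution = c(1, 1, 0, 0, 0)),
               "summing to 1")
})

test_that("default retest fraction reproduces the study's session count in expectation", {
  spec <- cohort_spec()
  n_participants <- spec$n_pd + spec$n_hoa
  expected_sessions <- n_participants * (1 + spec$retest_fraction)
  expect_equal(expected_sessions, 47, tolerance = 0.05)
})

test_that("recordings round-trip through the delimited-text format", {
  spec <- cohort_spec(n_pd = 1, n_hoa = 1, retest_fraction = 0, tasks = "PS",
                      duration = 5, seed = 9)
  cohort <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort_csv(cohort, dir)
  back <- read_cohort_csv(dir)
  expect_setequal(names(back$recordings), names(cohort$recordings))
  for (id in names(cohort$recordings)) {
    expect_equal(back$recordings[[id]]$samples[[1L]],
                 cohort$recordings[[id]]$samples[[1L]], tolerance = 1e-12)
    expect_identical(back$recordings[[id]]$severity,
                     cohort$recordings[[id]]$severity)
  }
})

test_that("severity separates raw movement amplitude by more than one SD", {
  set.seed(101)
  amp_of <- function(severity) {
    params <- severity_to_params(severity, "PD", "PS")
    rec <- simulate_recording(params, duration = 10, sampling_rate = 80)
    mean(sapply(1:2, function(s) sd(sqrt(rowSums(rec[[s]]^2)))))
  }
  low <- sapply(rep(c(0, 1), 30), amp_of)   # 60 low-severity recordings
  high <- sapply(rep(c(3, 4), 30), amp_of)  # 60 high-severity recordings
  pooled_sd <- sqrt((var(low) + var(high)) / 2)
  d <- abs(mean(low) - mean(high)) / pooled_sd
  expect_gt(d, 1)
})

test_that("high severity injects a 4-6 Hz spectral peak absent at severity 0", {
  set.seed(77)
  frac <- function(severity) {
    params <- severity_to_params(severity, "PD", "PS")
    rec <- simulate_recording(params, duration = 10, sampling_rate = 80)
    band_power_fraction(sqrt(rowSums(rec[[1L]]^2)), 80, 4, 6)
  }
  f0 <- replicate(10, frac(0))
  f3 <- replicate(10, frac(3))
  f4 <- replicate(10, frac(4))
  expect_gt(mean(f3), 5 * mean(f0))
  expect_gt(mean(f4), 5 * mean(f0))
})
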