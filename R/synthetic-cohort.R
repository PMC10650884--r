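## Synthetic two-sensor accelerometer cohort -----------------------------------
##
## The generator emulates the statistical structure of repetitive-movement
## recordings from a PD + healthy-older-adult wearable study: quasi-periodic
## limb movement whose amplitude, amplitude decrement, regularity, hesitation
## rate and 4-6 Hz tremor content vary monotonically with MDS-UPDRS severity,
## recorded by two phase-locked sensors with independent axis orientations,
## gains and additive noise.

## Severity anchors (severity 0 -> severity 4), shared across tasks; movement
## frequency is task-specific. Values are in g-units / Hz / events-per-second.
.sev_anchor0 <- list(amplitude = 1.0, decrement_rate = 0.00,
                     tremor_amplitude = 0.0, hesitation_rate = 0.0,
                     phase_jitter_sd = 0.02, freq_scale = 1.0)
.sev_anchor4 <- list(amplitude = 0.30, decrement_rate = 0.08,
                     tremor_amplitude = 0.35, hesitation_rate = 0.50,
                     phase_jitter_sd = 0.50, freq_scale = 0.70)

## Task movement rates (Hz). Chosen so the 2f rectification harmonic of the
## resultant stays clear of the 4-6 Hz tremor band for every task.
.task_freq <- c(FT = 3.2, HM = 1.9, PS = 1.6, TT = 1.8, LA = 1.7)

#' Cohort specification for the synthetic-recording generator
#'
#' Defaults emulate the reference study population: 20 PD participants,
#' 8 healthy older adults (HOA), a 19/28 retest fraction (so the expected
#' session total is ~48), all five MDS-UPDRS repetitive-movement tasks, and
#' 80 Hz two-sensor recordings.
#'
#' @param n_pd,n_hoa participant counts (non-negative integers).
#' @param retest_fraction probability in `[0,1]` that a participant
#'   contributes a second (retest) session.
#' @param tasks character subset of `c("FT","HM","PS","TT","LA")`.
#' @param severity_distribution probability vector over severities 0..4 used
#'   to draw each PD recording's label.
#' @param sampling_rate sampling rate in Hz.
#' @param duration recording duration in seconds.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pd = 20L, n_hoa = 8L, retest_fraction = 19 / 28,
                        tasks = TASKS,
                        severity_distribution = c(0.20, 0.25, 0.10, 0.25, 0.20),
                        sampling_rate = 80, duration = 20, seed = 1L) {
  if (length(tasks) == 0L) stopf("`tasks` must contain at least one task")
  if (!all(tasks %in% TASKS))
    stopf("unknown task(s): %s", paste(setdiff(tasks, TASKS), collapse = ", "))
  if (n_pd < 0L || n_hoa < 0L) stopf("participant counts must be >= 0")
  if (retest_fraction < 0 || retest_fraction > 1)
    stopf("`retest_fraction` must lie in [0, 1]")
  if (length(severity_distribution) != 5L || any(severity_distribution < 0) ||
      abs(sum(severity_distribution) - 1) > 1e-8)
    stopf("`severity_distribution` must be 5 non-negative values summing to 1")
  if (sampling_rate <= 0) stopf("`sampling_rate` must be positive")
  if (duration <= 0) stopf("`duration` must be positive")
  structure(list(n_pd = as.integer(n_pd), n_hoa = as.integer(n_hoa),
                 retest_fraction = retest_fraction, tasks = tasks,
                 severity_distribution = severity_distribution,
                 sampling_rate = sampling_rate, duration = duration,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

random_unit_vector <- function() {
  v <- rnorm(3L)
  v / sqrt(sum(v^2))
}

#' Map an MDS-UPDRS severity score to movement-simulation parameters
#'
#' Parameters are linear interpolations between a severity-0 and a severity-4
#' anchor, scaled by multiplicative log-normal participant heterogeneity drawn
#' from the current RNG stream (or `seed`). The maps are monotone in severity
#' under a common RNG state: amplitude is non-increasing; decrement rate,
#' tremor amplitude, hesitation rate and phase jitter are non-decreasing.
#' Severity 0 has exactly zero tremor and zero hesitations.
#'
#' @param severity integer 0..4.
#' @param cohort `"PD"` or `"HOA"`; HOA implies severity 0.
#' @param task task id (`"FT","HM","PS","TT","LA"`); sets the base frequency.
#' @param seed optional seed for the heterogeneity draws.
#' @return A `movement_params` list.
#' @export
severity_to_params <- function(severity, cohort = c("PD", "HOA"), task = "FT",
                               seed = NULL) {
  cohort <- match.arg(cohort)
  if (!is.numeric(severity) || length(severity) != 1L ||
      severity != round(severity) || severity < 0 || severity > 4)
    stopf("`severity` must be an integer in 0..4, got %s", format(severity))
  if (cohort == "HOA" && severity != 0)
    stopf("HOA recordings must have severity 0")
  if (!task %in% TASKS) stopf("unknown task '%s'", task)
  with_seed(seed, {
    w <- severity / 4
    lerp <- function(field) {
      (1 - w) * .sev_anchor0[[field]] + w * .sev_anchor4[[field]]
    }
    ## participant heterogeneity: one multiplier per parameter family,
    ## severity-independent so monotonicity survives under a shared RNG state
    het <- rlnorm(3L, meanlog = 0, sdlog = 0.15)
    params <- list(
      base_frequency    = .task_freq[[task]] * lerp("freq_scale") *
                            rlnorm(1L, 0, 0.05),
      amplitude         = lerp("amplitude") * het[1L],
      decrement_rate    = lerp("decrement_rate") * het[2L],
      tremor_frequency  = runif(1L, 4, 6),
      tremor_amplitude  = lerp("tremor_amplitude") * het[3L],
      ## rest tremor waxes and wanes slowly; the modulation rate is a
      ## participant trait, the depth a fixed fraction of the tremor
      tremor_mod_freq   = runif(1L, 0.2, 0.5),
      tremor_mod_depth  = 0.6,
      hesitation_rate   = lerp("hesitation_rate"),
      phase_jitter_sd   = lerp("phase_jitter_sd"),
      noise_sd          = 0.02,
      sensor_axis_directions = list(random_unit_vector(), random_unit_vector()),
      sensor_gains      = c(1, rlnorm(1L, 0, 0.10))
    )
    structure(params, class = "movement_params")
  })
}

#' Construct movement parameters directly
#'
#' Low-level constructor used by tests and custom simulations;
#' [severity_to_params()] is the severity-driven front end.
#'
#' @param base_frequency movement rate, Hz.
#' @param amplitude movement amplitude, g-units.
#' @param decrement_rate exponential amplitude decay, 1/s.
#' @param tremor_frequency tremor rate in Hz (conventionally 4-6).
#' @param tremor_amplitude tremor amplitude, g-units.
#' @param tremor_mod_freq slow waxing-waning rate of the tremor envelope, Hz.
#' @param tremor_mod_depth modulation depth of the tremor envelope in `[0,1]`
#'   (0 = constant-amplitude tremor).
#' @param hesitation_rate Poisson rate of transient pauses, events/s.
#' @param phase_jitter_sd random-walk phase jitter, radians.
#' @param noise_sd additive Gaussian sensor noise, g-units per axis.
#' @param sensor_axis_directions list of two unit 3-vectors.
#' @param sensor_gains two positive gains.
#' @return A `movement_params` list.
#' @export
movement_params <- function(base_frequency = 2, amplitude = 1,
                            decrement_rate = 0, tremor_frequency = 5,
                            tremor_amplitude = 0, tremor_mod_freq = 0,
                            tremor_mod_depth = 0, hesitation_rate = 0,
                            phase_jitter_sd = 0, noise_sd = 0,
                            sensor_axis_directions = list(c(1, 0, 0), c(0, 1, 0)),
                            sensor_gains = c(1, 1)) {
  vals <- c(base_frequency, amplitude, decrement_rate, tremor_frequency,
            tremor_amplitude, tremor_mod_freq, hesitation_rate,
            phase_jitter_sd, noise_sd)
  if (any(vals < 0)) stopf("rates and amplitudes must be non-negative")
  if (tremor_mod_depth < 0 || tremor_mod_depth > 1)
    stopf("`tremor_mod_depth` must lie in [0, 1]")
  for (v in sensor_axis_directions)
    if (abs(sum(v^2) - 1) > 1e-6) stopf("axis directions must be unit vectors")
  if (any(sensor_gains <= 0)) stopf("sensor gains must be positive")
  structure(list(base_frequency = base_frequency, amplitude = amplitude,
                 decrement_rate = decrement_rate,
                 tremor_frequency = tremor_frequency,
                 tremor_amplitude = tremor_amplitude,
                 tremor_mod_freq = tremor_mod_freq,
                 tremor_mod_depth = tremor_mod_depth,
                 hesitation_rate = hesitation_rate,
                 phase_jitter_sd = phase_jitter_sd, noise_sd = noise_sd,
                 sensor_axis_directions = sensor_axis_directions,
                 sensor_gains = sensor_gains),
            class = "movement_params")
}

## Smooth hesitation gate: Poisson-arriving cosine-tapered gain dips to zero,
## each lasting 0.3-1.0 s, so the jerk of the gated signal stays bounded.
hesitation_gate <- function(t, rate, duration) {
  g <- rep(1, length(t))
  if (rate <= 0) return(g)
  n_events <- stats::rpois(1L, rate * duration)
  if (n_events == 0L) return(g)
  starts <- runif(n_events, 0, duration)
  lens <- runif(n_events, 0.3, 1.0)
  for (e in seq_len(n_events)) {
    inside <- t >= starts[e] & t <= starts[e] + lens[e]
    ## raised-cosine dip: 1 at the edges, 0 at the centre of the pause
    phase <- (t[inside] - starts[e]) / lens[e]
    g[inside] <- pmin(g[inside], 0.5 + 0.5 * cos(2 * pi * (phase - 0.5)))
  }
  g
}

#' Simulate one two-sensor tri-axial recording
#'
#' Each sensor observes the movement signal
#' `amplitude * exp(-decrement_rate t) * cos(2 pi f t + jitter(t))`, gated by
#' Poisson-arriving cosine-tapered hesitation pauses, plus a tremor sinusoid,
#' projected on the sensor's axis direction and scaled by its gain, with
#' i.i.d. Gaussian noise per axis. Both sensors share the movement phase.
#'
#' @param params a `movement_params` object.
#' @param duration seconds; `duration * sampling_rate` must be at least 400
#'   so at least one downstream segment survives.
#' @param sampling_rate Hz.
#' @param seed optional seed.
#' @return A list of two `n x 3` matrices (columns ax, ay, az), class
#'   `sensor_samples`, with attributes `sampling_rate` and `duration`.
#' @export
simulate_recording <- function(params, duration = 20, sampling_rate = 80,
                               seed = NULL) {
  if (duration <= 0 || sampling_rate <= 0)
    stopf("`duration` and `sampling_rate` must be positive")
  n <- round(sampling_rate * duration)
  if (n < 400)
    stopf("duration x sampling_rate = %d < 400: too short to segment", n)
  with_seed(seed, {
    t <- (seq_len(n) - 1L) / sampling_rate
    jitter <- cumsum(rnorm(n, 0, params$phase_jitter_sd / sqrt(sampling_rate)))
    gate <- hesitation_gate(t, params$hesitation_rate, duration)
    movement <- params$amplitude * exp(-params$decrement_rate * t) *
      cos(2 * pi * params$base_frequency * t + jitter) * gate
    mod_depth <- params$tremor_mod_depth %||% 0
    mod_freq <- params$tremor_mod_freq %||% 0
    tremor_env <- if (mod_depth > 0 && mod_freq > 0) {
      (1 - mod_depth) + mod_depth *
        (0.5 + 0.5 * sin(2 * pi * mod_freq * t + runif(1L, 0, 2 * pi)))
    } else 1
    tremor <- params$tremor_amplitude * tremor_env *
      sin(2 * pi * params$tremor_frequency * t)
    core <- movement + tremor
    sensors <- lapply(1:2, function(s) {
      axis <- params$sensor_axis_directions[[s]]
      sig <- outer(params$sensor_gains[s] * core, axis)
      if (params$noise_sd > 0)
        sig <- sig + matrix(rnorm(3L * n, 0, params$noise_sd), n, 3L)
      colnames(sig) <- c("ax", "ay", "az")
      sig
    })
    structure(sensors, class = "sensor_samples",
              sampling_rate = sampling_rate, duration = duration)
  })
}

new_raw_recording <- function(participant_id, session_id, cohort, task,
                              severity, sampling_rate, samples, params = NULL) {
  stopifnot(nrow(samples[[1L]]) == nrow(samples[[2L]]))
  structure(list(participant_id = participant_id, session_id = session_id,
                 cohort = cohort, task = task, severity = as.integer(severity),
                 sampling_rate = sampling_rate, samples = samples,
                 ground_truth_params = params),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s/%s %s task=%s severity=%d (%d samples @ %g Hz)\n",
              x$participant_id, x$session_id, x$cohort, x$task, x$severity,
              nrow(x$samples[[1L]]), x$sampling_rate))
  invisible(x)
}

#' Generate a synthetic cohort of recordings
#'
#' Every participant contributes one session, plus a retest session with
#' probability `retest_fraction`. Each session yields one recording per
#' requested task; PD severities are drawn once per participant-session-task
#' from `severity_distribution`, HOA severities are always 0. The cohort is
#' byte-reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `cohort`: list with `recordings` (list of
#'   `raw_recording`) and `manifest` (one data.frame row per recording).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    recs <- list()
    rows <- list()
    participants <- c(
      if (spec$n_pd > 0L) sprintf("PD%02d", seq_len(spec$n_pd)),
      if (spec$n_hoa > 0L) sprintf("HOA%02d", seq_len(spec$n_hoa)))
    cohorts <- c(rep("PD", spec$n_pd), rep("HOA", spec$n_hoa))
    for (p in seq_along(participants)) {
      n_sessions <- 1L + rbinom(1L, 1L, spec$retest_fraction)
      for (s in seq_len(n_sessions)) {
        session_id <- sprintf("%s_S%d", participants[p], s)
        for (task in spec$tasks) {
          severity <- if (cohorts[p] == "PD")
            sample(0:4, 1L, prob = spec$severity_distribution) else 0L
          params <- severity_to_params(severity, cohorts[p], task)
          samples <- simulate_recording(params, spec$duration,
                                        spec$sampling_rate)
          rec_id <- sprintf("%s_%s", session_id, task)
          recs[[rec_id]] <- new_raw_recording(
            participants[p], session_id, cohorts[p], task, severity,
            spec$sampling_rate, samples, params)
          rows[[rec_id]] <- data.frame(
            recording_id = rec_id, participant_id = participants[p],
            session_id = session_id, cohort = cohorts[p], task = task,
            severity = severity, stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(recordings = recs,
                   manifest = do.call(rbind, c(rows, make.row.names = FALSE)),
                   spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<cohort> %d recordings: %d PD / %d HOA sessions, tasks %s\n",
              nrow(m), length(unique(m$session_id[m$cohort == "PD"])),
              length(unique(m$session_id[m$cohort == "HOA"])),
              paste(unique(m$task), collapse = ",")))
  invisible(x)
}

## Delimited-text interchange ---------------------------------------------------

#' Write / read one recording as delimited text
#'
#' Long format with columns `time_s, sensor_id, ax, ay, az`; the manifest CSV
#' written by [write_cohort_csv()] carries the metadata. Real recordings
#' converted to this layout flow through the pipeline unchanged.
#'
#' @param recording a `raw_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  n <- nrow(recording$samples[[1L]])
  t <- (seq_len(n) - 1L) / recording$sampling_rate
  df <- do.call(rbind, lapply(1:2, function(s) {
    data.frame(time_s = t, sensor_id = s,
               ax = recording$samples[[s]][, 1L],
               ay = recording$samples[[s]][, 2L],
               az = recording$samples[[s]][, 3L])
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param metadata named list or one-row data.frame with participant_id,
#'   session_id, cohort, task, severity, sampling_rate.
#' @export
read_recording_csv <- function(path, metadata) {
  df <- read.csv(path)
  need <- c("time_s", "sensor_id", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stopf("recording CSV must have columns %s", paste(need, collapse = ", "))
  samples <- lapply(1:2, function(s) {
    sub <- df[df$sensor_id == s, , drop = FALSE]
    sub <- sub[order(sub$time_s), , drop = FALSE]
    m <- as.matrix(sub[, c("ax", "ay", "az")])
    colnames(m) <- c("ax", "ay", "az")
    rownames(m) <- NULL
    m
  })
  if (nrow(samples[[1L]]) != nrow(samples[[2L]]))
    stopf("sensors 1 and 2 have different lengths in %s", path)
  new_raw_recording(metadata$participant_id, metadata$session_id,
                    metadata$cohort, metadata$task, metadata$severity,
                    metadata$sampling_rate, samples)
}

#' Write / read a cohort as a directory of CSV recordings plus a manifest
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest path (write) or a `cohort` (read).
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cohort$manifest
  m$file <- file.path(dir, paste0(m$recording_id, ".csv"))
  m$sampling_rate <- vapply(cohort$recordings[m$recording_id],
                            function(r) r$sampling_rate, numeric(1))
  for (i in seq_len(nrow(m)))
    write_recording_csv(cohort$recordings[[m$recording_id[i]]], m$file[i])
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(m, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) stopf("no manifest.csv under %s", dir)
  m <- read.csv(manifest_path, stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(m)), function(i)
    read_recording_csv(m$file[i], as.list(m[i, ])))
  names(recs) <- m$recording_id
  structure(list(recordings = recs,
                 manifest = m[, c("recording_id", "participant_id",
                                  "session_id", "cohort", "task", "severity")],
                 spec = NULL),
            class = "cohort")
}
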