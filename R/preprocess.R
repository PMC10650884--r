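## Preprocessing: resultant -> jerk -> windowed RMS -> segmentation ------------

#' Preprocessing configuration
#'
#' @param segment_length window length in samples (400 = 5 s at 80 Hz).
#' @param segment_stride hop between window starts, samples.
#' @param rms_window RMS window in seconds.
#' @param rms_stride RMS hop in samples; 1 keeps the series dense so 400
#'   samples still span 5 s, `round(rms_window * fs)` gives block-wise RMS.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(segment_length = 400L, segment_stride = 80L,
                              rms_window = 1, rms_stride = 1L) {
  if (segment_length < 1L || segment_stride < 1L || rms_stride < 1L)
    stopf("lengths and strides must be positive")
  if (rms_window <= 0) stopf("`rms_window` must be positive")
  structure(list(segment_length = as.integer(segment_length),
                 segment_stride = as.integer(segment_stride),
                 rms_window = rms_window, rms_stride = as.integer(rms_stride)),
            class = "preprocess_config")
}

#' Resultant (magnitude) acceleration per sensor
#'
#' `A[i, j] = sqrt(ax^2 + ay^2 + az^2)` for sensor i at time step j; the
#' Euclidean magnitude is invariant to sensor orientation.
#'
#' @param recording a `raw_recording` (or bare `sensor_samples`).
#' @return List with `values` (N x 2 matrix, one column per sensor) and
#'   `sampling_rate`, class `resultant_series`.
#' @export
compute_resultant <- function(recording) {
  samples <- if (inherits(recording, "raw_recording")) recording$samples
             else recording
  fs <- if (inherits(recording, "raw_recording")) recording$sampling_rate
        else attr(recording, "sampling_rate")
  if (nrow(samples[[1L]]) != nrow(samples[[2L]]))
    stopf("sensor streams have different lengths (%d vs %d)",
          nrow(samples[[1L]]), nrow(samples[[2L]]))
  n <- nrow(samples[[1L]])
  values <- matrix(0, n, length(samples))
  for (s in seq_along(samples)) values[, s] <- sqrt(rowSums(samples[[s]]^2))
  structure(list(values = values, sampling_rate = fs),
            class = "resultant_series")
}

#' Jerk: first difference of the resultant, scaled to physical units
#'
#' Forward difference `J[j] = (A[j+1] - A[j]) * fs` (units 1/s); the scale is
#' irrelevant after per-segment standardization but keeps the channel
#' physically interpretable. Output is one sample shorter than the input.
#'
#' @param resultant a `resultant_series` (or plain matrix with an `fs`).
#' @param fs sampling rate, used when `resultant` is a bare matrix.
#' @return N-1 x n_sensor matrix.
#' @export
compute_jerk <- function(resultant, fs = NULL) {
  if (inherits(resultant, "resultant_series")) {
    x <- resultant$values
    fs <- resultant$sampling_rate
  } else x <- as.matrix(resultant)
  if (nrow(x) < 2L) stopf("need at least 2 samples to differentiate")
  diff(x) * fs
}

#' Sliding root-mean-square over a trailing window
#'
#' `out[k] = sqrt(mean(x^2))` over `round(window * fs)` consecutive samples,
#' advancing by `stride`; output length `floor((N - w) / stride) + 1`.
#'
#' @param x numeric vector or matrix (columns processed independently).
#' @param fs sampling rate, Hz.
#' @param window window length in seconds (default 1).
#' @param stride hop in samples (default 1, dense).
#' @return Vector or matrix of windowed RMS values.
#' @export
rms_window <- function(x, fs, window = 1, stride = 1L) {
  if (is.matrix(x))
    return(apply(x, 2L, rms_window, fs = fs, window = window, stride = stride))
  w <- round(window * fs)
  if (w < 1L) stopf("`window` x `fs` must round to >= 1 sample")
  n <- length(x)
  if (n < w)
    stopf("series of length %d is shorter than one %d-sample window", n, w)
  ## cumulative sum of squares makes the dense case O(N)
  cs <- c(0, cumsum(x^2))
  starts <- seq(1L, n - w + 1L, by = stride)
  sqrt((cs[starts + w] - cs[starts]) / w)
}

#' Binarize an MDS-UPDRS severity score
#'
#' Scores 0/1 map to `"low"`, 3/4 to `"high"`; severity 2 is dropped from all
#' datasets (returns `NA`).
#'
#' @param severity integer scalar or vector in 0..4.
#' @return Character vector of `"low"`, `"high"`, or `NA` (dropped).
#' @export
binarize_severity <- function(severity) {
  if (any(!is.finite(severity)) || any(severity != round(severity)) ||
      any(severity < 0) || any(severity > 4))
    stopf("severity must be integers in 0..4")
  out <- rep(NA_character_, length(severity))
  out[severity <= 1] <- "low"
  out[severity >= 3] <- "high"
  out
}

#' Cut a processed sequence into overlapping fixed-length windows
#'
#' Windows start at 0, `stride`, `2 stride`, ...; a sequence shorter than one
#' window yields zero windows with a warning rather than an error, so short
#' recordings cannot abort a cohort run.
#'
#' @param s N' x C numeric matrix (the processed channels).
#' @param length window length in samples.
#' @param stride hop between window starts.
#' @return List of `length x C` matrices (possibly empty).
#' @export
segment_sequence <- function(s, length = 400L, stride = 80L) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (n < length) {
    warning(sprintf("sequence of length %d < segment length %d: skipped",
                    n, length), call. = FALSE)
    return(list())
  }
  starts <- seq(1L, n - length + 1L, by = stride)
  lapply(starts, function(i) s[i:(i + length - 1L), , drop = FALSE])
}

#' Standardize a segment per channel
#'
#' Each channel is centred on its within-window mean and scaled by its
#' within-window standard deviation; channels with sd below `eps` become all
#' zeros (never NaN).
#'
#' @param window numeric matrix (time x channels).
#' @param eps degenerate-channel guard.
#' @return Matrix of the same shape with per-channel mean ~0, sd ~1.
#' @export
standardize_segment <- function(window, eps = 1e-8) {
  window <- as.matrix(window)
  mu <- colMeans(window)
  sdv <- apply(window, 2L, sd)
  out <- sweep(window, 2L, mu, "-")
  for (c in seq_len(ncol(out))) {
    if (sdv[c] < eps) out[, c] <- 0 else out[, c] <- out[, c] / sdv[c]
  }
  out
}

#' Preprocess one recording into labeled standardized segments
#'
#' Applies, in order: resultant magnitude per sensor, jerk, trailing 1-s RMS,
#' overlapping 400-sample segmentation, per-channel standardization, and
#' severity binarization. Severity-2 recordings yield no segments.
#'
#' @param recording a `raw_recording`.
#' @param config a [preprocess_config()].
#' @return List of segments; each is a list with `window` (400 x 2), `label`,
#'   `group_id`, `cohort`, `task`, `severity`.
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  label <- binarize_severity(recording$severity)
  if (is.na(label)) return(list())
  res <- compute_resultant(recording)
  jerk <- compute_jerk(res)
  s <- rms_window(jerk, fs = res$sampling_rate, window = config$rms_window,
                  stride = config$rms_stride)
  windows <- segment_sequence(s, config$segment_length, config$segment_stride)
  group_id <- sprintf("%s_%s", recording$session_id, recording$task)
  lapply(seq_along(windows), function(k) {
    list(window = standardize_segment(windows[[k]]),
         label = label, group_id = group_id,
         segment_id = sprintf("%s_seg%03d", group_id, k),
         cohort = recording$cohort, task = recording$task,
         severity = recording$severity)
  })
}

#' Preprocess a cohort into a segment set
#'
#' @param cohort a `cohort`.
#' @param config a [preprocess_config()].
#' @param tasks optional task filter; `NULL` pools all tasks (aggregate mode).
#' @return A `segment_set`: list with `windows` (T x 2 x n array) and `meta`
#'   (data.frame with segment_id, group_id, participant_id, cohort, task,
#'   severity, label).
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config(),
                              tasks = NULL) {
  recs <- cohort$recordings
  if (!is.null(tasks))
    recs <- Filter(function(r) r$task %in% tasks, recs)
  segs <- list()
  for (r in recs) segs <- c(segs, preprocess_recording(r, config))
  if (length(segs) == 0L)
    return(new_segment_set(array(0, c(config$segment_length, 2L, 0L)),
                           empty_segment_meta()))
  windows <- array(0, c(nrow(segs[[1L]]$window), ncol(segs[[1L]]$window),
                        length(segs)))
  for (i in seq_along(segs)) windows[, , i] <- segs[[i]]$window
  part <- vapply(segs, function(s) sub("_S[0-9]+$", "",
                                       sub("_[A-Z]+$", "", s$group_id)),
                 character(1))
  meta <- data.frame(
    segment_id = vapply(segs, `[[`, character(1), "segment_id"),
    group_id = vapply(segs, `[[`, character(1), "group_id"),
    participant_id = part,
    cohort = vapply(segs, `[[`, character(1), "cohort"),
    task = vapply(segs, `[[`, character(1), "task"),
    severity = vapply(segs, `[[`, integer(1), "severity"),
    label = vapply(segs, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  new_segment_set(windows, meta)
}

empty_segment_meta <- function() {
  data.frame(segment_id = character(), group_id = character(),
             participant_id = character(), cohort = character(),
             task = character(), severity = integer(), label = character(),
             stringsAsFactors = FALSE)
}

new_segment_set <- function(windows, meta) {
  stopifnot(dim(windows)[3L] == nrow(meta))
  structure(list(windows = windows, meta = meta), class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments (%d x %d) from %d groups: %s\n",
              dim(x$windows)[3L], dim(x$windows)[1L], dim(x$windows)[2L],
              length(unique(x$meta$group_id)),
              paste(sprintf("%s=%d", names(table(x$meta$label)),
                            as.integer(table(x$meta$label))), collapse = " ")))
  invisible(x)
}

#' Subset a segment set by index or metadata predicate
#'
#' @param x a `segment_set`.
#' @param idx integer or logical index over segments.
#' @return A `segment_set` with the selected segments.
#' @export
subset_segments <- function(x, idx) {
  new_segment_set(x$windows[, , idx, drop = FALSE],
                  x$meta[idx, , drop = FALSE])
}

#' Write a segment-set index as CSV
#'
#' @param x a `segment_set`.
#' @param path output CSV path.
#' @export
write_segment_index <- function(x, path) {
  write.csv(x$meta, path, row.names = FALSE)
  invisible(path)
}
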