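# Shared fixtures: everything is generated in code at test time.

# Tiny model config used wherever architecture mechanics (not accuracy) are
# under test.
tiny_config <- function(head = "classification", n_modules = 2L,
                        filters = 2L, kernel = 9L, seed = 7L) {
  model_config(in_channels = 2L, n_modules = n_modules, base_kernel = kernel,
               filters = filters, head = head, seed = seed)
}

# Random standardized segment set with group structure: n_groups recordings,
# segs_per_group segments each, labels alternating low/high by group.
random_segment_set <- function(n_groups = 6L, segs_per_group = 3L,
                               n_time = 50L, cohort = "PD", seed = 1L) {
  withr_seed <- function(expr) {
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    old <- .Random.seed
    on.exit(.Random.seed <<- old)
    set.seed(seed)
    expr
  }
  withr_seed({
    n <- n_groups * segs_per_group
    windows <- array(rnorm(n_time * 2L * n), c(n_time, 2L, n))
    for (i in seq_len(n)) windows[, , i] <- standardize_segment(windows[, , i])
    gid <- rep(sprintf("G%02d", seq_len(n_groups)), each = segs_per_group)
    lab <- rep(rep(c("low", "high"), length.out = n_groups),
               each = segs_per_group)
    meta <- data.frame(
      segment_id = sprintf("%s_seg%02d", gid, sequence(rep(segs_per_group,
                                                           n_groups))),
      group_id = gid,
      participant_id = sub("G", "P", gid),
      cohort = cohort, task = "FT",
      severity = ifelse(lab == "high", 3L, 0L),
      label = lab, stringsAsFactors = FALSE)
    bradynet:::new_segment_set(windows, meta)
  })
}

# Segment set whose labels are linearly separable from window shape: low =
# one slow sine cycle, high = fast sine, plus small noise, standardized.
separable_segment_set <- function(n_groups = 10L, segs_per_group = 4L,
                                  n_time = 50L, seed = 2L) {
  set.seed(seed)
  n <- n_groups * segs_per_group
  lab <- rep(rep(c("low", "high"), length.out = n_groups),
             each = segs_per_group)
  windows <- array(0, c(n_time, 2L, n))
  t <- seq_len(n_time) / n_time
  for (i in seq_len(n)) {
    f <- if (lab[i] == "high") 8 else 2
    for (ch in 1:2)
      windows[, ch, i] <- standardize_segment(
        matrix(sin(2 * pi * f * t + runif(1, 0, 2 * pi)) + rnorm(n_time, 0, .1),
               ncol = 1))
  }
  gid <- rep(sprintf("G%02d", seq_len(n_groups)), each = segs_per_group)
  meta <- data.frame(
    segment_id = sprintf("%s_s%02d", gid, sequence(rep(segs_per_group,
                                                       n_groups))),
    group_id = gid, participant_id = sub("G", "P", gid),
    cohort = "PD", task = "FT",
    severity = ifelse(lab == "high", 3L, 0L), label = lab,
    stringsAsFactors = FALSE)
  bradynet:::new_segment_set(windows, meta)
}

# Brute-force periodogram: |DFT|^2 at positive frequencies, returns the
# frequency (Hz) of the maximum-power bin of the demeaned signal.
peak_frequency <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1L) * fs / n
  keep <- freqs > 0 & freqs <= fs / 2
  freqs[keep][which.max(p[keep])]
}

# Fraction of spectral power of the demeaned signal inside [lo, hi] Hz.
band_power_fraction <- function(x, fs, lo, hi) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1L) * fs / n
  keep <- freqs > 0 & freqs <= fs / 2
  sum(p[keep][freqs[keep] >= lo & freqs[keep] <= hi]) / sum(p[keep])
}
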