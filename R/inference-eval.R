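## Segmented and max-vote inference, metrics, noise probing --------------------

#' Segment-level predictions
#'
#' One probability of the `"high"` class per segment; the decision threshold
#' is 0.5, with `p_high = 0.5` mapping to `"high"` (documented boundary
#' convention).
#'
#' @param model a classification-headed `xt_model`.
#' @param segments a `segment_set`.
#' @return data.frame: segment_id, group_id, truth, p_high, predicted.
#' @export
predict_segments <- function(model, segments) {
  p <- model_forward(model, segments)
  data.frame(segment_id = segments$meta$segment_id,
             group_id = segments$meta$group_id,
             truth = segments$meta$label,
             p_high = p,
             predicted = ifelse(p >= 0.5, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Max-vote aggregation of segment predictions per group
#'
#' Each recording-level group is labeled with the mode of its segments'
#' predicted labels; ties (possible with even segment counts) are broken by
#' the group's mean `p_high` against 0.5.
#'
#' @param predictions data.frame from [predict_segments()].
#' @return data.frame: group_id, truth, n_segments, mean_p_high, predicted.
#' @export
maxvote <- function(predictions) {
  if (nrow(predictions) == 0L) stopf("no predictions to aggregate")
  out <- lapply(split(predictions, predictions$group_id), function(g) {
    n_high <- sum(g$predicted == "high")
    n_low <- nrow(g) - n_high
    mp <- mean(g$p_high)
    pred <- if (n_high > n_low) "high"
            else if (n_low > n_high) "low"
            else if (mp >= 0.5) "high" else "low"
    data.frame(group_id = g$group_id[1L],
               truth = if ("truth" %in% names(g)) g$truth[1L] else NA_character_,
               n_segments = nrow(g), mean_p_high = mp, predicted = pred,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  out[order(out$group_id), , drop = FALSE]
}

#' Accuracy and F1 of a prediction set
#'
#' Accuracy is the fraction of exact matches; F1 is the harmonic mean of
#' precision and recall with `"high"` as the positive class. When there are
#' neither positive predictions nor positive truths (so TP, FP and FN are all
#' zero), F1 is reported as 0 by convention.
#'
#' @param predicted,truth character vectors of `"low"`/`"high"`, matched
#'   element-wise.
#' @return List with `accuracy` and `f1`.
#' @export
compute_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stopf("predicted and truth lengths differ")
  if (length(predicted) == 0L) stopf("empty prediction set")
  tp <- sum(predicted == "high" & truth == "high")
  fp <- sum(predicted == "high" & truth == "low")
  fn <- sum(predicted == "low" & truth == "high")
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(accuracy = mean(predicted == truth), f1 = f1)
}

#' Test-time Gaussian noise specification
#'
#' @param mu noise mean (study value 0).
#' @param sigma noise standard deviation (study value 0.05, in standardized
#'   units since segments are stored standardized).
#' @param seed seed for reproducible perturbations.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(mu = 0, sigma = 0.05, seed = 1L) {
  if (sigma < 0) stopf("`sigma` must be non-negative")
  structure(list(mu = mu, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add i.i.d. Gaussian noise to every segment
#'
#' Noise is applied to the stored (standardized) windows; the input object is
#' untouched. `sigma = 0` returns the segments unchanged.
#'
#' @param segments a `segment_set`.
#' @param spec a [noise_spec()].
#' @return A perturbed `segment_set`.
#' @export
add_gaussian_noise <- function(segments, spec = noise_spec()) {
  if (spec$sigma == 0 && spec$mu == 0) return(segments)
  with_seed(spec$seed, {
    noisy <- segments
    noisy$windows <- segments$windows +
      array(rnorm(length(segments$windows), spec$mu, spec$sigma),
            dim(segments$windows))
    noisy
  })
}

#' Evaluate one trained variant on its fold's PD test set
#'
#' Computes segmented and max-vote accuracy/F1, with and without test-time
#' Gaussian noise. Test sets contain only PD groups.
#'
#' @param fit a [train_variant()] result.
#' @param segments the full `segment_set`.
#' @param fold_split the fold's `fold_split`.
#' @param nspec a [noise_spec()] or `NULL` to skip the noisy run.
#' @return One-row data.frame with variant attributes and metrics.
#' @export
evaluate_variant <- function(fit, segments, fold_split, nspec = noise_spec()) {
  idx <- split_segment_idx(segments, fold_split, "tst_pd")
  tst <- subset_segments(segments, idx)
  eval_one <- function(ss) {
    sp <- predict_segments(fit$model, ss)
    seg_m <- compute_metrics(sp$predicted, sp$truth)
    mv <- maxvote(sp)
    mv_m <- compute_metrics(mv$predicted, mv$truth)
    c(seg_acc = seg_m$accuracy, seg_f1 = seg_m$f1,
      mv_acc = mv_m$accuracy, mv_f1 = mv_m$f1)
  }
  clean <- eval_one(tst)
  row <- data.frame(variant_id = fit$variant$variant_id,
                    fold = fit$variant$fold,
                    train_set = fit$variant$train_set,
                    init = fit$variant$init, scheme = fit$variant$scheme,
                    seg_acc = clean[["seg_acc"]], seg_f1 = clean[["seg_f1"]],
                    mv_acc = clean[["mv_acc"]], mv_f1 = clean[["mv_f1"]],
                    stringsAsFactors = FALSE)
  if (!is.null(nspec)) {
    noisy <- eval_one(add_gaussian_noise(tst, nspec))
    row$seg_acc_noisy <- noisy[["seg_acc"]]
    row$seg_f1_noisy <- noisy[["seg_f1"]]
    row$mv_acc_noisy <- noisy[["mv_acc"]]
    row$mv_f1_noisy <- noisy[["mv_f1"]]
  }
  row
}

#' Aggregate an evaluation report by a model attribute
#'
#' Pools all matching model x fold rows and reports mean and standard
#' deviation of every metric column per attribute value (clean and noisy
#' columns side by side). Empty groups are omitted with a warning.
#'
#' @param report data.frame of [evaluate_variant()] rows.
#' @param axis `"train_set"` or `"init"`.
#' @return data.frame, one row per attribute value.
#' @export
aggregate_by_attribute <- function(report, axis = c("train_set", "init")) {
  axis <- match.arg(axis)
  metric_cols <- intersect(c("seg_acc", "seg_f1", "mv_acc", "mv_f1",
                             "seg_acc_noisy", "seg_f1_noisy",
                             "mv_acc_noisy", "mv_f1_noisy"),
                           names(report))
  levels <- if (axis == "train_set") c("PD", "PD_HOA")
            else c("RandInit", "W_PD", "W_PD_HOA")
  rows <- lapply(levels, function(v) {
    sub <- report[report[[axis]] == v, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("no models with %s = %s: omitted", axis, v),
              call. = FALSE)
      return(NULL)
    }
    out <- data.frame(axis = axis, value = v, n_models = nrow(sub),
                      stringsAsFactors = FALSE)
    for (mc in metric_cols) {
      out[[paste0(mc, "_mean")]] <- mean(sub[[mc]])
      out[[paste0(mc, "_sd")]] <- if (nrow(sub) > 1L) sd(sub[[mc]]) else 0
    }
    out
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Per-fold evaluation report for a set of trained variants
#'
#' @param fits nested list `fits[[fold]][[variant_id]]` of [train_variant()]
#'   results.
#' @param segments the full `segment_set`.
#' @param splits list of `fold_split`.
#' @param nspec a [noise_spec()] or `NULL`.
#' @return data.frame with one row per variant x fold.
#' @export
evaluation_report <- function(fits, segments, splits, nspec = noise_spec()) {
  rows <- list()
  for (i in seq_along(fits))
    for (fit in fits[[i]])
      rows[[length(rows) + 1L]] <-
        evaluate_variant(fit, segments, splits[[i]], nspec)
  do.call(rbind, c(rows, make.row.names = FALSE))
}
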