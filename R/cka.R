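## Linear centered kernel alignment --------------------------------------------

#' Linear CKA between two representation matrices
#'
#' Rows are probe inputs (the same set, in the same order, for both models);
#' columns are representation dimensions. After column-centering,
#' `CKA = ||Y'X||_F^2 / (||X'X||_F ||Y'Y||_F)`, the feature-space form of the
#' HSIC-based index, algebraically identical to the Gram-matrix form but
#' cheaper when d << n. The value lies in `[0, 1]`, is symmetric in its
#' arguments, and is invariant to orthogonal transforms and isotropic
#' scaling of either representation.
#'
#' @param X,Y numeric matrices with equal row counts (>= 2).
#' @return Scalar in `[0, 1]`.
#' @export
linear_cka <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stopf("X and Y must have the same number of rows (%d vs %d)",
          nrow(X), nrow(Y))
  if (nrow(X) < 2L) stopf("CKA is undefined for fewer than 2 rows")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  nx <- norm(crossprod(Xc), "F")
  ny <- norm(crossprod(Yc), "F")
  if (nx == 0 || ny == 0)
    stopf("CKA is undefined for an all-constant representation")
  ## averaging the two evaluation orders makes the index bit-exactly
  ## symmetric in its arguments (float summation is order-dependent)
  num <- (sum(crossprod(Yc, Xc)^2) + sum(crossprod(Xc, Yc)^2)) / 2
  num / (nx * ny)
}

#' CKA comparison of model attribute groups
#'
#' Reproduces the representation-similarity analysis: models trained with the
#' FTL scheme are excluded (leaving one model per training-set x
#' initialization cell), models are grouped along `axis`, and for every
#' cross-group pair within the same fold the representations of that fold's
#' PD test segments are extracted at `probe` and compared with linear CKA.
#' Pair values are averaged across pairs and folds.
#'
#' @param fits nested list `fits[[fold]][[variant_id]]` of [train_variant()]
#'   results (tags must carry train_set/init/scheme/fold).
#' @param segments the full `segment_set`.
#' @param splits list of `fold_split` (provides each fold's test probe set).
#' @param axis `"train_set"` or `"init"`.
#' @param probe `"first"` or `"last"`.
#' @param include_self include same-model pairs (always 1); default excludes
#'   them.
#' @return data.frame: comparison, probe, cka (mean), n_pairs.
#' @export
compare_attribute_groups <- function(fits, segments, splits,
                                     axis = c("train_set", "init"),
                                     probe = c("first", "last"),
                                     include_self = FALSE) {
  axis <- match.arg(axis)
  probe <- match.arg(probe)
  levels <- if (axis == "train_set") c("PD", "PD_HOA")
            else c("RandInit", "W_PD", "W_PD_HOA")
  pairs <- utils::combn(levels, 2L, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    vals <- numeric()
    for (i in seq_along(fits)) {
      fold_fits <- Filter(function(f) !identical(f$variant$scheme, "FTL"),
                          fits[[i]])
      ga <- Filter(function(f) f$variant[[axis]] == pr[1L], fold_fits)
      gb <- Filter(function(f) f$variant[[axis]] == pr[2L], fold_fits)
      if (length(ga) == 0L)
        stopf("no non-FTL models with %s = %s in fold %d", axis, pr[1L], i)
      if (length(gb) == 0L)
        stopf("no non-FTL models with %s = %s in fold %d", axis, pr[2L], i)
      idx <- split_segment_idx(segments, splits[[i]], "tst_pd")
      tst <- subset_segments(segments, idx)
      reps_a <- lapply(ga, function(f)
        extract_representation(f$model, tst, probe))
      reps_b <- lapply(gb, function(f)
        extract_representation(f$model, tst, probe))
      for (a in seq_along(ga))
        for (b in seq_along(gb)) {
          same_model <- identical(ga[[a]]$variant$variant_id,
                                  gb[[b]]$variant$variant_id)
          if (same_model && !include_self) next
          vals <- c(vals, linear_cka(reps_a[[a]], reps_b[[b]]))
        }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(comparison = paste(pr, collapse = "/"), probe = probe,
                 cka = mean(vals), n_pairs = length(vals),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Full CKA table over both probes and both attribute axes
#'
#' @inheritParams compare_attribute_groups
#' @return data.frame stacking [compare_attribute_groups()] results for
#'   axis in {train_set, init} x probe in {first, last}.
#' @export
cka_tables <- function(fits, segments, splits) {
  out <- list()
  for (axis in c("train_set", "init"))
    for (probe in c("first", "last")) {
      tb <- compare_attribute_groups(fits, segments, splits, axis, probe)
      tb$axis <- axis
      out[[length(out) + 1L]] <- tb
    }
  do.call(rbind, c(out, make.row.names = FALSE))
}
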