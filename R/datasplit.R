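## Grouped, stratified, leakage-free splitting ---------------------------------
##
## The unit of splitting is the group: all segments cut from one original
## recording. HOA groups get a simple 80-20 train/validation split; PD groups
## go through a stratified K-fold on their binarized labels, fold i becoming
## the test set while the remaining folds are split 70-30 into train and
## validation. Test sets are always PD-only.

#' Split configuration
#'
#' @param K number of folds (default 5).
#' @param hoa_train_fraction fraction of HOA groups used for training.
#' @param pd_train_fraction fraction of the non-test PD groups used for
#'   training (the rest validate).
#' @param seed integer seed.
#' @return A `split_config` list.
#' @export
split_config <- function(K = 5L, hoa_train_fraction = 0.8,
                         pd_train_fraction = 0.7, seed = 1L) {
  if (K < 2L) stopf("`K` must be at least 2")
  for (f in c(hoa_train_fraction, pd_train_fraction))
    if (f <= 0 || f >= 1) stopf("split fractions must lie in (0, 1)")
  structure(list(K = as.integer(K), hoa_train_fraction = hoa_train_fraction,
                 pd_train_fraction = pd_train_fraction,
                 seed = as.integer(seed)),
            class = "split_config")
}

#' Group table of a segment set
#'
#' One row per recording-level group with its cohort and group-level label
#' (all member segments share both by construction).
#'
#' @param segments a `segment_set`.
#' @return data.frame with group_id, cohort, label, n_segments.
#' @export
segment_groups <- function(segments) {
  m <- segments$meta
  idx <- !duplicated(m$group_id)
  g <- m[idx, c("group_id", "cohort", "label"), drop = FALSE]
  g$n_segments <- as.integer(table(m$group_id)[g$group_id])
  ## tripwire: a group must never carry two labels or cohorts
  chk <- tapply(paste(m$cohort, m$label), m$group_id,
                function(v) length(unique(v)))
  if (any(chk > 1L))
    stopf("internal error: group(s) with inconsistent label/cohort: %s",
          paste(names(chk)[chk > 1L], collapse = ", "))
  rownames(g) <- NULL
  g
}

#' 80-20 random split of HOA groups
#'
#' @param hoa_groups character vector of HOA group ids.
#' @param fraction training fraction (default 0.8).
#' @param seed optional seed.
#' @return List with `trn_hoa` and `val_hoa`; both empty when no HOA groups
#'   exist (PD-only experiments are valid).
#' @export
split_hoa <- function(hoa_groups, fraction = 0.8, seed = NULL) {
  if (fraction <= 0 || fraction >= 1) stopf("`fraction` must lie in (0, 1)")
  n <- length(hoa_groups)
  if (n == 0L) return(list(trn_hoa = character(), val_hoa = character()))
  with_seed(seed, {
    n_trn <- min(n, max(1L, floor(fraction * n + 0.5)))
    perm <- sample(hoa_groups)
    list(trn_hoa = sort(perm[seq_len(n_trn)]),
         val_hoa = sort(perm[-seq_len(n_trn)]))
  })
}

#' Stratified K-fold over groups
#'
#' Shuffles the groups of each label class and deals them round-robin across
#' folds, so folds differ in size by at most one group and each fold's label
#' counts are within one group of `n_class / K`.
#'
#' @param groups data.frame with columns group_id and label (see
#'   [segment_groups()]).
#' @param K number of folds.
#' @param seed optional seed.
#' @return List of K character vectors of group ids.
#' @export
stratified_group_kfold <- function(groups, K = 5L, seed = NULL) {
  classes <- split(groups$group_id, groups$label)
  for (cl in names(classes))
    if (length(classes[[cl]]) < K)
      stopf("stratification infeasible: class '%s' has %d group(s) < K = %d",
            cl, length(classes[[cl]]), K)
  with_seed(seed, {
    folds <- vector("list", K)
    offset <- 0L
    for (cl in names(classes)) {
      ids <- sample(classes[[cl]])
      ## rotate the starting fold per class so fold sizes stay balanced
      assign_to <- ((seq_along(ids) - 1L + offset) %% K) + 1L
      for (i in seq_along(ids))
        folds[[assign_to[i]]] <- c(folds[[assign_to[i]]], ids[i])
      offset <- (offset + length(ids)) %% K
    }
    lapply(folds, sort)
  })
}

#' Assemble the i-th fold split
#'
#' Fold `i` is the PD test set; the groups of the other K-1 folds are split
#' 70-30 at random into training and validation. A segment-level leakage
#' check runs at construction and errors if any group leaks.
#'
#' @param folds list of K group-id vectors from [stratified_group_kfold()].
#' @param i fold index in 1..K.
#' @param hoa_split list from [split_hoa()].
#' @param config a [split_config()].
#' @param seed optional seed for the 70-30 draw.
#' @return A `fold_split` with trn_pd, val_pd, tst_pd, trn_hoa, val_hoa.
#' @export
make_fold_split <- function(folds, i, hoa_split = split_hoa(character()),
                            config = split_config(), seed = NULL) {
  K <- length(folds)
  if (i < 1L || i > K) stopf("fold index %d outside 1..%d", i, K)
  tst <- folds[[i]]
  rest <- unlist(folds[-i], use.names = FALSE)
  with_seed(seed, {
    n_trn <- min(length(rest),
                 max(1L, floor(config$pd_train_fraction * length(rest) + 0.5)))
    perm <- sample(rest)
    fs <- structure(list(fold_index = i,
                         trn_pd = sort(perm[seq_len(n_trn)]),
                         val_pd = sort(perm[-seq_len(n_trn)]),
                         tst_pd = sort(tst),
                         trn_hoa = hoa_split$trn_hoa,
                         val_hoa = hoa_split$val_hoa),
                    class = "fold_split")
    check_fold_split(fs)
    fs
  })
}

check_fold_split <- function(fs) {
  sets <- fs[c("trn_pd", "val_pd", "tst_pd", "trn_hoa", "val_hoa")]
  all_ids <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stopf("leakage detected in fold %d: group(s) %s appear in multiple sets",
          fs$fold_index,
          paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  invisible(TRUE)
}

#' Build all K fold splits for a segment set
#'
#' @param segments a `segment_set` containing PD (and optionally HOA) groups.
#' @param config a [split_config()]; `config$seed` drives every random draw.
#' @return List of K `fold_split` objects.
#' @export
make_splits <- function(segments, config = split_config()) {
  g <- segment_groups(segments)
  pd <- g[g$cohort == "PD", , drop = FALSE]
  hoa <- g[g$cohort == "HOA", , drop = FALSE]
  folds <- stratified_group_kfold(pd, config$K,
                                  seed = derive_seed(config$seed, "kfold"))
  hoa_split <- split_hoa(hoa$group_id, config$hoa_train_fraction,
                         seed = derive_seed(config$seed, "hoa"))
  lapply(seq_len(config$K), function(i)
    make_fold_split(folds, i, hoa_split, config,
                    seed = derive_seed(config$seed, paste0("fold", i))))
}

#' Segment indices of one role of a fold split
#'
#' @param segments a `segment_set`.
#' @param fs a `fold_split`.
#' @param role one of `"trn_pd","val_pd","tst_pd","trn_hoa","val_hoa"`.
#' @return Integer segment indices.
#' @export
split_segment_idx <- function(segments, fs, role) {
  role <- match.arg(role, c("trn_pd", "val_pd", "tst_pd",
                            "trn_hoa", "val_hoa"))
  which(segments$meta$group_id %in% fs[[role]])
}

#' Write a fold split as a CSV manifest
#'
#' One row per group: group_id, cohort, label and its role in the fold. The
#' seed is recorded in a comment header line.
#'
#' @param fs a `fold_split`.
#' @param groups data.frame from [segment_groups()].
#' @param path output path.
#' @param seed seed to record.
#' @export
write_split_manifest <- function(fs, groups, path, seed = NA) {
  roles <- c("trn_pd", "val_pd", "tst_pd", "trn_hoa", "val_hoa")
  rows <- do.call(rbind, lapply(roles, function(r) {
    if (length(fs[[r]]) == 0L) return(NULL)
    data.frame(group_id = fs[[r]], fold_role = r, stringsAsFactors = FALSE)
  }))
  rows <- merge(rows, groups[, c("group_id", "cohort", "label")],
                by = "group_id", sort = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fold %d seed %s", fs$fold_index, seed), con)
  write.csv(rows, con, row.names = FALSE)
  invisible(path)
}
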