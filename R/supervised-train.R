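## Supervised fine-tuning of the ten model variants ----------------------------

#' Enumerate the ten supervised model variants of one fold
#'
#' The cross of training set {TrnPD, TrnPD u TrnHOA}, initialization
#' {RandInit, W_PD, W_PD_HOA} and fine-tuning scheme {FTL, FTA} (random
#' initialization has no scheme), in a stable order: 2 RandInit + 4 FTL +
#' 4 FTA rows per fold.
#'
#' @param fold fold index.
#' @return data.frame with columns variant_id, train_set, init, scheme, fold.
#' @export
enumerate_variants <- function(fold = 1L) {
  rows <- list()
  for (train_set in c("PD", "PD_HOA")) {
    rows[[length(rows) + 1L]] <-
      data.frame(train_set = train_set, init = "RandInit", scheme = "none")
    for (init in c("W_PD", "W_PD_HOA"))
      for (scheme in c("FTL", "FTA"))
        rows[[length(rows) + 1L]] <-
          data.frame(train_set = train_set, init = init, scheme = scheme)
  }
  out <- do.call(rbind, rows)
  out$fold <- as.integer(fold)
  out$variant_id <- sprintf("%s_%s_%s_f%d", out$train_set, out$init,
                            out$scheme, fold)
  out[, c("variant_id", "train_set", "init", "scheme", "fold")]
}

#' Binary cross-entropy between labels and predicted probabilities
#'
#' `-(1/N) sum(y log p + (1-y) log(1-p))` with probabilities clamped to
#' `[eps, 1-eps]` for numerical safety.
#'
#' @param labels 0/1 numeric vector (or `"low"`/`"high"` character; high = 1).
#' @param probabilities predicted probabilities of the positive (high) class.
#' @param eps clamp bound.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(labels, probabilities, eps = 1e-7) {
  if (is.character(labels)) labels <- as.numeric(labels == "high")
  if (length(labels) != length(probabilities))
    stopf("labels and probabilities have different lengths")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log1p(-p))
}

#' Supervised training configuration
#'
#' @param epochs_all full-network epochs (study-scale default 50).
#' @param epochs_head head-only epochs of the FTL scheme (default 10).
#' @param max_learning_rate peak of the one-cycle schedule.
#' @param batch_size mini-batch size.
#' @param seed seed for shuffling and head initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs_all = 50L, epochs_head = 10L,
                         max_learning_rate = 1e-3, batch_size = 64L,
                         seed = 1L) {
  if (epochs_all < 1L || epochs_head < 1L) stopf("epoch counts must be >= 1")
  if (max_learning_rate <= 0) stopf("`max_learning_rate` must be positive")
  structure(list(epochs_all = as.integer(epochs_all),
                 epochs_head = as.integer(epochs_head),
                 max_learning_rate = max_learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

## One supervised training phase (Adam + one-cycle), optionally restricted to
## the head parameters. Tracks the best-validation-loss checkpoint.
supervised_phase <- function(model, xtr, ytr, xva, yva, epochs, tconfig,
                             head_only = FALSE) {
  n <- dim(xtr)[3L]
  bs <- min(tconfig$batch_size, n)
  trainable <- if (head_only)
    Filter(function(nm) !is_backbone_param(nm), names(model$params))
  else names(model$params)
  opt <- adam_new(model$params)
  steps_per_epoch <- ceiling(n / bs)
  total <- epochs * steps_per_epoch
  step <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), val_acc = numeric())
  best <- list(loss = Inf, params = model$params, bn_state = model$bn_state)
  for (epoch in seq_len(epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    for (ib in seq_len(steps_per_epoch)) {
      idx <- ord[((ib - 1L) * bs + 1L):min(ib * bs, n)]
      xb <- xtr[, , idx, drop = FALSE]
      yb <- ytr[idx]
      step <- step + 1L
      lr <- onecycle_lr(step, total, tconfig$max_learning_rate)
      ## head-only phase keeps the backbone fully frozen: batch-norm runs in
      ## inference mode so even its running statistics stay untouched
      fw <- xt_forward(model, xb, train = !head_only)
      model <- apply_bn_updates(model, fw$tape)
      z <- as.numeric(tp_val(fw$tape, fw$out_id))
      p <- sigmoid(z)
      loss <- bce_loss(yb, p)
      dz <- matrix((p - yb) / length(yb), nrow = 1L)
      bw <- tp_backward(fw$tape, model, fw$out_id, dz)
      upd <- adam_step(model$params, bw$pgrads, opt, lr,
                       trainable = trainable)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss * length(idx)
    }
    pv <- model_forward(model, xva)
    vl <- bce_loss(yva, pv)
    va <- mean((pv >= 0.5) == (yva == 1))
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                 val_loss = vl, val_acc = va))
    if (vl < best$loss)
      best <- list(loss = vl, params = model$params,
                   bn_state = model$bn_state)
  }
  model$params <- best$params
  model$bn_state <- best$bn_state
  list(model = model, log = log, best_val_loss = best$loss)
}

variant_segment_idx <- function(segments, fs, train_set, role = c("trn", "val")) {
  role <- match.arg(role)
  idx <- split_segment_idx(segments, fs, paste0(role, "_pd"))
  if (train_set == "PD_HOA")
    idx <- c(idx, split_segment_idx(segments, fs, paste0(role, "_hoa")))
  idx
}

#' Train one supervised variant
#'
#' Assembles training/validation data per the variant's training-set
#' attribute (the test set is always PD-only), applies the initialization
#' (random, or transfer of `W_PD` / `W_PD_HOA` backbone weights), and runs
#' the scheme: `none` = all layers for `epochs_all`; `FTA` = all layers for
#' `epochs_all`; `FTL` = head only for `epochs_head`, then all layers for
#' `epochs_all`. Binary cross-entropy throughout, best-validation checkpoint
#' retained.
#'
#' @param variant one row of [enumerate_variants()] (data.frame or list).
#' @param fold_split the matching `fold_split`.
#' @param segments a `segment_set`.
#' @param weights_store list with elements `W_PD` and `W_PD_HOA`
#'   (`pretrained_weights`) for this fold; may be `NULL` for RandInit.
#' @param config a [model_config()] (head forced to classification).
#' @param tconfig a [train_config()].
#' @return List: `model` (tagged `xt_model`), `log` (epoch data.frame),
#'   `variant`.
#' @export
train_variant <- function(variant, fold_split, segments, weights_store = NULL,
                          config = model_config(), tconfig = train_config()) {
  variant <- as.list(variant)
  config$head <- "classification"
  config$seed <- derive_seed(tconfig$seed, variant$variant_id)
  model <- build_model(config, tags = list(
    fold = variant$fold, train_set = variant$train_set,
    init = variant$init, scheme = variant$scheme,
    variant_id = variant$variant_id))
  if (variant$init != "RandInit") {
    pw <- weights_store[[variant$init]]
    if (is.null(pw))
      stopf("missing pre-trained weights '%s' for fold %d: run pre-training first",
            variant$init, variant$fold)
    model <- transfer_weights(model, pw)
    model$tags$init <- variant$init
  }
  itr <- variant_segment_idx(segments, fold_split, variant$train_set, "trn")
  iva <- variant_segment_idx(segments, fold_split, variant$train_set, "val")
  if (length(itr) == 0L) stopf("variant %s has an empty training set",
                               variant$variant_id)
  xtr <- segments_to_input(subset_segments(segments, itr))
  ytr <- as.numeric(segments$meta$label[itr] == "high")
  xva <- segments_to_input(subset_segments(segments, iva))
  yva <- as.numeric(segments$meta$label[iva] == "high")
  logs <- list()
  with_seed(derive_seed(tconfig$seed, paste0("fit_", variant$variant_id)), {
    if (identical(variant$scheme, "FTL")) {
      ph1 <- supervised_phase(model, xtr, ytr, xva, yva,
                              tconfig$epochs_head, tconfig, head_only = TRUE)
      model <- ph1$model
      ph1$log$phase <- "head"
      logs$head <- ph1$log
    }
    ph2 <- supervised_phase(model, xtr, ytr, xva, yva, tconfig$epochs_all,
                            tconfig, head_only = FALSE)
    model <- ph2$model
    ph2$log$phase <- "all"
    logs$all <- ph2$log
  })
  list(model = model, log = do.call(rbind, c(logs, make.row.names = FALSE)),
       variant = variant)
}

#' Train all ten variants of one fold
#'
#' @param fold fold index.
#' @param fold_split the fold's `fold_split`.
#' @param segments a `segment_set`.
#' @param weights_store per-fold list with `W_PD` and `W_PD_HOA`.
#' @param config,tconfig as in [train_variant()].
#' @return Named list of [train_variant()] results, one per variant.
#' @export
train_fold_variants <- function(fold, fold_split, segments,
                                weights_store = NULL,
                                config = model_config(),
                                tconfig = train_config()) {
  variants <- enumerate_variants(fold)
  out <- lapply(seq_len(nrow(variants)), function(i)
    train_variant(variants[i, ], fold_split, segments, weights_store,
                  config, tconfig))
  names(out) <- variants$variant_id
  out
}
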