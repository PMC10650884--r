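## Masked self-supervised pre-training -----------------------------------------
##
## The input is corrupted by zeroing alternating runs whose lengths follow
## geometric distributions: masked runs with mean lm, unmasked runs with mean
## lu = lm (1 - r) / r, so a fraction r of time steps is masked on average. A
## reconstruction-headed network is trained to predict the masked values, with
## mean squared error measured over masked positions only.

#' Masking specification
#'
#' @param r masked proportion of the input, in (0, 1).
#' @param lm mean masked-run length in samples (>= 1).
#' @param per_channel draw an independent mask per channel (default), or
#'   share one mask across channels.
#' @return A `mask_spec` with the derived unmasked mean `lu = lm (1 - r) / r`.
#' @export
mask_spec <- function(r = 0.15, lm = 3, per_channel = TRUE) {
  if (r <= 0 || r >= 1) stopf("`r` must lie in (0, 1)")
  if (lm < 1) stopf("`lm` must be at least 1")
  structure(list(r = r, lm = lm, lu = lm * (1 - r) / r,
                 per_channel = isTRUE(per_channel)),
            class = "mask_spec")
}

## Geometric run length on support {1, 2, ...} with mean `mean_len`.
rgeom_len <- function(n, mean_len) {
  if (mean_len <= 1) return(rep(1L, n))
  rgeom(n, 1 / mean_len) + 1L
}

#' Sample a boolean masking vector
#'
#' Alternating masked/unmasked runs; masked-run lengths are Geometric with
#' mean `lm`, unmasked-run lengths Geometric with mean `lu`; the first run is
#' masked with probability `r`; the final run is truncated at the end.
#'
#' @param length sequence length in samples (>= 1).
#' @param spec a [mask_spec()].
#' @param seed optional seed.
#' @return Logical vector, `TRUE` = masked.
#' @export
sample_mask <- function(length, spec = mask_spec(), seed = NULL) {
  if (length < 1L) stopf("`length` must be at least 1")
  with_seed(seed, {
    first_masked <- runif(1L) < spec$r
    ## draw alternating run lengths in vectorized batches until they cover
    ## the sequence, then expand and truncate
    runs <- integer()
    states <- logical()
    covered <- 0L
    state0 <- first_masked
    while (covered < length) {
      n_draw <- max(8L, ceiling(2 * (length - covered) / (spec$lm + spec$lu)))
      a <- rgeom_len(n_draw, if (state0) spec$lm else spec$lu)
      b <- rgeom_len(n_draw, if (state0) spec$lu else spec$lm)
      batch <- as.integer(rbind(a, b))
      runs <- c(runs, batch)
      states <- c(states, rep(c(state0, !state0), n_draw))
      covered <- covered + sum(batch)
      ## each batch holds whole (state0, !state0) pairs, so the alternation
      ## phase is unchanged for the next batch
    }
    mask <- rep(states, runs)[seq_len(length)]
    mask
  })
}

#' Sample a mask matrix for a multichannel segment
#'
#' @param n_time,n_channels segment dimensions.
#' @param spec a [mask_spec()]; with `per_channel = FALSE` all channels share
#'   one mask.
#' @param seed optional seed.
#' @return `n_time x n_channels` logical matrix, `TRUE` = masked.
#' @export
sample_mask_matrix <- function(n_time, n_channels, spec = mask_spec(),
                               seed = NULL) {
  with_seed(seed, {
    if (spec$per_channel) {
      vapply(seq_len(n_channels), function(c) sample_mask(n_time, spec),
             logical(n_time))
    } else {
      matrix(sample_mask(n_time, spec), n_time, n_channels)
    }
  })
}

#' Zero out masked positions of a window
#'
#' @param window numeric matrix/array.
#' @param mask logical mask of the same shape.
#' @return `window` with masked entries set to 0.
#' @export
apply_mask <- function(window, mask) {
  if (!identical(dim(window), dim(mask)) &&
      !(is.null(dim(window)) && is.null(dim(mask)) &&
        length(window) == length(mask)))
    stopf("window and mask shapes differ")
  window[mask] <- 0
  window
}

#' Mean squared error over masked positions
#'
#' `(1/N) sum_i (y_i - yhat_i)^2` where i ranges over the N masked positions
#' only; predictions at unmasked positions never affect the loss.
#'
#' @param prediction,target numeric arrays of identical shape.
#' @param mask logical mask of the same shape with at least one `TRUE`.
#' @return Non-negative scalar.
#' @export
masked_mse_loss <- function(prediction, target, mask) {
  if (length(prediction) != length(target) ||
      length(prediction) != length(mask))
    stopf("prediction, target and mask shapes differ")
  n <- sum(mask)
  if (n == 0L) stopf("undefined loss: mask has no masked positions")
  sum((prediction[mask] - target[mask])^2) / n
}

#' Pre-training configuration
#'
#' @param epochs training epochs (study-scale default 200).
#' @param max_learning_rate peak of the one-cycle schedule.
#' @param batch_size mini-batch size.
#' @param seed seed for shuffling and mask sampling.
#' @param resample_masks resample masks every epoch (default) or freeze the
#'   masks drawn at epoch 1.
#' @return A `pretrain_config` list.
#' @export
pretrain_config <- function(epochs = 200L, max_learning_rate = 1e-3,
                            batch_size = 64L, seed = 1L,
                            resample_masks = TRUE) {
  if (epochs < 1L) stopf("`epochs` must be at least 1")
  if (max_learning_rate <= 0) stopf("`max_learning_rate` must be positive")
  structure(list(epochs = as.integer(epochs),
                 max_learning_rate = max_learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 resample_masks = isTRUE(resample_masks)),
            class = "pretrain_config")
}

## Draw masks for a (C, T, B) input block: (T, C) per segment, transposed in.
draw_mask_block <- function(d, spec) {
  mk <- array(FALSE, d)
  for (b in seq_len(d[3L]))
    mk[, , b] <- t(sample_mask_matrix(d[2L], d[1L], spec))
  mk
}

## Validation masked-MSE of a reconstruction model under fixed masks.
masked_val_loss <- function(model, x, masks) {
  xm <- x
  xm[masks] <- 0
  fw <- xt_forward(model, xm, train = FALSE)
  masked_mse_loss(tp_val(fw$tape, fw$out_id), x, masks)
}

#' Masked pre-training of a reconstruction model
#'
#' Trains a reconstruction-headed XceptionTime network to impute masked spans,
#' using Adam under a one-cycle learning-rate schedule; the checkpoint with
#' the best validation masked-MSE is retained. Labels are never used.
#'
#' @param train_segments,val_segments `segment_set`s (labels ignored).
#' @param config a [model_config()]; its head is forced to reconstruction.
#' @param spec a [mask_spec()].
#' @param pconfig a [pretrain_config()].
#' @param tag provenance tag, e.g. `"W_PD(1)"` or `"W_PD_HOA(1)"`.
#' @return A `pretrained_weights` object: backbone `params`, `bn_state`,
#'   `tag`, the model `config`, and the per-epoch `history` of train/val
#'   masked-MSE.
#' @export
pretrain <- function(train_segments, val_segments, config = model_config(),
                     spec = mask_spec(), pconfig = pretrain_config(),
                     tag = "W") {
  if (dim(train_segments$windows)[3L] == 0L)
    stopf("empty pre-training set")
  if (dim(val_segments$windows)[3L] == 0L)
    stopf("empty pre-training validation set")
  config$head <- "reconstruction"
  model <- build_model(config, tags = list(tag = tag))
  xtr <- segments_to_input(train_segments)
  xva <- segments_to_input(val_segments)
  n <- dim(xtr)[3L]
  bs <- min(pconfig$batch_size, n)
  with_seed(derive_seed(pconfig$seed, "pretrain"), {
    val_masks <- draw_mask_block(dim(xva), spec)
    opt <- adam_new(model$params)
    steps_per_epoch <- ceiling(n / bs)
    total <- pconfig$epochs * steps_per_epoch
    step <- 0L
    history <- data.frame(epoch = integer(), train_mse = numeric(),
                          val_mse = numeric())
    best <- list(loss = Inf, params = model$params, bn_state = model$bn_state)
    epoch_masks <- NULL
    for (epoch in seq_len(pconfig$epochs)) {
      if (pconfig$resample_masks || is.null(epoch_masks))
        epoch_masks <- draw_mask_block(dim(xtr), spec)
      ord <- sample(n)
      ep_loss <- 0
      for (ib in seq_len(steps_per_epoch)) {
        idx <- ord[((ib - 1L) * bs + 1L):min(ib * bs, n)]
        xb <- xtr[, , idx, drop = FALSE]
        mb <- epoch_masks[, , idx, drop = FALSE]
        xin <- xb
        xin[mb] <- 0
        step <- step + 1L
        lr <- onecycle_lr(step, total, pconfig$max_learning_rate)
        fw <- xt_forward(model, xin, train = TRUE)
        model <- apply_bn_updates(model, fw$tape)
        pred <- tp_val(fw$tape, fw$out_id)
        nmask <- sum(mb)
        if (nmask == 0L) next  # resampled next epoch; vanishing probability
        loss <- sum((pred[mb] - xb[mb])^2) / nmask
        dout <- array(0, dim(pred))
        dout[mb] <- 2 * (pred[mb] - xb[mb]) / nmask
        bw <- tp_backward(fw$tape, model, fw$out_id, dout)
        upd <- adam_step(model$params, bw$pgrads, opt, lr)
        model$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + loss * length(idx)
      }
      vl <- masked_val_loss(model, xva, val_masks)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_mse = ep_loss / n,
                                           val_mse = vl))
      if (vl < best$loss)
        best <- list(loss = vl, params = model$params,
                     bn_state = model$bn_state)
    }
    structure(list(params = backbone_params(best$params),
                   bn_state = best$bn_state, tag = tag, config = config,
                   history = history, best_val_mse = best$loss),
              class = "pretrained_weights")
  })
}

backbone_params <- function(params) {
  params[Filter(is_backbone_param, names(params))]
}

#' @export
print.pretrained_weights <- function(x, ...) {
  cat(sprintf("<pretrained_weights> %s: %d epochs, best val masked-MSE %.5f\n",
              x$tag, nrow(x$history), x$best_val_mse))
  invisible(x)
}

#' Pre-train the per-fold weight sets
#'
#' For each fold i, trains one model on the PD training groups alone (tag
#' `W_PD(i)`) and one on PD plus HOA training groups (tag `W_PD_HOA(i)`),
#' validated on the corresponding validation sets.
#'
#' @param segments a `segment_set`.
#' @param splits list of `fold_split` from [make_splits()].
#' @param config,spec,pconfig as in [pretrain()].
#' @return Nested list `weights[[fold]][[c("W_PD","W_PD_HOA")]]`.
#' @export
pretrain_weight_sets <- function(segments, splits, config = model_config(),
                                 spec = mask_spec(),
                                 pconfig = pretrain_config()) {
  lapply(seq_along(splits), function(i) {
    fs <- splits[[i]]
    trn_pd <- subset_segments(segments, split_segment_idx(segments, fs, "trn_pd"))
    val_pd <- subset_segments(segments, split_segment_idx(segments, fs, "val_pd"))
    pc <- pconfig
    pc$seed <- derive_seed(pconfig$seed, sprintf("pre_pd_%d", i))
    w_pd <- pretrain(trn_pd, val_pd, config, spec, pc,
                     tag = sprintf("W_PD(%d)", i))
    idx_trn <- c(split_segment_idx(segments, fs, "trn_pd"),
                 split_segment_idx(segments, fs, "trn_hoa"))
    idx_val <- c(split_segment_idx(segments, fs, "val_pd"),
                 split_segment_idx(segments, fs, "val_hoa"))
    pc$seed <- derive_seed(pconfig$seed, sprintf("pre_pdhoa_%d", i))
    w_pdhoa <- pretrain(subset_segments(segments, idx_trn),
                        subset_segments(segments, idx_val),
                        config, spec, pc, tag = sprintf("W_PD_HOA(%d)", i))
    list(W_PD = w_pd, W_PD_HOA = w_pdhoa)
  })
}
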