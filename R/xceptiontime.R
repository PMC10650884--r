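## XceptionTime-style 1-D convolutional backbone -------------------------------
##
## Each module: a pointwise bottleneck feeding three depthwise-separable
## convolutions at kernel scales {k, k/2, k/4}, plus a maxpool->pointwise
## branch, concatenated (each branch contributes f channels, so the module
## emits 4f) and batch-normalized. A residual path (pointwise conv + batch
## norm on the input of the preceding module) joins after every second
## module, followed by ReLU. Branch width doubles per module. Heads are
## interchangeable: reconstruction (length-preserving pointwise conv back to
## the input channels) or binary classification (global average pooling over
## time, then a two-layer pointwise stack to one logit). Backbone parameter
## shapes depend only on the config, never on the head, so weights transfer
## between heads with zero shape mismatches.

make_odd <- function(k) if (k %% 2L == 0L) k - 1L else k

#' Model configuration
#'
#' @param in_channels input channels (2 = one processed channel per sensor).
#' @param n_modules number of XceptionTime modules in the backbone.
#' @param base_kernel largest depthwise kernel (odd); the other two scales
#'   are the odd-rounded halves and quarters.
#' @param filters per-branch channel count `f` of the first module (each
#'   module emits `4 f` channels and `f` doubles per module).
#' @param head `"classification"` or `"reconstruction"`.
#' @param seed integer seed for parameter initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(in_channels = 2L, n_modules = 4L, base_kernel = 39L,
                         filters = 8L, head = c("classification",
                                                "reconstruction"),
                         seed = 1L) {
  head <- match.arg(head)
  if (in_channels <= 0L) stopf("`in_channels` must be positive")
  if (n_modules < 1L) stopf("`n_modules` must be at least 1")
  if (filters < 1L) stopf("`filters` must be at least 1")
  if (base_kernel %% 2L == 0L) stopf("`base_kernel` must be odd")
  structure(list(in_channels = as.integer(in_channels),
                 n_modules = as.integer(n_modules),
                 base_kernel = as.integer(base_kernel),
                 filters = as.integer(filters), head = head,
                 seed = as.integer(seed)),
            class = "model_config")
}

module_widths <- function(config) {
  f <- config$filters * 2L^(seq_len(config$n_modules) - 1L)
  list(f = f, out = 4L * f,
       inp = c(config$in_channels, 4L * f[-config$n_modules]))
}

kernel_scales <- function(k) {
  c(k, make_odd(max(3L, k %/% 2L)), make_odd(max(3L, k %/% 4L)))
}

he_mat <- function(nout, nin) {
  matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

init_backbone <- function(config) {
  w <- module_widths(config)
  ks <- kernel_scales(config$base_kernel)
  params <- list()
  bn_names <- character()
  for (m in seq_len(config$n_modules)) {
    p <- sprintf("m%d", m)
    fm <- w$f[m]
    cin <- w$inp[m]
    params[[paste0(p, ".bott.W")]] <- he_mat(fm, cin)
    params[[paste0(p, ".bott.b")]] <- numeric(fm)
    for (j in 1:3) {
      params[[sprintf("%s.br%d.dw", p, j)]] <-
        matrix(rnorm(fm * ks[j], 0, sqrt(2 / ks[j])), fm, ks[j])
      params[[sprintf("%s.br%d.pw.W", p, j)]] <- he_mat(fm, fm)
      params[[sprintf("%s.br%d.pw.b", p, j)]] <- numeric(fm)
    }
    params[[paste0(p, ".mp.pw.W")]] <- he_mat(fm, cin)
    params[[paste0(p, ".mp.pw.b")]] <- numeric(fm)
    params[[paste0(p, ".bn.gamma")]] <- rep(1, w$out[m])
    params[[paste0(p, ".bn.beta")]] <- numeric(w$out[m])
    bn_names <- c(bn_names, paste0(p, ".bn"))
    if (m %% 2L == 0L) {
      rin <- w$inp[m - 1L]  # residual taps the input of the previous module
      params[[sprintf("res%d.pw.W", m)]] <- he_mat(w$out[m], rin)
      params[[sprintf("res%d.pw.b", m)]] <- numeric(w$out[m])
      params[[sprintf("res%d.bn.gamma", m)]] <- rep(1, w$out[m])
      params[[sprintf("res%d.bn.beta", m)]] <- numeric(w$out[m])
      bn_names <- c(bn_names, sprintf("res%d.bn", m))
    }
  }
  list(params = params, bn_names = bn_names)
}

init_head <- function(config) {
  d <- module_widths(config)$out[config$n_modules]
  params <- list()
  if (config$head == "reconstruction") {
    params[["head.pw.W"]] <- he_mat(config$in_channels, d)
    params[["head.pw.b"]] <- numeric(config$in_channels)
  } else {
    h <- max(4L, d %/% 2L)
    params[["head.fc1.W"]] <- he_mat(h, d)
    params[["head.fc1.b"]] <- numeric(h)
    params[["head.fc2.W"]] <- he_mat(1L, h)
    params[["head.fc2.b"]] <- numeric(1L)
  }
  params
}

#' Build an XceptionTime model
#'
#' Initialization is reproducible: two builds from the same config (including
#' seed) have identical parameters.
#'
#' @param config a [model_config()].
#' @param tags optional named list of provenance tags (fold, train set,
#'   initialization, fine-tuning scheme).
#' @return An `xt_model`: list with `config`, `params` (named arrays),
#'   `bn_state` (batch-norm running statistics) and `tags`.
#' @export
build_model <- function(config, tags = list()) {
  with_seed(config$seed, {
    bb <- init_backbone(config)
    params <- c(bb$params, init_head(config))
    bn_state <- list()
    for (nm in bb$bn_names) {
      n_ch <- length(params[[paste0(nm, ".gamma")]])
      bn_state[[nm]] <- list(mean = numeric(n_ch), var = rep(1, n_ch))
    }
    structure(list(config = config, params = params, bn_state = bn_state,
                   tags = tags),
              class = "xt_model")
  })
}

#' @export
print.xt_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<xt_model> %s head, %d modules (f=%d, k=%d), %d parameters\n",
              x$config$head, x$config$n_modules, x$config$filters,
              x$config$base_kernel, n_par))
  if (length(x$tags))
    cat("  tags:", paste(names(x$tags), unlist(x$tags), sep = "=",
                         collapse = " "), "\n")
  invisible(x)
}

is_backbone_param <- function(name) !startsWith(name, "head.")

## Forward pass. `x` is (C, T, B). Returns the tape, the output node and the
## probe nodes at the first and last module outputs.
xt_forward <- function(model, x, train = FALSE) {
  config <- model$config
  tp <- tp_new()
  cur <- op_input(tp, x)
  pair_in <- cur
  probes <- integer(config$n_modules)
  for (m in seq_len(config$n_modules)) {
    if (m %% 2L == 1L) pair_in <- cur
    p <- sprintf("m%d", m)
    bott <- op_pw(tp, model, cur, paste0(p, ".bott"))
    branches <- lapply(1:3, function(j)
      op_pw(tp, model, op_dw(tp, model, bott, sprintf("%s.br%d.dw", p, j)),
            sprintf("%s.br%d.pw", p, j)))
    mp <- op_pw(tp, model, op_maxpool(tp, cur), paste0(p, ".mp.pw"))
    cc <- op_concat(tp, c(unlist(branches), mp))
    bn <- op_bn(tp, model, cc, paste0(p, ".bn"), train)
    if (m %% 2L == 0L) {
      r <- op_bn(tp, model, op_pw(tp, model, pair_in, sprintf("res%d.pw", m)),
                 sprintf("res%d.bn", m), train)
      bn <- op_add(tp, bn, r)
    }
    cur <- op_relu(tp, bn)
    probes[m] <- cur
  }
  out <- if (config$head == "reconstruction") {
    op_pw(tp, model, cur, "head.pw")
  } else {
    g <- op_gap(tp, cur)
    h1 <- op_relu(tp, op_pw(tp, model, g, "head.fc1"))
    op_pw(tp, model, h1, "head.fc2")
  }
  list(tape = tp, out_id = out,
       probe_ids = c(first = probes[1L], last = probes[config$n_modules]))
}

segments_to_input <- function(segments) {
  ## segment_set windows are (T, C, n); the network wants (C, T, B)
  aperm(segments$windows, c(2L, 1L, 3L))
}

#' Forward predictions / reconstructions for a segment set
#'
#' @param model an `xt_model`.
#' @param segments a `segment_set` or a `(C, T, B)` array.
#' @return Classification head: numeric vector of probabilities of the
#'   `"high"` class. Reconstruction head: a `(C, T, B)` array.
#' @export
model_forward <- function(model, segments) {
  x <- if (inherits(segments, "segment_set")) segments_to_input(segments)
       else segments
  if (dim(x)[3L] == 0L)
    return(if (model$config$head == "classification") numeric() else x)
  fw <- xt_forward(model, x, train = FALSE)
  out <- tp_val(fw$tape, fw$out_id)
  if (model$config$head == "classification") as.numeric(sigmoid(out)) else out
}

#' Extract pooled representations at a probe point
#'
#' Captures the activations at the output of the first or last XceptionTime
#' module and averages them over the time axis, yielding one d-vector per
#' segment (d = module output channels). Deterministic in inference mode.
#'
#' @param model an `xt_model`.
#' @param segments a `segment_set` or `(C, T, B)` array.
#' @param probe `"first"` or `"last"`.
#' @return `n x d` feature matrix, rows in segment order.
#' @export
extract_representation <- function(model, segments, probe = c("first", "last")) {
  probe <- match.arg(probe)
  x <- if (inherits(segments, "segment_set")) segments_to_input(segments)
       else segments
  fw <- xt_forward(model, x, train = FALSE)
  act <- tp_val(fw$tape, fw$probe_ids[[probe]])
  t(apply(act, c(1L, 3L), mean))  # (B, C)
}

#' Transfer pre-trained backbone weights into a model
#'
#' Copies every backbone parameter (and batch-norm running statistic) from
#' `pretrained` into `model`; the head keeps its own (fresh) initialization.
#' Requires identical backbone architecture.
#'
#' @param model target `xt_model` (any head).
#' @param pretrained a `pretrained_weights` object or `xt_model` source.
#' @return The model with the transferred backbone.
#' @export
transfer_weights <- function(model, pretrained) {
  src_params <- if (inherits(pretrained, "pretrained_weights"))
    pretrained$params else pretrained$params
  src_state <- if (inherits(pretrained, "pretrained_weights"))
    pretrained$bn_state else pretrained$bn_state
  bb <- Filter(is_backbone_param, names(model$params))
  src_bb <- Filter(is_backbone_param, names(src_params))
  if (!setequal(bb, src_bb))
    stopf("incompatible architectures: backbone parameter sets differ")
  for (nm in bb) {
    if (!identical(dim(model$params[[nm]]), dim(src_params[[nm]])) ||
        length(model$params[[nm]]) != length(src_params[[nm]]))
      stopf("incompatible architectures: shape mismatch in '%s'", nm)
    model$params[[nm]] <- src_params[[nm]]
  }
  model$bn_state <- src_state
  model$tags$init <- pretrained$tag %||% model$tags$init
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is the model list itself (config and tags embedded), so it
#' is self-describing.
#'
#' @param model an `xt_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

## Stable hash of a parameter subset; used to verify freeze contracts.
param_hash <- function(params, names_subset = names(params)) {
  v <- unlist(params[sort(names_subset)], use.names = FALSE)
  paste(format(sum(v), digits = 17), format(sum(v^2), digits = 17),
        format(sum(v * seq_along(v)), digits = 17))
}
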