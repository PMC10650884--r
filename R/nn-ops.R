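## Reverse-mode tape over the small set of primitives the network needs --------
##
## Activations are arrays laid out (channels, time, batch) so that pointwise
## convolutions reduce to one BLAS matrix product over channels; depthwise
## convolutions and max pooling run in C++ (src/conv_ops.cpp). The tape is a
## flat list of nodes appended in forward order; backward walks it in reverse
## and accumulates parameter gradients by name.

tp_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$nodes <- list()
  tp$bn_updates <- list()
  tp
}

## Merge the batch-norm running-statistic updates recorded during a
## training-mode forward pass back into the model.
apply_bn_updates <- function(model, tp) {
  for (nm in names(tp$bn_updates))
    model$bn_state[[nm]] <- tp$bn_updates[[nm]]
  model
}

tp_add <- function(tp, val, op, ins = integer(), pname = NULL, cache = NULL) {
  tp$n <- tp$n + 1L
  tp$nodes[[tp$n]] <- list(val = val, op = op, ins = ins, pname = pname,
                           cache = cache)
  tp$n
}

tp_val <- function(tp, id) {
  force(id)  # nested op calls grow the tape; force before touching tp$nodes
  tp$nodes[[id]]$val
}

nchan <- function(x) if (is.matrix(x)) nrow(x) else dim(x)[1L]

as_cmat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = dim(x)[1L])
}

op_input <- function(tp, x) tp_add(tp, x, "input")

## pointwise convolution / dense layer: y = W x + b over the channel dim
op_pw <- function(tp, model, id, pname) {
  x <- tp_val(tp, id)
  W <- model$params[[paste0(pname, ".W")]]
  b <- model$params[[paste0(pname, ".b")]]
  y <- W %*% as_cmat(x) + b
  if (!is.matrix(x)) dim(y) <- c(nrow(W), dim(x)[2L], dim(x)[3L])
  tp_add(tp, y, "pw", id, pname)
}

op_dw <- function(tp, model, id, pname) {
  x <- tp_val(tp, id)
  w <- model$params[[pname]]
  d <- dim(x)
  y <- dwconv_fwd(as.numeric(x), as.numeric(w), d[1L], d[2L], d[3L], ncol(w))
  dim(y) <- d
  tp_add(tp, y, "dw", id, pname, cache = list(k = ncol(w)))
}

op_bn <- function(tp, model, id, pname, train) {
  x <- tp_val(tp, id)
  d <- dim(x)
  gamma <- model$params[[paste0(pname, ".gamma")]]
  beta <- model$params[[paste0(pname, ".beta")]]
  st <- model$bn_state[[pname]]
  xm <- as_cmat(x)
  eps <- 1e-5
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
    ## models are plain lists (copy semantics), so running-stat updates are
    ## parked on the tape; trainers merge them via apply_bn_updates()
    tp$bn_updates[[pname]] <- list(mean = 0.9 * st$mean + 0.1 * mu,
                                   var = 0.9 * st$var + 0.1 * v)
  } else {
    mu <- st$mean
    v <- st$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * istd
  y <- gamma * xhat + beta
  dim(y) <- d
  tp_add(tp, y, "bn", id, pname,
         cache = list(xhat = xhat, istd = istd, train = train))
}

op_relu <- function(tp, id) {
  x <- tp_val(tp, id)
  tp_add(tp, x * (x > 0), "relu", id)
}

op_maxpool <- function(tp, id) {
  x <- tp_val(tp, id)
  d <- dim(x)
  r <- maxpool3_fwd(as.numeric(x), d[1L], d[2L], d[3L])
  y <- r$y
  dim(y) <- d
  tp_add(tp, y, "maxpool", id, cache = list(idx = r$idx))
}

op_concat <- function(tp, ids) {
  vals <- lapply(ids, tp_val, tp = tp)
  cs <- vapply(vals, nchan, integer(1))
  d <- dim(vals[[1L]])
  out <- array(0, c(sum(cs), d[2L], d[3L]))
  at <- 0L
  for (v in vals) {
    out[(at + 1L):(at + nchan(v)), , ] <- v
    at <- at + nchan(v)
  }
  tp_add(tp, out, "concat", ids, cache = list(cs = cs))
}

op_add <- function(tp, id1, id2) {
  tp_add(tp, tp_val(tp, id1) + tp_val(tp, id2), "add", c(id1, id2))
}

## global average over the time axis: (C,T,B) -> (C,B)
op_gap <- function(tp, id) {
  x <- tp_val(tp, id)
  d <- dim(x)
  y <- colMeans(aperm(x, c(2L, 1L, 3L)))  # mean over T -> (C,B)
  dim(y) <- c(d[1L], d[3L])
  tp_add(tp, y, "gap", id, cache = list(T = d[2L]))
}

## Backward pass: returns the named list of parameter gradients (and the
## gradient w.r.t. the input node when requested).
tp_backward <- function(tp, model, out_id, dout, want_input_grad = FALSE) {
  grads <- vector("list", tp$n)
  grads[[out_id]] <- dout
  pgrads <- list()
  padd <- function(name, v) {
    pgrads[[name]] <<- if (is.null(pgrads[[name]])) v else pgrads[[name]] + v
  }
  gadd <- function(i, v) {
    grads[[i]] <<- if (is.null(grads[[i]])) v else grads[[i]] + v
  }
  for (id in rev(seq_len(tp$n))) {
    node <- tp$nodes[[id]]
    g <- grads[[id]]
    if (is.null(g)) next
    x_ids <- node$ins
    switch(node$op,
      input = NULL,
      pw = {
        x <- tp_val(tp, x_ids)
        xm <- as_cmat(x)
        gm <- as_cmat(g)
        W <- model$params[[paste0(node$pname, ".W")]]
        padd(paste0(node$pname, ".W"), gm %*% t(xm))
        padd(paste0(node$pname, ".b"), rowSums(gm))
        dx <- t(W) %*% gm
        if (!is.matrix(x)) dim(dx) <- dim(x)
        gadd(x_ids, dx)
      },
      dw = {
        x <- tp_val(tp, x_ids)
        d <- dim(x)
        w <- model$params[[node$pname]]
        r <- dwconv_bwd(as.numeric(x), as.numeric(w), as.numeric(g),
                        d[1L], d[2L], d[3L], node$cache$k)
        padd(node$pname, matrix(r$dw, nrow = d[1L]))
        dx <- r$dx
        dim(dx) <- d
        gadd(x_ids, dx)
      },
      bn = {
        x <- tp_val(tp, x_ids)
        gm <- as_cmat(g)
        xhat <- node$cache$xhat
        istd <- node$cache$istd
        gamma <- model$params[[paste0(node$pname, ".gamma")]]
        padd(paste0(node$pname, ".gamma"), rowSums(gm * xhat))
        padd(paste0(node$pname, ".beta"), rowSums(gm))
        dxhat <- gm * gamma
        if (node$cache$train) {
          dx <- istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
        } else {
          dx <- istd * dxhat
        }
        dim(dx) <- dim(x)
        gadd(x_ids, dx)
      },
      relu = {
        x <- tp_val(tp, x_ids)
        gadd(x_ids, g * (x > 0))
      },
      maxpool = {
        x <- tp_val(tp, x_ids)
        d <- dim(x)
        dx <- maxpool3_bwd(as.numeric(g), node$cache$idx, d[1L], d[2L], d[3L])
        dim(dx) <- d
        gadd(x_ids, dx)
      },
      concat = {
        cs <- node$cache$cs
        at <- 0L
        for (j in seq_along(x_ids)) {
          gadd(x_ids[j], g[(at + 1L):(at + cs[j]), , , drop = FALSE])
          at <- at + cs[j]
        }
      },
      add = {
        gadd(x_ids[1L], g)
        gadd(x_ids[2L], g)
      },
      gap = {
        Tn <- node$cache$T
        d <- dim(tp_val(tp, x_ids))
        dx <- array(rep(as.numeric(g) / Tn, each = 1L), c(d[1L], d[3L]))
        dx <- aperm(array(dx, c(d[1L], d[3L], Tn)), c(1L, 3L, 2L))
        gadd(x_ids, dx)
      },
      stopf("unknown op '%s' on tape", node$op))
  }
  list(pgrads = pgrads,
       dinput = if (want_input_grad) grads[[1L]] else NULL)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
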