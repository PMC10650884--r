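## Adam optimizer with a one-cycle learning-rate schedule ----------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, trainable = names(params)) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    if (!nm %in% trainable) next
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

## One-cycle schedule: cosine warm-up from max_lr/div to max_lr over the first
## pct_start of the steps, then cosine anneal down to max_lr/final_div.
onecycle_lr <- function(step, total_steps, max_lr, pct_start = 0.25,
                        div = 25, final_div = 1e4) {
  if (total_steps <= 1L) return(max_lr)
  frac <- (step - 1) / (total_steps - 1)
  if (frac <= pct_start) {
    p <- if (pct_start > 0) frac / pct_start else 1
    lo <- max_lr / div
    lo + (max_lr - lo) * (1 - cos(pi * p)) / 2
  } else {
    p <- (frac - pct_start) / (1 - pct_start)
    lo <- max_lr / final_div
    lo + (max_lr - lo) * (1 + cos(pi * p)) / 2
  }
}
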