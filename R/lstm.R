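# Hand-rolled many-to-one LSTM: forward pass, backpropagation through time,
# and Adam updates, all as dense base-R matrix algebra vectorized over the
# batch. Gate order throughout is [input, forget, cell-candidate, output].
# Gradients are verified against central finite differences in the tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Uniform(-k, k) init with k = 1/sqrt(H); forget-gate bias offset +1 for
# early-training stability of the memory path.
lstm_init <- function(n_input, n_hidden, n_output) {
  k <- 1 / sqrt(n_hidden)
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  b <- matrix(stats::runif(4 * n_hidden, -k, k), 1)
  b[1, (n_hidden + 1):(2 * n_hidden)] <-
    b[1, (n_hidden + 1):(2 * n_hidden)] + 1
  list(Wx = u(n_input, 4 * n_hidden),
       Wh = u(n_hidden, 4 * n_hidden),
       b = b,
       Wy = u(n_hidden, n_output),
       by = matrix(stats::runif(n_output, -k, k), 1),
       n_input = n_input, n_hidden = n_hidden, n_output = n_output)
}

# x_steps: list of T matrices, each N x n_input.
# Returns predictions (N x n_output) plus caches for BPTT / interpretation.
lstm_forward <- function(w, x_steps, keep_cache = TRUE) {
  N <- nrow(x_steps[[1]])
  H <- w$n_hidden
  Tn <- length(x_steps)
  h <- matrix(0, N, H)
  c_state <- matrix(0, N, H)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  idx_i <- 1:H; idx_f <- (H + 1):(2 * H)
  idx_g <- (2 * H + 1):(3 * H); idx_o <- (3 * H + 1):(4 * H)
  ones_b <- matrix(1, N, 1)
  for (t in seq_len(Tn)) {
    a <- x_steps[[t]] %*% w$Wx + h %*% w$Wh + ones_b %*% w$b
    gi <- sigmoid(a[, idx_i, drop = FALSE])
    gf <- sigmoid(a[, idx_f, drop = FALSE])
    gg <- tanh(a[, idx_g, drop = FALSE])
    go <- sigmoid(a[, idx_o, drop = FALSE])
    c_prev <- c_state
    c_state <- gf * c_prev + gi * gg
    tc <- tanh(c_state)
    h_prev <- h
    h <- go * tc
    if (keep_cache) {
      cache[[t]] <- list(gi = gi, gf = gf, gg = gg, go = go,
                         c_prev = c_prev, tc = tc, h_prev = h_prev, h = h,
                         c_state = c_state)
    }
  }
  pred <- h %*% w$Wy + ones_b %*% w$by
  list(pred = pred, h_last = h, cache = cache)
}

# dpred: N x n_output gradient of the loss w.r.t. predictions.
lstm_backward <- function(w, x_steps, fwd, dpred) {
  N <- nrow(dpred)
  H <- w$n_hidden
  Tn <- length(x_steps)
  g <- list(Wx = 0 * w$Wx, Wh = 0 * w$Wh, b = 0 * w$b,
            Wy = 0 * w$Wy, by = 0 * w$by)
  g$Wy <- t(fwd$h_last) %*% dpred
  g$by <- matrix(colSums(dpred), 1)
  dh <- dpred %*% t(w$Wy)
  dc <- matrix(0, N, H)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    dgo <- dh * cc$tc
    dc <- dc + dh * cc$go * (1 - cc$tc^2)
    dgi <- dc * cc$gg
    dgg <- dc * cc$gi
    dgf <- dc * cc$c_prev
    dc <- dc * cc$gf
    da <- cbind(dgi * cc$gi * (1 - cc$gi),
                dgf * cc$gf * (1 - cc$gf),
                dgg * (1 - cc$gg^2),
                dgo * cc$go * (1 - cc$go))
    g$Wx <- g$Wx + t(x_steps[[t]]) %*% da
    g$Wh <- g$Wh + t(cc$h_prev) %*% da
    g$b <- g$b + matrix(colSums(da), 1)
    dh <- da %*% t(w$Wh)
  }
  g
}

adam_init <- function(w) {
  nm <- c("Wx", "Wh", "b", "Wy", "by")
  list(m = lapply(w[nm], function(p) 0 * p),
       v = lapply(w[nm], function(p) 0 * p),
       t = 0L)
}

adam_step <- function(w, grads, state, lr, beta1, beta2, epsilon,
                      clip_norm = NULL) {
  nm <- names(state$m)
  if (!is.null(clip_norm)) {
    gn <- sqrt(sum(vapply(nm, function(p) sum(grads[[p]]^2), numeric(1))))
    if (is.finite(gn) && gn > clip_norm) {
      grads[nm] <- lapply(grads[nm], function(gp) gp * (clip_norm / gn))
    }
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (p in nm) {
    state$m[[p]] <- beta1 * state$m[[p]] + (1 - beta1) * grads[[p]]
    state$v[[p]] <- beta2 * state$v[[p]] + (1 - beta2) * grads[[p]]^2
    mhat <- state$m[[p]] / bc1
    vhat <- state$v[[p]] / bc2
    w[[p]] <- w[[p]] - lr * mhat / (sqrt(vhat) + epsilon)
  }
  list(w = w, state = state)
}

# slice an N x T x C array into a list of T (N x C) matrices
array_to_steps <- function(x) {
  Tn <- dim(x)[2]
  lapply(seq_len(Tn), function(t) {
    m <- x[, t, , drop = FALSE]
    dim(m) <- dim(x)[c(1, 3)]
    m
  })
}
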