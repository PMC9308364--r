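# Shared neural-network primitives: a seeded one-hidden-layer perceptron used
# as the landmark agent's action scorer, softmax cross-entropy, and an Adam
# optimizer operating on flat lists of numeric arrays. All randomness goes
# through R's RNG so results are reproducible from a seed.

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), `-`)
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

# mean cross-entropy of one-hot targets (labels 1-based) under column softmax
xent_cols <- function(z, labels) {
  p <- softmax_cols(z)
  -mean(log(pmax(p[cbind(labels, seq_along(labels))], 1e-12)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

mlp_init <- function(d_in, d_hidden, d_out) {
  # He-scaled initialization; caller is responsible for seeding the RNG
  list(W1 = matrix(rnorm(d_hidden * d_in, sd = sqrt(2 / d_in)), d_hidden, d_in),
       b1 = numeric(d_hidden),
       W2 = matrix(rnorm(d_out * d_hidden, sd = sqrt(2 / d_hidden)), d_out, d_hidden),
       b2 = numeric(d_out))
}

# X: d_in x n (columns are samples); returns d_out x n scores
mlp_forward <- function(par, X) {
  h <- pmax(par$W1 %*% X + par$b1, 0)
  par$W2 %*% h + par$b2
}

# full-batch Adam training of softmax cross-entropy; labels 1-based
mlp_train <- function(par, X, labels, epochs = 150, lr = 1e-3, batch = 256) {
  n <- ncol(X)
  st <- adam_init(par)
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = batch)) {
      sel <- ord[start:min(n, start + batch - 1)]
      Xb <- X[, sel, drop = FALSE]
      yb <- labels[sel]
      h_pre <- par$W1 %*% Xb + par$b1
      h <- pmax(h_pre, 0)
      z <- par$W2 %*% h + par$b2
      p <- softmax_cols(z)
      tot <- tot - sum(log(pmax(p[cbind(yb, seq_along(yb))], 1e-12)))
      dz <- p
      dz[cbind(yb, seq_along(yb))] <- dz[cbind(yb, seq_along(yb))] - 1
      dz <- dz / length(sel)
      gW2 <- dz %*% t(h)
      gb2 <- rowSums(dz)
      dh <- t(par$W2) %*% dz
      dh[h_pre <= 0] <- 0
      gW1 <- dh %*% t(Xb)
      gb1 <- rowSums(dh)
      upd <- adam_step(par, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2), st, lr = lr)
      par <- upd$params
      st <- upd$state
    }
    loss[ep] <- tot / n
  }
  list(par = par, loss = loss)
}
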