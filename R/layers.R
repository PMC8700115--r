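# Layer primitives for the attention BiLSTM network.
#
# Conventions: a batch of windows is a B x S x D array (batch, time,
# channels). Flattening the first two dims with matrix(X, B*S, D) keeps
# column-major order consistent between forward and backward passes.
# All backward functions take the upstream gradient and a forward cache and
# return gradients for inputs and parameters.

sigmoid <- function(x) 1 / (1 + exp(-x))

# symmetric uniform fan-based initialisation (Glorot)
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# slice timestep t of a B x S x D array as a B x D matrix
slice_t <- function(X, t) {
  d <- dim(X)
  out <- X[, t, , drop = FALSE]
  dim(out) <- c(d[1], d[3])
  out
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

## ---- single-direction LSTM -------------------------------------------------

# gate order in the 4H-wide weight matrices: input, forget, candidate, output
lstm_init <- function(input_dim, units) {
  H <- units
  b <- numeric(4 * H)
  b[H + seq_len(H)] <- 1            # forget-gate bias at 1: remember early
  list(Wx = glorot(input_dim, 4 * H), Wh = glorot(H, 4 * H), b = b)
}

# X: B x S x d. Returns per-timestep hidden states and a cache for backprop.
# reverse = TRUE processes time back-to-front (states still stored at their
# own timestep, so H[, t, ] is always the state emitted for timestep t).
lstm_forward <- function(X, p, reverse = FALSE) {
  d <- dim(X)
  B <- d[1]; S <- d[2]
  H <- nrow(p$Wh)
  ord <- if (reverse) rev(seq_len(S)) else seq_len(S)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Ig <- array(0, c(B, S, H)); Fg <- array(0, c(B, S, H))
  Gg <- array(0, c(B, S, H)); Og <- array(0, c(B, S, H))
  Cs <- array(0, c(B, S, H)); Hs <- array(0, c(B, S, H))
  iH <- seq_len(H)
  for (t in ord) {
    xt <- slice_t(X, t)
    z <- add_bias(xt %*% p$Wx + h %*% p$Wh, p$b)
    i <- sigmoid(z[, iH, drop = FALSE])
    f <- sigmoid(z[, H + iH, drop = FALSE])
    g <- tanh(z[, 2 * H + iH, drop = FALSE])
    o <- sigmoid(z[, 3 * H + iH, drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    Ig[, t, ] <- i; Fg[, t, ] <- f; Gg[, t, ] <- g; Og[, t, ] <- o
    Cs[, t, ] <- cc; Hs[, t, ] <- h
  }
  list(H = Hs,
       cache = list(X = X, Ig = Ig, Fg = Fg, Gg = Gg, Og = Og, Cs = Cs,
                    Hs = Hs, ord = ord, units = H))
}

# dH: B x S x H upstream gradient on every timestep's emitted state.
lstm_backward <- function(dH, p, cache) {
  X <- cache$X; ord <- cache$ord; H <- cache$units
  d <- dim(X)
  B <- d[1]; S <- d[2]; din <- d[3]
  dWx <- matrix(0, din, 4 * H); dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dX <- array(0, dim = d)
  dh_carry <- matrix(0, B, H); dc <- matrix(0, B, H)
  for (k in rev(seq_len(S))) {
    t <- ord[k]
    i <- cache$Ig[, t, , drop = FALSE]; dim(i) <- c(B, H)
    f <- cache$Fg[, t, , drop = FALSE]; dim(f) <- c(B, H)
    g <- cache$Gg[, t, , drop = FALSE]; dim(g) <- c(B, H)
    o <- cache$Og[, t, , drop = FALSE]; dim(o) <- c(B, H)
    cc <- cache$Cs[, t, , drop = FALSE]; dim(cc) <- c(B, H)
    if (k > 1) {
      tp <- ord[k - 1]
      c_prev <- cache$Cs[, tp, , drop = FALSE]; dim(c_prev) <- c(B, H)
      h_prev <- cache$Hs[, tp, , drop = FALSE]; dim(h_prev) <- c(B, H)
    } else {
      c_prev <- matrix(0, B, H); h_prev <- matrix(0, B, H)
    }
    dh <- slice_t(dH, t) + dh_carry
    tc <- tanh(cc)
    do_ <- dh * tc
    dcc <- dc + dh * o * (1 - tc^2)
    df <- dcc * c_prev
    di <- dcc * g
    dg <- dcc * i
    dc <- dcc * f
    dz <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do_ * o * (1 - o))
    xt <- slice_t(X, t)
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(p$Wx)
    dh_carry <- dz %*% t(p$Wh)
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## ---- bidirectional LSTM ----------------------------------------------------

bilstm_init <- function(input_dim, units, combine = "concat") {
  p <- list(fwd = lstm_init(input_dim, units),
            rev = lstm_init(input_dim, units))
  if (combine == "sum") {
    p$wo1 <- 1
    p$wo2 <- 1
  }
  p
}

bilstm_out_dim <- function(units, combine) {
  if (combine == "concat") 2L * units else units
}

bilstm_forward <- function(X, p, combine = "concat") {
  fw <- lstm_forward(X, p$fwd, reverse = FALSE)
  rv <- lstm_forward(X, p$rev, reverse = TRUE)
  d <- dim(fw$H)
  if (combine == "concat") {
    out <- array(0, c(d[1], d[2], 2 * d[3]))
    out[, , seq_len(d[3])] <- fw$H
    out[, , d[3] + seq_len(d[3])] <- rv$H
    cache <- list(fw = fw$cache, rv = rv$cache, combine = combine)
  } else {
    pre <- p$wo1 * fw$H + p$wo2 * rv$H
    out <- tanh(pre)
    cache <- list(fw = fw$cache, rv = rv$cache, combine = combine,
                  out = out, Hf = fw$H, Hr = rv$H)
  }
  list(out = out, cache = cache)
}

bilstm_backward <- function(dOut, p, cache) {
  if (cache$combine == "concat") {
    H <- dim(dOut)[3] / 2
    dHf <- dOut[, , seq_len(H), drop = FALSE]
    dHr <- dOut[, , H + seq_len(H), drop = FALSE]
    extra <- NULL
  } else {
    dpre <- dOut * (1 - cache$out^2)
    dHf <- p$wo1 * dpre
    dHr <- p$wo2 * dpre
    extra <- list(wo1 = sum(dpre * cache$Hf), wo2 = sum(dpre * cache$Hr))
  }
  bf <- lstm_backward(dHf, p$fwd, cache$fw)
  br <- lstm_backward(dHr, p$rev, cache$rv)
  grads <- list(fwd = bf$grads, rev = br$grads)
  if (!is.null(extra)) grads <- c(grads, extra)
  list(dX = bf$dX + br$dX, grads = grads)
}

## ---- batch normalisation ---------------------------------------------------

bn_init <- function(dim) {
  list(gamma = rep(1, dim), beta = rep(0, dim))
}

bn_state_init <- function(dim) {
  list(mean = rep(0, dim), var = rep(1, dim))
}

# Normalises per channel. Sequence input (B x S x D): statistics pooled over
# batch x time. Vector input (B x D): over the batch. Training uses batch
# statistics and updates the running estimates; inference uses running
# statistics, which also makes prediction batch-size invariant.
bn_forward <- function(X, p, state, training, momentum = 0.99, eps = 1e-5) {
  is_seq <- length(dim(X)) == 3L
  d <- dim(X)
  M <- if (is_seq) matrix(X, d[1] * d[2], d[3]) else X
  n <- nrow(M)
  if (training) {
    mu <- colMeans(M)
    ctr <- M - rep(mu, each = n)
    va <- colMeans(ctr * ctr)          # biased, as is standard for BN
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean
    va <- state$var
    ctr <- M - rep(mu, each = n)
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- ctr * rep(inv_sd, each = n)
  Y <- xhat * rep(p$gamma, each = n) + rep(p$beta, each = n)
  if (is_seq) dim(Y) <- d
  list(out = Y, state = state,
       cache = list(xhat = xhat, inv_sd = inv_sd, dims = d, is_seq = is_seq,
                    n = n))
}

bn_backward <- function(dY, p, cache) {
  n <- cache$n
  dM <- if (cache$is_seq) matrix(dY, n, cache$dims[3]) else dY
  xhat <- cache$xhat
  dgamma <- colSums(dM * xhat)
  dbeta <- colSums(dM)
  dxhat <- dM * rep(p$gamma, each = n)
  # compact batch-statistics backprop (biased variance)
  t1 <- dxhat - rep(colMeans(dxhat), each = n) -
    xhat * rep(colMeans(dxhat * xhat), each = n)
  dX <- t1 * rep(cache$inv_sd, each = n)
  if (cache$is_seq) dim(dX) <- cache$dims
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- temporal attention ----------------------------------------------------

attn_init <- function(input_dim, attn_dim) {
  list(Ww = glorot(input_dim, attn_dim),
       b = numeric(attn_dim),
       uw = stats::runif(attn_dim, -sqrt(6 / (attn_dim + 1)),
                         sqrt(6 / (attn_dim + 1))))
}

# X: B x S x d. Projection u_t = tanh(X_t Ww + b); score s_t = <u_t, u_w>;
# a = softmax over time. pool = TRUE returns the context vector
# v = sum_t a_t X_t (B x d); pool = FALSE keeps the time axis and returns the
# re-weighted sequence a_t * X_t so a recurrent layer can follow.
attn_forward <- function(X, p, pool = TRUE) {
  d <- dim(X)
  B <- d[1]; S <- d[2]; din <- d[3]
  M <- matrix(X, B * S, din)
  U <- tanh(add_bias(M %*% p$Ww, p$b))
  scores <- matrix(U %*% p$uw, B, S)
  scores <- scores - apply(scores, 1, max)
  E <- exp(scores)
  A <- E / rowSums(E)
  if (pool) {
    out <- matrix(0, B, din)
    for (t in seq_len(S)) out <- out + A[, t] * slice_t(X, t)
  } else {
    out <- array(0, d)
    for (t in seq_len(S)) out[, t, ] <- A[, t] * slice_t(X, t)
  }
  list(out = out, weights = A,
       cache = list(X = X, M = M, U = U, A = A, pool = pool, dims = d))
}

attn_backward <- function(dOut, p, cache) {
  d <- cache$dims
  B <- d[1]; S <- d[2]; din <- d[3]
  A <- cache$A
  dX <- array(0, d)
  dA <- matrix(0, B, S)
  if (cache$pool) {
    for (t in seq_len(S)) {
      Xt <- slice_t(cache$X, t)
      dA[, t] <- rowSums(dOut * Xt)
      dX[, t, ] <- A[, t] * dOut
    }
  } else {
    for (t in seq_len(S)) {
      Xt <- slice_t(cache$X, t)
      dYt <- slice_t(dOut, t)
      dA[, t] <- rowSums(dYt * Xt)
      dX[, t, ] <- A[, t] * dYt
    }
  }
  # softmax backward, rowwise over time
  dS <- A * (dA - rowSums(A * dA))
  ds_flat <- as.vector(dS)             # (B*S), matches rows of M/U
  duw <- as.vector(crossprod(cache$U, ds_flat))
  dU <- outer(ds_flat, p$uw)
  dpre <- dU * (1 - cache$U^2)
  dWw <- crossprod(cache$M, dpre)
  db <- colSums(dpre)
  dM <- dpre %*% t(p$Ww)
  dX <- dX + array(dM, d)
  list(dX = dX, grads = list(Ww = dWw, b = db, uw = duw))
}

## ---- dense + softmax -------------------------------------------------------

dense_init <- function(input_dim, n_classes) {
  list(W = glorot(input_dim, n_classes), b = numeric(n_classes))
}

dense_forward <- function(V, p) {
  logits <- add_bias(V %*% p$W, p$b)
  logits <- logits - apply(logits, 1, max)
  E <- exp(logits)
  P <- E / rowSums(E)
  list(out = P, cache = list(V = V))
}

# y: 0-based integer labels. Returns mean cross-entropy and dV.
dense_backward_ce <- function(P, y, p, cache) {
  B <- nrow(P)
  Y <- matrix(0, B, ncol(P))
  Y[cbind(seq_len(B), y + 1L)] <- 1
  dlogits <- (P - Y) / B
  list(dV = dlogits %*% t(p$W),
       grads = list(W = crossprod(cache$V, dlogits), b = colSums(dlogits)))
}

cross_entropy <- function(P, y, eps = 1e-12) {
  B <- nrow(P)
  -mean(log(pmax(P[cbind(seq_len(B), y + 1L)], eps)))
}
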