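# Minimal 1D convolutional network engine.
#
# Activations are either 3D arrays dim (N, L, C) — batch, length, channels —
# or plain N x D matrices after flattening. All forward functions return
# list(out, cache); backward functions consume the cache and the upstream
# gradient and return the input gradient plus parameter gradients. Training
# is plain reverse-mode differentiation over a sequential stage list; no
# external autodiff framework is involved.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

# ---- conv1d (stride 1, "same" padding) ------------------------------------

# X (N,L,Cin), W (K,Cin,Cout), b length Cout or NULL.
conv1d_fw <- function(X, W, b) {
  d <- dim(X); N <- d[1]; L <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  pl <- (K - 1L) %/% 2L
  Lp <- L + K - 1L
  Xp <- array(0, c(N, Lp, Cin))
  Xp[, pl + seq_len(L), ] <- X
  out <- matrix(0, N * L, Cout)
  for (k in seq_len(K)) {
    m <- matrix(Xp[, k:(k + L - 1L), , drop = FALSE], N * L, Cin)
    out <- out + m %*% matrix(W[k, , ], Cin, Cout)
  }
  if (!is.null(b)) out <- out + rep(b, each = N * L)
  list(out = array(out, c(N, L, Cout)), cache = list(Xp = Xp, dims = d))
}

conv1d_bw <- function(cache, W, dOut) {
  d <- cache$dims; N <- d[1]; L <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  pl <- (K - 1L) %/% 2L
  dmat <- matrix(dOut, N * L, Cout)
  dW <- array(0, dim(W))
  dXp <- array(0, dim(cache$Xp))
  for (k in seq_len(K)) {
    idx <- k:(k + L - 1L)
    m <- matrix(cache$Xp[, idx, , drop = FALSE], N * L, Cin)
    dW[k, , ] <- crossprod(m, dmat)
    dXp[, idx, ] <- array(dXp[, idx, , drop = FALSE], c(N, L, Cin)) +
      array(dmat %*% t(matrix(W[k, , ], Cin, Cout)), c(N, L, Cin))
  }
  list(dX = dXp[, pl + seq_len(L), , drop = FALSE],
       dW = dW, db = colSums(dmat))
}

# ---- batch normalization over (N, L) per channel ---------------------------

bn_fw <- function(X, gamma, beta, rmean, rvar, training) {
  d <- dim(X); C <- d[3]
  M <- matrix(X, d[1] * d[2], C)
  if (training) {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    new_rmean <- BN_MOMENTUM * rmean + (1 - BN_MOMENTUM) * mu
    new_rvar <- BN_MOMENTUM * rvar + (1 - BN_MOMENTUM) * v
  } else {
    mu <- rmean; v <- rvar
    new_rmean <- rmean; new_rvar <- rvar
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- (M - rep(mu, each = nrow(M))) * rep(inv_sd, each = nrow(M))
  out <- xhat * rep(gamma, each = nrow(M)) + rep(beta, each = nrow(M))
  list(out = array(out, d),
       cache = list(xhat = xhat, inv_sd = inv_sd, dims = d,
                    training = training),
       rmean = new_rmean, rvar = new_rvar)
}

bn_bw <- function(cache, gamma, dOut) {
  d <- cache$dims
  n <- d[1] * d[2]
  dM <- matrix(dOut, n, d[3])
  dgamma <- colSums(dM * cache$xhat)
  dbeta <- colSums(dM)
  if (cache$training) {
    # dX = gamma*inv_sd * (dY - mean(dY) - xhat*mean(dY*xhat)) per channel
    dX <- (dM - rep(dbeta / n, each = n) -
             cache$xhat * rep(dgamma / n, each = n)) *
      rep(gamma * cache$inv_sd, each = n)
  } else {
    dX <- dM * rep(gamma * cache$inv_sd, each = n)
  }
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations -----------------------------------------------------------

act_fw <- function(X, act) {
  out <- switch(act,
                relu = pmax(X, 0),
                sigmoid = 1 / (1 + exp(-X)),
                linear = X)
  list(out = out, cache = out)
}

act_bw <- function(cache, act, dOut) {
  switch(act,
         relu = dOut * (cache > 0),
         sigmoid = dOut * cache * (1 - cache),
         linear = dOut)
}

# ---- dense -----------------------------------------------------------------

dense_fw <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), cache = X)
}

dense_bw <- function(cache, W, dOut) {
  list(dX = dOut %*% t(W), dW = crossprod(cache, dOut),
       db = colSums(dOut))
}

# ---- dropout ---------------------------------------------------------------

dropout_fw <- function(X, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = X, cache = NULL))
  }
  mask <- array(stats::runif(length(X)) >= rate, dim(X) %||% length(X)) /
    (1 - rate)
  list(out = X * mask, cache = mask)
}

dropout_bw <- function(cache, dOut) {
  if (is.null(cache)) dOut else dOut * cache
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- pooling (stride = pool width, valid) ----------------------------------

pool_fw <- function(X, pool, type) {
  d <- dim(X); N <- d[1]; L <- d[2]; C <- d[3]
  Lout <- L %/% pool
  Xt <- X[, seq_len(Lout * pool), , drop = FALSE]
  Xr <- array(Xt, c(N, pool, Lout, C))
  if (type == "avg") {
    out <- array(0, c(N, Lout, C))
    for (i in seq_len(pool)) {
      out <- out + array(Xr[, i, , , drop = FALSE], c(N, Lout, C))
    }
    out <- out / pool
    return(list(out = out, cache = list(dims = d, Lout = Lout)))
  }
  cur <- array(Xr[, 1, , , drop = FALSE], c(N, Lout, C))
  idx <- array(1L, c(N, Lout, C))
  for (i in seq.int(2, pool)) {
    cand <- array(Xr[, i, , , drop = FALSE], c(N, Lout, C))
    better <- cand > cur
    better[is.na(better)] <- FALSE # NaN inputs propagate via the first slot
    cur[better] <- cand[better]
    idx[better] <- i
  }
  list(out = cur, cache = list(dims = d, Lout = Lout, idx = idx))
}

pool_bw <- function(cache, pool, type, dOut) {
  d <- cache$dims; N <- d[1]; L <- d[2]; C <- d[3]
  Lout <- cache$Lout
  dXr <- array(0, c(N, pool, Lout, C))
  if (type == "avg") {
    for (i in seq_len(pool)) dXr[, i, , ] <- dOut / pool
  } else {
    for (i in seq_len(pool)) {
      sel <- cache$idx == i
      tmp <- array(0, c(N, Lout, C))
      tmp[sel] <- dOut[sel]
      dXr[, i, , ] <- tmp
    }
  }
  dX <- array(0, d)
  dX[, seq_len(Lout * pool), ] <- array(dXr, c(N, Lout * pool, C))
  dX
}

# max pooling with window 3, stride 1, same padding (Inception pool branch)
maxpool_same3_fw <- function(X) {
  d <- dim(X); N <- d[1]; L <- d[2]; C <- d[3]
  pad <- array(-Inf, c(N, L + 2L, C))
  pad[, 1L + seq_len(L), ] <- X
  cur <- pad[, seq_len(L), , drop = FALSE]
  idx <- array(1L, c(N, L, C))
  for (i in 2:3) {
    cand <- pad[, (i - 1L) + seq_len(L), , drop = FALSE]
    better <- cand > cur
    better[is.na(better)] <- FALSE
    cur[better] <- cand[better]
    idx[better] <- i
  }
  list(out = array(cur, c(N, L, C)), cache = list(dims = d, idx = idx))
}

maxpool_same3_bw <- function(cache, dOut) {
  d <- cache$dims; N <- d[1]; L <- d[2]; C <- d[3]
  dpad <- array(0, c(N, L + 2L, C))
  for (i in 1:3) {
    sel <- cache$idx == i
    tmp <- array(0, c(N, L, C))
    tmp[sel] <- dOut[sel]
    dpad[, (i - 1L) + seq_len(L), ] <-
      array(dpad[, (i - 1L) + seq_len(L), , drop = FALSE], c(N, L, C)) + tmp
  }
  dpad[, 1L + seq_len(L), , drop = FALSE]
}

# ---- global average pooling & flatten --------------------------------------

gap_fw <- function(X) {
  d <- dim(X)
  M <- matrix(aperm(X, c(2, 1, 3)), d[2], d[1] * d[3])
  list(out = matrix(colMeans(M), d[1], d[3]), cache = d)
}

gap_bw <- function(cache, dOut) {
  d <- cache
  g <- array(0, c(d[2], d[1], d[3]))
  for (l in seq_len(d[2])) g[l, , ] <- dOut / d[2]
  aperm(g, c(2, 1, 3))
}

flatten_fw <- function(X) {
  d <- dim(X)
  # channel-major flattening: columns are (position within channel 1,
  # ..., channel C); matches matrix(X, N, L*C) since dim order is (N,L,C)
  list(out = matrix(X, d[1], d[2] * d[3]), cache = d)
}

flatten_bw <- function(cache, dOut) array(dOut, cache)

# ---- softmax / cross-entropy ----------------------------------------------

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and gradient w.r.t. logits; onehot is N x C
xent_loss <- function(logits, onehot) {
  z <- logits - apply(logits, 1, max)
  lse <- log(rowSums(exp(z)))
  loss <- mean(rowSums(onehot * (lse - z)))
  p <- exp(z - lse)
  list(loss = loss, dlogits = (p - onehot) / nrow(logits))
}
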