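# Low-level neural-network primitives for the 1-D multi-scale networks.
#
# Activations are stored as (batch, length, channels) arrays so per-channel
# statistics reduce to column operations on matrix(A, B*L, C), and same-padded
# convolutions become one im2col gather followed by a BLAS matmul. Gather
# index matrices are cached per (B, L, C, k) shape.

.nn_cache <- new.env(parent = emptyenv())

conv_gather_idx <- function(B, L, C, k) {
  key <- paste(B, L, C, k, sep = "_")
  idx <- .nn_cache[[key]]
  if (!is.null(idx)) return(idx)
  Lp <- L + k - 1L
  bt <- rep(seq_len(B), times = L)                  # batch index, fastest
  tv <- rep(seq_len(L), each = B)                   # output position
  idx <- matrix(0L, B * L, k * C)
  for (c in seq_len(C)) {
    base <- (c - 1L) * B * Lp
    for (j in seq_len(k)) {
      idx[, (c - 1L) * k + j] <- bt + (tv + j - 2L) * B + base
    }
  }
  .nn_cache[[key]] <- idx
  idx
}

# Same-padded 1-D convolution. A: (B, L, Cin); W: (k*Cin, Cout); b: (Cout).
conv1d_forward <- function(A, W, b, k) {
  d <- dim(A); B <- d[1]; L <- d[2]; Cin <- d[3]
  pad <- (k - 1L) %/% 2L
  Apad <- array(0, dim = c(B, L + k - 1L, Cin))
  Apad[, pad + seq_len(L), ] <- A
  idx <- conv_gather_idx(B, L, Cin, k)
  M <- Apad[idx]
  dim(M) <- dim(idx)
  Y <- M %*% W
  Y <- sweep(Y, 2, b, "+")
  dim(Y) <- c(B, L, ncol(W))
  list(out = Y, cache = list(M = M, idx = idx, k = k, dimA = d, W = W))
}

conv1d_backward <- function(dY, cache) {
  d <- cache$dimA; B <- d[1]; L <- d[2]; Cin <- d[3]
  k <- cache$k
  pad <- (k - 1L) %/% 2L
  dY2 <- matrix(dY, B * L, dim(cache$W)[2])
  dW <- crossprod(cache$M, dY2)
  db <- colSums(dY2)
  dM <- tcrossprod(dY2, cache$W)
  # col2im scatter-add: column (j, c) of dM maps onto padded positions
  # j..j+L-1 of channel c, one contiguous slice-add per kernel offset
  dim(dM) <- c(B, L, k, Cin)
  dApad <- array(0, dim = c(B, L + k - 1L, Cin))
  for (j in seq_len(k)) {
    sl <- dM[, , j, ]
    dim(sl) <- c(B, L, Cin)
    dApad[, j:(j + L - 1L), ] <- dApad[, j:(j + L - 1L), , drop = FALSE] + sl
  }
  dA <- dApad[, pad + seq_len(L), , drop = FALSE]
  list(dA = dA, dW = dW, db = db)
}

relu_forward <- function(A) {
  out <- A
  out[out < 0] <- 0
  list(out = out, cache = A > 0)
}

relu_backward <- function(dY, cache) dY * cache

# Batch normalization over (batch x length) per channel. `state` carries
# gamma, beta, run_mean, run_var; biased batch variance, momentum 0.1.
bn_forward <- function(A, state, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(A); C <- d[3]
  Am <- matrix(A, d[1] * d[2], C)
  if (training) {
    mu <- colMeans(Am)
    v <- colMeans(Am^2) - mu^2
    v[v < 0] <- 0
    state$run_mean <- (1 - momentum) * state$run_mean + momentum * mu
    state$run_var <- (1 - momentum) * state$run_var + momentum * v
  } else {
    mu <- state$run_mean
    v <- state$run_var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(Am, 2, mu), 2, inv_std, "*")
  out <- sweep(sweep(xhat, 2, state$gamma, "*"), 2, state$beta, "+")
  dim(out) <- d
  list(out = out, state = state,
       cache = list(xhat = xhat, inv_std = inv_std, dimA = d,
                    gamma = state$gamma, training = training))
}

bn_backward <- function(dY, cache) {
  d <- cache$dimA
  N <- d[1] * d[2]
  dYm <- matrix(dY, N, d[3])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  if (cache$training) {
    t1 <- sweep(dYm, 2, colMeans(dYm))
    t2 <- sweep(cache$xhat, 2, colSums(dYm * cache$xhat) / N, "*")
    dX <- sweep(t1 - t2, 2, cache$gamma * cache$inv_std, "*")
  } else {
    dX <- sweep(dYm, 2, cache$gamma * cache$inv_std, "*")
  }
  dim(dX) <- d
  list(dA = dX, dgamma = dgamma, dbeta = dbeta)
}

# Max pooling, size 2 stride 2; an odd trailing position is dropped.
maxpool2_forward <- function(A) {
  d <- dim(A); L2 <- d[2] %/% 2L
  i1 <- seq(1L, 2L * L2, by = 2L)
  A1 <- A[, i1, , drop = FALSE]
  A2 <- A[, i1 + 1L, , drop = FALSE]
  take1 <- A1 >= A2
  out <- ifelse(take1, A1, A2)
  dim(out) <- c(d[1], L2, d[3])
  list(out = out, cache = list(take1 = take1, dimA = d, i1 = i1))
}

maxpool2_backward <- function(dY, cache) {
  d <- cache$dimA
  dA <- array(0, dim = d)
  dA[, cache$i1, ] <- dY * cache$take1
  dA[, cache$i1 + 1L, ] <- dY * !cache$take1
  dA
}

# Adaptive average pooling to `P` output positions: output bin i averages
# input positions floor((i-1)L/P)+1 .. ceiling(iL/P). For L < P bins repeat
# positions (upsampling by duplication).
adaptive_pool_matrix <- function(L, P) {
  key <- paste("ap", L, P, sep = "_")
  S <- .nn_cache[[key]]
  if (!is.null(S)) return(S)
  S <- matrix(0, L, P)
  for (i in seq_len(P)) {
    s <- floor((i - 1) * L / P) + 1L
    e <- ceiling(i * L / P)
    S[s:e, i] <- 1 / (e - s + 1L)
  }
  .nn_cache[[key]] <- S
  S
}

adaptive_avgpool_forward <- function(A, P) {
  d <- dim(A)
  S <- adaptive_pool_matrix(d[2], P)
  Am <- matrix(aperm(A, c(2, 1, 3)), d[2], d[1] * d[3])
  Ym <- crossprod(S, Am)
  out <- aperm(array(Ym, c(P, d[1], d[3])), c(2, 1, 3))
  list(out = out, cache = list(S = S, dimA = d, P = P))
}

adaptive_avgpool_backward <- function(dY, cache) {
  d <- cache$dimA
  dYm <- matrix(aperm(dY, c(2, 1, 3)), cache$P, d[1] * d[3])
  dAm <- cache$S %*% dYm
  aperm(array(dAm, c(d[2], d[1], d[3])), c(2, 1, 3))
}

dense_forward <- function(X, W, b) {
  Y <- X %*% W
  Y <- sweep(Y, 2, b, "+")
  list(out = Y, cache = list(X = X, W = W))
}

dense_backward <- function(dY, cache) {
  list(dA = dY %*% t(cache$W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

he_init <- function(nrow_, ncol_, fan_in) {
  matrix(stats::rnorm(nrow_ * ncol_, sd = sqrt(2 / fan_in)), nrow_, ncol_)
}

bn_state_new <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C))
}
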