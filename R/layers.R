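# Internal layer math for the 1D multi-stream network.
#
# Activation layout: a batch is a dense matrix of shape (C * L) x n, where
# row (c - 1) * L + t holds channel c at time t (time fastest). Convolutions
# are evaluated as matrix products against an im2col gather realized once
# per layer as a sparse 0/1 matrix, so both the gather (G %*% X) and the
# scatter-add of the backward pass (t(G) %*% dcol) run in compiled code.

.conv_out_len <- function(L_in, K, stride, pad) {
  floor((L_in + 2 * pad - K) / stride) + 1L
}

.make_conv <- function(C_in, C_out, K, stride, L_in, pad = (K - 1) %/% 2) {
  L_out <- .conv_out_len(L_in, K, stride, pad)
  if (L_out < 1) {
    stop(sprintf("input length %d too short for kernel %d / stride %d",
                 L_in, K, stride), call. = FALSE)
  }
  t_out <- rep(seq_len(L_out), each = K * C_in)
  c_in <- rep(rep(seq_len(C_in), each = K), times = L_out)
  k <- rep(seq_len(K), times = C_in * L_out)
  t_in <- stride * (t_out - 1L) - pad + k
  row <- (t_out - 1L) * K * C_in + (c_in - 1L) * K + k
  ok <- t_in >= 1L & t_in <= L_in
  G <- Matrix::sparseMatrix(
    i = row[ok], j = (c_in[ok] - 1L) * L_in + t_in[ok], x = 1,
    dims = c(K * C_in * L_out, C_in * L_in)
  )
  fan_in <- C_in * K
  list(type = "conv", K = K, C_in = C_in, C_out = C_out, stride = stride,
       pad = pad, L_in = L_in, L_out = L_out, G = G,
       W = matrix(stats::rnorm(C_out * fan_in, sd = sqrt(2 / fan_in)),
                  C_out, fan_in),
       b = numeric(C_out))
}

.conv_forward <- function(ly, X) {
  n <- ncol(X)
  colf <- as.matrix(ly$G %*% X)
  dim(colf) <- c(ly$K * ly$C_in, ly$L_out * n)
  Y <- ly$W %*% colf + ly$b
  out <- matrix(aperm(array(Y, c(ly$C_out, ly$L_out, n)), c(2, 1, 3)),
                ly$C_out * ly$L_out, n)
  list(out = out, cache = list(colf = colf, n = n))
}

.conv_backward <- function(ly, cache, dOut) {
  n <- cache$n
  dY <- matrix(aperm(array(dOut, c(ly$L_out, ly$C_out, n)), c(2, 1, 3)),
               ly$C_out, ly$L_out * n)
  dW <- dY %*% t(cache$colf)
  db <- rowSums(dY)
  dcol <- crossprod(ly$W, dY)
  dim(dcol) <- c(ly$K * ly$C_in * ly$L_out, n)
  dX <- as.matrix(Matrix::crossprod(ly$G, dcol))
  list(dX = dX, grads = list(W = dW, b = db))
}

.make_bn <- function(C, L) {
  list(type = "bn", C = C, L = L, gamma = rep(1, C), beta = numeric(C),
       rmean = numeric(C), rvar = rep(1, C), mom = 0.1, eps = 1e-5)
}

.to_lnc <- function(X, L, C, n) {
  matrix(aperm(array(X, c(L, C, n)), c(1, 3, 2)), L * n, C)
}
.from_lnc <- function(Xr, L, C, n) {
  matrix(aperm(array(Xr, c(L, n, C)), c(1, 3, 2)), L * C, n)
}

.bn_forward <- function(ly, X, training) {
  n <- ncol(X)
  L <- ly$L; C <- ly$C
  Xr <- .to_lnc(X, L, C, n)
  m <- L * n
  if (training) {
    mu <- colMeans(Xr)
    xc <- Xr - matrix(mu, m, C, byrow = TRUE)
    v <- colMeans(xc * xc)
    ivar <- 1 / sqrt(v + ly$eps)
    xhat <- xc * matrix(ivar, m, C, byrow = TRUE)
    ly$rmean <- (1 - ly$mom) * ly$rmean + ly$mom * mu
    vu <- if (m > 1) v * m / (m - 1) else v
    ly$rvar <- (1 - ly$mom) * ly$rvar + ly$mom * vu
    cache <- list(xhat = xhat, ivar = ivar, n = n)
  } else {
    ivar <- 1 / sqrt(ly$rvar + ly$eps)
    xhat <- (Xr - matrix(ly$rmean, m, C, byrow = TRUE)) *
      matrix(ivar, m, C, byrow = TRUE)
    cache <- NULL
  }
  Yr <- xhat * matrix(ly$gamma, m, C, byrow = TRUE) +
    matrix(ly$beta, m, C, byrow = TRUE)
  list(out = .from_lnc(Yr, L, C, n), cache = cache, layer = ly)
}

.bn_backward <- function(ly, cache, dOut) {
  n <- cache$n
  L <- ly$L; C <- ly$C; m <- L * n
  dYr <- .to_lnc(dOut, L, C, n)
  xhat <- cache$xhat
  dgamma <- colSums(dYr * xhat)
  dbeta <- colSums(dYr)
  dxhat <- dYr * matrix(ly$gamma, m, C, byrow = TRUE)
  mean_dxhat <- matrix(colMeans(dxhat), m, C, byrow = TRUE)
  mean_dxhat_x <- matrix(colMeans(dxhat * xhat), m, C, byrow = TRUE)
  dXr <- (dxhat - mean_dxhat - xhat * mean_dxhat_x) *
    matrix(cache$ivar, m, C, byrow = TRUE)
  list(dX = .from_lnc(dXr, L, C, n),
       grads = list(gamma = dgamma, beta = dbeta))
}

.relu_forward <- function(X) {
  list(out = pmax(X, 0), cache = X > 0)
}
.relu_backward <- function(cache, dOut) dOut * cache

.make_pool <- function(k, C, L_in) {
  L_out <- L_in %/% k
  if (L_out < 1) {
    stop(sprintf("input length %d too short for pool size %d", L_in, k),
         call. = FALSE)
  }
  list(type = "pool", k = k, C = C, L_in = L_in, L_out = L_out)
}

.pool_forward <- function(ly, X) {
  n <- ncol(X)
  k <- ly$k; L_in <- ly$L_in; L_out <- ly$L_out; C <- ly$C
  arr <- array(X, c(L_in, C, n))
  M <- matrix(arr[seq_len(k * L_out), , , drop = FALSE], nrow = k)
  w <- max.col(t(M), ties.method = "first")
  mx <- M[(seq_along(w) - 1L) * k + w]
  list(out = matrix(mx, L_out * C, n), cache = list(w = w, n = n))
}

.pool_backward <- function(ly, cache, dOut) {
  n <- cache$n
  k <- ly$k; L_in <- ly$L_in; L_out <- ly$L_out; C <- ly$C
  dM <- numeric(k * L_out * C * n)
  dM[(seq_along(cache$w) - 1L) * k + cache$w] <- as.vector(dOut)
  dXarr <- array(0, c(L_in, C, n))
  dXarr[seq_len(k * L_out), , ] <- array(dM, c(k * L_out, C, n))
  list(dX = matrix(dXarr, L_in * C, n))
}

# Global average pooling over time: (C * L) x n -> C x n.
.gap_forward <- function(X, L, C) {
  n <- ncol(X)
  out <- matrix(colMeans(matrix(X, L, C * n)), C, n)
  list(out = out, cache = n)
}
.gap_backward <- function(dOut, L, C, n) {
  matrix(rep(as.vector(dOut), each = L) / L, C * L, n)
}

.make_dense <- function(F_in, F_out, act_scale = 2) {
  list(type = "dense", F_in = F_in, F_out = F_out,
       W = matrix(stats::rnorm(F_out * F_in, sd = sqrt(act_scale / F_in)),
                  F_out, F_in),
       b = numeric(F_out))
}

.dense_forward <- function(ly, X) {
  list(out = ly$W %*% X + ly$b, cache = X)
}
.dense_backward <- function(ly, cache, dOut) {
  list(dX = crossprod(ly$W, dOut),
       grads = list(W = dOut %*% t(cache), b = rowSums(dOut)))
}
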