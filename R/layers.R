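# Low-level differentiable layers. Activations are stored channels-last:
# 2d feature maps as (N, L, D, C) arrays, 1d maps as (N, L, C). Each
# *_forward returns the output plus the cache its *_backward needs; the
# backward functions return gradients w.r.t. inputs and parameters.

# ---- 2d convolution, "same" padding -------------------------------------
# Kernel W is (Cin, l, d, Cout); padding ((l-1)/2, (d-1)/2) keeps the
# spatial shape, which requires odd l and d. Implemented as im2col + GEMM.

conv2d_forward <- function(x, W) {
  dims <- dim(x); N <- dims[1]; L <- dims[2]; D <- dims[3]; Cin <- dims[4]
  kd <- dim(W); l <- kd[2]; d <- kd[3]; Cout <- kd[4]
  pl <- (l - 1L) %/% 2L; pd <- (d - 1L) %/% 2L
  xp <- array(0, c(N, L + 2L * pl, D + 2L * pd, Cin))
  xp[, pl + seq_len(L), pd + seq_len(D), ] <- x
  cols <- matrix(0, N * L * D, Cin * l * d)
  for (b in seq_len(d)) for (a in seq_len(l)) {
    q0 <- Cin * ((a - 1L) + l * (b - 1L))
    cols[, q0 + seq_len(Cin)] <-
      xp[, a:(a + L - 1L), b:(b + D - 1L), , drop = FALSE]
  }
  # column order (ci, a, b) matches matrix(W, ncol = Cout) row order
  out <- array(cols %*% matrix(W, ncol = Cout), c(N, L, D, Cout))
  list(out = out, cols = cols, in_dim = dims)
}

conv2d_backward <- function(dout, cache, W) {
  dims <- cache$in_dim; N <- dims[1]; L <- dims[2]; D <- dims[3]; Cin <- dims[4]
  kd <- dim(W); l <- kd[2]; d <- kd[3]; Cout <- kd[4]
  pl <- (l - 1L) %/% 2L; pd <- (d - 1L) %/% 2L
  dout_mat <- matrix(dout, ncol = Cout)
  dW <- array(crossprod(cache$cols, dout_mat), dim(W))
  dcols <- tcrossprod(dout_mat, matrix(W, ncol = Cout))
  dxp <- array(0, c(N, L + 2L * pl, D + 2L * pd, Cin))
  for (b in seq_len(d)) for (a in seq_len(l)) {
    q0 <- Cin * ((a - 1L) + l * (b - 1L))
    dxp[, a:(a + L - 1L), b:(b + D - 1L), ] <-
      dxp[, a:(a + L - 1L), b:(b + D - 1L), , drop = FALSE] +
      array(dcols[, q0 + seq_len(Cin)], c(N, L, D, Cin))
  }
  dx <- dxp[, pl + seq_len(L), pd + seq_len(D), , drop = FALSE]
  list(dx = dx, dW = dW)
}

# ---- 1d convolution ------------------------------------------------------
conv1d_forward <- function(x, W) {
  dims <- dim(x); N <- dims[1]; L <- dims[2]; Cin <- dims[3]
  kd <- dim(W); l <- kd[2]; Cout <- kd[3]
  pl <- (l - 1L) %/% 2L
  xp <- array(0, c(N, L + 2L * pl, Cin))
  xp[, pl + seq_len(L), ] <- x
  cols <- matrix(0, N * L, Cin * l)
  for (a in seq_len(l)) {
    cols[, Cin * (a - 1L) + seq_len(Cin)] <-
      xp[, a:(a + L - 1L), , drop = FALSE]
  }
  out <- array(cols %*% matrix(W, ncol = Cout), c(N, L, Cout))
  list(out = out, cols = cols, in_dim = dims)
}

conv1d_backward <- function(dout, cache, W) {
  dims <- cache$in_dim; N <- dims[1]; L <- dims[2]; Cin <- dims[3]
  kd <- dim(W); l <- kd[2]; Cout <- kd[3]
  pl <- (l - 1L) %/% 2L
  dout_mat <- matrix(dout, ncol = Cout)
  dW <- array(crossprod(cache$cols, dout_mat), dim(W))
  dcols <- tcrossprod(dout_mat, matrix(W, ncol = Cout))
  dxp <- array(0, c(N, L + 2L * pl, Cin))
  for (a in seq_len(l)) {
    dxp[, a:(a + L - 1L), ] <- dxp[, a:(a + L - 1L), , drop = FALSE] +
      array(dcols[, Cin * (a - 1L) + seq_len(Cin)], c(N, L, Cin))
  }
  list(dx = dxp[, pl + seq_len(L), , drop = FALSE], dW = dW)
}

# ---- batch normalization -------------------------------------------------
# Operates per channel on an (M x C) matrix view of the activation (channels
# are the last array dimension, so matrix(x, ncol = C) groups correctly).
# Training mode normalizes by batch statistics (biased variance) and updates
# running estimates with momentum m; eval mode uses the running estimates.

bn_forward <- function(x, gamma, beta, state, mode, momentum = 0.1,
                       eps = 1e-5) {
  dims <- dim(x); C <- dims[length(dims)]
  xm <- matrix(x, ncol = C)
  if (mode == "train") {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    var <- colMeans(xc^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * var
  } else {
    mu <- state$mean
    var <- state$var
    xc <- sweep(xm, 2, mu)
  }
  inv_std <- 1 / sqrt(var + eps)
  xhat <- sweep(xc, 2, inv_std, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = array(out, dims), state = state,
       cache = list(xhat = xhat, inv_std = inv_std, dims = dims, mode = mode))
}

bn_backward <- function(dout, cache, gamma) {
  dims <- cache$dims; C <- dims[length(dims)]
  dm <- matrix(dout, ncol = C)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, gamma, "*")
  if (cache$mode == "train") {
    M <- nrow(dm)
    dx <- sweep(dxhat - matrix(colMeans(dxhat), M, C, byrow = TRUE) -
                  cache$xhat * matrix(colMeans(dxhat * cache$xhat), M, C,
                                      byrow = TRUE),
                2, cache$inv_std, "*")
  } else {
    dx <- sweep(dxhat, 2, cache$inv_std, "*")
  }
  list(dx = array(dx, dims), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations ---------------------------------------------------------
relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)

# Guided backpropagation additionally gates on the sign of the upstream
# gradient (only positive error signals flow through a ReLU).
relu_backward <- function(dout, mask, guided = FALSE) {
  d <- dout * mask
  if (guided) d <- d * (dout > 0)
  d
}

# ---- squeeze-excitation --------------------------------------------------
# Channel attention: z = global average over the spatial plane, gate =
# sigmoid(W2 ReLU(W1 z)), output = x scaled channel-wise by the gate.

se_forward <- function(x, W1, W2) {
  dims <- dim(x); N <- dims[1]; C <- dims[length(dims)]
  S <- prod(dims[-c(1, length(dims))])      # spatial size L*D (or L)
  xm <- matrix(x, nrow = N)                  # N x (S*C), channel-major blocks
  z <- matrix(0, N, C)
  for (c in seq_len(C)) z[, c] <- rowMeans(xm[, (c - 1L) * S + seq_len(S),
                                              drop = FALSE])
  u1 <- z %*% t(W1)
  a1 <- pmax(u1, 0)
  u2 <- a1 %*% t(W2)
  gate <- sigmoid(u2)                        # N x C
  # broadcast the gate over the spatial axis: (N, S, C) scale array
  sc <- aperm(array(gate, c(N, C, S)), c(1, 3, 2))
  out <- array(as.vector(array(x, c(N, S, C)) * sc), dims)
  list(out = out,
       cache = list(x = x, z = z, u1 = u1, a1 = a1, gate = gate,
                    dims = dims, S = S))
}

se_backward <- function(dout, cache, W1, W2) {
  dims <- cache$dims; N <- dims[1]; C <- dims[length(dims)]
  S <- cache$S
  d3 <- array(dout, c(N, S, C))
  x3 <- array(cache$x, c(N, S, C))
  sc <- aperm(array(cache$gate, c(N, C, S)), c(1, 3, 2))
  dx <- d3 * sc
  dgate <- matrix(0, N, C)
  for (c in seq_len(C)) dgate[, c] <- rowSums(d3[, , c, drop = FALSE] *
                                              x3[, , c, drop = FALSE])
  du2 <- dgate * cache$gate * (1 - cache$gate)
  dW2 <- crossprod(du2, cache$a1)
  da1 <- du2 %*% W2
  du1 <- da1 * (cache$u1 > 0)
  dW1 <- crossprod(du1, cache$z)
  dz <- du1 %*% W1                           # N x C
  dxz <- aperm(array(dz / S, c(N, C, S)), c(1, 3, 2))
  dx <- dx + dxz
  list(dx = array(as.vector(dx), dims), dW1 = dW1, dW2 = dW2)
}

# ---- average pooling over the depth axis ---------------------------------
# (N, L, D, C) -> (N, L, C); pools the 2d feature maps into 1d vectors.
avgpool_d_forward <- function(x) {
  dims <- dim(x); N <- dims[1]; L <- dims[2]; D <- dims[3]; C <- dims[4]
  out <- array(0, c(N, L, C))
  for (j in seq_len(D)) out <- out + array(x[, , j, ], c(N, L, C))
  list(out = out / D, D = D, dims = dims)
}

avgpool_d_backward <- function(dout, cache) {
  dims <- cache$dims
  dx <- array(0, dims)
  for (j in seq_len(cache$D)) dx[, , j, ] <- dout / cache$D
  dx
}

# ---- dropout (inverted) --------------------------------------------------
dropout_forward <- function(x, p, mode) {
  if (mode != "train" || p <= 0) return(list(out = x, mask = NULL))
  mask <- array((stats::runif(length(x)) > p) / (1 - p), dim(x))
  list(out = x * mask, mask = mask)
}

dropout_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# ---- fully connected -----------------------------------------------------
fc_forward <- function(x, W, b) {
  list(out = sweep(x %*% t(W), 2, b, "+"), x = x)
}

fc_backward <- function(dout, cache, W) {
  list(dx = dout %*% W, dW = crossprod(dout, cache$x), db = colSums(dout))
}
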