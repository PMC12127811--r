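# Independent brute-force oracles (plain loops, no shared code with the
# package's vectorized implementations) plus a finite-difference gradient
# checker.

agv <- gliotyper:::agv

# direct triple-loop 3D convolution
bruteConv3d <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(x); k <- dim(W)[1:3]; cin <- dim(W)[4]; cout <- dim(W)[5]
  xp <- array(0, d[1:3] + 2L * pad)
  od <- (d[1:3] + 2L * pad - k) %/% stride + 1L
  out <- array(0, c(od, cout))
  for (co in seq_len(cout)) for (oz in seq_len(od[3]))
    for (oy in seq_len(od[2])) for (ox in seq_len(od[1])) {
      acc <- b[co]
      for (ci in seq_len(cin)) for (kz in seq_len(k[3]))
        for (ky in seq_len(k[2])) for (kx in seq_len(k[1])) {
          ix <- (ox - 1L) * stride + kx - pad
          iy <- (oy - 1L) * stride + ky - pad
          iz <- (oz - 1L) * stride + kz - pad
          if (ix >= 1 && ix <= d[1] && iy >= 1 && iy <= d[2] &&
              iz >= 1 && iz <= d[3])
            acc <- acc + x[ix, iy, iz, ci] * W[kx, ky, kz, ci, co]
        }
      out[ox, oy, oz, co] <- acc
    }
  out
}

# loop evaluation of multi-head self-attention:
# per head, softmax(Q K^T / sqrt(d)) V, heads concatenated, output projected
bruteSelfAttention <- function(Z, p, n_heads) {
  e <- ncol(Z)
  dh <- e / n_heads
  Q <- sweep(Z %*% agv(p$Wq), 2, agv(p$bq), "+")
  K <- sweep(Z %*% agv(p$Wk), 2, agv(p$bk), "+")
  V <- sweep(Z %*% agv(p$Wv), 2, agv(p$bv), "+")
  out <- NULL
  for (h in seq_len(n_heads)) {
    idx <- (h - 1) * dh + seq_len(dh)
    Oh <- matrix(0, nrow(Z), dh)
    for (i in seq_len(nrow(Z))) {
      s <- numeric(nrow(Z))
      for (j in seq_len(nrow(Z)))
        s[j] <- sum(Q[i, idx] * K[j, idx]) / sqrt(dh)
      a <- exp(s - max(s)); a <- a / sum(a)
      for (j in seq_len(nrow(Z))) Oh[i, ] <- Oh[i, ] + a[j] * V[j, idx]
    }
    out <- cbind(out, Oh)
  }
  sweep(out %*% agv(p$Wo), 2, agv(p$bo), "+")
}

# loop evaluation of the channel-attention gate and gating
bruteChannelAttention <- function(M, p) {
  d <- dim(M); C <- d[4]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    v <- M[, , , c]
    avg[c] <- mean(v); mx[c] <- max(v)
  }
  mlp <- function(v) {
    h <- as.numeric(v %*% agv(p$W1)) + agv(p$b1)
    h[h < 0] <- 0
    as.numeric(h %*% agv(p$W2)) + agv(p$b2)
  }
  gate <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  out <- M
  for (c in seq_len(C)) out[, , , c] <- M[, , , c] * gate[c]
  list(out = out, gate = gate)
}

# loop evaluation of the spatial-attention gate (channel mean/max pooling,
# k^3 convolution with zero padding, sigmoid, broadcast multiply)
bruteSpatialAttention <- function(U, p) {
  d <- dim(U)
  pooled <- array(0, c(d[1:3], 2))
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    v <- U[x, y, z, ]
    pooled[x, y, z, 1] <- mean(v)
    pooled[x, y, z, 2] <- max(v)
  }
  k <- dim(agv(p$W))[1]
  conv <- bruteConv3d(pooled, agv(p$W), agv(p$b), 1L, (k - 1L) %/% 2L)
  gate <- 1 / (1 + exp(-conv[, , , 1]))
  out <- U
  for (c in seq_len(d[4])) out[, , , c] <- U[, , , c] * gate
  list(out = out, gate = gate)
}

# loop global average / max pooling per channel
brutePool <- function(M) {
  C <- dim(M)[4]
  gap <- numeric(C); gmp <- numeric(C)
  for (c in seq_len(C)) {
    gap[c] <- mean(M[, , , c])
    gmp[c] <- max(M[, , , c])
  }
  list(gap = gap, gmp = gmp)
}

# central finite differences against reverse-mode gradients
expect_grad_matches <- function(make_loss, params, eps = 1e-6, tol = 1e-4,
                                n_probe = 4) {
  gliotyper:::agZeroGrad(params)
  loss <- make_loss()
  gliotyper:::agBackward(loss)
  for (p in params) {
    g <- p$grad
    if (is.null(g)) g <- p$v * 0
    idx <- sample(length(p$v), min(n_probe, length(p$v)))
    for (i in idx) {
      v0 <- p$v[i]
      p$v[i] <- v0 + eps; lp <- agv(make_loss())
      p$v[i] <- v0 - eps; lm <- agv(make_loss())
      p$v[i] <- v0
      fd <- (lp - lm) / (2 * eps)
      expect_equal(g[i], fd, tolerance = tol,
                   label = sprintf("reverse-mode grad [%d]", i),
                   expected.label = "finite difference")
    }
  }
}
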