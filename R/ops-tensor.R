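## Volumetric tensor operations on (X, Y, Z, C) arrays, single sample.
## Convolution is evaluated as one GEMM per kernel offset: for offset (i,j,l)
## the shifted input slab, flattened to an (N_positions x C_in) matrix, is
## multiplied by the (C_in x C_out) kernel slice and accumulated. The backward
## pass mirrors this with the transposed products, scattering back into the
## padded input. This keeps all heavy lifting in BLAS.

padSpatial <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1:3] + 2L * pad, d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out
}

cropSpatial <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  x[pad + seq_len(d[1] - 2L * pad), pad + seq_len(d[2] - 2L * pad),
    pad + seq_len(d[3] - 2L * pad), , drop = FALSE]
}

## gather-index cache: for a given padded geometry, the (N x K) matrix of
## flat source positions for every output position and kernel offset
.convIdxCache <- new.env(parent = emptyenv())

convGatherIdx <- function(dp, k, stride, od) {
  key <- paste(c(dp, k, stride), collapse = ",")
  hit <- .convIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  ax <- seq.int(1L, by = stride, length.out = od[1])
  ay <- (seq.int(1L, by = stride, length.out = od[2]) - 1L) * dp[1]
  az <- (seq.int(1L, by = stride, length.out = od[3]) - 1L) * dp[1] * dp[2]
  base <- rep(ax, times = od[2] * od[3]) +
    rep(rep(ay, each = od[1]), times = od[3]) +
    rep(az, each = od[1] * od[2])
  di <- rep(seq_len(k[1]) - 1L, times = k[2] * k[3])
  dj <- rep(rep(seq_len(k[2]) - 1L, each = k[1]), times = k[3]) * dp[1]
  dl <- rep(seq_len(k[3]) - 1L, each = k[1] * k[2]) * dp[1] * dp[2]
  idx <- outer(base, di + dj + dl, "+")
  .convIdxCache[[key]] <- idx
  idx
}

## im2col is used when the gathered matrix stays small; otherwise one GEMM
## per kernel offset (the large-tensor regime, where BLAS dominates anyway)
.IM2COL_MAX <- 2^25

## offset deltas (flat padded-index displacement per kernel offset) and the
## base gather index of the first offset, built per geometry
.convGeom <- function(dp, k, stride, od) {
  ax <- seq.int(1L, by = stride, length.out = od[1])
  ay <- (seq.int(1L, by = stride, length.out = od[2]) - 1L) * dp[1]
  az <- (seq.int(1L, by = stride, length.out = od[3]) - 1L) * dp[1] * dp[2]
  base <- rep(ax, times = od[2] * od[3]) +
    rep(rep(ay, each = od[1]), times = od[3]) +
    rep(az, each = od[1] * od[2])
  di <- rep(seq_len(k[1]) - 1L, times = k[2] * k[3])
  dj <- rep(rep(seq_len(k[2]) - 1L, each = k[1]), times = k[3]) * dp[1]
  dl <- rep(seq_len(k[3]) - 1L, each = k[1] * k[2]) * dp[1] * dp[2]
  list(base = base, delta = di + dj + dl)
}

conv3dValue <- function(xv, Wv, bv, stride, pad) {
  k <- dim(Wv)[1:3]
  cin <- dim(Wv)[4]
  cout <- dim(Wv)[5]
  xp <- padSpatial(xv, pad)
  dp <- dim(xp)
  od <- (dp[1:3] - k) %/% stride + 1L
  n <- prod(od)
  kk <- prod(k)
  dim(xp) <- c(prod(dp[1:3]), cin)
  if (n * kk * cin <= .IM2COL_MAX) {
    idx <- convGatherIdx(dp, k, stride, od)
    xs <- xp[idx, , drop = FALSE]        # (N*K) x Cin
    dim(xs) <- c(n, kk * cin)            # cols ordered (offset, channel)
    acc <- xs %*% matrix(Wv, kk * cin, cout)
  } else {
    ## large-tensor path: each kernel offset is a flat shift on the padded
    ## grid, so every operand is a contiguous row range. Work proceeds in
    ## contiguous z-slabs to bound memory; within a slab, outputs are
    ## computed on the shifted grid and the valid corners gathered at the
    ## end (x-runs of the corner set are contiguous too).
    acc <- matrix(0, n, cout)
    Wm <- Wv
    dim(Wm) <- c(kk, cin * cout)
    ## rows reordered (channel fastest) to match offset-blocked unfolding
    Wm2 <- matrix(aperm(array(Wm, c(kk, cin, cout)), c(2, 1, 3)),
                  cin * kk, cout)
    for (sl in .convSlabs(dp, k, stride, od, cin, kk)) {
      slab <- xp[sl$xp_rows, , drop = FALSE]
      geom <- .convGeom(sl$dpl, k, stride, sl$odl)
      nr <- nrow(slab) - geom$delta[kk]
      xs <- matrix(0, nr, cin * kk)
      for (o in seq_len(kk)) {
        d0 <- geom$delta[o]
        xs[, ((o - 1L) * cin + 1L):(o * cin)] <-
          slab[(1L + d0):(nr + d0), , drop = FALSE]
      }
      big <- xs %*% Wm2
      acc[sl$out_rows, ] <- big[geom$base, , drop = FALSE]
    }
  }
  acc <- sweep(acc, 2L, bv, "+")
  dim(acc) <- c(od, cout)
  acc
}

## contiguous z-slab decomposition of a padded convolution
.convSlabs <- function(dp, k, stride, od, cin, kk = 4L) {
  plane <- dp[1] * dp[2]
  zlen <- max(1L, as.integer(.IM2COL_MAX %/% (plane * cin * kk)))
  out <- list()
  z0 <- 1L
  while (z0 <= od[3]) {
    z1 <- min(od[3], z0 + zlen - 1L)
    zs0 <- 1L + (z0 - 1L) * stride
    zs1 <- (z1 - 1L) * stride + k[3]
    out[[length(out) + 1L]] <- list(
      xp_rows = ((zs0 - 1L) * plane + 1L):(zs1 * plane),
      out_rows = ((z0 - 1L) * od[1] * od[2] + 1L):(z1 * od[1] * od[2]),
      dpl = c(dp[1], dp[2], zs1 - zs0 + 1L),
      odl = c(od[1], od[2], z1 - z0 + 1L))
    z0 <- z1 + 1L
  }
  out
}

#' 3D convolution node
#' @param x input node, (X,Y,Z,Cin) array
#' @param W kernel node, (k,k,k,Cin,Cout) array
#' @param b bias node, length Cout
#' @param stride,pad integer stride and symmetric zero padding
#' @noRd
agConv3d <- function(x, W, b, stride = 1L, pad = 1L) {
  xv <- x$v; Wv <- W$v; bv <- b$v
  stopifnot(dim(xv)[4] == dim(Wv)[4])
  v <- conv3dValue(xv, Wv, bv, stride, pad)
  agOp(v, list(x, W, b), function(g) {
    k <- dim(Wv)[1:3]
    cin <- dim(Wv)[4]
    cout <- dim(Wv)[5]
    od <- dim(g)[1:3]
    n <- prod(od)
    kk <- prod(k)
    gm <- g
    dim(gm) <- c(n, cout)
    xp <- padSpatial(xv, pad)
    dp <- dim(xp)
    np <- prod(dp[1:3])
    dim(xp) <- c(np, cin)
    if (n * kk * cin <= .IM2COL_MAX) {
      idx <- convGatherIdx(dp, k, stride, od)
      xs <- xp[idx, , drop = FALSE]
      dim(xs) <- c(n, kk * cin)
      dW <- crossprod(xs, gm)                    # (K*Cin) x Cout
      dim(dW) <- dim(Wv)
      contrib <- gm %*% t(matrix(Wv, kk * cin, cout))
      dim(contrib) <- c(n * kk, cin)
      rs <- rowsum(contrib, group = as.vector(idx), reorder = FALSE)
      dxp <- matrix(0, np, cin)
      dxp[as.integer(rownames(rs)), ] <- rs
      dim(dxp) <- dp
    } else {
      Wm <- Wv
      dim(Wm) <- c(kk, cin, cout)
      dW <- array(0, dim = c(kk, cin, cout))
      dxp <- matrix(0, np, cin)
      for (sl in .convSlabs(dp, k, stride, od, cin)) {
        slab <- xp[sl$xp_rows, , drop = FALSE]
        geom <- .convGeom(sl$dpl, k, stride, sl$odl)
        nr <- nrow(slab) - geom$delta[kk]
        g_big <- matrix(0, nr, cout)
        g_big[geom$base, ] <- gm[sl$out_rows, , drop = FALSE]
        d_slab <- matrix(0, nrow(slab), cin)
        for (o in seq_len(kk)) {
          d0 <- geom$delta[o]
          rows <- (1L + d0):(nr + d0)
          dW[o, , ] <- dW[o, , ] +
            crossprod(slab[rows, , drop = FALSE], g_big)
          d_slab[rows, ] <- d_slab[rows, , drop = FALSE] +
            g_big %*% t(matrix(Wm[o, , ], cin, cout))
        }
        dxp[sl$xp_rows, ] <- dxp[sl$xp_rows, , drop = FALSE] + d_slab
      }
      dim(dW) <- dim(Wv)
      dim(dxp) <- dp
    }
    dx <- cropSpatial(dxp, pad)
    list(dx, dW, colSums(gm))
  })
}

## Instance normalization: per-channel standardization over all spatial
## positions of one sample, with learnable per-channel gain/offset.
agInstanceNorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$v)
  n <- prod(d[1:3])
  m <- x$v
  dim(m) <- c(n, d[4])
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu)
  va <- colMeans(xc * xc)
  isd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, isd, "*")
  v <- sweep(sweep(xhat, 2L, gamma$v, "*"), 2L, beta$v, "+")
  dim(v) <- d
  agOp(v, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(n, d[4])
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    gh <- sweep(gm, 2L, gamma$v, "*")
    dx <- sweep(gh, 2L, colMeans(gh)) -
      xhat * matrix(colMeans(gh * xhat), n, d[4], byrow = TRUE)
    dx <- sweep(dx, 2L, isd, "*")
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

## Layer normalization over the feature (column) axis of an n x d matrix.
agLayerNormRows <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$v
  d <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  isd <- 1 / sqrt(va + eps)
  xhat <- xc * isd
  out <- sweep(sweep(xhat, 2L, gamma$v, "*"), 2L, beta$v, "+")
  agOp(out, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    gh <- sweep(g, 2L, gamma$v, "*")
    dx <- (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat)) * isd
    list(dx, dgamma, dbeta)
  })
}

## ---- pooling ---------------------------------------------------------------

## global average pooling: (X,Y,Z,C) -> length-C vector
agGapVec <- function(x) {
  d <- dim(x$v)
  n <- prod(d[1:3])
  m <- x$v
  dim(m) <- c(n, d[4])
  agOp(colMeans(m), list(x), function(g) {
    gr <- matrix(g / n, n, d[4], byrow = TRUE)
    dim(gr) <- d
    list(gr)
  })
}

## global max pooling: (X,Y,Z,C) -> length-C vector
agGmpVec <- function(x) {
  d <- dim(x$v)
  n <- prod(d[1:3])
  m <- x$v
  dim(m) <- c(n, d[4])
  idx <- apply(m, 2L, which.max)
  sel <- cbind(idx, seq_len(d[4]))
  agOp(m[sel], list(x), function(g) {
    gr <- matrix(0, n, d[4])
    gr[sel] <- g
    dim(gr) <- d
    list(gr)
  })
}

## per-voxel mean over channels: (X,Y,Z,C) -> (X,Y,Z,1)
agChannelMeanMap <- function(x) {
  d <- dim(x$v)
  n <- prod(d[1:3])
  m <- x$v
  dim(m) <- c(n, d[4])
  v <- rowMeans(m)
  dim(v) <- c(d[1:3], 1L)
  agOp(v, list(x), function(g) {
    gr <- matrix(as.numeric(g) / d[4], n, d[4])
    dim(gr) <- d
    list(gr)
  })
}

## per-voxel max over channels: (X,Y,Z,C) -> (X,Y,Z,1)
agChannelMaxMap <- function(x) {
  d <- dim(x$v)
  n <- prod(d[1:3])
  m <- x$v
  dim(m) <- c(n, d[4])
  idx <- max.col(m, ties.method = "first")
  sel <- cbind(seq_len(n), idx)
  v <- m[sel]
  dim(v) <- c(d[1:3], 1L)
  agOp(v, list(x), function(g) {
    gr <- matrix(0, n, d[4])
    gr[sel] <- as.numeric(g)
    dim(gr) <- d
    list(gr)
  })
}

## ---- attention gates --------------------------------------------------------

## multiply each channel c of x by gate[c] (channel attention)
agScaleChannels <- function(x, gate) {
  d <- dim(x$v)
  n <- prod(d[1:3])
  xv <- x$v
  gv <- gate$v
  m <- xv
  dim(m) <- c(n, d[4])
  v <- sweep(m, 2L, gv, "*")
  dim(v) <- d
  agOp(v, list(x, gate), function(g) {
    gm <- g
    dim(gm) <- c(n, d[4])
    dx <- sweep(gm, 2L, gv, "*")
    dim(dx) <- d
    list(dx, colSums(gm * m))
  })
}

## multiply every channel of x by a (X,Y,Z,1) spatial gate
agScaleSpatial <- function(x, gate) {
  d <- dim(x$v)
  n <- prod(d[1:3])
  xv <- x$v
  gv <- as.numeric(gate$v)
  m <- xv
  dim(m) <- c(n, d[4])
  v <- m * gv
  dim(v) <- d
  agOp(v, list(x, gate), function(g) {
    gm <- g
    dim(gm) <- c(n, d[4])
    dx <- gm * gv
    dim(dx) <- d
    dgate <- rowSums(gm * m)
    dim(dgate) <- c(d[1:3], 1L)
    list(dx, dgate)
  })
}
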