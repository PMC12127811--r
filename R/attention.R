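## High-order feature extractors: a 3D vision transformer on the enhanced
## path-1 features and attention-gated residual blocks (channel attention
## followed by spatial attention inside each residual block) on the path-2
## features.

## ---- 3D vision transformer --------------------------------------------------

vitParams <- function(cfg) {
  e <- cfg$embed_dim
  tok <- (cfg$input_size %/% 8L %/% cfg$patch_size)^3
  layer <- function() list(
    ln1 = normParams(e),
    Wq = heLinear(e, e), bq = zeroVec(e),
    Wk = heLinear(e, e), bk = zeroVec(e),
    Wv = heLinear(e, e), bv = zeroVec(e),
    Wo = heLinear(e, e), bo = zeroVec(e),
    ln2 = normParams(e),
    W1 = heLinear(e, 4L * e), b1 = zeroVec(4L * e),
    W2 = heLinear(4L * e, e), b2 = zeroVec(e))
  list(
    proj = convParams(3L, 8L * cfg$base_channels, e),
    pos = agParam(matrix(stats::rnorm(tok * e, sd = 0.02), tok, e)),
    layers = lapply(seq_len(cfg$n_layers), function(i) layer()),
    ln_out = normParams(e)
  )
}

#' Tokenize an enhanced feature map for the transformer
#'
#' A 3x3x3 convolution lifts the channel count to the embedding dimension
#' (128 -> 512 at full width), spatial positions are flattened into tokens
#' (one token per position at the default patch size 1; 16^3 = 4096 tokens)
#' and learnable position embeddings are added.
#'
#' @param f map node or (s,s,s,C) array
#' @param params transformer parameter list (`proj` + `pos`)
#' @param patch_size token granularity (convolution stride)
#' @return list with `tokens` (T x E node) and `embed` (patch embeddings
#'   before position addition)
#' @export
patchEmbed <- function(f, params, patch_size = 1L) {
  f <- asNode(f)
  h <- agConv3d(f, params$proj$W, params$proj$b,
                stride = as.integer(patch_size), pad = 1L)
  d <- dim(h$v)
  emb <- agReshape(h, c(prod(d[1:3]), d[4]))
  if (nrow(params$pos$v) != prod(d[1:3]))
    stop("patchEmbed: position-embedding length does not match token count")
  list(tokens = agAdd(emb, params$pos), embed = emb)
}

#' Multi-head self-attention
#'
#' Q, K, V are linear projections of the incoming tokens; per head,
#' softmax(Q K^T / sqrt(d)) V with d the per-head key dimension; heads are
#' concatenated and linearly projected.
#'
#' @param z token matrix node (T x E) or matrix
#' @param params layer parameters (Wq/Wk/Wv/Wo and biases)
#' @param n_heads number of attention heads (E divisible by n_heads)
#' @return token matrix node, same shape
#' @export
selfAttention <- function(z, params, n_heads = 8L) {
  z <- asNode(z)
  e <- ncol(z$v)
  if (e %% n_heads != 0L) stop("embed dim not divisible by n_heads")
  dh <- e %/% n_heads
  if (dh == 0L) stop("per-head dimension is zero")
  q <- agAddBias(agMatmul(z, params$Wq), params$bq)
  k <- agAddBias(agMatmul(z, params$Wk), params$bk)
  v <- agAddBias(agMatmul(z, params$Wv), params$bv)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    qh <- agSliceCols(q, idx)
    kh <- agSliceCols(k, idx)
    vh <- agSliceCols(v, idx)
    a <- agSoftmaxRows(agScale(agMatmulT2(qh, kh), 1 / sqrt(dh)))
    heads[[h]] <- agMatmul(a, vh)
  }
  agAddBias(agMatmul(agConcatCols(heads), params$Wo), params$bo)
}

#' One transformer layer: residual MSA block then residual MLP block
#'
#' Pre-norm arrangement: z + MSA(LN(z)), then + MLP(LN(.)); the MLP expands
#' the embedding 4x with GELU.
#'
#' @param z token matrix node or matrix
#' @param params layer parameters
#' @param n_heads attention heads
#' @return token matrix node, same shape
#' @export
transformerLayer <- function(z, params, n_heads = 8L) {
  z <- asNode(z)
  h <- agLayerNormRows(z, params$ln1$gamma, params$ln1$beta)
  z <- agAdd(z, selfAttention(h, params, n_heads))
  h <- agLayerNormRows(z, params$ln2$gamma, params$ln2$beta)
  h <- agGelu(agAddBias(agMatmul(h, params$W1), params$b1))
  h <- agAddBias(agMatmul(h, params$W2), params$b2)
  agAdd(z, h)
}

## full transformer branch: enhanced map -> token stack -> spatial map
vitForward <- function(f7, params, cfg) {
  pe <- patchEmbed(f7, params, cfg$patch_size)
  z <- pe$tokens
  for (ly in params$layers) z <- transformerLayer(z, ly, cfg$n_heads)
  z <- agLayerNormRows(z, params$ln_out$gamma, params$ln_out$beta)
  s <- dim(f7$v)[1] %/% cfg$patch_size
  list(tokens = z, map = agReshape(z, c(s, s, s, cfg$embed_dim)))
}

## ---- attention-gated residual blocks (channel + spatial attention) ---------

channelAttentionParams <- function(c, reduction = 16L) {
  hid <- max(1L, c %/% reduction)
  list(W1 = heLinear(c, hid), b1 = zeroVec(hid),
       W2 = heLinear(hid, c), b2 = zeroVec(c))
}

#' Channel attention gate
#'
#' U = sigmoid(MLP(AvgPool(M)) + MLP(MaxPool(M))) * M, with global average
#' and max pooling over all spatial positions per channel and a shared
#' two-layer MLP (bottleneck C/r), the gate broadcast spatially.
#'
#' @param m feature map node or (X,Y,Z,C) array
#' @param params `channelAttentionParams(C, r)`
#' @return list with gated map `out` and the length-C `gate` node
#' @export
channelAttention <- function(m, params) {
  m <- asNode(m)
  c <- dim(m$v)[4]
  mlp <- function(vec) {
    h <- agReshape(vec, c(1L, c))
    h <- agRelu(agAddBias(agMatmul(h, params$W1), params$b1))
    agAddBias(agMatmul(h, params$W2), params$b2)
  }
  pre <- agAdd(mlp(agGapVec(m)), mlp(agGmpVec(m)))
  gate <- agSigmoid(agReshape(pre, c))
  list(out = agScaleChannels(m, gate), gate = gate)
}

#' Spatial attention gate
#'
#' Per-voxel channel-wise average and maximum are concatenated (2 channels),
#' convolved with a 7x7x7 kernel (zero padding 3) and sigmoid-gated; the gate
#' multiplies every channel of the input.
#'
#' @param u feature map node or (X,Y,Z,C) array
#' @param params `convParams(7, 2, 1)`
#' @return list with gated map `out` and the (X,Y,Z,1) `gate` node
#' @export
spatialAttention <- function(u, params) {
  u <- asNode(u)
  pooled <- agConcatChannels(agChannelMeanMap(u), agChannelMaxMap(u))
  k <- dim(params$W$v)[1]
  gate <- agSigmoid(agConv3d(pooled, params$W, params$b,
                             stride = 1L, pad = (k - 1L) %/% 2L))
  list(out = agScaleSpatial(u, gate), gate = gate)
}

rdaBlockParams <- function(c, cfg) {
  list(conv = residualBlockParams(c),
       ca = channelAttentionParams(c, cfg$reduction_ratio),
       sa = convParams(cfg$spatial_kernel, 2L, 1L))
}

#' Attention-gated residual block
#'
#' output = F' + U', where U' is the spatial-attention gating of the
#' channel-attention gating of the block's two-convolution path applied to
#' F'. Shape is preserved.
#'
#' @param f input map node or (X,Y,Z,C) array
#' @param params `rdaBlockParams(C, cfg)`
#' @return output node, same shape as the input
#' @export
rdaBlock <- function(f, params) {
  f <- asNode(f)
  p <- params$conv
  h <- agRelu(agInstanceNorm(f, p$n1$gamma, p$n1$beta))
  h <- agConv3d(h, p$c1$W, p$c1$b)
  h <- agRelu(agInstanceNorm(h, p$n2$gamma, p$n2$beta))
  h <- agConv3d(h, p$c2$W, p$c2$b)
  u <- channelAttention(h, params$ca)$out
  u <- spatialAttention(u, params$sa)$out
  agAdd(f, u)
}

rdaTailParams <- function(cfg) {
  b <- cfg$base_channels
  stage <- function(cin) list(
    down = convParams(3L, cin, 2L * cin),
    blocks = lapply(seq_len(cfg$rda_blocks),
                    function(i) rdaBlockParams(2L * cin, cfg)))
  list(stage1 = stage(8L * b), stage2 = stage(16L * b))
}

## path-2 tail: F8 -> 2x-channel mid map -> 4x-channel final map
rdaForward <- function(f8, params) {
  h <- downsample(f8, params$stage1$down)
  for (blk in params$stage1$blocks) h <- rdaBlock(h, blk)
  mid <- h
  h <- downsample(h, params$stage2$down)
  for (blk in params$stage2$blocks) h <- rdaBlock(h, blk)
  list(mid = mid, out = h)
}
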