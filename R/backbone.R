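## The asymmetric dual-path convolutional front end.
##
## Path 1 consumes the 4-modality stack, path 2 the T2/FLAIR pair. Both open
## with a 3x3x3 stem producing `base_channels` maps at full resolution; the
## two low-level maps are fused (concatenation + convolution) and the fused
## map is injected back into each path by residual addition. Each path then
## alternates stride-2 downsampling convolutions (channels double, spatial
## halves; no pooling) with pre-activation residual blocks, ending at
## 8 x base_channels channels on a (input/8)^3 grid — 128 channels at 16^3 at
## full width. Mid-network enhancement concatenates the two path outputs
## (F3, F4) into F5, reduces back with a 1x1x1 convolution (F6) and adds F6
## onto each path output, yielding the enhanced maps F7 (transformer path)
## and F8 (dual-attention path).
##
## All functions accept plain arrays or `agNode`s and return `agNode`s;
## use `agv()` to extract values.

residualBlockParams <- function(c) {
  list(n1 = normParams(c), c1 = convParams(3L, c, c),
       n2 = normParams(c), c2 = convParams(3L, c, c))
}

#' Pre-activation residual block: y = x + Conv(Act(Norm(Conv(Act(Norm(x))))))
#'
#' Two 3x3x3 convolutions with instance normalization and ReLU, wrapped in an
#' identity shortcut; channel count and shape are preserved.
#'
#' @param x input node or (X,Y,Z,C) array
#' @param params block parameters from `residualBlockParams()`
#' @return output node of the same shape
#' @export
residualBlock <- function(x, params) {
  x <- asNode(x)
  if (dim(x$v)[4] != length(params$n1$gamma$v))
    stop("residualBlock: channel count does not match parameters")
  h <- agRelu(agInstanceNorm(x, params$n1$gamma, params$n1$beta))
  h <- agConv3d(h, params$c1$W, params$c1$b)
  h <- agRelu(agInstanceNorm(h, params$n2$gamma, params$n2$beta))
  h <- agConv3d(h, params$c2$W, params$c2$b)
  agAdd(x, h)
}

#' Strided downsampling convolution: spatial dims halve, channels double
#'
#' A 3x3x3 convolution with stride 2 (in place of pooling).
#'
#' @param x input node or array with even spatial dims
#' @param params `convParams(3, C, 2C)` parameters
#' @return node with halved spatial dims and doubled channels
#' @export
downsample <- function(x, params) {
  x <- asNode(x)
  agConv3d(x, params$W, params$b, stride = 2L, pad = 1L)
}

#' Early low-level fusion between the two paths
#'
#' Concatenates the two full-resolution low-level maps, convolves back to the
#' base channel count, and injects the fused map into both paths by residual
#' addition.
#'
#' @param low1,low2 low-level maps (nodes or arrays), same shape,
#'   base channels each
#' @param params `convParams(3, 2C, C)`
#' @return list with updated `p1`, `p2` maps and the shared `fused` map
#' @export
earlyFusion <- function(low1, low2, params) {
  low1 <- asNode(low1); low2 <- asNode(low2)
  if (!all(dim(low1$v)[1:3] == dim(low2$v)[1:3]))
    stop("earlyFusion: spatial dimensions differ between paths")
  fused <- agConv3d(agConcatChannels(low1, low2), params$W, params$b)
  list(p1 = agAdd(low1, fused), p2 = agAdd(low2, fused), fused = fused)
}

#' Mid-network feature enhancement (F3,F4 -> F5,F6,F7,F8)
#'
#' F5 = concat(F3, F4) along channels; F6 = 1x1x1 convolution of F5 back to
#' the path width; F7 = F6 + F3 (fed to the transformer path) and
#' F8 = F6 + F4 (fed to the dual-attention path).
#'
#' @param f3,f4 path outputs (nodes or arrays), equal shapes
#' @param params `convParams(1, 2C, C)`
#' @return list with nodes `f5`, `f6`, `f7`, `f8`
#' @export
enhanceFeatures <- function(f3, f4, params) {
  f3 <- asNode(f3); f4 <- asNode(f4)
  if (!identical(dim(f3$v), dim(f4$v)))
    stop("enhanceFeatures: F3/F4 shape mismatch")
  f5 <- agConcatChannels(f3, f4)
  f6 <- agConv3d(f5, params$W, params$b, stride = 1L, pad = 0L)
  list(f5 = f5, f6 = f6, f7 = agAdd(f6, f3), f8 = agAdd(f6, f4))
}

backboneParams <- function(cfg) {
  b <- cfg$base_channels
  stage <- function(cin, nblocks) {
    list(down = convParams(3L, cin, 2L * cin),
         blocks = lapply(seq_len(nblocks),
                         function(i) residualBlockParams(2L * cin)))
  }
  list(
    stem1 = convParams(3L, 4L, b),
    stem2 = convParams(3L, 2L, b),
    fusion = convParams(3L, 2L * b, b),
    path1 = lapply(0:2, function(s) stage(b * 2L^s, cfg$path1_blocks)),
    path2 = lapply(0:2, function(s) stage(b * 2L^s, cfg$path2_blocks)),
    enhance = convParams(1L, 16L * b, 8L * b)
  )
}

## full backbone forward; input (X,Y,Z,4) array or node. The full-resolution
## low-level maps are dropped as soon as the paths no longer need them unless
## the caller wants them (keeps peak memory bounded at full scale).
backboneForward <- function(x, params, keep_low = TRUE) {
  x <- asNode(x)
  x2 <- agNode(x$v[, , , 3:4, drop = FALSE])  # T2 + FLAIR stack
  low1 <- agConv3d(x, params$stem1$W, params$stem1$b)
  low2 <- agConv3d(x2, params$stem2$W, params$stem2$b)
  x2 <- NULL
  fus <- earlyFusion(low1, low2, params$fusion)
  out <- if (keep_low) list(low1 = low1, low2 = low2) else list()
  low1 <- NULL
  low2 <- NULL
  runPath <- function(h, stages) {
    for (st in stages) {
      h <- downsample(h, st$down)
      for (blk in st$blocks) h <- residualBlock(h, blk)
    }
    h
  }
  f3 <- runPath(fus$p1, params$path1)
  fus$p1 <- NULL
  f4 <- runPath(fus$p2, params$path2)
  fus <- NULL
  enh <- enhanceFeatures(f3, f4, params$enhance)
  c(out, list(f3 = f3, f4 = f4), enh)
}
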