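## The inter-gene-relationship classification head.
##
## Multi-scale features are summarized parameter-free by global average and
## max pooling at three scales (128-, 256- and 512-channel maps at full
## width, giving a 2 x (128+256+512) = 1792-dim vector), then passed through
## per-gene fully connected stacks 1792 -> 1280 -> 512 -> 32 -> 2 with
## softmax outputs. The 1p/19q head is conditioned on the IDH and ATRX
## predictions: its 32-dim penultimate representation is concatenated with
## the two prediction-confidence scalars max P_idh and max P_atrx before the
## final linear layer. Gradients are not stopped through those scalars, so
## the 1p/19q loss also trains the IDH and ATRX heads.

#' Parameter-free multi-scale pooling
#'
#' For each supplied feature map, global average pooling (GAP) and global max
#' pooling (GMP) per channel; the per-map (GAP, GMP) pairs are concatenated
#' in order into one vector of dimension 2 x sum(channels).
#'
#' @param maps list of feature map nodes or (X,Y,Z,C) arrays (any spatial
#'   sizes)
#' @return pooled vector node
#' @export
multiscalePool <- function(maps) {
  if (!length(maps)) stop("multiscalePool: no feature maps supplied")
  maps <- lapply(maps, asNode)
  pieces <- lapply(maps, function(m) list(agGapVec(m), agGmpVec(m)))
  agConcatVec(do.call(c, pieces))
}

## Glorot-initialized linear layers keep the deep stack's activation variance
## bounded; the final 2-logit layer starts at zero so untrained heads output
## uniform probabilities and early gradients are unsaturated.
geneHeadParams <- function(din, widths, extra_final = 0L) {
  ws <- c(din, widths)
  glorot <- function(a, b)
    list(W = agParam(matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))), a, b)),
         b = zeroVec(b))
  stack <- lapply(seq_len(length(ws) - 1L),
                  function(i) glorot(ws[i], ws[i + 1L]))
  final <- list(W = agParam(matrix(0, widths[length(widths)] + extra_final, 2L)),
                b = zeroVec(2L))
  list(stack = stack, final = final)
}

## run the shared FC stack on a 1 x D or n x D matrix; leaky activation so
## the narrow penultimate layer cannot die entirely
.headStack <- function(feat, params) {
  h <- feat
  for (ly in params$stack) {
    h <- agAddBias(agMatmul(h, ly$W), ly$b)
    h <- agLeakyRelu(h)
  }
  h
}

#' Forward pass of an unconditioned gene head (IDH or ATRX)
#'
#' Fully connected stack (1792 -> 1280 -> 512 -> 32 at full width) followed
#' by a linear layer to 2 logits and softmax.
#'
#' @param feat pooled feature node (length-D vector or n x D matrix)
#' @param params `geneHeadParams(...)`
#' @return list with `logits` and `probs` nodes (n x 2)
#' @export
geneHeadForward <- function(feat, params) {
  feat <- asNode(feat)
  if (is.null(dim(feat$v))) feat <- agReshape(feat, c(1L, length(feat$v)))
  h <- .headStack(feat, params)
  logits <- agAddBias(agMatmul(h, params$final$W), params$final$b)
  list(logits = logits, probs = agSoftmaxRows(logits))
}

#' Forward pass of the conditioned 1p/19q head
#'
#' The 32-dim penultimate representation is concatenated with the prediction
#' confidences max(P_idh) and max(P_atrx) (each in [0.5, 1] for a two-class
#' simplex point) and mapped by the final linear layer to 2 logits, then
#' softmax. Either conditioning input may be omitted (ablation).
#'
#' @param feat pooled feature node (length-D vector or n x D matrix)
#' @param params `geneHeadParams(..., extra_final = #conditioners)`
#' @param p_idh,p_atrx probability nodes/matrices (n x 2) or NULL to disable
#'   that auxiliary path
#' @return list with `logits` and `probs` nodes (n x 2)
#' @export
codelHeadForward <- function(feat, params, p_idh = NULL, p_atrx = NULL) {
  feat <- asNode(feat)
  if (is.null(dim(feat$v))) feat <- agReshape(feat, c(1L, length(feat$v)))
  h <- .headStack(feat, params)
  extras <- list()
  for (p in list(p_idh, p_atrx)) {
    if (is.null(p)) next
    p <- asNode(p)
    n <- nrow(p$v)
    extras[[length(extras) + 1L]] <- agReshape(agRowMax(p), c(n, 1L))
  }
  if (length(extras)) h <- agConcatCols(c(list(h), extras))
  if (ncol(h$v) != nrow(params$final$W$v))
    stop("codelHeadForward: conditioning inputs do not match head parameters")
  logits <- agAddBias(agMatmul(h, params$final$W), params$final$b)
  list(logits = logits, probs = agSoftmaxRows(logits))
}
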