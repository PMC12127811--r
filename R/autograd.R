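## Minimal reverse-mode automatic differentiation over dense arrays.
##
## Nodes are environments holding a value (`v`), an accumulated gradient
## (`grad`), the parent nodes and a pull-back closure mapping the node's
## gradient to gradients for each parent. Large operations (convolution,
## attention) reduce to BLAS matrix products, so the engine stays fast on CPU
## despite being plain R. Graph construction is skipped entirely inside
## `noGrad()` so inference never caches intermediates.

.ag <- new.env(parent = emptyenv())
.ag$grad_on <- TRUE

agNode <- function(v, parents = list(), bw = NULL, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$bw <- bw
  e$requires <- requires
  class(e) <- "agNode"
  e
}

agConst <- function(v) agNode(v)
agParam <- function(v) agNode(v, requires = TRUE)

#' @noRd
agv <- function(x) if (inherits(x, "agNode")) x$v else x

asNode <- function(x) if (inherits(x, "agNode")) x else agConst(x)

## Build an op node. When gradients are off (or no parent needs them) the
## parents and pull-back are dropped so the intermediate can be collected.
agOp <- function(v, parents, bw) {
  if (.ag$grad_on && any(vapply(parents, function(p) p$requires, logical(1)))) {
    agNode(v, parents = parents, bw = bw, requires = TRUE)
  } else {
    agNode(v)
  }
}

#' Evaluate an expression with gradient tracking disabled
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @noRd
noGrad <- function(expr) {
  old <- .ag$grad_on
  .ag$grad_on <- FALSE
  on.exit(.ag$grad_on <- old)
  expr
}

## Reverse pass. Iterative postorder so deep graphs never hit R's recursion
## limit; node identity is tracked with a per-call visit stamp.
agBackward <- function(root, grad = NULL) {
  if (is.null(grad)) {
    grad <- agv(root)
    grad[] <- 1
  }
  stamp <- new.env(parent = emptyenv())
  stamp$n <- 0L
  topo <- vector("list", 256L)
  ntopo <- 0L
  stack <- list(list(node = root, i = 0L))
  root$.seen <- TRUE
  while (length(stack)) {
    top <- stack[[length(stack)]]
    node <- top$node
    ps <- node$parents
    i <- top$i + 1L
    advanced <- FALSE
    while (i <= length(ps)) {
      p <- ps[[i]]
      if (p$requires && !isTRUE(p$.seen)) {
        p$.seen <- TRUE
        stack[[length(stack)]] <- list(node = node, i = i)
        stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
        advanced <- TRUE
        break
      }
      i <- i + 1L
    }
    if (!advanced) {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  root$grad <- grad
  for (k in rev(seq_len(ntopo))) {
    node <- topo[[k]]
    node$.seen <- NULL
    if (is.null(node$bw) || is.null(node$grad)) next
    gs <- node$bw(node$grad)
    ps <- node$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      g <- gs[[i]]
      if (!p$requires || is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    ## intermediate grads are not needed once propagated
    if (!is.null(node$bw)) node$grad <- NULL
  }
  invisible(root)
}

agZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- elementwise / structural ops ------------------------------------------

agAdd <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  if (length(a$v) != length(b$v))
    stop("agAdd: operand sizes differ (", length(a$v), " vs ", length(b$v), ")")
  agOp(a$v + b$v, list(a, b), function(g) list(g, g))
}

agScale <- function(a, k) {
  agOp(a$v * k, list(a), function(g) list(g * k))
}

agMul <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  av <- a$v; bv <- b$v
  agOp(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

agReshape <- function(a, d) {
  od <- dim(a$v)
  v <- a$v
  dim(v) <- if (length(d) == 1L) NULL else d  # length-1 dims become vectors
  agOp(v, list(a), function(g) { dim(g) <- od; list(g) })
}

agRelu <- function(a) {
  m <- a$v > 0
  agOp(a$v * m, list(a), function(g) list(g * m))
}

agLeakyRelu <- function(a, slope = 0.01) {
  w <- ifelse(a$v > 0, 1, slope)
  agOp(a$v * w, list(a), function(g) list(g * w))
}

agSigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  agOp(s, list(a), function(g) list(g * s * (1 - s)))
}

agGelu <- function(a) {
  x <- a$v
  ph <- stats::pnorm(x)
  agOp(x * ph, list(a), function(g) list(g * (ph + x * stats::dnorm(x))))
}

agLog <- function(a) {
  v <- a$v
  agOp(log(v), list(a), function(g) list(g / v))
}

agExp <- function(a) {
  ev <- exp(a$v)
  agOp(ev, list(a), function(g) list(g * ev))
}

agPow <- function(a, p) {
  v <- a$v
  agOp(v^p, list(a), function(g) list(g * p * v^(p - 1)))
}

agSum <- function(a) {
  d <- dim(a$v)
  agOp(sum(a$v), list(a), function(g) {
    gr <- array(as.numeric(g), dim = if (is.null(d)) length(a$v) else d)
    if (is.null(d)) gr <- as.numeric(gr)
    list(gr)
  })
}

agMean <- function(a) {
  n <- length(a$v)
  d <- dim(a$v)
  agOp(mean(a$v), list(a), function(g) {
    gr <- array(as.numeric(g) / n, dim = if (is.null(d)) n else d)
    if (is.null(d)) gr <- as.numeric(gr)
    list(gr)
  })
}

## ---- linear algebra ---------------------------------------------------------

agMatmul <- function(a, b) {
  av <- a$v; bv <- b$v
  agOp(av %*% bv, list(a, b), function(g)
    list(g %*% t(bv), crossprod(av, g)))
}

## x: n x p matrix, b: length-p bias
agAddBias <- function(x, b) {
  v <- sweep(x$v, 2L, b$v, "+")
  agOp(v, list(x, b), function(g) list(g, colSums(g)))
}

.rowMaxes <- function(v) v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]

agSoftmaxRows <- function(x) {
  v <- x$v
  m <- v - .rowMaxes(v)
  e <- exp(m)
  p <- e / rowSums(e)
  agOp(p, list(x), function(g) list(p * (g - rowSums(g * p))))
}

agLogSoftmaxRows <- function(x) {
  v <- x$v
  m <- v - .rowMaxes(v)
  ls <- m - log(rowSums(exp(m)))
  agOp(ls, list(x), function(g) list(g - exp(ls) * rowSums(g)))
}

## v[i] = x[i, idx[i]]
agGatherRows <- function(x, idx) {
  n <- nrow(x$v)
  sel <- cbind(seq_len(n), idx)
  d <- dim(x$v)
  agOp(x$v[sel], list(x), function(g) {
    gr <- array(0, d)
    gr[sel] <- g
    list(gr)
  })
}

## row-wise maximum (used for the prediction-confidence scalars max P(i));
## gradient flows to the argmax entry
agRowMax <- function(x) {
  idx <- max.col(x$v, ties.method = "first")
  agGatherRows(x, idx)
}

agConcatCols <- function(xs) {
  vs <- lapply(xs, agv)
  nc <- vapply(vs, ncol, integer(1))
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  agOp(do.call(cbind, vs), xs, function(g)
    lapply(seq_along(xs), function(i) g[, starts[i]:ends[i], drop = FALSE]))
}

agConcatVec <- function(xs) {
  vs <- lapply(xs, agv)
  ns <- vapply(vs, length, integer(1))
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  agOp(unlist(vs, use.names = FALSE), xs, function(g)
    lapply(seq_along(xs), function(i) g[starts[i]:ends[i]]))
}

agAffine <- function(a, mul = 1, add = 0) {
  agOp(a$v * mul + add, list(a), function(g) list(g * mul))
}

agSliceCols <- function(x, idx) {
  d <- dim(x$v)
  agOp(x$v[, idx, drop = FALSE], list(x), function(g) {
    gr <- matrix(0, d[1], d[2])
    gr[, idx] <- g
    list(gr)
  })
}

## A %*% t(B)
agMatmulT2 <- function(a, b) {
  av <- a$v; bv <- b$v
  agOp(tcrossprod(av, bv), list(a, b), function(g)
    list(g %*% bv, crossprod(g, av)))
}

## subtract per-class margins from the target-class logit (LDAM adjustment)
agMarginAdjust <- function(logits, target, margins) {
  v <- logits$v
  sel <- cbind(seq_len(nrow(v)), target)
  v[sel] <- v[sel] - margins[target]
  agOp(v, list(logits), function(g) list(g))
}

## concatenate 4D (X,Y,Z,C) arrays along the channel (last) axis
agConcatChannels <- function(a, b) {
  da <- dim(a$v); db <- dim(b$v)
  stopifnot(all(da[1:3] == db[1:3]))
  v <- array(c(a$v, b$v), dim = c(da[1:3], da[4] + db[4]))
  na <- prod(da)
  agOp(v, list(a, b), function(g) {
    list(array(g[seq_len(na)], dim = da),
         array(g[-seq_len(na)], dim = db))
  })
}
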