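## Parameter containers and the Adam optimizer.
##
## Parameters live in (possibly nested) named lists of `agNode` leaves created
## with `agParam()`. Optimizer state (first/second moments) is stored on the
## node environments themselves so a parameter set plus its optimizer travels
## as one object.

heConv <- function(k, cin, cout) {
  sd <- sqrt(2 / (prod(k) * cin))
  agParam(array(stats::rnorm(prod(k) * cin * cout, sd = sd),
                dim = c(k, cin, cout)))
}

heLinear <- function(din, dout) {
  agParam(matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout))
}

zeroVec <- function(n) agParam(numeric(n))
onesVec <- function(n) agParam(rep(1, n))

convParams <- function(k, cin, cout) {
  list(W = heConv(rep(k, 3L), cin, cout), b = zeroVec(cout))
}

linearParams <- function(din, dout) {
  list(W = heLinear(din, dout), b = zeroVec(dout))
}

normParams <- function(c) list(gamma = onesVec(c), beta = zeroVec(c))

## flatten a nested parameter list into a flat list of agNode leaves
collectParams <- function(x) {
  if (inherits(x, "agNode")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collectParams)))
  list()
}

#' Count trainable parameters of a nested parameter list
#' @noRd
nParams <- function(params) {
  sum(vapply(collectParams(params), function(p) length(p$v), numeric(1)))
}

## Adam with decoupled behavior matching the classic formulation: L2 weight
## decay is added to the gradient. `decay_mask` switches decay off for
## normalization gains/offsets and the uncertainty parameters.
adamInit <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay, t = 0L)
}

adamStep <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (p in opt$params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (opt$weight_decay > 0 && !isTRUE(p$no_decay)) g <- g + opt$weight_decay * p$v
    if (is.null(p$m)) { p$m <- g * 0; p$s <- g * 0 }
    p$m <- b1 * p$m + (1 - b1) * g
    p$s <- b2 * p$s + (1 - b2) * g * g
    p$v <- p$v - opt$lr * (p$m / bc1) / (sqrt(p$s / bc2) + opt$eps)
  }
  opt
}

## deep copies of parameter values, for checkpointing the best epoch
paramValues <- function(params) lapply(params, function(p) p$v)

setParamValues <- function(params, values) {
  stopifnot(length(params) == length(values))
  for (i in seq_along(params)) params[[i]]$v <- values[[i]]
  invisible(params)
}
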