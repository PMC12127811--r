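## Imbalance-aware loss stack: focal loss, label-distribution-aware-margin
## (LDAM) loss, their weighted combination, and the homoscedastic-uncertainty
## multi-task objective.
##
## Every loss has a plain-numeric form (for closed-form checks and reporting)
## and an autodiff form used during training; both share the same arithmetic.
## Note on the margin loss: the printed form of this loss circulating in the
## application literature is not evaluable as written (the margin enters
## through a sign-inconsistent rescaling of the probability), so the
## canonical formulation is used: per-class margins m_j proportional to
## n_j^{-1/4}, scaled so the largest margin equals `max_margin` and floored
## at `delta`, subtracted from the target-class logit before softmax
## cross-entropy. Rarer classes therefore receive larger margins.

.EPS <- 1e-12

#' Per-gene class priors, margins and focal weights
#'
#' Counts the two classes of each gene in the training labels and derives the
#' LDAM margins (larger for rarer classes) and inverse-frequency focal
#' weights.
#'
#' @param labels data.frame with 0/1 columns `idh`, `atrx`, `codel`
#'   (as from [genotypeLabels()])
#' @param max_margin largest class margin after scaling
#' @param delta margin floor
#' @param pseudocount added to each class count; keeps margins finite when a
#'   tiny training split lacks one class entirely (set 0 to error instead)
#' @return named list per gene with `counts`, `margins`, `alpha` (class
#'   order: 0 then 1)
#' @export
classPriors <- function(labels, max_margin = 0.5, delta = 0,
                        pseudocount = 0.5) {
  genes <- c("idh", "atrx", "codel")
  stopifnot(all(genes %in% names(labels)))
  out <- lapply(genes, function(g) {
    n <- c(sum(labels[[g]] == 0), sum(labels[[g]] == 1)) + pseudocount
    if (any(n <= 0))
      stop("gene ", g, ": a class has no training examples and pseudocount=0")
    raw <- n^(-1 / 4)
    margins <- pmax(delta, max_margin * raw / max(raw))
    alpha <- (1 / n) / mean(1 / n)
    list(counts = n, margins = margins, alpha = alpha)
  })
  names(out) <- genes
  c(out, list(max_margin = max_margin, delta = delta))
}

## targets: 0/1 labels -> 1-based class index
.classIndex <- function(target) as.integer(target) + 1L

#' Focal loss
#'
#' -alpha_t (1 - p_t)^gamma log(p_t), averaged over the batch, with p_t the
#' predicted probability of the target class. gamma = 0 and alpha = 1
#' recover plain cross-entropy. Probabilities are clamped at a tiny epsilon.
#'
#' @param p probability matrix (n x 2, rows on the simplex) or length-2
#'   vector
#' @param target 0/1 labels (length n)
#' @param alpha per-class weight vector (class order 0, 1) or scalar
#' @param gamma focusing exponent (>= 0)
#' @return scalar loss
#' @export
focalLoss <- function(p, target, alpha = 1, gamma = 2) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  idx <- .classIndex(target)
  pt <- pmax(p[cbind(seq_len(nrow(p)), idx)], .EPS)
  a <- if (length(alpha) > 1) alpha[idx] else alpha
  mean(-a * (1 - pt)^gamma * log(pt))
}

## autodiff focal from logits
agFocalLoss <- function(logits, target, alpha = 1, gamma = 2) {
  idx <- .classIndex(target)
  a <- if (length(alpha) > 1) alpha[idx] else rep(alpha, length(idx))
  lpt <- agGatherRows(agLogSoftmaxRows(logits), idx)
  pt <- agExp(lpt)
  w <- agPow(agAffine(pt, -1, 1), gamma)     # (1 - p_t)^gamma
  agScale(agMean(agMul(agMul(w, lpt), agConst(a))), -1)
}

#' Margin (LDAM) loss
#'
#' Softmax cross-entropy after subtracting the target class margin from the
#' target logit; margins come from [classPriors()] (per class, larger for
#' rarer classes). Zero margins recover plain cross-entropy.
#'
#' @param logits n x 2 logit matrix or length-2 vector
#' @param target 0/1 labels
#' @param margins per-class margin vector (class order 0, 1)
#' @return scalar loss
#' @export
ldamLoss <- function(logits, target, margins) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  idx <- .classIndex(target)
  if (any(idx < 1L | idx > ncol(logits))) stop("unknown class in target")
  sel <- cbind(seq_len(nrow(logits)), idx)
  z <- logits
  z[sel] <- z[sel] - margins[idx]
  m <- z - apply(z, 1, max)
  mean(-(m[sel] - log(rowSums(exp(m)))))
}

agLdamLoss <- function(logits, target, margins) {
  idx <- .classIndex(target)
  z <- agMarginAdjust(logits, idx, margins)
  agScale(agMean(agGatherRows(agLogSoftmaxRows(z), idx)), -1)
}

#' Combined margin + focal (LMF) loss
#'
#' alpha * LDAM + beta * focal, the per-gene training loss.
#'
#' @param logits n x 2 logits
#' @param target 0/1 labels
#' @param priors one gene's entry of [classPriors()] (`margins`, `alpha`)
#' @param alpha,beta mixing weights of the margin and focal terms
#' @param gamma focal focusing exponent
#' @return scalar loss
#' @export
lmfLoss <- function(logits, target, priors, alpha = 0.5, beta = 0.5,
                    gamma = 2) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  alpha * ldamLoss(logits, target, priors$margins) +
    beta * focalLoss(p, target, priors$alpha, gamma)
}

agLmfLoss <- function(logits, target, priors, alpha = 0.5, beta = 0.5,
                      gamma = 2) {
  agAdd(agScale(agLdamLoss(logits, target, priors$margins), alpha),
        agScale(agFocalLoss(logits, target, priors$alpha, gamma), beta))
}

#' Homoscedastic-uncertainty multi-task objective
#'
#' sum_g l_g / (3 sigma_g^2) + log(sigma_idh sigma_atrx sigma_codel), with
#' the sigma_g positive learnable task-uncertainty weights (optimized on the
#' log scale during training so positivity is structural). At the stated
#' initialization sigma = (5, 6, 6) and zero sub-losses the objective equals
#' log(180).
#'
#' @param losses numeric vector of the three per-gene losses
#'   (idh, atrx, codel)
#' @param sigma positive uncertainty weights, same order
#' @return scalar objective
#' @export
multitaskLoss <- function(losses, sigma = c(5, 6, 6)) {
  stopifnot(length(losses) == length(sigma), all(sigma > 0))
  sum(losses / (3 * sigma^2)) + sum(log(sigma))
}

## autodiff form over log-sigma parameter nodes
agMultitaskLoss <- function(loss_nodes, log_sigma_nodes) {
  stopifnot(length(loss_nodes) == length(log_sigma_nodes))
  total <- NULL
  for (i in seq_along(loss_nodes)) {
    s <- log_sigma_nodes[[i]]
    term <- agAdd(agScale(agMul(loss_nodes[[i]], agExp(agScale(s, -2))), 1 / 3), s)
    total <- if (is.null(total)) term else agAdd(total, term)
  }
  total
}

#' Stationary uncertainty weight for a fixed sub-loss
#'
#' Gradient descent on the multi-task objective with a frozen sub-loss l
#' converges to sigma = sqrt(2 l / 3).
#'
#' @param loss fixed sub-loss value
#' @return the stationary sigma
#' @export
sigmaStationary <- function(loss) sqrt(2 * loss / 3)
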