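## Training loop, model selection and evaluation metrics.

#' Training configuration
#'
#' @param epochs maximum epochs
#' @param lr Adam learning rate
#' @param weight_decay L2 penalty added to weight gradients (normalization
#'   gains/offsets and the uncertainty parameters are exempt)
#' @param batch_size minibatch size
#' @param seed seed controlling initialization, shuffling and augmentation
#' @param lmf_alpha,lmf_beta margin/focal mixing weights
#' @param focal_gamma focal focusing exponent
#' @param max_margin,delta margin-loss scale and floor
#' @param augment apply random crop/flip to training samples (validation
#'   always uses the deterministic center crop)
#' @param verbose print one line per epoch
#' @return list of training settings
#' @export
trainConfig <- function(epochs = 50L, lr = 1e-4, weight_decay = 1e-5,
                        batch_size = 2L, seed = 1L,
                        lmf_alpha = 0.5, lmf_beta = 0.5, focal_gamma = 2,
                        max_margin = 0.5, delta = 0,
                        augment = TRUE, verbose = FALSE) {
  stopifnot(epochs >= 1, lr > 0, batch_size >= 1)
  list(epochs = as.integer(epochs), lr = lr, weight_decay = weight_decay,
       batch_size = as.integer(batch_size), seed = as.integer(seed),
       lmf_alpha = lmf_alpha, lmf_beta = lmf_beta,
       focal_gamma = focal_gamma, max_margin = max_margin, delta = delta,
       augment = augment, verbose = verbose)
}

.GENES <- c("idh", "atrx", "codel")

## stack a cohort once; augmentation crops/flips reuse the cached tensors
.prepareInputs <- function(samples) lapply(samples, stackModalities)

## per-gene LMF losses for a list of prepared inputs (graph-building)
.batchLosses <- function(model, inputs, labels, priors, tc, augmented) {
  s <- model@config$input_size
  logit_rows <- list(idh = list(), atrx = list(), codel = list())
  for (i in seq_along(inputs)) {
    inp <- inputs[[i]]
    inp <- if (augmented) {
      randomFlip(randomCrop(inp, s), model@config$flip_prob)
    } else centerCrop(inp, s)
    out <- modelForward(model, inp)
    for (g in .GENES) logit_rows[[g]][[i]] <- out$logits[[g]]
  }
  lapply(.GENES, function(g) {
    logits <- if (length(logit_rows[[g]]) > 1L) {
      agOp(do.call(rbind, lapply(logit_rows[[g]], agv)), logit_rows[[g]],
           function(gr) lapply(seq_along(logit_rows[[g]]),
                               function(i) gr[i, , drop = FALSE]))
    } else logit_rows[[g]][[1L]]
    agLmfLoss(logits, labels[[g]], priors[[g]],
              alpha = tc$lmf_alpha, beta = tc$lmf_beta,
              gamma = tc$focal_gamma)
  }) |> stats::setNames(.GENES)
}

#' Train a genotyping model
#'
#' Adam on the uncertainty-weighted sum of the three per-gene margin+focal
#' losses. Class priors (margins, focal weights) are computed from the
#' training labels. The checkpoint is the epoch with minimum validation loss
#' (the multi-task objective evaluated with the then-current frozen sigma).
#' Fully deterministic for a fixed seed on CPU.
#'
#' @param train_set,val_set lists of [SubjectSample-class]
#' @param config a [modelConfig()] list
#' @param tc a [trainConfig()] list
#' @return a trained [GenotypeModel-class]; inspect [trainingHistory()]
#' @export
trainGenotyper <- function(train_set, val_set = NULL,
                           config = modelConfig(),
                           tc = trainConfig()) {
  stopifnot(length(train_set) >= 1)
  if (is.null(val_set)) val_set <- train_set
  model <- initGenotypeModel(config, seed = tc$seed)
  labels_df <- genotypeLabels(train_set)
  priors <- classPriors(labels_df, max_margin = tc$max_margin,
                        delta = tc$delta)
  model@priors <- priors

  tr_inputs <- .prepareInputs(train_set)
  va_inputs <- .prepareInputs(val_set)
  tr_labels <- lapply(.GENES, function(g) labels_df[[g]]) |>
    stats::setNames(.GENES)
  va_df <- genotypeLabels(val_set)
  va_labels <- lapply(.GENES, function(g) va_df[[g]]) |> stats::setNames(.GENES)

  flat <- c(collectParams(model@params), model@sigma)
  opt <- adamInit(flat, lr = tc$lr, weight_decay = tc$weight_decay)

  n <- length(tr_inputs)
  same_val <- identical(tr_inputs, va_inputs)
  hist_rows <- vector("list", tc$epochs)
  best <- list(val = Inf, values = NULL, epoch = 0L)
  set.seed(tc$seed + 1L)

  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    correct <- c(idh = 0, atrx = 0, codel = 0)
    nb <- 0L
    for (start in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n)]
      agZeroGrad(flat)
      losses <- .batchLosses(model, tr_inputs[idx],
                             lapply(tr_labels, function(v) v[idx]),
                             priors, tc, augmented = tc$augment)
      total <- agMultitaskLoss(losses, model@sigma)
      if (!is.finite(agv(total)))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      agBackward(total)
      opt <- adamStep(opt)
      ep_loss <- ep_loss + agv(total)
      nb <- nb + 1L
    }
    ## deterministic training-set accuracy (center crop, frozen weights)
    tr_eval <- .evalLosses(model, tr_inputs, tr_labels, priors, tc)
    va_eval <- if (same_val) tr_eval else
      .evalLosses(model, va_inputs, va_labels, priors, tc)
    sig <- vapply(model@sigma, function(s) exp(s$v), numeric(1))
    val_total <- multitaskLoss(va_eval$losses, sig)
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss / nb, val_loss = val_total,
      acc_idh = tr_eval$acc[["idh"]], acc_atrx = tr_eval$acc[["atrx"]],
      acc_codel = tr_eval$acc[["codel"]],
      val_acc_idh = va_eval$acc[["idh"]], val_acc_atrx = va_eval$acc[["atrx"]],
      val_acc_codel = va_eval$acc[["codel"]],
      sigma_idh = sig[["idh"]], sigma_atrx = sig[["atrx"]],
      sigma_codel = sig[["codel"]])
    if (val_total < best$val) {
      best <- list(val = val_total, values = paramValues(flat), epoch = epoch)
    }
    if (tc$verbose)
      message(sprintf(
        "epoch %3d  train %.4f  val %.4f  acc %.2f/%.2f/%.2f  sigma %.2f/%.2f/%.2f",
        epoch, ep_loss / nb, val_total,
        tr_eval$acc[["idh"]], tr_eval$acc[["atrx"]], tr_eval$acc[["codel"]],
        sig[["idh"]], sig[["atrx"]], sig[["codel"]]))
  }
  setParamValues(flat, best$values)
  model@history <- do.call(rbind, hist_rows)
  attr(model@history, "selected_epoch") <- best$epoch
  model
}

## frozen-weight losses and accuracies on a prepared input list
## (single center-crop forward per sample; numeric loss recomputation)
.evalLosses <- function(model, inputs, labels, priors, tc) {
  s <- model@config$input_size
  logit_mats <- lapply(.GENES, function(g) matrix(0, length(inputs), 2L)) |>
    stats::setNames(.GENES)
  noGrad(for (i in seq_along(inputs)) {
    out <- modelForward(model, centerCrop(inputs[[i]], s))
    for (g in .GENES) logit_mats[[g]][i, ] <- agv(out$logits[[g]])
  })
  losses <- vapply(.GENES, function(g)
    lmfLoss(logit_mats[[g]], labels[[g]], priors[[g]],
            alpha = tc$lmf_alpha, beta = tc$lmf_beta, gamma = tc$focal_gamma),
    numeric(1))
  acc <- vapply(.GENES, function(g)
    mean(max.col(logit_mats[[g]], ties.method = "first") - 1L == labels[[g]]),
    numeric(1))
  list(losses = losses, acc = acc)
}

## ---- metrics ----------------------------------------------------------------

#' Rank-statistic AUC (Mann-Whitney form)
#'
#' Ties handled through midranks; returns NA when only one class is present.
#'
#' @param scores predicted scores for the positive class
#' @param labels 0/1 labels
#' @return AUC in [0, 1], or NA
#' @export
rankAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity at a matched specificity
#'
#' Largest attainable true-positive rate among thresholds whose specificity
#' is at least `spec_target` (empirical ROC point).
#'
#' @param scores positive-class scores
#' @param labels 0/1 labels
#' @param spec_target required specificity
#' @return sensitivity in [0, 1]
#' @export
sensAtSpec <- function(scores, labels, spec_target = 0.9) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  ## evaluate only at distinct-score cuts (threshold between ties is invalid)
  cut_ok <- c(s[-1] < s[-length(s)], TRUE)
  spec <- 1 - fp / n0
  sens <- tp / n1
  ok <- cut_ok & spec >= spec_target
  if (!any(ok)) 0 else max(sens[ok])
}

#' Per-gene evaluation report
#'
#' @slot metrics data.frame with one row per gene: Acc, AUC, Sens
#'   (true-positive rate on the mutant/codeleted class), Spec and the
#'   confusion counts
#' @slot predictions prediction table as from [predictGenotypes()]
#' @export
setClass("EvalReport",
         representation(metrics = "data.frame", predictions = "data.frame"))

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (", nrow(object@predictions), "subjects )\n")
  m <- object@metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-6s Acc %.3f  AUC %s  Sens %.3f  Spec %.3f\n",
                m$gene[i], m$acc[i],
                ifelse(is.na(m$auc[i]), "NA", sprintf("%.3f", m$auc[i])),
                m$sens[i], m$spec[i]))
})

#' Metrics accessor
#' @param report an [EvalReport-class]
#' @return the per-gene metrics data.frame
#' @export
evalMetrics <- function(report) report@metrics

#' Evaluate a trained model on a cohort
#'
#' Deterministic center-crop inference; accuracy, rank AUC, sensitivity
#' (mutant/codeleted class) and specificity per gene with confusion counts.
#'
#' @param model a [GenotypeModel-class]
#' @param samples list of [SubjectSample-class]
#' @return an [EvalReport-class]
#' @export
## confusion-based metrics for one gene
.geneMetrics <- function(y, yhat, score) {
  tp <- sum(yhat == 1 & y == 1); fn <- sum(yhat == 0 & y == 1)
  tn <- sum(yhat == 0 & y == 0); fp <- sum(yhat == 1 & y == 0)
  data.frame(acc = (tp + tn) / length(y),
             auc = rankAUC(score, y),
             sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
             tp = tp, fn = fn, tn = tn, fp = fp)
}

evaluateGenotyper <- function(model, samples) {
  preds <- predictGenotypes(model, samples)
  truth <- genotypeLabels(samples)
  rows <- lapply(.GENES, function(g) {
    score <- preds[[paste0("p_", c(idh = "idh_mut", atrx = "atrx_mut",
                                   codel = "codel")[[g]])]]
    cbind(data.frame(gene = g),
          .geneMetrics(truth[[g]], preds[[paste0("pred_", g)]], score))
  })
  methods::new("EvalReport", metrics = do.call(rbind, rows),
               predictions = preds)
}
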