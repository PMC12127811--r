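## Full genotyping model: configuration, initialization, forward pass,
## prediction and feature-map export.

#' Model configuration
#'
#' A single `scale` multiplier shrinks channel widths, embedding size, head
#' widths and the input crop jointly so the identical architecture runs at
#' desk scale; `scale = 1` reproduces the full printed dimensions
#' (128^3 input, 16..128 backbone channels, 512-dim tokens, 1792-dim pooled
#' features).
#'
#' @param scale joint width/size multiplier
#' @param input_size input crop side (default 128 x scale)
#' @param base_channels stem width (default 16 x scale)
#' @param embed_dim transformer embedding (default 512 x scale)
#' @param n_layers transformer depth
#' @param n_heads attention heads
#' @param patch_size token granularity of the transformer branch
#' @param reduction_ratio channel-attention bottleneck ratio
#' @param spatial_kernel spatial-attention kernel size
#' @param fc_widths widths of the shared gene-head stack (before the final
#'   2-logit layer)
#' @param codel_conditioning which auxiliary predictions condition the
#'   1p/19q head (subset of "idh", "atrx")
#' @param path1_blocks,path2_blocks residual blocks per stage in each path
#' @param rda_blocks attention-gated blocks per tail stage
#' @param flip_prob training-time flip probability per axis
#' @return a config list
#' @export
modelConfig <- function(scale = 1,
                        input_size = NULL,
                        base_channels = NULL,
                        embed_dim = NULL,
                        n_layers = 4L,
                        n_heads = 8L,
                        patch_size = 1L,
                        reduction_ratio = 16L,
                        spatial_kernel = 7L,
                        fc_widths = NULL,
                        codel_conditioning = c("idh", "atrx"),
                        path1_blocks = 1L,
                        path2_blocks = 2L,
                        rda_blocks = 2L,
                        flip_prob = 0.5) {
  base_channels <- as.integer(base_channels %||% max(2L, round(16 * scale)))
  input_size <- as.integer(input_size %||% max(8L, round(128 * scale)))
  if (input_size %% 8L != 0L) stop("input_size must be divisible by 8")
  embed_dim <- as.integer(embed_dim %||% (32L * base_channels))
  if (embed_dim != 32L * base_channels)
    stop("embed_dim must equal 32 x base_channels so the transformer and ",
         "attention-branch final maps can be pooled together")
  n_heads <- as.integer(n_heads)
  while (embed_dim %% n_heads != 0L) n_heads <- n_heads - 1L
  fc_widths <- as.integer(fc_widths %||% pmax(4L, round(c(1280, 512, 32) * scale)))
  list(scale = scale, input_size = input_size, base_channels = base_channels,
       embed_dim = embed_dim, n_layers = as.integer(n_layers),
       n_heads = n_heads, patch_size = as.integer(patch_size),
       reduction_ratio = as.integer(reduction_ratio),
       spatial_kernel = as.integer(spatial_kernel),
       fc_widths = fc_widths,
       codel_conditioning = codel_conditioning,
       path1_blocks = as.integer(path1_blocks),
       path2_blocks = as.integer(path2_blocks),
       rda_blocks = as.integer(rda_blocks),
       flip_prob = flip_prob)
}

#' Trained or initialized genotyping model
#'
#' @slot config the [modelConfig()] list
#' @slot params nested list of parameter nodes
#' @slot sigma list of log-scale uncertainty parameter nodes (one per gene)
#' @slot priors class-prior table from [classPriors()], or empty list
#' @slot history per-epoch training log (possibly empty)
#' @export
setClass("GenotypeModel", representation(
  config = "list", params = "list", sigma = "list",
  priors = "list", history = "data.frame"))

setMethod("show", "GenotypeModel", function(object) {
  cfg <- object@config
  cat("GenotypeModel (scale", cfg$scale, ")\n")
  cat("  input", paste(rep(cfg$input_size, 3), collapse = "x"),
      "| base channels", cfg$base_channels,
      "| embed", cfg$embed_dim, "\n")
  cat("  parameters:", format(nParams(object@params), big.mark = ","), "\n")
  if (nrow(object@history))
    cat("  trained", nrow(object@history), "epochs; best val loss",
        sprintf("%.4f", min(object@history$val_loss)), "\n")
  cat("  sigma:", paste(sprintf("%.3f", sigmaValues(object)), collapse = ", "),
      "(idh, atrx, codel)\n")
})

#' Model configuration accessor
#' @param model a [GenotypeModel-class]
#' @return the config list
#' @export
modelConfigOf <- function(model) model@config

#' Current uncertainty weights sigma (idh, atrx, codel order)
#' @param model a [GenotypeModel-class]
#' @return named numeric vector of sigma values
#' @export
sigmaValues <- function(model) {
  vapply(model@sigma, function(s) exp(s$v), numeric(1))
}

#' Training history accessor
#' @param model a [GenotypeModel-class]
#' @return data.frame of per-epoch losses, accuracies and sigma values
#' @export
trainingHistory <- function(model) model@history

#' Initialize a genotyping model
#'
#' @param config a [modelConfig()] list
#' @param seed RNG seed for weight initialization
#' @param sigma_init initial uncertainty weights (idh, atrx, codel); the
#'   defaults are 5, 6, 6 with 1p/19q and ATRX started at the larger value
#' @return a [GenotypeModel-class]
#' @export
initGenotypeModel <- function(config = modelConfig(),
                              seed = 1L,
                              sigma_init = c(idh = 5, atrx = 6, codel = 6)) {
  set.seed(seed)
  b <- config$base_channels
  pooled_dim <- 2L * (8L + 16L + 32L) * b
  params <- list(
    backbone = backboneParams(config),
    vit = vitParams(config),
    rda = rdaTailParams(config),
    heads = list(
      idh = geneHeadParams(pooled_dim, config$fc_widths),
      atrx = geneHeadParams(pooled_dim, config$fc_widths),
      codel = geneHeadParams(pooled_dim, config$fc_widths,
                             extra_final = length(config$codel_conditioning)))
  )
  sigma <- lapply(sigma_init, function(s) {
    p <- agParam(log(s))
    p$no_decay <- TRUE
    p
  })
  for (p in collectParams(list(params$backbone, params$vit, params$rda))) {
    if (length(dim(p$v)) < 2L) p$no_decay <- TRUE  # norm gains/offsets, biases
  }
  methods::new("GenotypeModel", config = config, params = params,
               sigma = sigma, priors = list(),
               history = data.frame())
}

#' Full forward pass
#'
#' Backbone (dual path + enhancement) -> transformer and attention-gated
#' branches -> multi-scale pooling -> three gene heads. The 512-channel scale
#' pools the transformer and attention-branch final maps and averages the two
#' summaries.
#'
#' @param model a [GenotypeModel-class]
#' @param input a `modelInput` (tensor already cropped to the configured
#'   input size) or a bare (s,s,s,4) array
#' @param keep_stages also return all named stage tensors
#' @return list with `logits`, `probs` (per-gene nodes) and `pooled`; plus
#'   `stages` when requested
#' @export
modelForward <- function(model, input, keep_stages = FALSE) {
  x <- if (is.list(input)) input$tensor else input
  d <- dim(x)
  s <- model@config$input_size
  if (length(d) != 4L || d[4] != 4L || !all(d[1:3] == s))
    stop("modelForward: expected a ", s, "^3 x 4 input, got ",
         paste(d, collapse = "x"))
  p <- model@params
  bk <- backboneForward(x, p$backbone, keep_low = keep_stages)
  vit <- vitForward(bk$f7, p$vit, model@config)
  rda <- rdaForward(bk$f8, p$rda)

  gap512 <- agScale(agAdd(agGapVec(vit$map), agGapVec(rda$out)), 0.5)
  gmp512 <- agScale(agAdd(agGmpVec(vit$map), agGmpVec(rda$out)), 0.5)
  pooled <- agConcatVec(list(
    agGapVec(bk$f6), agGmpVec(bk$f6),
    agGapVec(rda$mid), agGmpVec(rda$mid),
    gap512, gmp512))
  feat <- agReshape(pooled, c(1L, length(pooled$v)))

  idh <- geneHeadForward(feat, p$heads$idh)
  atrx <- geneHeadForward(feat, p$heads$atrx)
  cond <- model@config$codel_conditioning
  codel <- codelHeadForward(feat, p$heads$codel,
    p_idh = if ("idh" %in% cond) idh$probs else NULL,
    p_atrx = if ("atrx" %in% cond) atrx$probs else NULL)

  out <- list(
    logits = list(idh = idh$logits, atrx = atrx$logits, codel = codel$logits),
    probs = list(idh = idh$probs, atrx = atrx$probs, codel = codel$probs),
    pooled = pooled)
  if (keep_stages) {
    out$stages <- list(low1 = bk$low1, low2 = bk$low2,
                       F3 = bk$f3, F4 = bk$f4, F5 = bk$f5, F6 = bk$f6,
                       F7 = bk$f7, F8 = bk$f8,
                       vit_tokens = vit$tokens, vit_map = vit$map,
                       rda_mid = rda$mid, rda_out = rda$out)
  }
  out
}

#' Predict genotype probabilities for one subject
#'
#' Deterministic evaluation-mode inference: center crop to the configured
#' input size, forward pass without gradient tracking, argmax hard labels.
#'
#' @param model a [GenotypeModel-class]
#' @param sample a [SubjectSample-class] or prepared `modelInput`
#' @return list with `probs` (named list of length-2 probability vectors,
#'   classes ordered wild-type/non-codeleted then mutant/codeleted) and
#'   `labels` (named 0/1 vector)
#' @export
predictSubject <- function(model, sample) {
  input <- if (methods::is(sample, "SubjectSample"))
    stackModalities(sample) else sample
  input <- centerCrop(input, model@config$input_size)
  out <- noGrad(modelForward(model, input))
  probs <- lapply(out$probs, function(p) as.numeric(agv(p)))
  labels <- vapply(probs, function(p) which.max(p) - 1L, integer(1))
  list(probs = probs, labels = labels)
}

#' Predict a cohort into the standard prediction table
#'
#' @param model a [GenotypeModel-class]
#' @param samples list of [SubjectSample-class]
#' @return data.frame with columns subject_id, p_idh_mut, p_atrx_mut,
#'   p_codel, pred_idh, pred_atrx, pred_codel
#' @export
predictGenotypes <- function(model, samples) {
  rows <- lapply(samples, function(s) {
    pr <- predictSubject(model, s)
    data.frame(subject_id = s@subject_id,
               p_idh_mut = pr$probs$idh[2], p_atrx_mut = pr$probs$atrx[2],
               p_codel = pr$probs$codel[2],
               pred_idh = pr$labels[["idh"]], pred_atrx = pr$labels[["atrx"]],
               pred_codel = pr$labels[["codel"]])
  })
  do.call(rbind, rows)
}

#' Export named stage tensors as NIfTI volumes
#'
#' Dumps one chosen channel of each requested stage (F3, F4, F6, F7, F8 by
#' default; any stage name returned by [modelForward()] works) for visual
#' inspection.
#'
#' @param model a [GenotypeModel-class]
#' @param sample a [SubjectSample-class] or `modelInput`
#' @param stages stage names to export
#' @param out_dir output directory
#' @param channel channel index to dump
#' @return invisibly, the written file paths
#' @export
exportFeatureMaps <- function(model, sample,
                              stages = c("F3", "F4", "F6", "F7", "F8"),
                              out_dir = ".", channel = 1L) {
  input <- if (methods::is(sample, "SubjectSample"))
    stackModalities(sample) else sample
  input <- centerCrop(input, model@config$input_size)
  out <- noGrad(modelForward(model, input, keep_stages = TRUE))
  unknown <- setdiff(stages, names(out$stages))
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  for (st in stages) {
    v <- agv(out$stages[[st]])
    if (length(dim(v)) != 4L)
      stop("stage ", st, " is not a spatial feature map")
    vol <- array(v[, , , min(channel, dim(v)[4])], dim(v)[1:3])
    path <- file.path(out_dir, paste0("stage_", st, ".nii.gz"))
    RNifti::writeNifti(vol, path, datatype = "double")
    paths <- c(paths, path)
  }
  invisible(paths)
}
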