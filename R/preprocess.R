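## Normalization, stacking, cropping and flipping of multi-modal volumes into
## fixed-size network inputs.
##
## A model input is a list with class "modelInput": `tensor`, an
## (X, Y, Z, 4) array in fixed channel order (T1, T1-ce, T2, FLAIR), and
## `availability`, four logical flags. Channels of absent modalities are
## identically zero; zero-filling happens after per-modality normalization so
## absent channels are exactly zero.

#' Z-score normalize a volume over its brain mask
#'
#' Standardizes to mean 0 / sd 1 over the nonzero (brain) voxels; background
#' voxels stay exactly 0.
#'
#' @param volume 3D intensity array
#' @return normalized array of the same shape
#' @export
zscoreNormalize <- function(volume) {
  mask <- volume != 0
  x <- volume[mask]
  if (length(unique(x)) < 2L)
    stop("cannot z-score a volume that is constant inside the brain mask")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))   # population sd: two-point volumes map to +/-1
  volume[mask] <- (x - m) / s
  volume
}

#' Stack a subject's modalities into a 4-channel model input
#'
#' Present modalities are z-score normalized and stacked in the fixed order
#' T1, T1-ce, T2, FLAIR; missing modalities become all-zero channels. The
#' T2/FLAIR path requires both of those modalities.
#'
#' @param sample a [SubjectSample-class]
#' @param normalize apply [zscoreNormalize()] per present modality
#' @return a `modelInput` list with elements `tensor`, `availability`,
#'   `labels`, `subject_id`
#' @export
stackModalities <- function(sample, normalize = TRUE) {
  av <- sample@availability
  if (!av[3] || !av[4])
    stop("T2 and FLAIR are required (the second path consumes both)")
  shapes <- lapply(sample@volumes, dim)
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
    stop("present volumes have mismatched shapes")
  shp <- shapes[[1]]
  tensor <- array(0, dim = c(shp, 4L))
  for (i in seq_along(MODALITIES)) {
    if (!av[i]) next
    v <- sample@volumes[[MODALITIES[i]]]
    if (normalize) v <- zscoreNormalize(v)
    tensor[, , , i] <- v
  }
  structure(list(tensor = tensor, availability = av,
                 labels = sample@labels, subject_id = sample@subject_id),
            class = "modelInput")
}

## zero-pad spatial axes symmetrically up to at least `size`
.padTo <- function(tensor, size) {
  d <- dim(tensor)
  need <- pmax(0L, as.integer(size) - d[1:3])
  if (all(need == 0L)) return(tensor)
  lo <- need %/% 2L
  out <- array(0, dim = c(d[1:3] + need, d[4]))
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3]), ] <-
    tensor
  out
}

#' Random spatial crop to a cube
#'
#' Offsets are uniform over all valid positions; the same window is applied to
#' every channel. Inputs smaller than the crop in any axis are symmetrically
#' zero-padded first. Consumes the RNG stream.
#'
#' @param input a `modelInput`
#' @param size cube side in voxels (default 128)
#' @return the cropped `modelInput`
#' @export
randomCrop <- function(input, size = 128L) {
  size <- as.integer(size)
  tensor <- .padTo(input$tensor, size)
  d <- dim(tensor)
  off <- vapply(d[1:3] - size, function(m) sample.int(m + 1L, 1L) - 1L,
                integer(1))
  input$tensor <- tensor[off[1] + seq_len(size), off[2] + seq_len(size),
                         off[3] + seq_len(size), , drop = FALSE]
  input
}

#' Deterministic center crop (evaluation-time counterpart of [randomCrop()])
#' @param input a `modelInput`
#' @param size cube side in voxels
#' @return the cropped `modelInput`
#' @export
centerCrop <- function(input, size = 128L) {
  size <- as.integer(size)
  tensor <- .padTo(input$tensor, size)
  d <- dim(tensor)
  off <- (d[1:3] - size) %/% 2L
  input$tensor <- tensor[off[1] + seq_len(size), off[2] + seq_len(size),
                         off[3] + seq_len(size), , drop = FALSE]
  input
}

#' Random per-axis flips
#'
#' Each spatial axis is independently reversed with probability `p`; channels
#' flip jointly. Consumes the RNG stream.
#'
#' @param input a `modelInput`
#' @param p flip probability per axis
#' @return the flipped `modelInput`
#' @export
randomFlip <- function(input, p = 0.5) {
  d <- dim(input$tensor)
  for (ax in 1:3) {
    if (stats::runif(1) < p) {
      idx <- rev(seq_len(d[ax]))
      input$tensor <- switch(ax,
        input$tensor[idx, , , , drop = FALSE],
        input$tensor[, idx, , , drop = FALSE],
        input$tensor[, , idx, , drop = FALSE])
    }
  }
  input
}

#' @export
print.modelInput <- function(x, ...) {
  d <- dim(x$tensor)
  cat("modelInput", x$subject_id %||% "", ":",
      paste(d[1:3], collapse = "x"), "voxels x", d[4], "channels;",
      "present:", paste(MODALITIES[x$availability], collapse = "+"), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
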