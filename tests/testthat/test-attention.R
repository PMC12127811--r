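# Transformer branch (patch embedding, multi-head self-attention, stacked
# layers) and the attention-gated residual blocks.

mkLayerParams <- mkAccLayerParams

test_that("patch embedding lifts channels, flattens tokens and adds positions", {
  cfg <- vitOnlyConfig(12L, input_size = 16L)
  set.seed(1)
  vp <- gliotyper:::vitParams(cfg)
  f <- array(rnorm(2^3 * 16), c(2, 2, 2, 16))
  pe <- patchEmbed(f, vp, cfg$patch_size)
  expect_equal(dim(agv(pe$tokens)), c(8L, 12L))
  # zero input, zero bias: tokens equal the position embeddings
  vp$proj$b$v[] <- 0
  pe0 <- patchEmbed(array(0, dim(f)), vp, 1L)
  expect_equal(agv(pe0$tokens), agv(vp$pos), tolerance = 1e-12)
  expect_error(patchEmbed(array(0, c(3, 3, 3, 16)), vp, 1L), "position")
})

test_that("a single-voxel change only perturbs tokens inside the conv footprint", {
  cfg <- vitOnlyConfig(8L, input_size = 32L)
  set.seed(2)
  vp <- gliotyper:::vitParams(cfg)
  f <- array(rnorm(4^3 * 16), c(4, 4, 4, 16))
  f2 <- f
  f2[2, 3, 2, 5] <- f2[2, 3, 2, 5] + 1
  d <- abs(agv(patchEmbed(f2, vp, 1L)$embed) -
           agv(patchEmbed(f, vp, 1L)$embed))
  changed <- which(rowSums(d) > 1e-12)
  # flat indices of the 3^3 neighborhood of (2,3,2) on the 4^3 grid
  nb <- as.matrix(expand.grid(x = 1:3, y = 2:4, z = 1:3))
  allowed <- nb[, 1] + (nb[, 2] - 1) * 4 + (nb[, 3] - 1) * 16
  expect_true(all(changed %in% allowed))
})

test_that("self-attention matches a brute-force loop evaluation", {
  e <- 4L
  p <- mkLayerParams(e)
  set.seed(3)
  Z <- matrix(rnorm(3 * e), 3, e)
  ours <- agv(selfAttention(Z, p, n_heads = 2L))
  expect_equal(ours, bruteSelfAttention(Z, p, 2L), tolerance = 1e-6)
  # 5-token instance, single head
  Z5 <- matrix(rnorm(5 * e), 5, e)
  expect_equal(agv(selfAttention(Z5, p, n_heads = 1L)),
               bruteSelfAttention(Z5, p, 1L), tolerance = 1e-6)
})

test_that("self-attention averages identical tokens and is permutation-equivariant", {
  e <- 8L
  p <- mkLayerParams(e)
  z_row <- rnorm(e)
  Z <- matrix(z_row, 4, e, byrow = TRUE)
  out <- agv(selfAttention(Z, p, 2L))
  for (i in 2:4) expect_equal(out[i, ], out[1, ], tolerance = 1e-12)

  set.seed(4)
  Z2 <- matrix(rnorm(5 * e), 5, e)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(agv(selfAttention(Z2[perm, ], p, 2L)),
               agv(selfAttention(Z2, p, 2L))[perm, ], tolerance = 1e-10)
})

test_that("transformer layers are residual pass-throughs at zero weights", {
  e <- 8L
  p <- mkLayerParams(e)
  p$Wo$v[] <- 0; p$bo$v[] <- 0
  p$W2$v[] <- 0; p$b2$v[] <- 0
  set.seed(5)
  Z <- matrix(rnorm(6 * e), 6, e)
  expect_equal(agv(transformerLayer(Z, p, 2L)), Z, tolerance = 1e-12)
})

test_that("a stack of 4 transformer layers preserves shape and stays finite", {
  cfg <- vitOnlyConfig(16L, n_layers = 4L, n_heads = 4L)
  set.seed(6)
  vp <- gliotyper:::vitParams(cfg)
  f <- array(rnorm(16), c(1, 1, 1, 16))
  out <- gliotyper:::vitForward(gliotyper:::asNode(f), vp, cfg)
  expect_equal(dim(agv(out$tokens)), c(1L, 16L))
  expect_true(all(is.finite(agv(out$tokens))))
  expect_equal(length(vp$layers), 4L)
})

test_that("channel attention matches the loop oracle and gates lie in (0,1)", {
  set.seed(7)
  p <- gliotyper:::channelAttentionParams(2L, reduction = 1L)
  M <- array(rnorm(2^3 * 2), c(2, 2, 2, 2))
  res <- channelAttention(M, p)
  oracle <- bruteChannelAttention(M, p)
  expect_equal(agv(res$out), oracle$out, tolerance = 1e-6)
  expect_equal(agv(res$gate), oracle$gate, tolerance = 1e-6)
  expect_true(all(agv(res$gate) > 0 & agv(res$gate) < 1))

  # per-channel constant map: average and max pooling coincide, so the
  # pre-activation is 2 MLP(c)
  Mc <- array(rep(c(1.5, -0.5), each = 8), c(2, 2, 2, 2))
  gate <- agv(channelAttention(Mc, p)$gate)
  mlp <- function(v) {
    h <- pmax(0, as.numeric(v %*% agv(p$W1)) + agv(p$b1))
    as.numeric(h %*% agv(p$W2)) + agv(p$b2)
  }
  expect_equal(gate, 1 / (1 + exp(-2 * mlp(c(1.5, -0.5)))), tolerance = 1e-10)
})

test_that("spatial attention matches the loop oracle with a 7^3 kernel", {
  set.seed(8)
  p <- gliotyper:::convParams(7L, 2L, 1L)
  p$W$v <- p$W$v * 0.2
  U <- array(rnorm(3^3 * 2), c(3, 3, 3, 2))
  res <- spatialAttention(U, p)
  oracle <- bruteSpatialAttention(U, p)
  expect_equal(agv(res$out), oracle$out, tolerance = 1e-6)
  g <- agv(res$gate)
  expect_true(all(g > 0 & g < 1))
})

test_that("attention-gated residual blocks collapse to identity at zero weights", {
  set.seed(9)
  cfg <- microConfig()
  p <- gliotyper:::rdaBlockParams(4L, cfg)
  for (q in gliotyper:::collectParams(p))
    if (!is.null(dim(q$v))) q$v[] <- 0
  x <- array(rnorm(3^3 * 4), c(3, 3, 3, 4))
  expect_equal(agv(rdaBlock(x, p)), x, tolerance = 1e-12)
  # with live weights, shape is preserved
  p2 <- gliotyper:::rdaBlockParams(4L, cfg)
  expect_equal(dim(agv(rdaBlock(x, p2))), dim(x))
})

test_that("the attention tail yields the 4x-channel final map", {
  cfg <- microConfig()
  set.seed(10)
  tp <- gliotyper:::rdaTailParams(cfg)
  b <- cfg$base_channels
  f8 <- array(rnorm(2^3 * 8 * b), c(2, 2, 2, 8L * b))
  out <- gliotyper:::rdaForward(gliotyper:::asNode(f8), tp)
  expect_equal(dim(agv(out$mid))[4], 16L * b)
  expect_equal(dim(agv(out$out))[4], 32L * b)
})
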