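# Focal, margin (LDAM), combined (LMF) and uncertainty-weighted multi-task
# losses: closed forms, limits, monotonicity and the sigma dynamics.

test_that("focal loss closed forms", {
  # gamma = 0, alpha = 1: plain cross-entropy
  p <- matrix(c(0.3, 0.7), 1)
  expect_equal(focalLoss(p, 1, alpha = 1, gamma = 0), -log(0.7),
               tolerance = 1e-12)
  # perfectly confident correct prediction: zero loss
  expect_equal(focalLoss(matrix(c(0, 1), 1), 1, 1, 2), 0, tolerance = 1e-12)
  # p_t = 0.5, gamma = 2: 0.25 ln 2
  expect_equal(focalLoss(matrix(c(0.5, 0.5), 1), 1, 1, 2), 0.25 * log(2),
               tolerance = 1e-12)
})

test_that("focal never exceeds cross-entropy for gamma > 0", {
  set.seed(1)
  for (i in 1:50) {
    p1 <- runif(1, 0.01, 0.99)
    p <- matrix(c(1 - p1, p1), 1)
    y <- sample(0:1, 1)
    expect_lte(focalLoss(p, y, 1, 2), focalLoss(p, y, 1, 0) + 1e-12)
  }
})

test_that("autodiff focal agrees with the numeric form on a batch", {
  set.seed(2)
  logits <- matrix(rnorm(10), 5, 2)
  y <- c(0, 1, 1, 0, 1)
  p <- exp(logits) / rowSums(exp(logits))
  a <- c(0.4, 1.6)
  expect_equal(agv(gliotyper:::agFocalLoss(gliotyper:::agConst(logits), y, a, 2)),
               focalLoss(p, y, a, 2), tolerance = 1e-10)
})

test_that("margin loss limits and closed forms", {
  set.seed(3)
  logits <- matrix(rnorm(8), 4, 2)
  y <- c(0, 1, 0, 1)
  # zero margins: softmax cross-entropy
  p <- exp(logits) / rowSums(exp(logits))
  ce <- mean(-log(p[cbind(1:4, y + 1)]))
  expect_equal(ldamLoss(logits, y, c(0, 0)), ce, tolerance = 1e-12)
  # equal logits with margin m on the target: ln(1 + e^m)
  m <- 0.7
  expect_equal(ldamLoss(matrix(c(1, 1), 1), 1, c(0, m)), log(1 + exp(m)),
               tolerance = 1e-12)
  expect_error(ldamLoss(matrix(c(1, 1), 1), 5, c(0, 0)), "unknown class")
})

test_that("class priors give rarer classes larger margins and weights", {
  labels <- data.frame(idh = rep(c(0, 1), c(200, 40)),
                       atrx = rep(c(0, 1), c(200, 40)),
                       codel = rep(c(0, 1), c(220, 20)))
  pr <- classPriors(labels, max_margin = 0.5)
  expect_gt(pr$idh$margins[2], pr$idh$margins[1])
  expect_equal(max(pr$idh$margins), 0.5)
  expect_gt(pr$idh$alpha[2], pr$idh$alpha[1])
  # rarer minority -> relatively smaller majority margin (max is pinned)
  expect_lt(pr$codel$margins[1], pr$idh$margins[1])
  # single-class gene: pseudocount keeps margins finite, zero errors out
  one <- data.frame(idh = rep(1, 10), atrx = rep(0, 10), codel = rep(0, 10))
  expect_silent(classPriors(one))
  expect_error(classPriors(one, pseudocount = 0), "no training examples")
})

test_that("the combined loss degenerates to its components", {
  set.seed(4)
  logits <- matrix(rnorm(12), 6, 2)
  y <- c(0, 1, 1, 0, 0, 1)
  pr <- list(margins = c(0.2, 0.5), alpha = c(0.5, 1.5))
  p <- exp(logits) / rowSums(exp(logits))
  expect_equal(lmfLoss(logits, y, pr, alpha = 1, beta = 0),
               ldamLoss(logits, y, pr$margins), tolerance = 1e-12)
  expect_equal(lmfLoss(logits, y, pr, alpha = 0, beta = 1, gamma = 2),
               focalLoss(p, y, pr$alpha, 2), tolerance = 1e-12)
  expect_equal(lmfLoss(logits, y, pr, 0.5, 0.5),
               0.5 * ldamLoss(logits, y, pr$margins) +
                 0.5 * focalLoss(p, y, pr$alpha, 2), tolerance = 1e-12)
  # autodiff form agrees
  expect_equal(agv(gliotyper:::agLmfLoss(gliotyper:::agConst(logits), y, pr)),
               lmfLoss(logits, y, pr), tolerance = 1e-10)
})

test_that("multi-task objective closed form and monotonicity", {
  # zero sub-losses at the stated initialization: log(5 * 6 * 6) = log 180
  expect_equal(multitaskLoss(c(0, 0, 0), c(5, 6, 6)), log(180),
               tolerance = 1e-12)
  l0 <- multitaskLoss(c(1, 1, 1), c(5, 6, 6))
  expect_gt(multitaskLoss(c(2, 1, 1), c(5, 6, 6)), l0)
  expect_error(multitaskLoss(c(1, 1, 1), c(-1, 6, 6)))
})

test_that("multi-task gradient in sigma matches the calculus closed form", {
  l <- c(0.8, 1.7, 0.4)
  s <- lapply(log(c(5, 6, 6)), gliotyper:::agParam)
  loss <- gliotyper:::agMultitaskLoss(
    lapply(l, gliotyper:::agConst), s)
  gliotyper:::agBackward(loss)
  for (i in 1:3) {
    sig <- exp(s[[i]]$v)
    # d/d log(sigma) = sigma * (-2 l / (3 sigma^3) + 1 / sigma)
    expected <- sig * (-2 * l[i] / (3 * sig^3) + 1 / sig)
    expect_equal(s[[i]]$grad, expected, tolerance = 1e-10)
  }
})

test_that("gradient descent recovers the stationary sigma = sqrt(2 l / 3)", {
  l <- c(0.3, 0.9, 1.5)
  s <- lapply(log(c(5, 6, 6)), gliotyper:::agParam)
  for (step in 1:4000) {
    gliotyper:::agZeroGrad(s)
    loss <- gliotyper:::agMultitaskLoss(lapply(l, gliotyper:::agConst), s)
    gliotyper:::agBackward(loss)
    for (p in s) p$v <- p$v - 0.01 * p$grad
  }
  got <- exp(vapply(s, function(p) p$v, numeric(1)))
  expect_equal(got, sigmaStationary(l), tolerance = 1e-3)
})
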