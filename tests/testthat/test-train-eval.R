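# Metrics, training determinism, model selection, feature-map export and
# the command-line surface.

test_that("rank AUC: separation, chance, tie handling and monotone invariance", {
  y <- c(rep(0, 5), rep(1, 5))
  s <- c(1:5, 6:10) / 10
  expect_equal(rankAUC(s, y), 1)
  expect_equal(rankAUC(-s, y), 0)
  # random scores: near 0.5 at large n
  set.seed(1)
  y2 <- rbinom(4000, 1, 0.3)
  s2 <- runif(4000)
  expect_lt(abs(rankAUC(s2, y2) - 0.5), 0.03)
  # invariant to monotone transforms
  expect_equal(rankAUC(qlogis(pmin(pmax(s2, 1e-6), 1 - 1e-6)), y2),
               rankAUC(s2, y2), tolerance = 1e-12)
  expect_true(is.na(rankAUC(s, rep(1, 10))))
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  y <- rbinom(300, 1, 0.25)
  s <- rnorm(300) + y
  expect_equal(rankAUC(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("confusion metrics match hand-computed counts", {
  # TP=3, FN=1, TN=5, FP=1
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  yhat <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  m <- gliotyper:::.geneMetrics(y, yhat, score = yhat)
  expect_equal(m$sens, 0.75)
  expect_equal(m$spec, 5 / 6)
  expect_equal(m$acc, 0.8)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(3, 1, 5, 1))
})

test_that("sensitivity at matched specificity reads the empirical ROC", {
  y <- c(0, 0, 0, 0, 1, 1)
  s <- c(0.1, 0.2, 0.3, 0.9, 0.8, 0.95)
  # at spec >= 0.75 (at most 1 FP): threshold 0.8 gives sens 1
  expect_equal(sensAtSpec(s, y, 0.75), 1)
  expect_equal(sensAtSpec(s, y, 1.0), 0.5)
})

test_that("short training runs are bit-deterministic under a fixed seed", {
  cohort <- tinyOverfitCohort(shape = c(8L, 8L, 8L))
  tc <- trainConfig(epochs = 2, lr = 1e-3, seed = 9, augment = TRUE)
  m1 <- trainGenotyper(cohort, cohort, config = microConfig(), tc = tc)
  m2 <- trainGenotyper(cohort, cohort, config = microConfig(), tc = tc)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
})

test_that("the checkpoint is the epoch of minimum validation loss", {
  cohort <- tinyOverfitCohort(shape = c(8L, 8L, 8L))
  tc <- trainConfig(epochs = 3, lr = 1e-3, seed = 4)
  m <- trainGenotyper(cohort, cohort, config = microConfig(), tc = tc)
  h <- trainingHistory(m)
  expect_lte(nrow(h), 3L)
  expect_equal(attr(h, "selected_epoch"), which.min(h$val_loss))
  # sigma trajectory is logged and positive
  expect_true(all(h$sigma_idh > 0))
  expect_equal(h$sigma_idh[1] < 5, TRUE)  # moves off its initialization
})

test_that("evaluation reports per-gene metrics consistent with predictions", {
  cohort <- tinyOverfitCohort(shape = c(8L, 8L, 8L))
  m <- initGenotypeModel(microConfig(), seed = 2)
  rep <- evaluateGenotyper(m, cohort)
  met <- evalMetrics(rep)
  expect_setequal(met$gene, c("idh", "atrx", "codel"))
  expect_true(all(met$acc >= 0 & met$acc <= 1))
  expect_equal(met$tp + met$fn + met$tn + met$fp, rep(8L, 3))
  expect_equal(nrow(rep@predictions), 8L)
})

test_that("feature-map export writes the requested stages deterministically", {
  s <- tinyOverfitCohort(shape = c(8L, 8L, 8L))[[1]]
  m <- initGenotypeModel(microConfig(), seed = 3)
  d1 <- withr::local_tempdir()
  paths <- exportFeatureMaps(m, s, stages = c("F3", "F6"), out_dir = d1)
  expect_length(paths, 2L)
  expect_true(all(file.exists(paths)))
  v1 <- RNifti::readNifti(paths[2])
  d2 <- withr::local_tempdir()
  paths2 <- exportFeatureMaps(m, s, stages = c("F3", "F6"), out_dir = d2)
  expect_equal(array(as.numeric(RNifti::readNifti(paths2[2])), dim(v1)),
               array(as.numeric(v1), dim(v1)))
  expect_true(all(is.finite(as.numeric(v1))))
  expect_error(exportFeatureMaps(m, s, stages = "F99", out_dir = d1),
               "unknown stage")
})

test_that("checkpoints round-trip through save/load", {
  cohort <- tinyOverfitCohort(shape = c(8L, 8L, 8L))
  tc <- trainConfig(epochs = 1, lr = 1e-3, seed = 5)
  m <- trainGenotyper(cohort, cohort, config = microConfig(), tc = tc)
  dir <- withr::local_tempdir()
  saveCheckpoint(m, dir)
  m2 <- loadCheckpoint(dir)
  expect_equal(predictSubject(m2, cohort[[1]]), predictSubject(m, cohort[[1]]))
  expect_equal(m2@priors$idh$margins, m@priors$idh$margins)
})

test_that("the command line handles help, simulate and bad input", {
  expect_output(code <- gliotyperMain("--help"), "usage: gliotyper")
  expect_equal(code, 0L)
  expect_equal(suppressMessages(gliotyperMain("frobnicate")), 2L)
  dir <- withr::local_tempdir()
  code <- suppressMessages(gliotyperMain(c(
    "simulate", "--n", "2", "--seed", "3", "--out", dir,
    "--shape", "12,12,12", "--imbalance", "idh=0.5,atrx=0.25,codel=0.25")))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_length(list.files(dir, pattern = "nii.gz$"), 8L)
})
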