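# Genotype sampling, phantom rendering, missing-modality patterns and
# cohort round-trips.

test_that("genotype dependency rules hold exactly at full adherence", {
  spec <- tinySpec(4000, class_fractions = c(idh = 0.33, atrx = 0.20,
                                             codel = 0.11))
  set.seed(1)
  g <- sampleGenotypes(spec)
  expect_true(all(g %in% 0:1))
  # wild-type IDH and mutant ATRX each force non-codeleted 1p/19q
  expect_equal(sum(g[g[, "idh"] == 0, "codel"]), 0)
  expect_equal(sum(g[g[, "atrx"] == 1, "codel"]), 0)
})

test_that("genotype marginals approach the target minority fractions", {
  spec <- tinySpec(10000, class_fractions = c(idh = 0.33, atrx = 0.20,
                                              codel = 0.11))
  set.seed(7)
  g <- sampleGenotypes(spec)
  expect_equal(mean(g[, "idh"]), 0.33, tolerance = 0.02 / 0.33)
  expect_lt(abs(mean(g[, "idh"]) - 0.33), 0.02)
  expect_lt(abs(mean(g[, "atrx"]) - 0.20), 0.02)
  expect_lt(abs(mean(g[, "codel"]) - 0.11), 0.02)
})

test_that("partial rule adherence still hits the codeletion marginal", {
  spec <- tinySpec(10000, rule_adherence = 0.5,
                   class_fractions = c(idh = 0.4, atrx = 0.2, codel = 0.15))
  set.seed(3)
  g <- sampleGenotypes(spec)
  expect_lt(abs(mean(g[, "codel"]) - 0.15), 0.02)
  # violations now occur but are diluted
  expect_gt(sum(g[g[, "idh"] == 0, "codel"]), 0)
})

test_that("unattainable codeletion fraction is a configuration error", {
  expect_error(
    tinySpec(10, class_fractions = c(idh = 0.2, atrx = 0.5, codel = 0.3)),
    "unattainable")
})

test_that("IDH-mutant phantoms carry the T2-FLAIR mismatch signature", {
  spec <- tinySpec(1, volume_shape = c(32L, 32L, 32L),
                   lesion_radius_range = c(5, 7), noise_sd = 0)
  set.seed(5)
  s_mut <- renderSubject(c(1, 1, 0), spec)
  set.seed(5)
  s_wt <- renderSubject(c(0, 0, 0), spec)
  rho_of <- function(s) {
    m <- s@meta
    sqrt(gliotyper:::.ellipsoidRho2(c(32L, 32L, 32L), m$center, m$semi))
  }
  core <- rho_of(s_mut) < 0.5
  # uniformly bright T2, dark FLAIR core for the mutant
  expect_gt(mean(s_mut@volumes$t2[core]), mean(s_mut@volumes$flair[core]))
  # the mismatch contrast separates the genotypes
  mismatch <- function(s, core) mean(s@volumes$t2[core] - s@volumes$flair[core])
  expect_gt(mismatch(s_mut, core), mismatch(s_wt, rho_of(s_wt) < 0.5))
})

test_that("IDH-wild-type phantoms show annular T1-ce enhancement with necrosis", {
  spec <- tinySpec(1, volume_shape = c(32L, 32L, 32L),
                   lesion_radius_range = c(5, 7), noise_sd = 0)
  set.seed(9)
  s <- renderSubject(c(0, 0, 0), spec)
  rho <- sqrt(gliotyper:::.ellipsoidRho2(c(32L, 32L, 32L),
                                         s@meta$center, s@meta$semi))
  rim <- rho > 0.7 & rho < 0.9
  core <- rho < 0.4
  expect_gt(mean(s@volumes$t1ce[rim]), mean(s@volumes$t1ce[core]))
})

test_that("ATRX mutation reduces edema halo extent", {
  spec <- tinySpec(1, volume_shape = c(32L, 32L, 32L),
                   lesion_radius_range = c(5, 6), noise_sd = 0,
                   edema_prob = 1)
  set.seed(2)
  s_wt <- renderSubject(c(1, 0, 0), spec)
  set.seed(2)
  s_mut <- renderSubject(c(1, 1, 0), spec)
  expect_true(s_wt@meta$has_edema)
  expect_equal(s_mut@meta$halo, s_wt@meta$halo / 2)
})

test_that("1p/19q codeletion blurs lesion margins", {
  spec <- tinySpec(1, volume_shape = c(32L, 32L, 32L),
                   lesion_radius_range = c(5, 6), noise_sd = 0,
                   edema_prob = 0)
  set.seed(4)
  s_cod <- renderSubject(c(1, 0, 1), spec)
  set.seed(4)
  s_non <- renderSubject(c(1, 0, 0), spec)
  rho <- sqrt(gliotyper:::.ellipsoidRho2(c(32L, 32L, 32L),
                                         s_cod@meta$center, s_cod@meta$semi))
  just_outside <- rho > 1.12 & rho < 1.2
  # the blurred lesion leaks T2 signal beyond the nominal boundary
  expect_gt(mean(s_cod@volumes$t2[just_outside]),
            mean(s_non@volumes$t2[just_outside]) + 0.05)
})

test_that("rendering is bit-deterministic at zero noise under a fixed seed", {
  spec <- tinySpec(1, noise_sd = 0)
  set.seed(123)
  a <- renderSubject(c(1, 0, 0), spec)
  set.seed(123)
  b <- renderSubject(c(1, 0, 0), spec)
  expect_identical(a@volumes, b@volumes)
})

test_that("missing-modality patterns never drop T2 or FLAIR and match weights", {
  spec <- tinySpec(1, missing_weights = c(full = 0.168, no_t1ce = 0.495,
                                          no_t1 = 0.337))
  set.seed(6)
  base <- renderSubject(c(0, 0, 0), spec)
  set.seed(8)
  pats <- replicate(1000, {
    s <- applyMissingModalities(base, spec)
    paste(as.integer(s@availability), collapse = "")
  })
  tab <- table(pats) / 1000
  expect_true(all(substr(names(tab), 3, 4) == "11"))  # T2+FLAIR always kept
  expect_lt(abs(tab[["1111"]] - 0.168), 0.05)
  expect_lt(abs(tab[["1011"]] - 0.495), 0.05)
  expect_lt(abs(tab[["0111"]] - 0.337), 0.05)
})

test_that("degenerate pattern weights behave as stated", {
  base <- { set.seed(1); renderSubject(c(0, 0, 0), tinySpec(1)) }
  s_full <- applyMissingModalities(base, tinySpec(1, missing_weights = c(1, 0, 0)))
  expect_equal(length(s_full@volumes), 4L)
  s_not1ce <- applyMissingModalities(base, tinySpec(1, missing_weights = c(0, 1, 0)))
  expect_false("t1ce" %in% names(s_not1ce@volumes))
  expect_equal(s_not1ce@availability, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("cohort write/read round-trips exactly, counting files", {
  spec <- tinySpec(2, seed = 21)
  cohort <- simulateCohort(spec)
  dir <- withr::local_tempdir()
  manifest <- writeCohort(cohort, dir)
  expect_equal(nrow(manifest), 8L)  # 2 subjects x 4 modalities
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- readCohort(dir)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    expect_identical(genotypeLabels(back[[i]]), genotypeLabels(cohort[[i]]))
    for (m in names(cohort[[i]]@volumes))
      expect_equal(back[[i]]@volumes[[m]], cohort[[i]]@volumes[[m]],
                   tolerance = 0)
  }
})

test_that("a subject missing T1-ce writes three volumes and the right mask", {
  spec <- tinySpec(1, missing_weights = c(0, 1, 0), seed = 31)
  cohort <- simulateCohort(spec)
  dir <- withr::local_tempdir()
  manifest <- writeCohort(cohort, dir)
  expect_equal(nrow(manifest), 3L)
  back <- readCohort(dir)[[1]]
  expect_equal(back@availability, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("simulateCohort is fully deterministic under its seed", {
  a <- simulateCohort(tinySpec(3, seed = 77))
  b <- simulateCohort(tinySpec(3, seed = 77))
  expect_identical(lapply(a, function(s) s@volumes),
                   lapply(b, function(s) s@volumes))
})
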