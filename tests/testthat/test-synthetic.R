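test_that("generator configuration is validated", {
  expect_error(syntheticCohortConfig(functionalEffectEdges = list(c(1, 99))),
               "effect edges")
  expect_error(syntheticCohortConfig(
    structuralEffectBlobs = list(list(center = c(2, 2, 2), radius = 5,
                                      delta = -0.5))),
    "outside the volume")
  expect_error(syntheticCohortConfig(temporalArCoeff = 1), "\\[0, 1\\)")
  expect_error(syntheticCohortConfig(modalitySignalSplit = 2), "\\[0, 1\\]")
})

test_that("null covariance produces no group difference on the effect edges", {
  cfg <- syntheticCohortConfig(nClass0 = 2, nClass1 = 2, nRois = 10,
                               nTimepoints = 120,
                               functionalEffectEdges = list(c(1, 6)),
                               functionalEffectDelta = 0, seed = 1)
  set.seed(123)
  est <- function(label) {
    replicate(100, {
      ts <- generateTimeSeries(cfg, label)
      as.matrix(pearsonFCN(ts))[1, 6]
    })
  }
  diff <- mean(est(1)) - mean(est(0))
  expect_lte(abs(diff), 0.05)
})

test_that("a covariance shift on an edge raises the group difference of its correlation", {
  cfg <- syntheticCohortConfig(nClass0 = 2, nClass1 = 2, nRois = 10,
                               nTimepoints = 120,
                               functionalEffectEdges = list(c(1, 2)),
                               functionalEffectDelta = 0.4, seed = 1)
  set.seed(321)
  est <- function(label) {
    replicate(100, {
      ts <- generateTimeSeries(cfg, label)
      as.matrix(pearsonFCN(ts))[1, 2]
    })
  }
  diff <- mean(est(1)) - mean(est(0))
  expect_gte(diff, 0.15)
})

test_that("generation is a pure function of configuration and seed", {
  cfg <- syntheticCohortConfig(nClass0 = 3, nClass1 = 3, nRois = 6,
                               nTimepoints = 30, volumeShape = c(8, 8, 8),
                               functionalEffectEdges = list(c(1, 6)),
                               structuralEffectBlobs = list(
                                 list(center = c(4, 4, 4), radius = 2,
                                      delta = -0.3)),
                               seed = 99)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(lapply(c1, function(s) s$ts@values),
                   lapply(c2, function(s) s$ts@values))
  expect_identical(lapply(c1, function(s) s$volume@values),
                   lapply(c2, function(s) s$volume@values))
})

test_that("volumes follow the blob contract", {
  shape <- c(16, 16, 16)
  blob <- list(center = c(8, 8, 8), radius = 3, delta = -0.5)
  base <- syntheticCohortConfig(nClass0 = 2, nClass1 = 2,
                                volumeShape = shape,
                                structuralEffectBlobs = list(blob),
                                structuralSeverityRange = c(1, 1),
                                noiseSd = 0, seed = 1)
  # noiseless null: identical volumes across classes when delta is zero
  cfg0 <- base
  cfg0$structuralEffectBlobs[[1]]$delta <- 0
  v0 <- generateVolume(cfg0, 0)@values
  v1 <- generateVolume(cfg0, 1)@values
  expect_identical(v0, v1)
  expect_identical(dim(v0), as.integer(shape))

  # Monte-Carlo in-blob mean difference within 20% of the configured delta
  cfgN <- base
  cfgN$noiseSd <- 0.3
  idx <- which(outer(outer((seq_len(16) - 8)^2, (seq_len(16) - 8)^2, `+`),
                     (seq_len(16) - 8)^2, `+`) <= 9)
  set.seed(55)
  d <- replicate(100,
    mean(generateVolume(cfgN, 1)@values[idx]) -
      mean(generateVolume(cfgN, 0)@values[idx]))
  expect_lt(abs(mean(d) - (-0.5)), 0.1)
})

test_that("modality routing extremes silence exactly one modality", {
  mk <- function(split) {
    syntheticCohortConfig(nClass0 = 4, nClass1 = 4, nRois = 8,
                          nTimepoints = 30, volumeShape = c(8, 8, 8),
                          functionalEffectEdges = list(c(1, 6), c(2, 7)),
                          structuralEffectBlobs = list(
                            list(center = c(4, 4, 4), radius = 2,
                                 delta = -0.5)),
                          structuralSeverityRange = c(1, 1),
                          noiseSd = 0, modalitySignalSplit = split,
                          seed = 3)
  }
  # split 1: all signal functional, volumes carry no class effect
  c1 <- generateCohort(mk(1))
  vols <- lapply(c1, function(s) s$volume@values)
  expect_identical(vols[[1]], vols[[8]])  # class 0 vs class 1, noiseless
  expect_length(c1[[8]]$groundTruth$structuralBlobs, 0)
  expect_length(c1[[8]]$groundTruth$functionalEdges, 2)

  # split 0: all signal structural, time series share one covariance
  c0 <- generateCohort(mk(0))
  expect_length(c0[[8]]$groundTruth$functionalEdges, 0)
  expect_length(c0[[8]]$groundTruth$structuralBlobs, 1)
  expect_false(identical(vols[[8]],
                         generateCohort(mk(0))[[8]]$volume@values))
})

test_that("estimated correlations converge to the generating correlation for long series", {
  # AR smoothing preserves the covariance but lowers the effective
  # sample count, so the raw sampler is what convergence is checked on
  cfg <- syntheticCohortConfig(nClass0 = 2, nClass1 = 2, nRois = 6,
                               nTimepoints = 2000, temporalArCoeff = 0,
                               functionalEffectEdges = list(c(1, 6)),
                               functionalEffectDelta = 0.3, seed = 1)
  set.seed(77)
  for (label in c(0, 1)) {
    ts <- generateTimeSeries(cfg, label)
    got <- as.matrix(pearsonFCN(ts))
    want <- neurofuse:::class_covariance(
      cfg, if (label == 1) cfg$functionalEffectEdges else list())
    expect_lte(max(abs(got - want)), 0.05)
  }
})

test_that("with all deltas zero the two class generators are indistinguishable", {
  cfg <- syntheticCohortConfig(nClass0 = 2, nClass1 = 2, nRois = 10,
                               nTimepoints = 60,
                               functionalEffectDelta = 0,
                               functionalEffectEdges = list(c(1, 6)),
                               seed = 1)
  set.seed(404)
  feat <- function(label) {
    replicate(200, {
      b <- as.matrix(pearsonFCN(generateTimeSeries(cfg, label)))
      mean(abs(b[upper.tri(b)]))
    })
  }
  ks <- suppressWarnings(ks.test(feat(0), feat(1)))
  expect_gt(ks$p.value, 0.01)
})

test_that("positive definiteness is enforced by shrinkage toward the base covariance", {
  cfg <- syntheticCohortConfig(nRois = 6, nClass0 = 2, nClass1 = 2,
                               functionalEffectEdges =
                                 list(c(1, 2), c(1, 3), c(2, 3)),
                               functionalEffectDelta = 0.95, seed = 1)
  s1 <- neurofuse:::class_covariance(cfg, cfg$functionalEffectEdges)
  ev <- eigen(s1, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  # shrinkage pulled the shifted edges below the raw target
  expect_lt(s1[1, 2], cfg$baseCorrelation + 0.95)
  expect_gt(s1[1, 2], neurofuse:::base_covariance(cfg)[1, 2])
})

test_that("cohorts round-trip through the on-disk layout", {
  cfg <- syntheticCohortConfig(nClass0 = 2, nClass1 = 2, nRois = 5,
                               nTimepoints = 20, volumeShape = c(6, 6, 6),
                               functionalEffectEdges = list(c(1, 5)),
                               structuralEffectBlobs = list(
                                 list(center = c(3, 3, 3), radius = 1,
                                      delta = -0.2)),
                               seed = 8)
  coh <- generateCohort(cfg)
  dir <- withr::local_tempdir()
  manifest <- writeCohort(coh, dir)
  back <- readCohortManifest(manifest)
  expect_length(back, 4)
  expect_equal(back[[1]]$ts@values, coh[[1]]$ts@values,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back[[3]]$volume@values, coh[[3]]$volume@values,
               tolerance = 1e-6)
  expect_identical(sapply(back, `[[`, "label"),
                   sapply(coh, `[[`, "label"))
})
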