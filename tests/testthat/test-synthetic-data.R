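test_that("config validation rejects inconsistent generators", {
  expect_error(cohortConfig(offTopicPool = c("tea", "garden")), "overlap")
  expect_error(cohortConfig(offTopicPool = c("the", "garden")), "stoplist")
  expect_error(cohortConfig(controlDrift = c(picture_description = 0.9,
                                             storytelling = 0.04,
                                             procedural = 0.02)),
               "control drift")
  expect_error(cohortConfig(noiseSd = -1), "noise SD")
  expect_error(cohortConfig(criticalRegion = list(lo = c(1L, 1L, 1L),
                                                  hi = c(99L, 9L, 9L))),
               "inside the grid")
})

test_that("corpus construction separates topics and is byte-deterministic", {
  cfg <- cohortConfig(seed = 5, k = 12, docsPerPool = 6, docLength = 20)
  cs <- makeCorpusAndSpace(cfg)
  V <- attr(cs$space, "vectors")
  within <- between <- c()
  pools <- cs$pools
  for (i in seq_along(pools)) {
    pi <- intersect(pools[[i]], rownames(V))
    C <- V[pi, ] %*% t(V[pi, ])
    within <- c(within, mean(C[upper.tri(C)]))
    for (j in seq_along(pools)) if (j > i) {
      pj <- intersect(pools[[j]], rownames(V))
      between <- c(between, mean(V[pi, ] %*% t(V[pj, ])))
    }
  }
  expect_gt(min(within), max(between))

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  saveSpace(cs$space, f1)
  saveSpace(makeCorpusAndSpace(cfg)$space, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(makeCorpusAndSpace(cohortConfig(seed = 5, k = 500)),
               "attainable maximum")
})

test_that("transcripts are deterministic and drift separates the groups", {
  cfg <- cohortConfig(seed = 3, nControls = 6, nPatients = 8)
  tr1 <- makeTranscripts(cfg)
  tr2 <- makeTranscripts(cfg)
  expect_identical(tr1$data, tr2$data)
  expect_identical(tr1$truth, tr2$truth)
  d <- tr1$truth
  expect_gt(mean(d$drift[d$group == "patient"]),
            mean(d$drift[d$group == "control"]))
  expect_equal(nrow(tr1$data), (6 + 8) * 3)
})

test_that("zero drift for both groups removes the group effect", {
  cfg <- cohortConfig(seed = 11, nControls = 8, nPatients = 8,
                      controlDrift = c(picture_description = 0,
                                       storytelling = 0, procedural = 0),
                      patientDrift = c(picture_description = 0,
                                       storytelling = 0, procedural = 0),
                      emptyRate = 0)
  cs <- makeCorpusAndSpace(cfg)
  tr <- makeTranscripts(cfg)
  sc <- scoreCohort(recordsFromTable(tr$data, cs$space))
  an <- mixedAnova(sc)
  expect_gt(an$p[an$effect == "group"], 0.01)
})

test_that("component scores are exactly orthogonal with planted truth", {
  cfg <- cohortConfig(seed = 9)
  cp <- makeComponentScores(cfg, mode = "forward")
  X <- as.matrix(cp$components[, cohmap:::.COMPONENTS])
  C <- cor(X)
  expect_lt(max(abs(C[upper.tri(C)])), 1e-10)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 7), tolerance = 1e-12)
  expect_equal(unname(cp$truth$coefficients["phonological_production"]),
               0.132)
  expect_error(makeComponentScores(cfg, nPatients = 5), "at least 10")
})

test_that("null-mode components leave coherence unexplained at the nominal rate", {
  pvals <- sapply(1:60, function(s) {
    cp <- makeComponentScores(cohortConfig(seed = s + 1000), mode = "null")
    reg <- stagedRegressions(cp$composite, cp$components)
    co <- reg$coefficients
    co$p[co$label == "M3" & co$term == "executive_functions"]
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0)      # sanity
  expect_lte(rate, 0.15)   # ~5% nominal, generous binomial slack at 60 reps
})

test_that("lesion cohorts are deterministic with volumes in the configured range", {
  cfg <- cohortConfig(seed = 13, nPatients = 12, grid = c(16L, 16L, 16L),
                      criticalRegion = list(lo = c(7L, 7L, 7L),
                                            hi = c(9L, 9L, 9L)),
                      seedZone = list(lo = c(4L, 4L, 4L),
                                      hi = c(12L, 12L, 12L)),
                      sizeMeanLog = log(200), sizeSdLog = 0.6,
                      sizeRange = c(30, 1000))
  lc1 <- makeLesionCohort(cfg)
  lc2 <- makeLesionCohort(cfg)
  expect_identical(lc1$binary@images, lc2$binary@images)
  expect_identical(lc1$binary@behaviour, lc2$binary@behaviour)
  expect_true(all(lc1$truth$volumes >= 30 & lc1$truth$volumes <= 1000))
  # every lesion is one connected component
  for (i in 1:4) {
    idx <- which(lc1$binary@images[, , , i] == 1)
    expect_length(labelClusters(idx, c(16, 16, 16), 6), 1)
  }
  # continuous images derive from the binary by smoothing
  expect_equal(lc1$continuous@images[, , , 1],
               smoothImage(lc1$binary@images[, , , 1], cfg$fwhm,
                           cfg$voxelSize), tolerance = 1e-12)
})

test_that("default lesion volumes respect the published range", {
  lc <- makeLesionCohort(cohortConfig(seed = 21))
  expect_true(all(lc$truth$volumes >= 175 & lc$truth$volumes <= 41379))
})

test_that("a wider drift gap increases the expected group effect", {
  fOf <- function(gap, s) {
    cfg <- cohortConfig(seed = s, nControls = 8, nPatients = 10,
                        emptyRate = 0,
                        patientDrift = c(picture_description = 0.05 + gap,
                                         storytelling = 0.04 + gap,
                                         procedural = 0.02 + gap))
    cs <- makeCorpusAndSpace(cfg)
    tr <- makeTranscripts(cfg)
    sc <- scoreCohort(recordsFromTable(tr$data, cs$space))
    an <- mixedAnova(sc)
    an$F[an$effect == "group"]
  }
  f0 <- mean(sapply(1:3, fOf, gap = 0))
  f1 <- mean(sapply(1:3, fOf, gap = 0.45))
  expect_gt(f1, f0)
})
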