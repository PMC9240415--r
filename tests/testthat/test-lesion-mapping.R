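test_that("smoothing has identity, constancy and impulse-response properties", {
  set.seed(1)
  img <- array(runif(16^3), c(16, 16, 16))
  expect_identical(smoothImage(img, 0, c(2, 2, 2)), img)

  u <- array(1, c(24, 24, 24))
  su <- smoothImage(u, 8, c(2, 2, 2))
  expect_equal(su[9:16, 9:16, 9:16], u[9:16, 9:16, 9:16], tolerance = 1e-10)

  imp <- array(0, c(17, 17, 17)); imp[9, 9, 9] <- 1
  got <- smoothImage(imp, 8, c(2, 2, 2))
  expect_equal(got, gaussSmoothOracle(imp, 8, c(2, 2, 2)), tolerance = 1e-6)
  # mass preserved away from boundary
  expect_equal(sum(got), 1, tolerance = 1e-10)
  expect_error(smoothImage(img, 8), "voxel size")
})

test_that("binarization uses a strict threshold and volume counts voxels", {
  img <- array(c(0.51, 0.5, 0.49, rep(0, 24)), c(3, 3, 3))
  b <- binarizeImage(img, 0.5)
  expect_equal(b[1, 1, 1], 1)
  expect_equal(b[2, 1, 1], 0)
  expect_warning(binarizeImage(array(0, c(2, 2, 2))), "all zero")

  m <- array(0, c(3, 3, 3)); m[c(1, 5, 9, 14, 27)] <- 1
  expect_equal(lesionVolume(m), 5)
  expect_equal(lesionVolume(array(0, c(3, 3, 3))), 0)
  expect_error(lesionVolume(img), "binary")
})

test_that("cluster labeling respects connectivity and partitions the input", {
  dims <- c(5, 5, 5)
  # two voxels touching only diagonally in 3D
  a <- c(1, 1, 1); b <- c(2, 2, 2)
  lin <- function(v) (v[3] - 1) * 25 + (v[2] - 1) * 5 + v[1]
  idx <- c(lin(a), lin(b))
  expect_length(labelClusters(idx, dims, 26), 1)
  expect_length(labelClusters(idx, dims, 6), 2)
  # face-touching voxels merge even at 6-connectivity
  idx2 <- c(lin(c(1, 1, 1)), lin(c(2, 1, 1)), lin(c(5, 5, 5)))
  cl <- labelClusters(idx2, dims, 6)
  expect_length(cl, 2)
  expect_setequal(unlist(cl), idx2)
  expect_equal(sum(lengths(cl)), 3)
  # edge-touching voxels merge at 18 but not 6
  idx3 <- c(lin(c(3, 3, 3)), lin(c(4, 4, 3)))
  expect_length(labelClusters(idx3, dims, 18), 1)
  expect_length(labelClusters(idx3, dims, 6), 2)
})

test_that("voxel t statistics equal the correlation-t closed form", {
  set.seed(10)
  n <- 10
  X <- matrix(rnorm(n * 5, 0.4, 0.15), 5, n)
  X <- pmin(pmax(X, 0), 1)
  beh <- runif(n)
  ds <- handLesionDataset(X, c(5, 1, 1), beh, binary = FALSE)
  res <- suppressWarnings(vbcm(ds, nPerm = 99, seed = 1))
  tmap <- res$map@statistic[, 1, 1]
  for (v in 1:5)
    expect_equal(tmap[v], corrTOracle(X[v, ], beh), tolerance = 1e-8)
  expect_equal(res$map@info$df, n - 2)
})

test_that("constant behaviour yields no suprathreshold voxels", {
  set.seed(2)
  X <- matrix(runif(20 * 12), 20, 12)
  ds <- handLesionDataset(X, c(5, 2, 2), rep(0.7, 12), binary = FALSE)
  res <- suppressWarnings(vbcm(ds, nPerm = 99, seed = 1))
  expect_equal(nrow(clusterTable(res$clusters)), 0)
  expect_true(all(res$map@statistic[!is.na(res$map@statistic)] == 0))
})

test_that("zero-variance voxels are excluded from the analysis mask", {
  set.seed(3)
  X <- matrix(runif(8 * 15), 8, 15)
  X[3, ] <- 0.5
  ds <- handLesionDataset(X, c(8, 1, 1), runif(15), binary = FALSE)
  expect_message(res <- vbcm(ds, nPerm = 100, seed = 1), "zero-variance")
  expect_true(is.na(res$map@statistic[3, 1, 1]))
  expect_warning(vbcm(ds, nPerm = 50, seed = 1), "coarse")
})

test_that("permutation cluster p-values are bounded away from zero", {
  cfg <- cohortConfig(seed = 6, grid = c(16, 16, 16),
                      criticalRegion = list(lo = c(7L, 7L, 7L),
                                            hi = c(9L, 9L, 9L)),
                      seedZone = list(lo = c(4L, 4L, 4L),
                                      hi = c(12L, 12L, 12L)),
                      sizeMeanLog = log(150), sizeSdLog = 0.5,
                      sizeRange = c(30, 800), signalMode = "direct",
                      lesionEffect = 0.6, lesionNoiseSd = 0.05, fwhm = 4)
  lc <- makeLesionCohort(cfg)
  res <- suppressMessages(vbcm(lc$continuous, nPerm = 199, seed = 3))
  tab <- clusterTable(res$clusters)
  expect_gt(nrow(tab), 0)
  expect_true(all(tab$p_fwe >= 1 / 200 & tab$p_fwe <= 1))
  # the planted cluster is recovered and significant
  expect_lt(tab$p_fwe[1], 0.05)
  expect_gt(length(intersect(res$clusters@voxels[[1]],
                             which(lc$truth$critical_mask))), 0)
})

test_that("multi-regressor VBCM isolates unique effects and rejects collinearity", {
  cfg <- cohortConfig(seed = 8, grid = c(16, 16, 16),
                      criticalRegion = list(lo = c(7L, 7L, 7L),
                                            hi = c(9L, 9L, 9L)),
                      seedZone = list(lo = c(4L, 4L, 4L),
                                      hi = c(12L, 12L, 12L)),
                      sizeMeanLog = log(150), sizeSdLog = 0.5,
                      sizeRange = c(30, 800), signalMode = "direct",
                      lesionEffect = 0.6, lesionNoiseSd = 0.05, fwhm = 4)
  lc <- makeLesionCohort(cfg)
  ds <- lc$continuous

  expect_error(vbcmMulti(ds, list(dup = ds@behaviour), nPerm = 99),
               "collinear")

  # extra pure-noise regressors leave the coherence map essentially unchanged
  set.seed(99)
  noise <- list(n1 = runif(nPatients(ds)), n2 = runif(nPatients(ds)))
  base <- suppressMessages(vbcm(ds, nPerm = 199, seed = 5))
  multi <- suppressMessages(vbcmMulti(ds, noise, nPerm = 199, seed = 5))
  a <- unlist(base$clusters@voxels); b <- unlist(multi$coherence$clusters@voxels)
  dice <- 2 * length(intersect(a, b)) / (length(a) + length(b))
  expect_gt(dice, 0.8)

  # a signal carried entirely by regressor A leaves no coherence cluster:
  # A is the planted severity, coherence is pure noise
  dsNull <- ds
  set.seed(7)
  dsNull@behaviour <- runif(nPatients(ds))
  multi2 <- suppressMessages(
    vbcmMulti(dsNull, list(A = ds@behaviour), nPerm = 199, seed = 5))
  tabC <- clusterTable(multi2$coherence$clusters)
  expect_true(nrow(tabC) == 0 || min(tabC$p_fwe) > 0.05)
  expect_lt(clusterTable(multi2$A$clusters)$p_fwe[1], 0.05)
})

test_that("SVR-LSM enforces the lesion-threshold contract", {
  set.seed(20)
  n <- 46; V <- 64
  X <- matrix(rbinom(V * n, 1, 0.4), V, n)
  X[5, ] <- 0; X[5, 1:3] <- 1   # coverage 3: below threshold
  X[6, ] <- 0; X[6, 1:4] <- 1   # coverage 4: retained
  ds <- handLesionDataset(X, c(4, 4, 4), runif(n),
                          covariates = data.frame(age = rnorm(n, 63, 10)))
  res <- svrLsm(ds, lesionThreshold = 4, nPerm = 19, seed = 1, nTune = 2)
  expect_true(is.na(res$map@statistic[5]))
  expect_false(is.na(res$map@statistic[6]))
  expect_error(svrLsm(ds, lesionThreshold = 47, nPerm = 19, seed = 1),
               "empty feature set")
  expect_error(svrLsm(handLesionDataset(X, c(4, 4, 4), rep(0.5, n)),
                      nPerm = 19, seed = 1), "degenerate behaviour")
  ds2 <- handLesionDataset(X * 0.7, c(4, 4, 4), runif(n), binary = FALSE)
  expect_error(svrLsm(ds2, nPerm = 19, seed = 1), "binary")
})

test_that("a noiseless planted voxel attains the largest SVR weight", {
  for (s in 1:5) {
    set.seed(s)
    n <- 46; g <- 8; V <- g^3
    X <- matrix(rbinom(V * n, 1, 0.3), V, n)
    v <- 260L
    beh <- 1 - X[v, ]
    ds <- handLesionDataset(X, c(g, g, g), beh,
                            covariates = data.frame(age = rnorm(n, 63, 10)))
    res <- svrLsm(ds, nPerm = 19, seed = s, nTune = 2)
    b <- res$map@statistic
    fi <- which(!is.na(b))
    expect_equal(fi[which.max(abs(b[fi]))], v)
    expect_lt(b[v], 0)  # deficit direction
  }
})

test_that("SVR permutation p-values are bounded and in [1/(nPerm+1), 1]", {
  set.seed(31)
  n <- 46; X <- matrix(rbinom(125 * n, 1, 0.3), 125, n)
  ds <- handLesionDataset(X, c(5, 5, 5), runif(n))
  res <- svrLsm(ds, nPerm = 99, seed = 2, nTune = 2)
  p <- res$map@pVoxel[!is.na(res$map@pVoxel)]
  expect_true(all(p >= 1 / 100 - 1e-12 & p <= 1 + 1e-12))
})

test_that("behaviour equal to lesion volume vanishes under volume control", {
  set.seed(40)
  n <- 46; g <- 8; V <- g^3
  X <- matrix(0, V, n)
  for (i in seq_len(n)) X[sample(V, sample(40:300, 1)), i] <- 1
  vols <- colSums(X)
  ds <- handLesionDataset(X, c(g, g, g), vols / max(vols),
                          covariates = data.frame(age = rnorm(n, 63, 10),
                                                  lesion_volume = vols))
  res <- svrLsm(ds, nPerm = 99, seed = 3, controlVolume = TRUE, nTune = 2)
  tab <- clusterTable(res$clusters)
  expect_true(nrow(tab) == 0 || min(tab$p_fwe) > 0.05)
})
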