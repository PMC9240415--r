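# Independent oracles used to freeze expected values. Each deliberately
# takes a different computational path from the implementation it checks.

# dense SVD via the eigendecomposition of W'W (rather than svd()):
# V from eigenvectors, d = sqrt(eigenvalues), U = W V D^-1; same sign
# convention as the package (largest-|u| entry positive)
svdOracleTermVectors <- function(W, k) {
  e <- eigen(crossprod(W), symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))[1:k]
  V <- e$vectors[, 1:k, drop = FALSE]
  U <- W %*% V %*% diag(1 / d, k)
  for (j in 1:k) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  tv <- U %*% diag(d, k)
  tv / sqrt(rowSums(tv^2))
}

# brute-force sums-of-squares decomposition for a balanced 2-group by
# q-task mixed design; y is an n x q matrix, g a group factor
mixedAnovaOracle <- function(y, g) {
  n <- nrow(y); q <- ncol(y)
  gm <- mean(y)
  subj <- rowMeans(y)
  taskm <- colMeans(y)
  groups <- unique(g)
  gmean <- sapply(groups, function(gg) mean(y[g == gg, , drop = FALSE]))
  cellm <- sapply(seq_len(q), function(j)
    sapply(groups, function(gg) mean(y[g == gg, j])))
  ng <- sapply(groups, function(gg) sum(g == gg))

  ss_group <- q * sum(ng * (gmean - gm)^2)
  ss_subj_within <- q * sum((subj - gmean[match(g, groups)])^2)
  ss_task <- n * sum((taskm - gm)^2)
  ss_gxt <- sum(sapply(seq_len(q), function(j)
    sum(ng * (cellm[, j] - gmean - taskm[j] + gm)^2)))
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_group - ss_subj_within - ss_task - ss_gxt

  df_g <- length(groups) - 1; df_sw <- n - length(groups)
  df_t <- q - 1; df_gt <- df_g * df_t; df_e <- df_sw * df_t
  data.frame(
    effect = c("group", "task", "group:task"),
    F = c((ss_group / df_g) / (ss_subj_within / df_sw),
          (ss_task / df_t) / (ss_err / df_e),
          (ss_gxt / df_gt) / (ss_err / df_e)),
    df1 = c(df_g, df_t, df_gt),
    df2 = c(df_sw, df_e, df_e),
    partial_eta_sq = c(ss_group / (ss_group + ss_subj_within),
                       ss_task / (ss_task + ss_err),
                       ss_gxt / (ss_gxt + ss_err)))
}

# normal-equations OLS
olsOracle <- function(X, y) {
  Xi <- cbind(1, X)
  as.numeric(solve(t(Xi) %*% Xi) %*% t(Xi) %*% y)
}

# correlation-t identity for a no-covariate voxel fit
corrTOracle <- function(x, y) {
  r <- cor(x, y)
  n <- length(x)
  r * sqrt((n - 2) / (1 - r^2))
}

# brute-force 3D Gaussian smoothing by direct kernel evaluation over the
# truncated cubic support
gaussSmoothOracle <- function(img, fwhm, voxelSize) {
  sigma <- (fwhm / (2 * sqrt(2 * log(2)))) / voxelSize
  r <- pmax(1, ceiling(4 * sigma))
  d <- dim(img)
  out <- array(0, d)
  off <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
  w <- exp(-(off[, 1]^2 / (2 * sigma[1]^2) + off[, 2]^2 / (2 * sigma[2]^2) +
               off[, 3]^2 / (2 * sigma[3]^2)))
  w <- w / sum(w)
  nz <- which(img != 0, arr.ind = TRUE)
  for (v in seq_len(nrow(nz))) {
    tgt <- sweep(off, 2, nz[v, ], `+`)
    ok <- tgt[, 1] >= 1 & tgt[, 1] <= d[1] & tgt[, 2] >= 1 &
      tgt[, 2] <= d[2] & tgt[, 3] >= 1 & tgt[, 3] <= d[3]
    out[tgt[ok, , drop = FALSE]] <-
      out[tgt[ok, , drop = FALSE]] + img[nz[v, , drop = FALSE]] * w[ok]
  }
  out
}

# a tiny hand-set semantic space from named vectors
handSpace <- function(...) {
  v <- rbind(...)
  v <- v / sqrt(rowSums(v^2))
  new("SemanticSpace", vectors = v, provenance = "hand-built test space")
}

# a hand-built LesionDataset from a voxel-by-patient matrix
handLesionDataset <- function(X, dims, behaviour, covariates = NULL,
                              binary = TRUE, voxelSize = c(2, 2, 2)) {
  n <- ncol(X)
  if (is.null(covariates))
    covariates <- as.data.frame(matrix(nrow = n, ncol = 0))
  imgs <- array(as.numeric(X), c(dims, n))
  mask <- array(TRUE, dims)
  new("LesionDataset", images = imgs, behaviour = as.numeric(behaviour),
      covariates = covariates, mask = mask, voxelSize = voxelSize,
      binary = binary, affine = NULL)
}

# a small response-record cohort from hand-set token lists
handRecords <- function(space, spec) {
  lapply(spec, function(s)
    responseRecord(s$id, s$group, s$task, paste(s$tokens, collapse = " "),
                   space, stoplist = character(0)))
}
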