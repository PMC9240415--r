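#' Gaussian smoothing of a lesion image
#'
#' Separable Gaussian convolution with \code{sigma = fwhm / (2 sqrt(2 ln 2))}
#' per axis, converted to voxels through the voxel size. The kernel is
#' truncated at 4 sigma and normalized; boundaries are zero-padded, so mass
#' is preserved away from the image edge. \code{fwhm = 0} returns the input
#' unchanged.
#'
#' @param image 3D numeric array
#' @param fwhm full width at half maximum of the kernel, in mm (>= 0)
#' @param voxelSize numeric(3), voxel edge lengths in mm
#' @return 3D numeric array of the same dimensions
#' @export
smoothImage <- function(image, fwhm, voxelSize) {
  stopifnot(length(dim(image)) == 3L, fwhm >= 0)
  if (missing(voxelSize) || length(voxelSize) != 3L ||
      any(!is.finite(voxelSize)) || any(voxelSize <= 0))
    stop("unknown voxel size: supply voxelSize as three positive mm lengths")
  if (fwhm == 0) return(image)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  out <- image
  for (axis in 1:3) {
    sigma <- sigma_mm / voxelSize[axis]
    out <- .convolveAxis(out, .gaussKernel(sigma), axis)
  }
  out
}

.gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w / sum(w)
}

# 1D convolution along one axis of a 3D array via a banded kernel matrix
# (zero boundary padding)
.convolveAxis <- function(x, w, axis) {
  p <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, p)
  n <- dim(xp)[1]
  r <- (length(w) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (d in (-r):r) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- w[d + r + 1L]
  }
  res <- array(K %*% matrix(xp, n), dim = dim(xp))
  aperm(res, order(p))
}

#' Binarize a continuous lesion image
#'
#' Voxel value 1 iff the continuous abnormality exceeds \code{u} (strict
#' ">": a voxel exactly at the threshold stays 0).
#'
#' @param image 3D numeric array of values in [0, 1]
#' @param u threshold (default 0.5)
#' @return 3D array of 0/1
#' @export
binarizeImage <- function(image, u = 0.5) {
  out <- (image > u) * 1
  if (all(out == 0)) warning("binarized image is all zero")
  out
}

#' Lesion volume in voxels
#'
#' @param image binary 3D array
#' @return integer count of lesioned voxels
#' @export
lesionVolume <- function(image) {
  if (!all(image %in% c(0, 1))) stop("lesionVolume expects a binary image")
  sum(image == 1)
}

.connOffsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  lim <- c(`6` = 1L, `18` = 2L, `26` = 3L)[[as.character(connectivity)]]
  g[rowSums(abs(g)) <= lim, , drop = FALSE]
}

#' Connected components of a voxel set
#'
#' Labels the given voxels (linear indices into a 3D grid) into connected
#' clusters under 6-, 18- or 26-neighbourhood connectivity.
#'
#' @param idx integer vector of linear voxel indices
#' @param dims integer(3) grid dimensions
#' @param connectivity 6, 18 or 26 (default 26)
#' @return list of integer vectors, one per cluster, partitioning \code{idx}
#' @export
labelClusters <- function(idx, dims, connectivity = 26L) {
  off <- .connOffsets(connectivity)
  if (length(idx) == 0L) return(list())
  idx <- as.integer(idx)
  vol <- array(0L, dims)
  vol[idx] <- seq_along(idx)
  coords <- arrayInd(idx, dims)
  mult <- c(1L, dims[1], dims[1] * dims[2])
  visited <- logical(length(idx))
  clusters <- list()
  for (s in seq_along(idx)) {
    if (visited[s]) next
    visited[s] <- TRUE
    members <- s
    frontier <- s
    while (length(frontier)) {
      cs <- coords[frontier, , drop = FALSE]
      nb <- cs[rep(seq_len(nrow(cs)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(cs)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) break
      lin <- (nb[, 3] - 1L) * mult[3] + (nb[, 2] - 1L) * mult[2] + nb[, 1]
      rows <- unique(vol[lin])
      rows <- rows[rows > 0L]
      rows <- rows[!visited[rows]]
      if (!length(rows)) break
      visited[rows] <- TRUE
      members <- c(members, rows)
      frontier <- rows
    }
    clusters[[length(clusters) + 1L]] <- sort(idx[members])
  }
  clusters
}

.maxClusterSize <- function(idx, dims, connectivity) {
  if (length(idx) <= 1L) return(length(idx))
  max(lengths(labelClusters(idx, dims, connectivity)))
}

# residualize columns of M against the column space of Z (Z includes the
# intercept)
.residualize <- function(M, Z) {
  M - Z %*% solve(crossprod(Z), crossprod(Z, M))
}

.covariateMatrix <- function(ds, controlVolume) {
  cov <- ds@covariates
  if (controlVolume) {
    if (!"lesion_volume" %in% names(cov))
      stop("controlVolume = TRUE requires a 'lesion_volume' covariate column")
  } else {
    cov <- cov[, setdiff(names(cov), "lesion_volume"), drop = FALSE]
  }
  as.matrix(cov)
}

.buildClusterSet <- function(gridIdx, statVals, dims, connectivity, maxNull,
                             nPerm) {
  cl <- labelClusters(gridIdx, dims, connectivity)
  if (length(cl)) {
    tab <- do.call(rbind, lapply(seq_along(cl), function(i) {
      vox <- cl[[i]]
      st <- statVals[match(vox, gridIdx)]
      pk <- vox[which.max(abs(st))]
      pc <- arrayInd(pk, dims) - 1L
      data.frame(cluster_id = i, size = length(vox),
                 peak_stat = st[which.max(abs(st))],
                 peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
                 p_fwe = (1 + sum(maxNull >= length(vox))) / (nPerm + 1))
    }))
    ord <- order(tab$size, decreasing = TRUE)
    tab <- tab[ord, , drop = FALSE]
    cl <- cl[ord]
    tab$cluster_id <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(cluster_id = integer(0), size = integer(0),
                      peak_stat = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      p_fwe = numeric(0))
  }
  new("ClusterSet", table = tab, voxels = cl,
      connectivity = as.integer(connectivity), dim = as.integer(dims))
}

.newStatMap <- function(dims, maskIdx, stat, p, mask, info) {
  sa <- array(NA_real_, dims); sa[maskIdx] <- stat
  pa <- array(NA_real_, dims); pa[maskIdx] <- p
  new("StatMap", statistic = sa, pVoxel = pa, mask = mask, info = info)
}

#' Voxel-based correlational mapping (VBCM)
#'
#' Mass-univariate lesion-symptom mapping for continuous (smoothed)
#' abnormality images: at every voxel in the analysis mask, behaviour is
#' regressed on the voxel value plus nuisance covariates, and the t
#' statistic of the voxel-value coefficient is stored (negative t = more
#' abnormality associated with lower behaviour, the deficit direction).
#' Suprathreshold voxels (two-tailed voxel-wise p below \code{voxelP}, in
#' the deficit direction by default) are grouped into connected clusters,
#' and each cluster's family-wise-error corrected p-value is the
#' permutation tail probability of the maximum cluster size under
#' behaviour permutations. Covariates are handled by the Freedman-Lane
#' scheme: the residuals of behaviour on the covariates are permuted.
#'
#' @param ds a \linkS4class{LesionDataset} (continuous images)
#' @param voxelP voxel-level two-tailed p threshold (default 0.001)
#' @param clusterP cluster-level FWE threshold recorded in the metadata
#'   (default 0.05); clusters of all sizes are reported with their p_fwe
#' @param nPerm number of behaviour permutations (default 1000; fewer than
#'   100 triggers a warning)
#' @param connectivity cluster connectivity, 6, 18 or 26 (default 26)
#' @param controlVolume include the 'lesion_volume' covariate column
#'   (default FALSE; when FALSE an existing lesion_volume column is
#'   ignored)
#' @param direction "deficit" (default) clusters voxels where damage
#'   predicts lower behaviour; "both" clusters each sign separately
#' @param seed optional integer seed for the permutations
#' @return list with \code{map} (a \linkS4class{StatMap}) and
#'   \code{clusters} (a \linkS4class{ClusterSet})
#' @export
vbcm <- function(ds, voxelP = 0.001, clusterP = 0.05, nPerm = 1000L,
                 connectivity = 26L, controlVolume = FALSE,
                 direction = c("deficit", "both"), seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(is(ds, "LesionDataset"))
  if (nPerm < 100L) warning("nPerm < 100 gives very coarse FWE p-values")
  if (!is.null(seed)) set.seed(seed)
  cov <- .covariateMatrix(ds, controlVolume)
  n <- nPatients(ds)
  if (n < ncol(cov) + 3L)
    stop("need at least ", ncol(cov) + 3L, " patients, got ", n)
  dims <- dim(ds@images)[1:3]
  maskIdx <- which(ds@mask)
  if (!length(maskIdx)) stop("empty analysis mask")
  M <- matrix(ds@images, prod(dims), n)
  X <- t(M[maskIdx, , drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " zero-variance voxel(s) excluded from the mask")
    maskIdx <- maskIdx[sds > 0]
    X <- X[, sds > 0, drop = FALSE]
  }
  mask <- array(FALSE, dims); mask[maskIdx] <- TRUE

  Z <- cbind(1, cov)
  df <- n - ncol(Z) - 1L
  Xr <- .residualize(X, Z)
  yr <- as.numeric(.residualize(matrix(ds@behaviour), Z))
  xn <- sqrt(colSums(Xr^2))
  yscale <- max(1, sqrt(sum(ds@behaviour^2)))
  tFromY <- function(Yres) {
    # Yres: n x B matrix of (re-residualized) behaviour vectors
    yn <- sqrt(colSums(Yres^2))
    r <- crossprod(Xr, Yres) / outer(pmax(xn, .Machine$double.eps),
                                     pmax(yn, .Machine$double.eps))
    # numerically zero residual behaviour carries no signal
    r[, yn < yscale * sqrt(.Machine$double.eps)] <- 0
    r[!is.finite(r)] <- 0
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    r * sqrt(df / (1 - r^2))
  }
  tobs <- as.numeric(tFromY(matrix(yr)))
  pvox <- 2 * stats::pt(-abs(tobs), df)
  tcrit <- stats::qt(1 - voxelP / 2, df)

  supra <- function(tv) {
    if (direction == "deficit") which(tv <= -tcrit) else which(abs(tv) >= tcrit)
  }

  maxNull <- numeric(nPerm)
  block <- 250L
  done <- 0L
  while (done < nPerm) {
    b <- min(block, nPerm - done)
    P <- vapply(seq_len(b), function(i) yr[sample.int(n)], numeric(n))
    Tp <- tFromY(.residualize(P, Z))
    for (j in seq_len(b)) {
      sj <- supra(Tp[, j])
      maxNull[done + j] <- .maxClusterSize(maskIdx[sj], dims, connectivity)
    }
    done <- done + b
  }

  so <- supra(tobs)
  if (direction == "both") {
    neg <- so[tobs[so] < 0]; pos <- so[tobs[so] > 0]
    csNeg <- .buildClusterSet(maskIdx[neg], tobs[neg], dims, connectivity,
                              maxNull, nPerm)
    csPos <- .buildClusterSet(maskIdx[pos], tobs[pos], dims, connectivity,
                              maxNull, nPerm)
    tab <- rbind(csNeg@table, csPos@table)
    vox <- c(csNeg@voxels, csPos@voxels)
    ord <- order(tab$size, decreasing = TRUE)
    tab <- tab[ord, , drop = FALSE]
    if (nrow(tab)) tab$cluster_id <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    clusters <- new("ClusterSet", table = tab, voxels = vox[ord],
                    connectivity = as.integer(connectivity),
                    dim = as.integer(dims))
  } else {
    clusters <- .buildClusterSet(maskIdx[so], tobs[so], dims, connectivity,
                                 maxNull, nPerm)
  }
  info <- list(statistic = "t", df = df, voxel_p = voxelP,
               cluster_p = clusterP, n_perm = nPerm,
               connectivity = as.integer(connectivity),
               direction = direction, control_volume = controlVolume)
  list(map = .newStatMap(dims, maskIdx, tobs, pvox, mask, info),
       clusters = clusters)
}

#' VBCM with multiple behavioural regressors
#'
#' Re-runs the voxel-wise analysis once per behavioural variable, each time
#' assessing that variable's unique effect with the other behavioural
#' variables added to the nuisance covariates (alongside the dataset's own
#' covariates). The dataset's behaviour slot is labelled "coherence".
#'
#' @param ds a \linkS4class{LesionDataset}
#' @param extraRegressors named list or data.frame of additional
#'   behavioural vectors (one value per patient)
#' @param ... passed to [vbcm()]
#' @return named list of \code{list(map, clusters)} results, one per
#'   regressor
#' @export
vbcmMulti <- function(ds, extraRegressors, ...) {
  ex <- as.data.frame(extraRegressors)
  stopifnot(nrow(ex) == nPatients(ds), ncol(ex) >= 1L)
  B <- cbind(coherence = ds@behaviour, as.matrix(ex))
  if (qr(scale(B, scale = FALSE))$rank < ncol(B))
    stop("collinear regressors: the behavioural variables are linearly dependent")
  out <- lapply(seq_len(ncol(B)), function(j) {
    dsj <- ds
    dsj@behaviour <- B[, j]
    dsj@covariates <- cbind(ds@covariates,
                            as.data.frame(B[, -j, drop = FALSE]))
    vbcm(dsj, ...)
  })
  names(out) <- colnames(B)
  out
}

#' Support-vector-regression lesion-symptom mapping (SVR-LSM)
#'
#' Multivariate lesion-symptom mapping: binary lesion images are the
#' features of an epsilon-SVR with a linear kernel, behaviour (residualized
#' for the nuisance covariates) is the target, and the back-projected
#' weight per voxel is the statistic of interest. Only voxels lesioned in
#' at least \code{lesionThreshold} patients enter the model. With
#' \code{controlVolume = TRUE}, lesion volume is regressed out of every
#' retained voxel column and out of behaviour before fitting. Voxel-wise
#' p-values are two-tailed permutation tail probabilities of |beta| under
#' behaviour permutations refit with the same hyper-parameters; reported
#' clusters are restricted to the deficit direction (negative weights).
#' Cluster FWE correction uses the permutation distribution of the maximum
#' cluster size.
#'
#' Hyper-parameters (cost C and epsilon) are chosen by a seeded
#' cross-validated search over log-uniform C in [1e-2, 1e3] and epsilon in
#' [1e-3, 1] (5-fold CV on mean squared error), then held fixed across
#' permutations.
#'
#' @param ds a \linkS4class{LesionDataset} with binary images
#' @param lesionThreshold minimum patient lesion coverage per voxel
#'   (default 4)
#' @param voxelP voxel-wise p threshold (default 0.005)
#' @param clusterP cluster-level FWE threshold recorded in metadata
#'   (default 0.05)
#' @param nPerm number of permutations (default 1000)
#' @param connectivity 6, 18 or 26 (default 26)
#' @param controlVolume regress lesion volume out of features and behaviour
#' @param nTune number of random hyper-parameter candidates (default 10)
#' @param seed optional integer seed (hyper-parameter search and
#'   permutations)
#' @return list with \code{map}, \code{clusters} and \code{tuning} (the
#'   chosen C and epsilon)
#' @export
svrLsm <- function(ds, lesionThreshold = 4L, voxelP = 0.005,
                   clusterP = 0.05, nPerm = 1000L, connectivity = 26L,
                   controlVolume = FALSE, nTune = 10L, seed = NULL) {
  stopifnot(is(ds, "LesionDataset"))
  if (!isTRUE(ds@binary)) stop("svrLsm expects binary lesion images")
  if (!is.null(seed)) set.seed(seed)
  n <- nPatients(ds)
  if (stats::sd(ds@behaviour) == 0)
    stop("degenerate behaviour: constant across patients")
  dims <- dim(ds@images)[1:3]
  maskIdx <- which(ds@mask)
  M <- matrix(ds@images, prod(dims), n)
  X <- t(M[maskIdx, , drop = FALSE])
  coverage <- colSums(X)
  keep <- coverage >= lesionThreshold
  if (!any(keep))
    stop("empty feature set: no voxel lesioned in >= ", lesionThreshold,
         " patients")
  featIdx <- maskIdx[keep]
  X <- X[, keep, drop = FALSE]

  cov <- .covariateMatrix(ds, controlVolume = FALSE)
  Z <- cbind(1, cov)
  y <- as.numeric(.residualize(matrix(ds@behaviour), Z))
  if (controlVolume) {
    vol <- colSums(M)  # voxel count per patient over the whole grid
    Zv <- cbind(1, vol)
    y <- as.numeric(.residualize(matrix(y), Zv))
    X <- .residualize(X, Zv)
  }
  ys <- if (stats::sd(y) > 0) y / stats::sd(y) else y

  # the linear-kernel SVR dual depends on X only through the Gram matrix
  # G = X X', so fitting on an n x n factor Q (Q Q' = G) gives the exact
  # same solution at a cost independent of the number of voxels; voxel
  # weights are back-projected as w = X' alpha afterwards
  ev <- eigen(tcrossprod(X), symmetric = TRUE)
  Q <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n)
  tune <- .tuneSvr(Q, ys, nTune)
  fitAlpha <- function(target) {
    fit <- e1071::svm(x = Q, y = target, type = "eps-regression",
                      kernel = "linear", cost = tune$cost,
                      epsilon = tune$epsilon, scale = FALSE)
    al <- numeric(n)
    if (length(fit$coefs)) al[fit$index] <- fit$coefs
    al
  }
  A <- vapply(c(list(ys), lapply(seq_len(nPerm), function(i) sample(ys))),
              fitAlpha, numeric(n))
  B <- crossprod(X, A)  # voxel weights for observed (col 1) + permutations
  betaObs <- B[, 1]
  W <- B[, -1, drop = FALSE]

  # pooled exchangeable p-values: observed and permuted maps are ranked
  # together per voxel
  O <- cbind(betaObs, W)
  nMaps <- ncol(O)
  Pmat <- t(apply(abs(O), 1, function(v)
    (length(v) - rank(v, ties.method = "min") + 1) / nMaps))
  if (ncol(X) == 1L) Pmat <- matrix(Pmat, nrow = 1L)
  pObs <- Pmat[, 1]

  maxNull <- vapply(seq_len(nPerm), function(j) {
    sj <- which(Pmat[, j + 1L] < voxelP & O[, j + 1L] < 0)
    .maxClusterSize(featIdx[sj], dims, connectivity)
  }, numeric(1))

  so <- which(pObs < voxelP & betaObs < 0)
  clusters <- .buildClusterSet(featIdx[so], betaObs[so], dims, connectivity,
                               maxNull, nPerm)
  mask <- array(FALSE, dims); mask[featIdx] <- TRUE
  info <- list(statistic = "svr_beta", voxel_p = voxelP, cluster_p = clusterP,
               n_perm = nPerm, connectivity = as.integer(connectivity),
               lesion_threshold = lesionThreshold,
               control_volume = controlVolume,
               cost = tune$cost, epsilon = tune$epsilon)
  list(map = .newStatMap(dims, featIdx, betaObs, pObs, mask, info),
       clusters = clusters, tuning = tune)
}

# seeded random search over log-uniform (C, epsilon) with 5-fold CV MSE;
# the default (C = 1, epsilon = 0.1) is always a candidate
.tuneSvr <- function(X, y, nTune) {
  cand <- data.frame(
    cost = c(1, if (nTune > 0) 10^stats::runif(nTune, -2, 3)),
    epsilon = c(0.1, if (nTune > 0) 10^stats::runif(nTune, -3, 0)))
  if (nrow(cand) == 1L)
    return(list(cost = 1, epsilon = 0.1, cv_mse = NA_real_))
  n <- length(y)
  k <- min(5L, n)
  folds <- sample(rep(seq_len(k), length.out = n))
  mse <- vapply(seq_len(nrow(cand)), function(i) {
    err <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (stats::sd(y[tr]) == 0) return(mean((y[!tr] - mean(y[tr]))^2))
      fit <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr],
                        type = "eps-regression", kernel = "linear",
                        cost = cand$cost[i], epsilon = cand$epsilon[i],
                        scale = FALSE)
      mean((y[!tr] - stats::predict(fit, X[!tr, , drop = FALSE]))^2)
    }, numeric(1))
    mean(err)
  }, numeric(1))
  list(cost = cand$cost[which.min(mse)],
       epsilon = cand$epsilon[which.min(mse)], cv_mse = min(mse))
}
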