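.DEFAULT_POOLS <- list(
  picture_description = c("boy", "girl", "mother", "woman", "cookie",
    "cookies", "jar", "stool", "sink", "plate", "dishes", "kitchen",
    "stealing", "reaching", "falling", "washing", "overflowing", "curtain",
    "window", "cupboard"),
  storytelling = c("man", "wife", "guests", "dinner", "party", "table",
    "chairs", "wine", "glasses", "oven", "roast", "burnt", "smoke",
    "cooking", "serving", "evening", "candles", "napkin", "dessert",
    "toast"),
  procedural = c("tea", "kettle", "water", "cup", "mug", "teabag", "milk",
    "sugar", "spoon", "stir", "boil", "pour", "brew", "teapot", "saucer",
    "biscuit", "tray", "steep", "strainer", "leaves"))

.DEFAULT_OFFTOPIC <- c("weather", "football", "holiday", "garden", "travel",
  "music", "politics", "shopping", "haircut", "bicycle", "mountain",
  "river", "painting", "computer", "telephone", "newspaper", "hospital",
  "doctor", "cinema", "dancing")

#' Configuration for the synthetic cohort generators
#'
#' Bundles every tunable of the synthetic study: cohort sizes, the per-task
#' topic lexicons and the off-topic pool, group drift rates (the
#' probability that a sampled content token comes from the off-topic
#' pool), topic-focus concentrations (how idiosyncratically a speaker
#' samples words within the on-topic pool; lower = noisier word choice and
#' lower coherence), response lengths, the planted coefficient vector
#' linking cognitive components to coherence, and the lesion-cohort
#' geometry (grid, critical region, lesion size distribution, effect
#' size).
#'
#' Defaults emulate the published study conditions: 20 controls vs 46
#' patients; drift and focus calibrated so that scored group means land
#' near the reported task means (controls about 0.86/0.84/0.91 and
#' patients 0.65/0.61/0.74 for storytelling, picture description and
#' procedural discourse); planted coefficients 0.132 (phonological
#' production), 0.101 (semantic processing) and 0.08 (verbal fluency);
#' lesion volumes drawn within the reported 175-41379 voxel range (upper
#' tail truncated to what the desk-scale 32^3 grid can hold).
#'
#' @param seed integer master seed
#' @param nControls,nPatients cohort sizes
#' @param taskPools named list of on-topic word pools (one per task)
#' @param offTopicPool off-topic word pool
#' @param controlDrift,patientDrift named per-task mean drift rates in
#'   [0, 1]; every control rate must be <= the patient rate
#' @param driftKappa named vector: Beta concentration of per-participant
#'   drift for each group (smaller = more heterogeneous)
#' @param focus named per-task Dirichlet concentration of within-pool word
#'   preference
#' @param controlLength,patientLength integer(2) ranges of content tokens
#'   per response
#' @param emptyRate probability a patient response is empty (exercises
#'   missing-task handling)
#' @param k,weighting,minCount semantic-space build parameters
#' @param docConcentration Dirichlet sparsity of corpus documents' word
#'   preference (smaller = each document covers a narrower sub-topic, so
#'   words within a pool get more differentiated vectors)
#' @param docsPerPool,docLength corpus shape
#' @param coefficients named coefficient vector for component-to-coherence
#'   generation; unnamed components get 0
#' @param noiseSd residual SD of the component-to-coherence model
#' @param interceptCoherence intercept of that model
#' @param grid integer(3) lesion grid
#' @param voxelSize numeric(3) voxel size in mm
#' @param criticalRegion list(lo, hi): corner voxels (1-based, inclusive)
#'   of the planted critical region
#' @param seedZone list(lo, hi): box from which lesion growth seeds are
#'   drawn
#' @param sizeMeanLog,sizeSdLog lognormal lesion-size parameters (voxels)
#' @param sizeRange numeric(2) truncation range for lesion sizes
#' @param lesionEffect coherence drop when the critical region is fully
#'   lesioned
#' @param lesionBaseline behaviour at zero critical-region damage
#' @param lesionNoiseSd residual SD of the lesion-to-behaviour model
#' @param signalMode how the brain-behaviour relationship is planted:
#'   \code{"overlap"} (default) drives behaviour by the fraction of the
#'   critical region covered by the binary lesion, so neighbouring voxels
#'   inherit real signal through lesion contiguity; \code{"direct"} adds a
#'   graded abnormality severity to the critical region of the continuous
#'   images and drives behaviour by that severity, confining the true
#'   signal exactly to the planted voxels (the cleanest recovery target)
#' @param fwhm smoothing kernel FWHM in mm for the continuous images
#' @return a validated list of class "cohmapConfig"
#' @export
cohortConfig <- function(seed = 1L,
                         nControls = 20L, nPatients = 46L,
                         taskPools = .DEFAULT_POOLS,
                         offTopicPool = .DEFAULT_OFFTOPIC,
                         controlDrift = c(picture_description = 0.05,
                                          storytelling = 0.04,
                                          procedural = 0.02),
                         patientDrift = c(picture_description = 0.52,
                                          storytelling = 0.46,
                                          procedural = 0.38),
                         driftKappa = c(control = 25, patient = 3),
                         focus = c(picture_description = 0.35,
                                   storytelling = 0.42,
                                   procedural = 0.8),
                         controlLength = c(40L, 90L),
                         patientLength = c(15L, 60L),
                         emptyRate = 0.04,
                         k = 40L, weighting = "log-entropy", minCount = 1L,
                         docConcentration = 0.15,
                         docsPerPool = 20L, docLength = 40L,
                         coefficients = c(phonological_production = 0.132,
                                          semantic_processing = 0.101,
                                          verbal_fluency = 0.08),
                         noiseSd = 0.05,
                         interceptCoherence = 0.67,
                         grid = c(32L, 32L, 32L),
                         voxelSize = c(2, 2, 2),
                         criticalRegion = list(lo = c(8L, 22L, 14L),
                                               hi = c(11L, 25L, 17L)),
                         seedZone = list(lo = c(5L, 8L, 8L),
                                         hi = c(16L, 28L, 24L)),
                         sizeMeanLog = log(1500), sizeSdLog = 0.9,
                         sizeRange = c(175, 6000),
                         lesionEffect = 0.45,
                         lesionBaseline = 0.8,
                         lesionNoiseSd = 0.08,
                         signalMode = c("overlap", "direct"),
                         fwhm = 8) {
  cfg <- list(seed = as.integer(seed), nControls = as.integer(nControls),
              nPatients = as.integer(nPatients), taskPools = taskPools,
              offTopicPool = offTopicPool, controlDrift = controlDrift,
              patientDrift = patientDrift, driftKappa = driftKappa,
              focus = focus, controlLength = controlLength,
              patientLength = patientLength, emptyRate = emptyRate,
              k = as.integer(k), weighting = weighting,
              minCount = as.integer(minCount),
              docConcentration = docConcentration,
              docsPerPool = as.integer(docsPerPool),
              docLength = as.integer(docLength),
              coefficients = coefficients,
              noiseSd = noiseSd, interceptCoherence = interceptCoherence,
              grid = as.integer(grid), voxelSize = voxelSize,
              criticalRegion = criticalRegion, seedZone = seedZone,
              sizeMeanLog = sizeMeanLog, sizeSdLog = sizeSdLog,
              sizeRange = sizeRange, lesionEffect = lesionEffect,
              lesionBaseline = lesionBaseline,
              lesionNoiseSd = lesionNoiseSd,
              signalMode = match.arg(signalMode), fwhm = fwhm)
  class(cfg) <- "cohmapConfig"
  validateConfig(cfg)
  cfg
}

#' @rdname cohortConfig
#' @param cfg a cohmapConfig
#' @export
validateConfig <- function(cfg) {
  pools <- c(cfg$taskPools, list(off_topic = cfg$offTopicPool))
  if (any(lengths(pools) == 0L)) stop("empty word pool")
  flat <- unlist(pools, use.names = FALSE)
  if (anyDuplicated(flat))
    stop("word pools overlap: ", paste(unique(flat[duplicated(flat)]),
                                       collapse = ", "))
  overlap <- intersect(flat, defaultStoplist())
  if (length(overlap))
    stop("word pools overlap the stoplist: ", paste(overlap, collapse = ", "))
  tasks <- names(cfg$taskPools)
  if (!all(tasks %in% names(cfg$controlDrift)) ||
      !all(tasks %in% names(cfg$patientDrift)))
    stop("drift rates must name every task")
  if (any(cfg$controlDrift[tasks] > cfg$patientDrift[tasks]))
    stop("control drift must not exceed patient drift for any task")
  if (any(c(cfg$controlDrift, cfg$patientDrift) < 0) ||
      any(c(cfg$controlDrift, cfg$patientDrift) > 1))
    stop("drift rates must lie in [0, 1]")
  if (cfg$noiseSd < 0) stop("noise SD must be non-negative")
  if (any(cfg$criticalRegion$lo < 1L) ||
      any(cfg$criticalRegion$hi > cfg$grid))
    stop("critical region must lie inside the grid")
  invisible(cfg)
}

#' Build the synthetic corpus and its semantic space
#'
#' Writes one coherent topic block per pool: each document samples its
#' tokens from a single pool (with a document-specific Dirichlet word
#' preference so that words within a pool are differentiated rather than
#' interchangeable). The resulting LSA space gives higher within-pool than
#' between-pool cosine similarity by construction.
#'
#' @param cfg a [cohortConfig()]
#' @return list with \code{corpus} (list of token vectors), \code{space}
#'   (a \linkS4class{SemanticSpace}) and \code{pools}
#' @export
makeCorpusAndSpace <- function(cfg) {
  validateConfig(cfg)
  set.seed(cfg$seed)
  pools <- c(cfg$taskPools, list(off_topic = cfg$offTopicPool))
  corpus <- list()
  for (pool in pools) {
    for (d in seq_len(cfg$docsPerPool)) {
      wts <- stats::rgamma(length(pool), shape = cfg$docConcentration)
      wts <- pmax(wts, 1e-9)
      corpus[[length(corpus) + 1L]] <-
        sample(pool, cfg$docLength, replace = TRUE, prob = wts / sum(wts))
    }
  }
  space <- buildSpace(corpus, k = cfg$k, weighting = cfg$weighting,
                      minCount = cfg$minCount)
  list(corpus = corpus, space = space, pools = pools)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Generate synthetic discourse transcripts
#'
#' Each response interleaves content tokens with function words. A content
#' token is drawn from the off-topic pool with the participant's drift
#' probability, otherwise from the task's on-topic pool under a
#' participant-by-task Dirichlet word preference (concentration
#' \code{focus[task]}). Per-participant drift is Beta-distributed around
#' the group-by-task mean with concentration \code{driftKappa[group]}.
#' A configurable fraction of patient responses is empty, exercising the
#' missing-task path downstream.
#'
#' @param cfg a [cohortConfig()]
#' @param dir optional directory: when given, one UTF-8 .txt file per
#'   response plus a manifest.tsv are written there
#' @return list with \code{data} (data.frame participant_id, group, task,
#'   text) and \code{truth} (per-response drift rates)
#' @export
makeTranscripts <- function(cfg, dir = NULL) {
  validateConfig(cfg)
  set.seed(cfg$seed + 1L)
  tasks <- names(cfg$taskPools)
  ids <- c(sprintf("C%02d", seq_len(cfg$nControls)),
           sprintf("P%02d", seq_len(cfg$nPatients)))
  groups <- rep(c("control", "patient"), c(cfg$nControls, cfg$nPatients))
  fillers <- c("the", "and", "um", "is", "a", "of", "it", "was")

  rows <- list(); truths <- list()
  for (i in seq_along(ids)) {
    g <- groups[i]
    kap <- cfg$driftKappa[[g]]
    lenRange <- if (g == "control") cfg$controlLength else cfg$patientLength
    for (tk in tasks) {
      m <- if (g == "control") cfg$controlDrift[[tk]] else cfg$patientDrift[[tk]]
      d <- if (m <= 0) 0 else if (m >= 1) 1 else
        stats::rbeta(1, m * kap, (1 - m) * kap)
      L <- sample(seq(lenRange[1], lenRange[2]), 1)
      if (L <= 0) stop("zero response length")
      empty <- g == "patient" && stats::runif(1) < cfg$emptyRate
      if (empty) {
        text <- ""
      } else {
        pool <- cfg$taskPools[[tk]]
        pref <- .rdirichlet1(rep(cfg$focus[[tk]], length(pool)))
        off <- stats::runif(L) < d
        toks <- character(L)
        toks[!off] <- sample(pool, sum(!off), replace = TRUE, prob = pref)
        toks[off] <- sample(cfg$offTopicPool, sum(off), replace = TRUE)
        # interleave function words (removed again by the stoplist)
        out <- character(0)
        for (t in toks) {
          if (stats::runif(1) < 0.45)
            out <- c(out, sample(fillers, 1))
          out <- c(out, t)
        }
        text <- paste(out, collapse = " ")
      }
      rows[[length(rows) + 1L]] <-
        data.frame(participant_id = ids[i], group = g, task = tk,
                   text = text, stringsAsFactors = FALSE)
      truths[[length(truths) + 1L]] <-
        data.frame(participant_id = ids[i], group = g, task = tk,
                   drift = d, empty = empty, stringsAsFactors = FALSE)
    }
  }
  data <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    data$file <- sprintf("%s_%s.txt", data$participant_id, data$task)
    for (r in seq_len(nrow(data)))
      writeLines(data$text[r], file.path(dir, data$file[r]), useBytes = TRUE)
    utils::write.table(data[, c("participant_id", "group", "task", "file")],
                       file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(data = data, truth = truth)
}

#' Build ResponseRecords from a transcript table
#'
#' @param data data.frame with participant_id, group, task, text
#' @param space a \linkS4class{SemanticSpace}
#' @param ... passed to [responseRecord()]
#' @return list of \linkS4class{ResponseRecord}
#' @export
recordsFromTable <- function(data, space, ...) {
  lapply(seq_len(nrow(data)), function(i)
    responseRecord(data$participant_id[i], data$group[i], data$task[i],
                   data$text[i], space, ...))
}

#' Generate synthetic cognitive component scores
#'
#' Produces seven exactly orthogonalized standard-normal component columns
#' (centred, QR-orthogonalized, unit variance). In \code{"forward"} mode a
#' composite coherence is regenerated as \code{intercept + X B + noise} so
#' regression-recovery tests have exact known truth; in \code{"null"} mode
#' the returned coherence is independent of every component.
#'
#' @param cfg a [cohortConfig()]
#' @param mode "forward" or "null"
#' @param nPatients number of patients (default from config)
#' @return list with \code{components} (data.frame with participant_id and
#'   the seven columns), \code{composite} (data.frame participant_id,
#'   composite_coherence) and \code{truth} (the planted coefficient
#'   vector, intercept and noise SD)
#' @export
makeComponentScores <- function(cfg, mode = c("forward", "null"),
                                nPatients = cfg$nPatients) {
  validateConfig(cfg)
  mode <- match.arg(mode)
  if (nPatients < 10L) stop("need at least 10 patients")
  set.seed(cfg$seed + 2L)
  n <- nPatients
  X <- matrix(stats::rnorm(n * 7L), n, 7L)
  X <- scale(X, scale = FALSE)
  X <- qr.Q(qr(X))
  X <- scale(X, center = TRUE, scale = TRUE)[, , drop = FALSE]
  colnames(X) <- .COMPONENTS
  b <- stats::setNames(numeric(7), .COMPONENTS)
  b[names(cfg$coefficients)] <- cfg$coefficients
  y <- if (mode == "forward")
    cfg$interceptCoherence + as.numeric(X %*% b) +
      stats::rnorm(n, 0, cfg$noiseSd)
  else
    cfg$interceptCoherence + stats::rnorm(n, 0, cfg$noiseSd)
  ids <- sprintf("P%02d", seq_len(n))
  list(components = data.frame(participant_id = ids, X,
                               stringsAsFactors = FALSE),
       composite = data.frame(participant_id = ids, composite_coherence = y,
                              stringsAsFactors = FALSE),
       truth = list(coefficients = b, mode = mode,
                    intercept = cfg$interceptCoherence,
                    noise_sd = cfg$noiseSd))
}

# contiguous random lesion blob grown from a seed voxel (6-connected
# wave growth with random frontier thinning)
.growLesion <- function(seedCoord, size, dims) {
  mult <- c(1L, dims[1], dims[1] * dims[2])
  lin <- function(co) (co[, 3] - 1L) * mult[3] + (co[, 2] - 1L) * mult[2] + co[, 1]
  off <- .connOffsets(6L)
  inVol <- array(FALSE, dims)
  seedIdx <- lin(matrix(seedCoord, 1))
  inVol[seedIdx] <- TRUE
  sel <- seedIdx
  frontier <- matrix(seedCoord, 1)
  while (length(sel) < size) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                   drop = FALSE] +
      off[rep(seq_len(nrow(off)), times = nrow(frontier)), , drop = FALSE]
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    li <- lin(nb)
    new <- !duplicated(li) & !inVol[li]
    nb <- nb[new, , drop = FALSE]; li <- li[new]
    if (!length(li)) break  # trapped (grid full); return what we have
    want <- size - length(sel)
    takeN <- min(length(li), max(1L, min(want, stats::rbinom(1, length(li), 0.7))))
    take <- sample.int(length(li), takeN)
    inVol[li[take]] <- TRUE
    sel <- c(sel, li[take])
    frontier <- nb[take, , drop = FALSE]
    if (nrow(frontier) == 0L) frontier <- arrayInd(sel, dims)
  }
  sel
}

#' Generate a synthetic lesion cohort
#'
#' Per patient, a contiguous random lesion blob is grown from a seed voxel
#' in the configured seeding zone, with its size drawn from a truncated
#' lognormal distribution. Behaviour is
#' \code{baseline - effect * (fraction of the critical region lesioned) +
#' noise}, clipped to [0, 1]. Continuous abnormality images are the binary
#' masks smoothed with the configured FWHM. Covariates (age, months
#' post-onset) are drawn independently of behaviour; lesion volume is
#' included as a covariate column so volume-controlled analyses can use
#' it.
#'
#' @param cfg a [cohortConfig()]
#' @param effect overrides \code{cfg$lesionEffect} (0 gives a null cohort)
#' @param noiseSd overrides \code{cfg$lesionNoiseSd}
#' @return list with \code{binary} and \code{continuous}
#'   \linkS4class{LesionDataset}s sharing behaviour/covariates, and
#'   \code{truth} (critical-region mask, per-patient lesioned fraction,
#'   effect size)
#' @export
makeLesionCohort <- function(cfg, effect = cfg$lesionEffect,
                             noiseSd = cfg$lesionNoiseSd) {
  validateConfig(cfg)
  set.seed(cfg$seed + 3L)
  dims <- cfg$grid
  n <- cfg$nPatients
  crit <- array(FALSE, dims)
  crit[cfg$criticalRegion$lo[1]:cfg$criticalRegion$hi[1],
       cfg$criticalRegion$lo[2]:cfg$criticalRegion$hi[2],
       cfg$criticalRegion$lo[3]:cfg$criticalRegion$hi[3]] <- TRUE
  nCrit <- sum(crit)
  medSize <- exp(cfg$sizeMeanLog)
  if (nCrit > medSize)
    warning("critical region larger than the typical lesion; ",
            "the planted effect will rarely be expressed")

  imgs <- array(0, c(dims, n))
  frac <- numeric(n)
  for (i in seq_len(n)) {
    size <- round(min(cfg$sizeRange[2],
                      max(cfg$sizeRange[1],
                          stats::rlnorm(1, cfg$sizeMeanLog, cfg$sizeSdLog))))
    seedCoord <- vapply(1:3, function(a)
      sample(seq(cfg$seedZone$lo[a], cfg$seedZone$hi[a]), 1), integer(1))
    vox <- .growLesion(seedCoord, size, dims)
    b <- array(0, dims); b[vox] <- 1
    imgs[, , , i] <- b
    frac[i] <- sum(b[crit]) / nCrit
  }
  vols <- apply(imgs, 4, sum)
  severity <- if (cfg$signalMode == "direct") stats::runif(n) else frac
  behaviourRaw <- cfg$lesionBaseline - effect * severity +
    stats::rnorm(n, 0, noiseSd)
  beh <- pmin(1, pmax(0, behaviourRaw))
  age <- round(pmin(87, pmax(44, stats::rnorm(n, 63.21, 11.93))))
  months <- round(pmin(280, pmax(16, stats::rlnorm(n, log(55), 0.7))))
  cov <- data.frame(age = age, months_post_onset = months,
                    lesion_volume = vols)
  maskBin <- apply(imgs, 1:3, max) > 0

  smoothImgs <- array(0, c(dims, n))
  for (i in seq_len(n)) {
    si <- smoothImage(imgs[, , , i], cfg$fwhm, cfg$voxelSize)
    if (cfg$signalMode == "direct")
      si <- 0.45 * si + crit * 0.55 * severity[i]
    smoothImgs[, , , i] <- si
  }
  maskCont <- apply(smoothImgs, 1:3, max) > 1e-6

  binary <- new("LesionDataset", images = imgs, behaviour = beh,
                covariates = cov, mask = maskBin, voxelSize = cfg$voxelSize,
                binary = TRUE, affine = NULL)
  continuous <- new("LesionDataset", images = smoothImgs, behaviour = beh,
                    covariates = cov, mask = maskCont,
                    voxelSize = cfg$voxelSize, binary = FALSE, affine = NULL)
  list(binary = binary, continuous = continuous,
       truth = list(critical_mask = crit, frac_lesioned = frac,
                    severity = severity, signal_mode = cfg$signalMode,
                    effect = effect, noise_sd = noiseSd, volumes = vols))
}
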