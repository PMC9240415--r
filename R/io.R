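#' Read a transcript manifest
#'
#' The manifest is a TSV with columns participant_id, group, task, file.
#' Groups must be "control"/"patient" and tasks one of the three discourse
#' tasks; duplicated participant-by-task rows and rows pointing at missing
#' files are errors naming the offending row.
#'
#' @param path manifest path; response files are resolved relative to the
#'   manifest's directory unless absolute
#' @param readText also read each transcript file into a \code{text}
#'   column (default TRUE)
#' @return data.frame with participant_id, group, task, file (and text)
#' @export
readManifest <- function(path, readText = TRUE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("participant_id", "group", "task", "file")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  badTask <- !d$task %in% .TASKS
  if (any(badTask))
    stop("unknown task label '", d$task[which(badTask)[1]], "' at row ",
         which(badTask)[1], "; allowed: ", paste(.TASKS, collapse = ", "))
  badGroup <- !d$group %in% .GROUPS
  if (any(badGroup))
    stop("unknown group label '", d$group[which(badGroup)[1]], "' at row ",
         which(badGroup)[1], "; allowed: ", paste(.GROUPS, collapse = ", "))
  dup <- duplicated(d[, c("participant_id", "task")])
  if (any(dup))
    stop("duplicate participant x task at row ", which(dup)[1], ": ",
         d$participant_id[which(dup)[1]], " / ", d$task[which(dup)[1]])
  base <- dirname(path)
  full <- ifelse(grepl("^(/|[A-Za-z]:)", d$file), d$file,
                 file.path(base, d$file))
  missing <- !file.exists(full)
  if (any(missing))
    stop("file not found for row ", which(missing)[1], " (",
         d$participant_id[which(missing)[1]], " / ",
         d$task[which(missing)[1]], "): ", full[which(missing)[1]])
  if (readText)
    d$text <- vapply(full, function(f)
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = " "),
      character(1), USE.NAMES = FALSE)
  d
}

#' Read a stack of NIfTI lesion images into a LesionDataset
#'
#' All images must share one grid; the analysis mask defaults to voxels
#' that are nonzero in at least one image. The first image's affine (if
#' any) is carried opaquely onto the dataset.
#'
#' @param files character vector of NIfTI paths (or a directory of
#'   .nii/.nii.gz files, sorted by name)
#' @param behaviour numeric vector, one value per image
#' @param covariates data.frame, one row per image
#' @param voxelSize voxel size in mm; taken from the NIfTI header when
#'   omitted
#' @param mask optional logical 3D array overriding the default mask
#' @param binary whether the images are binary masks (default: detected)
#' @return a \linkS4class{LesionDataset}
#' @export
readLesionStack <- function(files, behaviour, covariates, voxelSize = NULL,
                            mask = NULL, binary = NULL) {
  if (length(files) == 1L && dir.exists(files))
    files <- sort(list.files(files, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
  if (length(files) == 0L) stop("no NIfTI files found")
  imgs <- lapply(files, RNifti::readNifti)
  dims <- lapply(imgs, dim)
  ref <- dims[[1]]
  bad <- which(!vapply(dims, identical, logical(1), ref))
  if (length(bad))
    stop("image grid mismatch: ", basename(files[bad[1]]), " is ",
         paste(dims[[bad[1]]], collapse = "x"), ", expected ",
         paste(ref, collapse = "x"), " (", basename(files[1]), ")")
  arr <- array(0, c(ref, length(imgs)))
  for (i in seq_along(imgs)) {
    v <- as.array(imgs[[i]])
    if (any(!is.finite(v)))
      stop("non-finite voxels in ", basename(files[i]))
    arr[, , , i] <- v
  }
  if (is.null(voxelSize)) {
    pd <- attr(RNifti::niftiHeader(imgs[[1]]), "pixdim")
    voxelSize <- if (!is.null(pd)) pd[1:3] else
      RNifti::pixdim(imgs[[1]])[1:3]
  }
  if (is.null(mask)) {
    mask <- apply(arr, 1:3, max) > 0
  } else {
    if (!identical(dim(mask), as.integer(ref)))
      stop("user mask dimensions ", paste(dim(mask), collapse = "x"),
           " do not match the image grid ", paste(ref, collapse = "x"))
    mask <- array(as.logical(mask), ref)
  }
  if (is.null(binary)) binary <- all(arr %in% c(0, 1))
  new("LesionDataset", images = arr, behaviour = as.numeric(behaviour),
      covariates = as.data.frame(covariates), mask = mask,
      voxelSize = as.numeric(voxelSize), binary = binary,
      affine = tryCatch(RNifti::xform(imgs[[1]]), error = function(e) NULL))
}

#' Write a StatMap (and optional cluster mask) as NIfTI
#'
#' Writes the statistic volume, the voxel-wise p volume and, when a
#' \linkS4class{ClusterSet} is given, a labelled cluster mask. NA voxels
#' outside the mask are written as 0.
#'
#' @param map a \linkS4class{StatMap}
#' @param prefix output path prefix (files get _stat.nii.gz, _p.nii.gz,
#'   _clusters.nii.gz suffixes)
#' @param clusters optional \linkS4class{ClusterSet}
#' @param template optional NIfTI image or affine carried onto the outputs
#' @return invisibly, the written paths
#' @export
writeStatMapNifti <- function(map, prefix, clusters = NULL,
                              template = NULL) {
  fill <- function(a) { a[is.na(a)] <- 0; a }
  paths <- c(stat = paste0(prefix, "_stat.nii.gz"),
             p = paste0(prefix, "_p.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(fill(map@statistic),
                                     reference = template), paths["stat"])
  RNifti::writeNifti(RNifti::asNifti(fill(map@pVoxel), reference = template),
                     paths["p"])
  if (!is.null(clusters)) {
    lab <- array(0, dim(map@statistic))
    for (i in seq_along(clusters@voxels))
      lab[clusters@voxels[[i]]] <- clusters@table$cluster_id[i]
    paths <- c(paths, clusters = paste0(prefix, "_clusters.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(lab, reference = template),
                       paths["clusters"])
  }
  invisible(paths)
}

#' Write coherence tables as CSV
#'
#' @param tab a \linkS4class{CoherenceTable}
#' @param dir output directory (created if needed)
#' @return invisibly, the two written paths (scores.csv, composite.csv)
#' @export
writeScoresCsv <- function(tab, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "scores.csv")
  p2 <- file.path(dir, "composite.csv")
  utils::write.csv(coherenceScores(tab), p1, row.names = FALSE)
  utils::write.csv(compositeScores(tab), p2, row.names = FALSE)
  invisible(c(scores = p1, composite = p2))
}

#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates the analysis end to end on generated data: builds the
#' semantic space, generates and scores transcripts, runs the mixed ANOVA
#' and the staged regressions (forward-mode component generator), then the
#' lesion-mapping stage (VBCM on the continuous images and, optionally,
#' SVR-LSM on the binary masks), writing all tables, maps and a run log
#' under \code{outDir}. Deterministic under a fixed config seed.
#'
#' @param cfg a [cohortConfig()]
#' @param outDir output directory
#' @param nPerm permutations for the lesion stage (default 1000)
#' @param runSvr also run SVR-LSM (default TRUE)
#' @param svrPerm permutations for SVR-LSM (default \code{nPerm})
#' @return invisibly, a list with every intermediate result
#' @export
runPipeline <- function(cfg, outDir, nPerm = 1000L, runSvr = TRUE,
                        svrPerm = nPerm) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run_log.txt")
  logLine <- function(...) cat(..., "\n", sep = "", file = logPath,
                               append = TRUE)
  cat("", file = logPath)
  logLine("cohmap pipeline run")
  logLine("seed: ", cfg$seed)
  sl <- defaultStoplist()
  logLine("stoplist: ", length(sl), " words, md5 ", attr(sl, "md5"))
  logLine("R: ", R.version.string)

  cs <- makeCorpusAndSpace(cfg)
  saveSpace(cs$space, file.path(outDir, "space.tsv"))
  tr <- makeTranscripts(cfg, dir = file.path(outDir, "transcripts"))
  records <- recordsFromTable(tr$data, cs$space)
  scored <- scoreCohort(records)
  writeScoresCsv(scored, outDir)
  logLine("scored ", nrow(coherenceScores(scored)), " responses")

  anova <- mixedAnova(scored)
  utils::write.csv(anova, file.path(outDir, "anova.csv"), row.names = FALSE)
  utils::write.csv(attr(anova, "posthoc"),
                   file.path(outDir, "anova_posthoc.csv"), row.names = FALSE)

  comp <- makeComponentScores(cfg, mode = "forward")
  reg <- stagedRegressions(comp$composite, comp$components)
  utils::write.csv(reg$models, file.path(outDir, "regression_models.csv"),
                   row.names = FALSE)
  utils::write.csv(reg$coefficients,
                   file.path(outDir, "regression_coefficients.csv"),
                   row.names = FALSE)
  execOnly <- executiveOnlyRegression(comp$composite, comp$components)
  utils::write.csv(execOnly$models,
                   file.path(outDir, "regression_executive_only.csv"),
                   row.names = FALSE)

  lc <- makeLesionCohort(cfg)
  vb <- vbcm(lc$continuous, nPerm = nPerm, seed = cfg$seed + 10L)
  writeStatMapNifti(vb$map, file.path(outDir, "vbcm"), vb$clusters)
  utils::write.csv(clusterTable(vb$clusters),
                   file.path(outDir, "vbcm_clusters.csv"), row.names = FALSE)
  logLine("vbcm: ", nrow(clusterTable(vb$clusters)), " cluster(s)")

  sv <- NULL
  if (runSvr) {
    sv <- svrLsm(lc$binary, nPerm = svrPerm, seed = cfg$seed + 11L)
    writeStatMapNifti(sv$map, file.path(outDir, "svr"), sv$clusters)
    utils::write.csv(clusterTable(sv$clusters),
                     file.path(outDir, "svr_clusters.csv"), row.names = FALSE)
    logLine("svr: ", nrow(clusterTable(sv$clusters)), " cluster(s)")
  }
  invisible(list(space = cs$space, transcripts = tr, scored = scored,
                 anova = anova, components = comp, regressions = reg,
                 executiveOnly = execOnly, lesions = lc, vbcm = vb,
                 svr = sv))
}
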