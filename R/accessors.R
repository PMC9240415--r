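#' @describeIn SemanticSpace-accessors vocabulary words
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' @describeIn SemanticSpace-accessors dimensionality k
#' @export
setGeneric("spaceDim", function(x) standardGeneric("spaceDim"))

#' @describeIn SemanticSpace-accessors provenance string
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Accessors for SemanticSpace objects
#'
#' @param x a \linkS4class{SemanticSpace}
#' @name SemanticSpace-accessors
#' @aliases vocabulary spaceDim provenance
NULL

#' @rdname SemanticSpace-accessors
#' @export
setMethod("vocabulary", "SemanticSpace", function(x) rownames(x@vectors))

#' @rdname SemanticSpace-accessors
#' @export
setMethod("spaceDim", "SemanticSpace", function(x) ncol(x@vectors))

#' @rdname SemanticSpace-accessors
#' @export
setMethod("provenance", "SemanticSpace", function(x) x@provenance)

setMethod("show", "SemanticSpace", function(object) {
  cat("SemanticSpace:", nrow(object@vectors), "words x",
      ncol(object@vectors), "dimensions\n")
  cat("  provenance:", object@provenance, "\n")
})

#' Accessors for CoherenceTable objects
#'
#' @param x a \linkS4class{CoherenceTable}
#' @return \code{coherenceScores} returns the long per-participant per-task
#'   score table; \code{compositeScores} the per-participant composite table.
#' @name CoherenceTable-accessors
NULL

#' @rdname CoherenceTable-accessors
#' @export
setGeneric("coherenceScores", function(x) standardGeneric("coherenceScores"))

#' @rdname CoherenceTable-accessors
#' @export
setGeneric("compositeScores", function(x) standardGeneric("compositeScores"))

#' @rdname CoherenceTable-accessors
#' @export
setMethod("coherenceScores", "CoherenceTable", function(x) x@scores)

#' @rdname CoherenceTable-accessors
#' @export
setMethod("compositeScores", "CoherenceTable", function(x) x@composite)

setMethod("show", "CoherenceTable", function(object) {
  sc <- object@scores
  cat("CoherenceTable:", length(unique(sc$participant_id)), "participants,",
      nrow(sc), "participant x task rows\n")
  for (g in unique(sc$group)) {
    m <- tapply(sc$global_coherence[sc$group == g], sc$task[sc$group == g],
                mean, na.rm = TRUE)
    cat(sprintf("  %s mean coherence: %s\n", g,
                paste(sprintf("%s=%.3f", names(m), m), collapse = ", ")))
  }
})

#' Accessors for LesionDataset objects
#'
#' @param x a \linkS4class{LesionDataset}
#' @name LesionDataset-accessors
NULL

#' @rdname LesionDataset-accessors
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' @rdname LesionDataset-accessors
#' @export
setGeneric("behaviour", function(x) standardGeneric("behaviour"))

#' @rdname LesionDataset-accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname LesionDataset-accessors
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))

#' @rdname LesionDataset-accessors
#' @export
setGeneric("lesionImages", function(x) standardGeneric("lesionImages"))

#' @rdname LesionDataset-accessors
#' @export
setMethod("nPatients", "LesionDataset", function(x) dim(x@images)[4])

#' @rdname LesionDataset-accessors
#' @export
setMethod("behaviour", "LesionDataset", function(x) x@behaviour)

#' @rdname LesionDataset-accessors
#' @export
setMethod("covariates", "LesionDataset", function(x) x@covariates)

#' @rdname LesionDataset-accessors
#' @export
setMethod("analysisMask", "LesionDataset", function(x) x@mask)

#' @rdname LesionDataset-accessors
#' @export
setMethod("lesionImages", "LesionDataset", function(x) x@images)

setMethod("show", "LesionDataset", function(object) {
  d <- dim(object@images)
  cat(sprintf("LesionDataset: %d patients on a %dx%dx%d grid (%s mm voxels)\n",
              d[4], d[1], d[2], d[3],
              paste(object@voxelSize, collapse = "x")))
  cat(sprintf("  %s images, %d voxels in analysis mask\n",
              if (object@binary) "binary" else "continuous",
              sum(object@mask)))
  cat("  covariates:", paste(names(object@covariates), collapse = ", "), "\n")
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap (%s): %d masked voxels\n",
              object@info$statistic %||% "statistic", sum(object@mask)))
  if (!is.null(object@info$n_perm))
    cat("  permutations:", object@info$n_perm, "\n")
})

#' Cluster table of a ClusterSet
#'
#' @param x a \linkS4class{ClusterSet}
#' @return data.frame with cluster size, peak statistic, peak voxel
#'   coordinate (0-based) and FWE-corrected p-value.
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname clusterTable
#' @export
setMethod("clusterTable", "ClusterSet", function(x) x@table)

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", nrow(object@table), "cluster(s), connectivity",
      object@connectivity, "\n")
  if (nrow(object@table)) print(object@table, row.names = FALSE)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
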