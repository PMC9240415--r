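#' @import methods
NULL

#' SemanticSpace: a word-vector space for coherence scoring
#'
#' Holds a vocabulary of lowercase words mapped to k-dimensional real
#' vectors, typically built by latent semantic analysis (truncated SVD of a
#' weighted term-document matrix). All stored vectors are L2-normalized so
#' that cosine similarity reduces to a dot product.
#'
#' @slot vectors numeric matrix, one row per vocabulary word (rownames are
#'   the words), \code{k} columns.
#' @slot provenance character(1), free-text descriptor of how the space was
#'   built (corpus, weighting, dimensionality).
#'
#' @seealso [buildSpace()], [loadSpace()], [getVector()]
#' @export
setClass("SemanticSpace",
  slots = c(vectors = "matrix", provenance = "character"))

setValidity("SemanticSpace", function(object) {
  v <- object@vectors
  if (!is.numeric(v)) return("'vectors' must be a numeric matrix")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("'vectors' must have unique rownames (the vocabulary)")
  if (any(rownames(v) != tolower(rownames(v))))
    return("vocabulary words must be lowercase")
  if (!all(is.finite(v))) return("vectors must be finite")
  if (nrow(v) > 0L && any(rowSums(v^2) == 0))
    return("no vocabulary word may map to the all-zero vector")
  TRUE
})

#' ResponseRecord: one participant-by-task discourse response
#'
#' @slot participantId character(1)
#' @slot group character(1), "control" or "patient"
#' @slot task character(1), one of "picture_description", "storytelling",
#'   "procedural"
#' @slot rawText character(1), the transcript
#' @slot contentTokens character vector of content tokens (lowercased,
#'   function words removed)
#' @slot responseVector numeric vector of dimension k, or length 0 when no
#'   content token is in the semantic-space vocabulary
#' @slot nOov integer(1), number of content tokens that were out of
#'   vocabulary when the vector was composed
#'
#' @export
setClass("ResponseRecord",
  slots = c(participantId = "character", group = "character",
            task = "character", rawText = "character",
            contentTokens = "character", responseVector = "numeric",
            nOov = "integer"))

.TASKS <- c("picture_description", "storytelling", "procedural")
.GROUPS <- c("control", "patient")

setValidity("ResponseRecord", function(object) {
  if (!object@group %in% .GROUPS)
    return(sprintf("group must be one of: %s", paste(.GROUPS, collapse = ", ")))
  if (!object@task %in% .TASKS)
    return(sprintf("task must be one of: %s", paste(.TASKS, collapse = ", ")))
  TRUE
})

#' PrototypeVector: control-derived prototype of typical semantic content
#'
#' The element-wise mean of control participants' response vectors for one
#' discourse task; the reference against which global coherence is scored.
#'
#' @slot task character(1)
#' @slot vector numeric, dimension k
#' @slot nContributors integer(1), number of control responses averaged
#' @slot excludedId character(1) or NA, participant excluded (leave-one-out)
#'
#' @export
setClass("PrototypeVector",
  slots = c(task = "character", vector = "numeric",
            nContributors = "integer", excludedId = "character"))

setValidity("PrototypeVector", function(object) {
  if (object@nContributors < 1L) return("nContributors must be >= 1")
  TRUE
})

#' CoherenceTable: per-participant per-task global coherence
#'
#' @slot scores data.frame with columns participant_id, group, task,
#'   global_coherence (in [-1, 1] or NA), deficit (logical or NA)
#' @slot composite data.frame with columns participant_id, group,
#'   composite_coherence (mean of the participant's present per-task scores)
#'
#' @export
setClass("CoherenceTable",
  slots = c(scores = "data.frame", composite = "data.frame"))

setValidity("CoherenceTable", function(object) {
  sc <- object@scores
  need <- c("participant_id", "group", "task", "global_coherence", "deficit")
  if (!all(need %in% names(sc)))
    return(sprintf("scores must have columns: %s", paste(need, collapse = ", ")))
  gc <- sc$global_coherence
  if (any(!is.na(gc) & (gc < -1 - 1e-12 | gc > 1 + 1e-12)))
    return("global_coherence must lie in [-1, 1]")
  if (!all(c("participant_id", "group", "composite_coherence") %in%
           names(object@composite)))
    return("composite must have participant_id, group, composite_coherence")
  TRUE
})

#' LesionDataset: an aligned stack of lesion images with behaviour
#'
#' A cohort of co-registered 3D lesion images (continuous abnormality in
#' [0, 1] or binary masks) on a common grid, together with the behavioural
#' score of interest (composite discourse coherence) and nuisance
#' covariates (age, months post-stroke onset, optionally lesion volume).
#'
#' @slot images 4D numeric array (x, y, z, patient)
#' @slot behaviour numeric, one value per patient
#' @slot covariates data.frame, one row per patient, named columns
#' @slot mask logical 3D array, the analysis mask
#' @slot voxelSize numeric(3), voxel edge lengths in mm
#' @slot binary logical(1), whether images are binary masks
#' @slot affine 4x4 numeric matrix or NULL-like (carried opaquely in/out)
#'
#' @export
setClass("LesionDataset",
  slots = c(images = "array", behaviour = "numeric",
            covariates = "data.frame", mask = "array",
            voxelSize = "numeric", binary = "logical", affine = "ANY"))

setValidity("LesionDataset", function(object) {
  d <- dim(object@images)
  if (length(d) != 4L) return("images must be a 4D array (x, y, z, patient)")
  n <- d[4]
  if (length(object@behaviour) != n)
    return("length(behaviour) must equal the number of images")
  if (nrow(object@covariates) != n)
    return("covariates must have one row per patient")
  if (!identical(dim(object@mask), d[1:3]))
    return("mask must match the image grid")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be three positive numbers (mm)")
  if (any(!is.finite(object@images))) return("images contain non-finite voxels")
  rng <- range(object@images)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("image values must lie in [0, 1]")
  if (isTRUE(object@binary) && !all(object@images %in% c(0, 1)))
    return("binary dataset has non-binary voxel values")
  TRUE
})

#' StatMap: a voxel-wise statistic volume with permutation p-values
#'
#' @slot statistic 3D numeric array (t or back-projected SVR beta); NA
#'   outside the analysis mask
#' @slot pVoxel 3D numeric array of voxel-wise p-values; NA outside mask
#' @slot mask logical 3D array
#' @slot info list of threshold metadata (voxel p, cluster p, n
#'   permutations, connectivity, statistic type, df where applicable)
#'
#' @export
setClass("StatMap",
  slots = c(statistic = "array", pVoxel = "array", mask = "array",
            info = "list"))

setValidity("StatMap", function(object) {
  if (!identical(dim(object@statistic), dim(object@pVoxel)))
    return("statistic and pVoxel must share a grid")
  p <- object@pVoxel[!is.na(object@pVoxel)]
  if (length(p) && (min(p) < 0 || max(p) > 1)) return("p-values outside [0, 1]")
  TRUE
})

#' ClusterSet: FWE-corrected suprathreshold clusters
#'
#' @slot table data.frame with one row per cluster: cluster_id, size,
#'   peak_stat, peak_x, peak_y, peak_z (0-based voxel coordinates), p_fwe
#' @slot voxels list of integer vectors (linear voxel indices per cluster)
#' @slot connectivity integer(1), 6, 18 or 26
#' @slot dim integer(3), the grid the indices refer to
#'
#' @export
setClass("ClusterSet",
  slots = c(table = "data.frame", voxels = "list",
            connectivity = "integer", dim = "integer"))

setValidity("ClusterSet", function(object) {
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("connectivity must be 6, 18 or 26")
  if (length(object@voxels) != nrow(object@table))
    return("one voxel list per cluster row required")
  if (length(object@voxels) > 1L &&
      anyDuplicated(unlist(object@voxels)))
    return("clusters must be disjoint")
  TRUE
})
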