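#' @import methods
NULL

#' VolumeGrid: the sampling grid shared by all volumes in an analysis
#'
#' Describes a 3-D voxel grid: dimensions, voxel size in mm, and the 4x4
#' affine mapping 0-based voxel indices to world (MNI) mm coordinates.
#' Every multi-volume operation in the package checks grid compatibility
#' and fails fast on a mismatch; nothing is silently resampled.
#'
#' @slot dims integer(3), voxels per axis.
#' @slot voxelSize numeric(3), voxel edge length in mm.
#' @slot affine 4x4 numeric matrix, voxel-index -> world mm.
#' @export
setClass("VolumeGrid",
  representation(dims = "integer", voxelSize = "numeric", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@dims) != 3L || any(object@dims < 1L))
      msg <- c(msg, "dims must be 3 integers >= 1")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive reals")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be 4x4")
    else if (abs(det(object@affine)) < .Machine$double.eps * 64)
      msg <- c(msg, "affine must be invertible")
    if (length(msg)) msg else TRUE
  })

#' BrainVolume: a real-valued 3-D volume on a VolumeGrid
#'
#' @slot grid a [VolumeGrid-class].
#' @slot data numeric 3-D array matching the grid dims.
#' @export
setClass("BrainVolume",
  representation(grid = "VolumeGrid", data = "array"),
  validity = function(object) {
    if (!identical(dim(object@data), as.integer(object@grid@dims)))
      return("data shape must equal grid dims")
    TRUE
  })

#' BrainMask: a binary 3-D volume
#'
#' Values are exactly 0/1. `nVoxels()` counts the 1-voxels. A mask built by
#' [computeBrainMask()] additionally carries the canonical in-brain voxel
#' index (attribute-free: see [voxelIndex()]), the column order of all
#' downstream matrices.
#'
#' @slot voxelIdx integer vector of linear (column-major, x fastest) indices
#'   of the 1-voxels, in increasing order.
#' @export
setClass("BrainMask", contains = "BrainVolume",
  representation(voxelIdx = "integer"),
  validity = function(object) {
    v <- object@data
    if (!all(v %in% c(0, 1)))
      return("mask data must be binary 0/1")
    if (!identical(object@voxelIdx, which(v != 0)))
      return("voxelIdx must equal which(data != 0)")
    TRUE
  })

#' Fmri4D: one subject/session of resting-state fMRI
#'
#' @slot grid a [VolumeGrid-class].
#' @slot series numeric 4-D array (x, y, z, t).
#' @slot tr repetition time in seconds.
#' @slot subjectId,sessionId identifiers; multiple sessions of one subject
#'   share the subjectId and are averaged within subject downstream.
#' @export
setClass("Fmri4D",
  representation(grid = "VolumeGrid", series = "array", tr = "numeric",
                 subjectId = "character", sessionId = "character"),
  validity = function(object) {
    d <- dim(object@series)
    if (length(d) != 4L) return("series must be 4-D")
    if (!identical(d[1:3], as.integer(object@grid@dims)))
      return("series spatial dims must equal grid dims")
    if (d[4] < 2L) return("series must have >= 2 timepoints")
    if (!all(is.finite(object@series)))
      return(sprintf("series contains %d non-finite values",
                     sum(!is.finite(object@series))))
    if (object@tr <= 0) return("tr must be positive")
    TRUE
  })

#' LesionCohort: per-patient binary lesion masks on one shared grid
#'
#' @slot grid the shared [VolumeGrid-class].
#' @slot lesions named list of [BrainMask-class], names are patient ids.
#' @slot meta data.frame of per-patient generator bookkeeping (may be empty);
#'   synthetic cohorts record which networks each lesion hits and the true
#'   target-network damage, used by recovery tests.
#' @export
setClass("LesionCohort",
  representation(grid = "VolumeGrid", lesions = "list", meta = "data.frame"),
  validity = function(object) {
    ids <- names(object@lesions)
    if (length(ids) && anyDuplicated(ids))
      return("patient ids must be unique")
    for (m in object@lesions) {
      if (!is(m, "BrainMask")) return("lesions must be BrainMask objects")
      if (!gridsCompatible(m@grid, object@grid))
        return("all lesions must share the cohort grid")
      if (length(m@voxelIdx) < 1L)
        return("every lesion must have >= 1 voxel")
    }
    TRUE
  })

#' FCVector: one lesion-seeded Fisher-Z connectivity map
#'
#' Values live over the canonical in-brain voxel index; entries at voxels
#' inside this patient's lesion (cap brain) are exactly 0.
#'
#' @slot patientId,subjectId identifiers (subjectId "" once averaged
#'   across the normative cohort).
#' @slot values numeric vector over the in-brain voxel index.
#' @slot lesionCols integer positions (into values) zeroed by the lesion.
#' @slot nValid number of non-lesion in-brain voxels.
#' @export
setClass("FCVector",
  representation(patientId = "character", subjectId = "character",
                 values = "numeric", lesionCols = "integer",
                 nValid = "integer"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("values must be finite")
    if (length(object@lesionCols) &&
        any(object@values[object@lesionCols] != 0))
      return("lesion entries must be exactly 0")
    if (object@nValid !=
        length(object@values) - length(object@lesionCols))
      return("nValid must equal voxels minus lesion entries")
    TRUE
  })

#' FCMatrix: patients x in-brain-voxels lesion-seeded connectivity
#'
#' Rows are patients, columns the canonical in-brain voxel index. Entries
#' are averaged Fisher-Z lesion-seeded connectivity; voxels inside a
#' patient's own lesion are exactly 0 ("empty elements filled with zeroes").
#' After standardization each row has mean 0 and unit (sample) variance over
#' its non-lesion entries, zeros restored afterwards.
#'
#' @slot values numeric matrix, patients x voxels.
#' @slot patientIds row names.
#' @slot voxelIndex linear voxel indices of the columns (from the brain mask).
#' @slot lesionCols list per patient of column positions zeroed (lesion cap
#'   brain), in matrix column coordinates.
#' @slot grid the shared [VolumeGrid-class].
#' @slot standardized logical.
#' @export
setClass("FCMatrix",
  representation(values = "matrix", patientIds = "character",
                 voxelIndex = "integer", lesionCols = "list",
                 grid = "VolumeGrid", standardized = "logical"),
  validity = function(object) {
    if (nrow(object@values) != length(object@patientIds))
      return("row count must match patientIds")
    if (ncol(object@values) != length(object@voxelIndex))
      return("column count must match voxelIndex")
    if (length(object@lesionCols) != length(object@patientIds))
      return("lesionCols must have one entry per patient")
    if (!all(is.finite(object@values)))
      return("FC matrix must be finite")
    TRUE
  })

#' PCAResult: signal-subspace reduction of an FCMatrix
#'
#' @slot basis patients x q left singular vectors.
#' @slot singularValues all singular values (not just the first q).
#' @slot whitened q x voxels whitened signal subspace (rows uncorrelated,
#'   unit variance) fed to ICA.
#' @slot dewhiten patients x q matrix mapping subspace mixing back to
#'   patient loadings.
#' @slot cumVar cumulative explained variance, nondecreasing in (0, 1].
#' @slot q selected order.
#' @export
setClass("PCAResult",
  representation(basis = "matrix", singularValues = "numeric",
                 whitened = "matrix", dewhiten = "matrix",
                 cumVar = "numeric", q = "integer"),
  validity = function(object) {
    if (object@q < 1L) return("q must be >= 1")
    if (is.unsorted(object@cumVar)) return("cumVar must be nondecreasing")
    if (utils::tail(object@cumVar, 1) > 1 + 1e-9)
      return("cumVar must end <= 1")
    TRUE
  })

#' ICARun: one Infomax restart
#'
#' @slot demixing q x q matrix W; sources = W %*% whitened.
#' @slot mixing q x q matrix solve(W) (subspace scale).
#' @slot sources q x voxels estimated source matrix.
#' @slot seed integer RNG seed of this restart.
#' @slot converged logical; nIter iterations used.
#' @export
setClass("ICARun",
  representation(demixing = "matrix", mixing = "matrix", sources = "matrix",
                 seed = "integer", converged = "logical", nIter = "integer"))

#' Decomposition: multi-restart ICA of the FC matrix
#'
#' @slot runs list of [ICARun-class].
#' @slot selectedRun index of the most consistent run (min mean cross-ISI).
#' @slot crossISI symmetric matrix of pairwise Amari-ISI scores, zero diag.
#' @slot sources q x voxels z-scored, skew-oriented component maps of the
#'   selected run (mean 0, unit variance over brain voxels).
#' @slot patientMixing patients x q loadings consistent with the oriented
#'   sources.
#' @slot voxelIndex,grid,brainMask the spatial frame of the source columns.
#' @export
setClass("Decomposition",
  representation(runs = "list", selectedRun = "integer", crossISI = "matrix",
                 sources = "matrix", patientMixing = "matrix",
                 voxelIndex = "integer", grid = "VolumeGrid",
                 brainMask = "BrainMask"),
  validity = function(object) {
    ci <- object@crossISI
    if (nrow(ci) != ncol(ci)) return("crossISI must be square")
    if (any(abs(diag(ci)) > 1e-12)) return("crossISI diagonal must be 0")
    if (max(abs(ci - t(ci))) > 1e-8) return("crossISI must be symmetric")
    TRUE
  })

#' NetworkMap: a thresholded spatial component (or reference) map
#'
#' @slot zmap continuous z-scored [BrainVolume-class] (0 outside brain).
#' @slot threshold positive z threshold.
#' @slot positiveMask voxels with z > threshold.
#' @slot negativeMask voxels with z < -threshold.
#' @slot label free-text name.
#' @export
setClass("NetworkMap",
  representation(zmap = "BrainVolume", threshold = "numeric",
                 positiveMask = "BrainMask", negativeMask = "BrainMask",
                 label = "character"),
  validity = function(object) {
    if (object@threshold <= 0) return("threshold must be > 0")
    if (length(intersect(object@positiveMask@voxelIdx,
                         object@negativeMask@voxelIdx)))
      return("positive and negative masks must be disjoint")
    TRUE
  })

#' ReferenceNetwork: a canonical network to compare components against
#'
#' Either binary (a parcel, Yeo-17 style) or continuous (a meta-analytic
#' z-map). Must share the analysis grid; use [resampleNearest()] explicitly
#' for mismatched grids.
#'
#' @slot name label.
#' @slot map [BrainVolume-class]; binary kinds hold 0/1 data.
#' @slot kind "binary" or "continuous".
#' @export
setClass("ReferenceNetwork",
  representation(name = "character", map = "BrainVolume", kind = "character"),
  validity = function(object) {
    if (!object@kind %in% c("binary", "continuous"))
      return("kind must be 'binary' or 'continuous'")
    if (object@kind == "binary" && !all(object@map@data %in% c(0, 1)))
      return("binary reference must have 0/1 data")
    TRUE
  })

#' GroundTruth: planted networks behind a synthetic cohort
#'
#' @slot networks list of continuous spatial maps ([BrainVolume-class]).
#' @slot targetIndex which network drives the language-like behavior score.
#' @slot sourceSeries timepoints x K canonical source time courses.
#' @slot centers K x 3 voxel-index centres of the blobs.
#' @slot seed generator seed.
#' @export
setClass("GroundTruth",
  representation(networks = "list", targetIndex = "integer",
                 sourceSeries = "matrix", centers = "matrix",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@networks) < 2L) return("need >= 2 networks")
    for (nw in object@networks)
      if (sum(nw@data > 0) < 20L)
        return("each network needs positive support >= 20 voxels")
    if (object@targetIndex < 1L ||
        object@targetIndex > length(object@networks))
      return("targetIndex out of range")
    TRUE
  })

#' SyntheticCohort: everything one simulated study contains
#'
#' @slot groundTruth [GroundTruth-class].
#' @slot hcFmris list of [Fmri4D-class] normative scans.
#' @slot lesions [LesionCohort-class].
#' @slot behavior data.frame (patient_id, WAB subtests, aq, lesion_size, ...).
#' @slot config named list of generator parameters, including the master seed.
#' @export
setClass("SyntheticCohort",
  representation(groundTruth = "GroundTruth", hcFmris = "list",
                 lesions = "LesionCohort", behavior = "data.frame",
                 config = "list"),
  validity = function(object) {
    if (!setequal(object@behavior$patient_id, names(object@lesions@lesions)))
      return("behavior rows must match lesion patient ids")
    TRUE
  })
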