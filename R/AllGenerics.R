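#' Number of 1-voxels in a mask
#' @param x a [BrainMask-class]
#' @return integer count
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "BrainMask", function(x) length(x@voxelIdx))

#' Linear in-brain / in-mask voxel index
#'
#' The canonical column order of all matrices in the package: linear
#' (column-major, x fastest, 1-based) indices of the 1-voxels.
#' @param x a [BrainMask-class] or [FCMatrix-class] or [Decomposition-class]
#' @return integer vector
#' @export
setGeneric("voxelIndex", function(x) standardGeneric("voxelIndex"))

#' @rdname voxelIndex
#' @export
setMethod("voxelIndex", "BrainMask", function(x) x@voxelIdx)
#' @rdname voxelIndex
#' @export
setMethod("voxelIndex", "FCMatrix", function(x) x@voxelIndex)
#' @rdname voxelIndex
#' @export
setMethod("voxelIndex", "Decomposition", function(x) x@voxelIndex)

#' Patient identifiers of a cohort-like object
#' @param x a [LesionCohort-class] or [FCMatrix-class]
#' @return character vector
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname patientIds
#' @export
setMethod("patientIds", "LesionCohort", function(x) names(x@lesions))
#' @rdname patientIds
#' @export
setMethod("patientIds", "FCMatrix", function(x) x@patientIds)

#' Number of patients
#' @param x a [LesionCohort-class] or [FCMatrix-class]
#' @return integer
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' @rdname nPatients
#' @export
setMethod("nPatients", "LesionCohort", function(x) length(x@lesions))
#' @rdname nPatients
#' @export
setMethod("nPatients", "FCMatrix", function(x) nrow(x@values))

#' Component z-maps of a decomposition
#' @param x a [Decomposition-class]
#' @return q x voxels matrix of z-scored oriented source maps
#' @export
setGeneric("componentMaps", function(x) standardGeneric("componentMaps"))

#' @rdname componentMaps
#' @export
setMethod("componentMaps", "Decomposition", function(x) x@sources)

#' Number of independent components
#' @param x a [Decomposition-class]
#' @return integer
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname nComponents
#' @export
setMethod("nComponents", "Decomposition", function(x) nrow(x@sources))

setMethod("show", "VolumeGrid", function(object) {
  cat(sprintf("VolumeGrid: %s voxels, %s mm\n",
              paste(object@dims, collapse = " x "),
              paste(format(object@voxelSize), collapse = " x ")))
})

setMethod("show", "BrainVolume", function(object) {
  cat(sprintf("BrainVolume on %s grid; range [%.4g, %.4g]\n",
              paste(object@grid@dims, collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "BrainMask", function(object) {
  cat(sprintf("BrainMask on %s grid; %d voxels set\n",
              paste(object@grid@dims, collapse = "x"),
              length(object@voxelIdx)))
})

setMethod("show", "Fmri4D", function(object) {
  d <- dim(object@series)
  cat(sprintf("Fmri4D subject %s session %s: %s x %d timepoints, TR %.3gs\n",
              object@subjectId, object@sessionId,
              paste(d[1:3], collapse = "x"), d[4], object@tr))
})

setMethod("show", "LesionCohort", function(object) {
  sz <- vapply(object@lesions, function(m) length(m@voxelIdx), integer(1))
  cat(sprintf("LesionCohort: %d patients on %s grid; lesion size %d-%d voxels\n",
              length(object@lesions),
              paste(object@grid@dims, collapse = "x"),
              if (length(sz)) min(sz) else 0L,
              if (length(sz)) max(sz) else 0L))
})

setMethod("show", "FCMatrix", function(object) {
  cat(sprintf("FCMatrix: %d patients x %d in-brain voxels (%s)\n",
              nrow(object@values), ncol(object@values),
              if (object@standardized) "row-standardized" else "raw Fisher-Z"))
})

setMethod("show", "Decomposition", function(object) {
  conv <- sum(vapply(object@runs, function(r) r@converged, logical(1)))
  cat(sprintf(
    "Decomposition: %d ICs x %d voxels; %d/%d converged runs; selected run %d\n",
    nrow(object@sources), ncol(object@sources), conv,
    length(object@runs), object@selectedRun))
})

setMethod("show", "NetworkMap", function(object) {
  cat(sprintf("NetworkMap '%s': |z| > %.3g; %d positive, %d negative voxels\n",
              object@label, object@threshold,
              length(object@positiveMask@voxelIdx),
              length(object@negativeMask@voxelIdx)))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d networks (target %d), %d HC scans, %d patients\n",
    length(object@groundTruth@networks), object@groundTruth@targetIndex,
    length(object@hcFmris), length(object@lesions@lesions)))
})
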