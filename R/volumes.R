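#' Construct a VolumeGrid
#'
#' @param dims integer(3) voxels per axis.
#' @param voxelSize numeric(3) or scalar, mm per voxel (default 1).
#' @param affine optional 4x4 voxel-to-world matrix; default is a diagonal
#'   scaling by `voxelSize` (0-based voxel indices to mm).
#' @return a [VolumeGrid-class]
#' @export
volumeGrid <- function(dims, voxelSize = 1, affine = NULL) {
  dims <- as.integer(dims)
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  if (is.null(affine)) {
    affine <- diag(c(voxelSize, 1))
  }
  new("VolumeGrid", dims = dims, voxelSize = voxelSize, affine = affine)
}

#' Construct a BrainVolume
#' @param data numeric 3-D array.
#' @param grid a [VolumeGrid-class]; default unit grid of the array's dims.
#' @return a [BrainVolume-class]
#' @export
brainVolume <- function(data, grid = volumeGrid(dim(data))) {
  storage.mode(data) <- "double"
  new("BrainVolume", grid = grid, data = data)
}

#' Construct a BrainMask from binary data
#' @param data array coercible to 0/1 (logical or numeric).
#' @param grid a [VolumeGrid-class].
#' @return a [BrainMask-class]
#' @export
brainMask <- function(data, grid = volumeGrid(dim(data))) {
  arr <- array(as.double(data != 0), dim = dim(data))
  new("BrainMask", grid = grid, data = arr, voxelIdx = which(arr != 0))
}

gridFromNifti <- function(img) {
  d <- dim(img)[seq_len(3)]
  pix <- attr(img, "pixdim")
  volumeGrid(d, voxelSize = rep_len(as.numeric(pix)[seq_len(3)], 3L),
             affine = unclass(RNifti::xform(img))[seq_len(4), seq_len(4)])
}

#' Read a NIfTI-1 volume
#'
#' 3-D files yield a [BrainVolume-class]; 4-D files yield an
#' [Fmri4D-class] (subject/session ids taken from `subjectId`/`sessionId`).
#' Non-finite voxels are an error, never imputed: NaN propagates silently
#' through correlations downstream.
#'
#' @param path file path (.nii or .nii.gz).
#' @param subjectId,sessionId identifiers attached to 4-D reads.
#' @return [BrainVolume-class] or [Fmri4D-class]
#' @export
readVolume <- function(path, subjectId = basename(path), sessionId = "1") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI-1 file: ",
                                           path, " (", conditionMessage(e), ")",
                                           call. = FALSE))
  arr <- structure(as.vector(img), dim = dim(img))
  nbad <- sum(!is.finite(arr))
  if (nbad > 0)
    stop(sprintf("volume %s contains %d non-finite voxels", path, nbad))
  grid <- gridFromNifti(img)
  nd <- length(dim(arr))
  if (nd == 3L) {
    brainVolume(arr, grid)
  } else if (nd == 4L) {
    pix <- attr(img, "pixdim")
    tr <- if (length(pix) >= 4) as.numeric(pix[4]) else 1
    if (!is.finite(tr) || tr <= 0) tr <- 1
    new("Fmri4D", grid = grid, series = arr, tr = tr,
        subjectId = subjectId, sessionId = sessionId)
  } else {
    stop("expected a 3-D or 4-D NIfTI volume, got ", nd, " dims")
  }
}

#' Write a volume, mask or 4-D series as NIfTI-1
#'
#' Masks are written as unsigned 8-bit, other volumes as 32-bit float
#' (z-maps) unless `datatype` overrides.
#'
#' @param x [BrainVolume-class], [BrainMask-class] or [Fmri4D-class].
#' @param path destination (.nii or .nii.gz).
#' @param datatype RNifti datatype string; default by class.
#' @return `path`, invisibly
#' @export
writeVolume <- function(x, path, datatype = NULL) {
  if (is(x, "BrainMask")) {
    arr <- x@data; dt <- datatype %||% "uint8"
  } else if (is(x, "Fmri4D")) {
    arr <- x@series; dt <- datatype %||% "float"
  } else if (is(x, "BrainVolume")) {
    arr <- x@data; dt <- datatype %||% "float"
  } else stop("cannot write object of class ", class(x))
  grid <- x@grid
  img <- RNifti::asNifti(arr)
  # pixdim first: assigning the sform afterwards re-derives the spatial
  # spacings from it, so the order matters
  attr(img, "pixdim") <- if (is(x, "Fmri4D")) c(grid@voxelSize, x@tr)
                         else grid@voxelSize
  img <- RNifti::`sform<-`(img, structure(grid@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binarize a volume at a threshold
#'
#' Voxels strictly greater than `threshold` become 1.
#'
#' @param vol a [BrainVolume-class].
#' @param threshold finite real.
#' @return a [BrainMask-class]
#' @export
binarize <- function(vol, threshold = 0) {
  stopifnot(is.finite(threshold))
  brainMask(vol@data > threshold, vol@grid)
}

#' Are two grids compatible?
#'
#' Equal dims and affines agreeing within `tol` (mm) entrywise. All
#' multi-volume operations call this and fail fast on FALSE; there is no
#' silent resampling (see [resampleNearest()] for the explicit path).
#'
#' @param a,b [VolumeGrid-class] objects.
#' @param tol max absolute affine difference, default 1e-4 mm.
#' @return logical
#' @export
gridsCompatible <- function(a, b, tol = 1e-4) {
  identical(as.integer(a@dims), as.integer(b@dims)) &&
    max(abs(a@affine - b@affine)) <= tol
}

stopIfGridMismatch <- function(a, b, what = "volumes") {
  if (!gridsCompatible(a, b))
    stop("grid mismatch between ", what,
         "; resample explicitly with resampleNearest() if intended")
  invisible(TRUE)
}

#' Nearest-neighbour resampling onto a target grid
#'
#' Explicit utility for reference maps delivered on a different grid.
#' Each target voxel takes the value of the nearest source voxel (by world
#' mm coordinates through the affines). Deliberately nearest-neighbour so
#' binary masks stay binary.
#'
#' @param vol [BrainVolume-class] or [BrainMask-class].
#' @param grid target [VolumeGrid-class].
#' @return same class as `vol`, on `grid`
#' @export
resampleNearest <- function(vol, grid) {
  src <- vol@grid
  dims <- grid@dims
  ijk <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  world <- cbind(ijk, 1) %*% t(grid@affine)
  srcIdx <- world %*% t(solve(src@affine))
  srcIjk <- round(srcIdx[, 1:3])
  ok <- srcIjk[, 1] >= 0 & srcIjk[, 1] < src@dims[1] &
        srcIjk[, 2] >= 0 & srcIjk[, 2] < src@dims[2] &
        srcIjk[, 3] >= 0 & srcIjk[, 3] < src@dims[3]
  out <- numeric(nrow(ijk))
  lin <- srcIjk[ok, 1] + src@dims[1] * (srcIjk[ok, 2] +
         src@dims[2] * srcIjk[ok, 3]) + 1
  out[ok] <- vol@data[lin]
  arr <- array(out, dim = dims)
  if (is(vol, "BrainMask")) brainMask(arr, grid) else brainVolume(arr, grid)
}

#' Common in-brain mask of a set of normative scans
#'
#' A voxel is in brain for one subject iff its time series is finite with
#' nonzero variance in every session of that subject; the returned mask is
#' the voxelwise intersection (AND) across subjects — the normative-cohort
#' brain mask that defines the column order of all FC matrices.
#'
#' @param fmris list of [Fmri4D-class] (multiple sessions per subject
#'   allowed, grouped by `subjectId`).
#' @return a [BrainMask-class] carrying the ordered in-brain voxel index
#' @export
computeBrainMask <- function(fmris) {
  stopifnot(length(fmris) >= 1L)
  grid <- fmris[[1]]@grid
  nvox <- prod(grid@dims)
  keep <- rep(TRUE, nvox)
  for (f in fmris) {
    stopIfGridMismatch(f@grid, grid, "fMRI scans")
    mat <- matrix(f@series, nrow = nvox)
    v <- rowSums((mat - rowMeans(mat))^2)
    keep <- keep & (v > 0) & apply_finite_rows(mat)
  }
  if (!any(keep)) stop("no common brain voxels")
  brainMask(array(keep, dim = grid@dims), grid)
}

apply_finite_rows <- function(mat) {
  rowSums(!is.finite(mat)) == 0L
}

#' Build a LesionCohort
#' @param lesions named list of [BrainMask-class] (names = patient ids).
#' @param meta optional per-patient data.frame.
#' @return a [LesionCohort-class]
#' @export
lesionCohort <- function(lesions, meta = data.frame()) {
  stopifnot(length(lesions) >= 1L, !is.null(names(lesions)))
  grid <- lesions[[1]]@grid
  new("LesionCohort", grid = grid, lesions = lesions, meta = meta)
}

#' Read a directory of lesion masks
#'
#' Reads every `.nii`/`.nii.gz` in `dir` (file stem = patient id),
#' binarizes at `threshold`, and checks the shared grid.
#'
#' @param dir directory of NIfTI lesion masks.
#' @param threshold binarization threshold (default 0.5 for probabilistic
#'   masks; spec'd masks are already 0/1).
#' @return a [LesionCohort-class]
#' @export
readLesionCohort <- function(dir, threshold = 0.5) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) stop("no NIfTI files in ", dir)
  lesions <- lapply(files, function(f) binarize(readVolume(f), threshold))
  names(lesions) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  lesionCohort(lesions)
}
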