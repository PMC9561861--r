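# Minimal rs-fMRI cleaning, lesion-seeded functional connectivity per
# normative subject, two-stage averaging, and assembly of the union FC
# matrix that feeds the decomposition.

#' Nuisance regression and band-pass filtering
#'
#' Per voxel, the supplied confound series (motion parameters, any
#' mask-averaged nuisance series) plus, optionally, the global mean series
#' over `brain` are regressed out by least squares, then a zero-phase
#' ideal (frequency-domain) band-pass in `band` Hz is applied; the mean is
#' removed with the DC bin. The ideal filter is the band-pass used by the
#' standard rs-fMRI toolchains: unit gain on retained bins, zero outside.
#'
#' @param fmri an [Fmri4D-class].
#' @param confounds optional numeric matrix/data.frame, one row per
#'   timepoint.
#' @param band numeric pair (low, high) in Hz, default c(0.01, 0.08);
#'   requires low < high < Nyquist.
#' @param brain optional [BrainMask-class]; when given, the mean series
#'   over the mask is appended as a global-signal regressor.
#' @return an [Fmri4D-class]
#' @export
preprocessFmri <- function(fmri, confounds = NULL, band = c(0.01, 0.08),
                           brain = NULL) {
  d <- dim(fmri@series)
  nt <- d[4]
  nyq <- 1 / (2 * fmri@tr)
  stopifnot(band[1] < band[2])
  if (band[2] >= nyq)
    stop(sprintf("band high %.4g Hz must be below Nyquist %.4g Hz",
                 band[2], nyq))
  Y <- t(matrix(fmri@series, nrow = prod(d[1:3])))  # t x voxels
  X <- matrix(1, nt, 1)
  cn <- "intercept"
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nt)
      stop("confound rows must match timepoints")
    X <- cbind(X, confounds)
    cn <- c(cn, colnames(confounds) %||% sprintf("confound%d",
                                                 seq_len(ncol(confounds))))
  }
  if (!is.null(brain)) {
    X <- cbind(X, rowMeans(Y[, brain@voxelIdx, drop = FALSE]))
    cn <- c(cn, "global")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- cn[-qrX$pivot[seq_len(qrX$rank)]]
    stop("rank-deficient confound matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- Y - X %*% qr.coef(qrX, Y)
  # zero-phase ideal band-pass: keep bins with band[1] <= f <= band[2]
  freqs <- (seq_len(nt) - 1) / (nt * fmri@tr)
  freqs <- pmin(freqs, 1 / fmri@tr - freqs)  # two-sided
  keep <- freqs >= band[1] & freqs <= band[2]
  F <- stats::mvfft(Y)
  F[!keep, ] <- 0
  Y <- Re(stats::mvfft(F, inverse = TRUE)) / nt
  out <- fmri
  out@series <- array(t(Y), dim = d)
  out
}

#' Lesion-seeded functional connectivity of one normative scan
#'
#' The seed series is the mean time course over lesion-cap-brain voxels;
#' every non-lesion in-brain voxel gets the Fisher-Z transform of its
#' Pearson correlation with the seed (r clamped to +/-(1 - 1e-7) before
#' arctanh so duplicated series stay finite); lesion-cap-brain entries are
#' exactly 0.
#'
#' @param fmri an [Fmri4D-class] (typically after [preprocessFmri()]).
#' @param lesion a [BrainMask-class].
#' @param brain the cohort [BrainMask-class] from [computeBrainMask()].
#' @param patientId identifier attached to the vector.
#' @return an [FCVector-class]
#' @export
seedFC <- function(fmri, lesion, brain, patientId = "patient") {
  stopIfGridMismatch(fmri@grid, brain@grid, "fMRI and brain mask")
  stopIfGridMismatch(lesion@grid, brain@grid, "lesion and brain mask")
  bidx <- brain@voxelIdx
  seedIdx <- intersect(lesion@voxelIdx, bidx)
  if (!length(seedIdx)) stop("lesion does not intersect the brain mask")
  nvox <- prod(fmri@grid@dims)
  M <- t(matrix(fmri@series, nrow = nvox))
  Y <- M[, bidx, drop = FALSE]
  seedSeries <- rowMeans(M[, seedIdx, drop = FALSE])
  if (stats::var(seedSeries) <= 0) stop("seed series has zero variance")
  r <- as.vector(stats::cor(seedSeries, Y))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  lesionCols <- which(bidx %in% seedIdx)
  z[lesionCols] <- 0
  new("FCVector", patientId = patientId, subjectId = fmri@subjectId,
      values = z, lesionCols = as.integer(lesionCols),
      nValid = length(bidx) - length(lesionCols))
}

#' Average FC vectors across the normative cohort
#'
#' Two-stage mean: sessions are first averaged within subject, then
#' subjects averaged with equal weights, so subjects with more sessions do
#' not dominate. All vectors must share the voxel index length and the
#' lesion zero-pattern (they describe one patient's lesion).
#'
#' @param vectors list of [FCVector-class] for one patient, one per
#'   normative scan.
#' @return an [FCVector-class] with subjectId ""
#' @export
averageFC <- function(vectors) {
  stopifnot(length(vectors) >= 1L)
  ref <- vectors[[1]]
  for (v in vectors) {
    if (!identical(v@lesionCols, ref@lesionCols) ||
        length(v@values) != length(ref@values))
      stop("mismatched voxel index or lesion zero-pattern in FC vectors")
  }
  bySubj <- split(vectors, vapply(vectors, function(v) v@subjectId,
                                  character(1)))
  subjMeans <- lapply(bySubj, function(vs)
    rowMeans(vapply(vs, function(v) v@values,
                    numeric(length(ref@values)))))
  avg <- rowMeans(do.call(cbind, subjMeans))
  avg[ref@lesionCols] <- 0
  new("FCVector", patientId = ref@patientId, subjectId = "",
      values = avg, lesionCols = ref@lesionCols, nValid = ref@nValid)
}

#' Assemble the union FC matrix
#'
#' Stacks per-patient averaged FC vectors in patient order, lesion entries
#' filled with zeroes. With `standardize = TRUE` each row (scope "row") is
#' centred and scaled to unit sample variance over its non-lesion entries,
#' zeros restored afterwards; scope "global" standardizes over all
#' non-lesion entries of the whole matrix at once.
#'
#' @param vectors named list of [FCVector-class], one per patient.
#' @param grid,brain the spatial frame ([VolumeGrid-class],
#'   [BrainMask-class]).
#' @param standardize logical, default TRUE.
#' @param zscoreScope "row" (default) or "global".
#' @return an [FCMatrix-class]
#' @export
assembleFCMatrix <- function(vectors, grid, brain, standardize = TRUE,
                             zscoreScope = c("row", "global")) {
  zscoreScope <- match.arg(zscoreScope)
  stopifnot(length(vectors) >= 2L)
  ids <- vapply(vectors, function(v) v@patientId, character(1))
  X <- t(vapply(vectors, function(v) v@values,
                numeric(length(vectors[[1]]@values))))
  lesionCols <- lapply(vectors, function(v) v@lesionCols)
  if (standardize) {
    if (zscoreScope == "row") {
      for (i in seq_len(nrow(X))) {
        valid <- setdiff(seq_len(ncol(X)), lesionCols[[i]])
        v <- X[i, valid]
        s <- stats::sd(v)
        if (!is.finite(s) || s == 0)
          stop("zero-variance FC row for patient ", ids[i])
        X[i, valid] <- (v - mean(v)) / s
        X[i, lesionCols[[i]]] <- 0
      }
    } else {
      validMask <- matrix(TRUE, nrow(X), ncol(X))
      for (i in seq_len(nrow(X))) validMask[i, lesionCols[[i]]] <- FALSE
      v <- X[validMask]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) stop("zero-variance FC matrix")
      X[validMask] <- (v - mean(v)) / s
      X[!validMask] <- 0
    }
  }
  ids <- unname(ids)
  rownames(X) <- ids
  new("FCMatrix", values = X, patientIds = unname(ids),
      voxelIndex = brain@voxelIdx, lesionCols = unname(lesionCols),
      grid = grid, standardized = standardize)
}

#' Lesion-seeded FC for every patient across the normative cohort
#'
#' Convenience wrapper: for each patient, [seedFC()] against every
#' normative scan, then [averageFC()]. Returns both the per-scan vectors
#' (needed by the LNM baseline and the HC-subset robustness scan) and the
#' per-patient averages.
#'
#' @param fmris list of preprocessed [Fmri4D-class].
#' @param cohort a [LesionCohort-class].
#' @param brain the cohort [BrainMask-class].
#' @param keepPerSubject keep the unaveraged vectors (default TRUE).
#' @return list with elements `averaged` (named list of [FCVector-class])
#'   and `perSubject` (named list of lists, or NULL)
#' @export
cohortFC <- function(fmris, cohort, brain, keepPerSubject = TRUE) {
  ids <- names(cohort@lesions)
  perSubject <- stats::setNames(vector("list", length(ids)), ids)
  averaged <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    vs <- lapply(fmris, seedFC, lesion = cohort@lesions[[id]],
                 brain = brain, patientId = id)
    averaged[[id]] <- averageFC(vs)
    if (keepPerSubject) perSubject[[id]] <- vs
  }
  list(averaged = averaged,
       perSubject = if (keepPerSubject) perSubject else NULL)
}
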