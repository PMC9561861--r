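# Comparison methods: lesion-overlap heterogeneity analysis, voxel-based
# lesion-symptom mapping (VLSM), and classic overlay lesion network
# mapping (LNM).

#' Lesion overlap heterogeneity summary
#'
#' Overlap map (voxelwise lesion count), the overlap curve (proportion of
#' ever-lesioned voxels shared by at least k patients, k = 1..n), and the
#' mean/sd of pairwise overlap between patients. Pairwise overlap of
#' lesions Li, Lj defaults to |Li cap Lj| / min(|Li|, |Lj|); "dice" and
#' "union" (Jaccard) denominators are available.
#'
#' @param cohort a [LesionCohort-class] (>= 2 patients).
#' @param pairwise overlap denominator: "min" (default), "dice", "union".
#' @return list(overlapMap = [BrainVolume-class] of counts,
#'   curve = data.frame(k, proportion), pairwiseMean, pairwiseSd,
#'   pairwise = full vector)
#' @export
overlapSummary <- function(cohort, pairwise = c("min", "dice", "union")) {
  pairwise <- match.arg(pairwise)
  n <- length(cohort@lesions)
  stopifnot(n >= 2)
  counts <- Reduce(`+`, lapply(cohort@lesions, function(l) l@data))
  ever <- sum(counts >= 1)
  curve <- data.frame(
    k = seq_len(n),
    proportion = vapply(seq_len(n), function(k) sum(counts >= k) / ever,
                        numeric(1)))
  idx <- lapply(cohort@lesions, function(l) l@voxelIdx)
  pv <- numeric(0)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    ov <- length(intersect(idx[[i]], idx[[j]]))
    den <- switch(pairwise,
      min = min(length(idx[[i]]), length(idx[[j]])),
      dice = (length(idx[[i]]) + length(idx[[j]])) / 2,
      union = length(union(idx[[i]], idx[[j]])))
    pv <- c(pv, ov / den)
  }
  list(overlapMap = brainVolume(counts, cohort@grid), curve = curve,
       pairwiseMean = mean(pv), pairwiseSd = stats::sd(pv), pairwise = pv)
}

#' Voxel-based lesion-symptom mapping
#'
#' Eligible voxels are lesioned in at least `minFrac` and at most
#' `maxFrac` of the cohort. Per eligible voxel, a two-sample t-test
#' (pooled variance by default, Welch optional) compares the behavior of
#' lesioned vs non-lesioned patients; two-sided p-values are
#' Benjamini-Hochberg corrected across eligible voxels at `alpha`, and
#' significant t-values are projected into a t-map.
#'
#' @param cohort a [LesionCohort-class].
#' @param behavior numeric vector in cohort patient order (e.g. AQ).
#' @param minFrac,maxFrac eligibility bounds (default 0.25/0.75).
#' @param alpha FDR level (default 0.05).
#' @param welch use Welch's t instead of pooled variance.
#' @return list(eligible = voxel indices, t = named t-vector, p = named
#'   p-vector, pAdj, significant = [BrainMask-class], tMap, pMap,
#'   dropped = voxels with a group of size < 2, alpha)
#' @export
vlsm <- function(cohort, behavior, minFrac = 0.25, maxFrac = 0.75,
                 alpha = 0.05, welch = FALSE) {
  n <- length(cohort@lesions)
  stopifnot(length(behavior) == n, minFrac > 0, maxFrac < 1,
            minFrac < maxFrac)
  counts <- Reduce(`+`, lapply(cohort@lesions, function(l) l@data))
  eligible <- which(counts >= minFrac * n & counts <= maxFrac * n)
  lesMat <- vapply(cohort@lesions, function(l) l@data[eligible],
                   numeric(length(eligible)))  # voxels x patients
  tvals <- rep(NA_real_, length(eligible))
  pvals <- rep(NA_real_, length(eligible))
  dropped <- integer(0)
  for (v in seq_along(eligible)) {
    g <- lesMat[v, ] > 0
    x <- behavior[g]; y <- behavior[!g]
    if (length(x) < 2 || length(y) < 2) {
      dropped <- c(dropped, eligible[v])
      next
    }
    tt <- stats::t.test(x, y, var.equal = !welch)
    tvals[v] <- unname(tt$statistic); pvals[v] <- tt$p.value
  }
  keep <- !is.na(pvals)
  pAdj <- rep(NA_real_, length(eligible))
  pAdj[keep] <- stats::p.adjust(pvals[keep], method = "BH")
  sig <- which(keep & pAdj < alpha)
  tMap <- array(0, cohort@grid@dims)
  tMap[eligible[sig]] <- tvals[sig]
  pMap <- array(1, cohort@grid@dims)
  pMap[eligible[keep]] <- pvals[keep]
  sigArr <- array(0, cohort@grid@dims)
  sigArr[eligible[sig]] <- 1
  list(eligible = eligible, t = tvals, p = pvals, pAdj = pAdj,
       significant = brainMask(sigArr, cohort@grid),
       tMap = brainVolume(tMap, cohort@grid),
       pMap = brainVolume(pMap, cohort@grid),
       dropped = dropped, alpha = alpha)
}

#' Per-patient lesion network map (classic LNM)
#'
#' One-sample t-test of the Fisher-Z connectivity values against 0 across
#' normative subjects at every non-lesion in-brain voxel; Bonferroni
#' (voxel-level FWE) correction over tested voxels; positive mask =
#' corrected p below `alphaCorrected` and t > 0. Zero-variance voxels are
#' excluded and reported.
#'
#' @param perSubjectFC list of unaveraged [FCVector-class] for one
#'   patient (>= 3 subjects).
#' @param brain the [BrainMask-class].
#' @param alphaCorrected corrected significance level (default 1e-6).
#' @return list(t = t per voxel column (NA where untested), tMap =
#'   [BrainVolume-class], positiveMask = [BrainMask-class], excluded =
#'   column positions skipped, nTested)
#' @export
lnmPatientMap <- function(perSubjectFC, brain, alphaCorrected = 1e-6) {
  stopifnot(length(perSubjectFC) >= 3)
  nsub <- length(perSubjectFC)
  M <- vapply(perSubjectFC, function(v) v@values,
              numeric(length(perSubjectFC[[1]]@values)))  # voxels x subj
  lesionCols <- perSubjectFC[[1]]@lesionCols
  mu <- rowMeans(M)
  sdv <- apply(M, 1, stats::sd)
  testable <- sdv > 0
  testable[lesionCols] <- FALSE
  excluded <- setdiff(which(!testable), lesionCols)
  nTested <- sum(testable)
  tvals <- rep(NA_real_, nrow(M))
  tvals[testable] <- mu[testable] / (sdv[testable] / sqrt(nsub))
  p <- 2 * stats::pt(-abs(tvals), df = nsub - 1)
  pCorr <- pmin(p * nTested, 1)
  posCols <- which(testable & tvals > 0 & pCorr < alphaCorrected)
  bidx <- brain@voxelIdx
  tArr <- array(0, brain@grid@dims)
  tArr[bidx[testable]] <- tvals[testable]
  posArr <- array(0, brain@grid@dims)
  posArr[bidx[posCols]] <- 1
  list(t = tvals, tMap = brainVolume(tArr, brain@grid),
       positiveMask = brainMask(posArr, brain@grid),
       excluded = excluded, nTested = nTested)
}

#' Overlay of per-patient positive LNM masks
#'
#' Voxelwise count of patients whose positive map covers each voxel, and
#' common maps keeping voxels identified in at least ceil(f * n) patients
#' for each requested fraction.
#'
#' @param masks list of positive [BrainMask-class], one per patient.
#' @param fractions thresholds in (0, 1], default c(0.7, 0.8, 0.9).
#' @return list(overlay = [BrainVolume-class] of counts, commonMaps =
#'   named list of [BrainMask-class])
#' @export
lnmOverlay <- function(masks, fractions = c(0.7, 0.8, 0.9)) {
  stopifnot(length(masks) >= 1, all(fractions > 0), all(fractions <= 1))
  grid <- masks[[1]]@grid
  for (m in masks) stopIfGridMismatch(m@grid, grid, "LNM masks")
  counts <- Reduce(`+`, lapply(masks, function(m) m@data))
  n <- length(masks)
  commonMaps <- lapply(fractions, function(f)
    brainMask(counts >= ceiling(f * n), grid))
  names(commonMaps) <- sprintf("%d%%", round(100 * fractions))
  list(overlay = brainVolume(counts, grid), commonMaps = commonMaps)
}
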