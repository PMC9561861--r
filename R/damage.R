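# Per-patient network damage scores, lesion-size residualization,
# brain-behavior correlation, correlation comparison, WAB AQ helper, and
# the specificity panel.

#' Western Aphasia Battery Aphasia Quotient
#'
#' AQ = (naming/10 + comprehension/20 + fluency + repetition/10) * 2,
#' range 0..100, lower = more severe.
#'
#' @param naming 0..100; @param comprehension 0..200; @param fluency
#'   0..10; @param repetition 0..100. Vectorized.
#' @return AQ score(s)
#' @export
wabAQ <- function(naming, comprehension, fluency, repetition) {
  chk <- function(x, lo, hi, what) {
    if (any(!is.finite(x) | x < lo | x > hi))
      stop(what, " out of WAB range [", lo, ", ", hi, "]")
  }
  chk(naming, 0, 100, "naming"); chk(comprehension, 0, 200, "comprehension")
  chk(fluency, 0, 10, "fluency"); chk(repetition, 0, 100, "repetition")
  (naming / 10 + comprehension / 20 + fluency + repetition / 10) * 2
}

#' Network damage score of one lesion
#'
#' The maximum z-value of the network map inside the intersection of its
#' positive (thresholded) mask and the lesion; the binarized map defines
#' where, the continuous z-values how much. An empty intersection scores
#' 0 with a warning (the patient is retained, not dropped).
#'
#' @param network a [NetworkMap-class].
#' @param lesion a [BrainMask-class].
#' @return list(raw = real, nIntersect = integer)
#' @export
damageScore <- function(network, lesion) {
  stopIfGridMismatch(network@zmap@grid, lesion@grid,
                     "network map and lesion")
  inter <- intersect(network@positiveMask@voxelIdx, lesion@voxelIdx)
  if (!length(inter)) {
    warning("lesion does not intersect network '", network@label,
            "'; damage score 0")
    return(list(raw = 0, nIntersect = 0L))
  }
  list(raw = max(network@zmap@data[inter]), nIntersect = length(inter))
}

#' Count-based damage scores for a binary reference network
#'
#' Per patient, the number of lesion voxels inside the binary reference,
#' standardized (z-scored, sample sd) across the cohort.
#'
#' @param ref a binary [ReferenceNetwork-class] (or [BrainMask-class]).
#' @param cohort a [LesionCohort-class].
#' @return named numeric vector of z-scored counts
#' @export
damageScoreBinary <- function(ref, cohort) {
  mask <- if (is(ref, "BrainMask")) ref else {
    stopifnot(ref@kind == "binary")
    binarize(ref@map, 0)
  }
  counts <- vapply(cohort@lesions, function(l)
    length(intersect(mask@voxelIdx, l@voxelIdx)), integer(1))
  s <- stats::sd(counts)
  if (!is.finite(s) || s == 0)
    stop("zero variance of intersection counts across the cohort")
  (counts - mean(counts)) / s
}

#' Regress lesion size out of damage scores
#'
#' Residuals of the OLS fit of scores on (intercept, lesion size); by
#' construction mean 0 and uncorrelated with lesion size.
#'
#' @param scores numeric vector (length >= 3).
#' @param lesionSizes numeric vector, nonconstant.
#' @return residual vector
#' @export
residualize <- function(scores, lesionSizes) {
  stopifnot(length(scores) == length(lesionSizes), length(scores) >= 3)
  if (stats::sd(lesionSizes) == 0)
    stop("lesion sizes are constant; cannot residualize")
  unname(stats::residuals(stats::lm(scores ~ lesionSizes)))
}

#' Pearson brain-behavior correlation
#'
#' Pearson r with the two-sided p-value from the t distribution with
#' n - 2 degrees of freedom.
#'
#' @param scores,behavior equal-length numeric vectors (n >= 4), both
#'   nonconstant.
#' @return list(r, p, n)
#' @export
behaviorCorrelation <- function(scores, behavior) {
  stopifnot(length(scores) == length(behavior), length(scores) >= 4)
  if (stats::sd(scores) == 0 || stats::sd(behavior) == 0)
    stop("constant input to correlation")
  ct <- stats::cor.test(scores, behavior, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(scores))
}

#' Compare two correlation coefficients (independent Fisher test)
#'
#' Fisher r-to-z on each coefficient, z = (z1 - z2) /
#' sqrt(1/(n1 - 3) + 1/(n2 - 3)), two-sided normal p.
#'
#' @param r1,r2 correlations, |r| < 1.
#' @param n1,n2 sample sizes (>= 4).
#' @return list(z, p)
#' @export
compareCorrelations <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 >= 4, n2 >= 4)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Residualized damage scores of a network map over a cohort
#'
#' @param network a [NetworkMap-class].
#' @param cohort a [LesionCohort-class].
#' @return data.frame: patient_id, raw, n_intersect, lesion_size, residual
#' @export
cohortDamage <- function(network, cohort) {
  ids <- names(cohort@lesions)
  raw <- numeric(length(ids)); ni <- integer(length(ids))
  for (i in seq_along(ids)) {
    d <- withCallingHandlers(
      damageScore(network, cohort@lesions[[i]]),
      warning = function(w) invokeRestart("muffleWarning"))
    raw[i] <- d$raw; ni[i] <- d$nIntersect
  }
  sizes <- vapply(cohort@lesions, function(l) length(l@voxelIdx),
                  integer(1))
  data.frame(patient_id = ids, raw = raw, n_intersect = ni,
             lesion_size = unname(sizes),
             residual = residualize(raw, sizes), row.names = NULL)
}

#' Specificity panel: every network against every behavior measure
#'
#' For every component of the decomposition (max-z damage scores) and
#' every reference network (count-based scores for binary references,
#' max-z on the z-scored thresholded map for continuous ones), computes
#' lesion-size-residualized damage scores and their correlation with AQ
#' and each WAB subtest. One row per (network, measure): the table behind
#' the specificity contrast of the target component against all controls.
#'
#' @param decomp a [Decomposition-class].
#' @param refs list of [ReferenceNetwork-class] (may be empty).
#' @param cohort a [LesionCohort-class].
#' @param behavior data.frame with patient_id, aq and subtest columns.
#' @param z component/reference threshold (default 1).
#' @param measures behavior columns to correlate.
#' @return data.frame: network, kind, measure, r, p, n
#' @export
specificityPanel <- function(decomp, refs, cohort, behavior, z = 1,
    measures = c("aq", "naming", "comprehension", "fluency", "repetition")) {
  behavior <- behavior[match(names(cohort@lesions), behavior$patient_id), ]
  measures <- intersect(measures, names(behavior))
  sizes <- vapply(cohort@lesions, function(l) length(l@voxelIdx),
                  integer(1))
  scoreSets <- list()
  for (i in seq_len(nComponents(decomp))) {
    dmg <- cohortDamage(componentNetworkMap(decomp, i, z), cohort)
    scoreSets[[sprintf("IC%d", i)]] <-
      list(kind = "component", scores = dmg$residual)
  }
  for (ref in refs) {
    raw <- if (ref@kind == "binary") {
      damageScoreBinary(ref, cohort)
    } else {
      v <- ref@map@data
      idx <- decomp@brainMask@voxelIdx
      zz <- array(0, ref@map@grid@dims)
      zz[idx] <- (v[idx] - mean(v[idx])) / stats::sd(v[idx])
      nm <- thresholdMap(brainVolume(zz, ref@map@grid), z, ref@name)
      cohortDamage(nm, cohort)$raw
    }
    scoreSets[[ref@name]] <-
      list(kind = "reference", scores = residualize(as.numeric(raw), sizes))
  }
  rows <- list()
  for (nm in names(scoreSets)) for (m in measures) {
    bc <- tryCatch(behaviorCorrelation(scoreSets[[nm]]$scores,
                                       behavior[[m]]),
                   error = function(e) list(r = NA_real_, p = NA_real_,
                                            n = nrow(behavior)))
    rows[[length(rows) + 1L]] <-
      data.frame(network = nm, kind = scoreSets[[nm]]$kind, measure = m,
                 r = bc$r, p = bc$p, n = bc$n)
  }
  do.call(rbind, rows)
}
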