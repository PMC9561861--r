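# Orchestration of the full run plus the reproducibility / stability
# harnesses. Every paper-stated constant lives in the run configuration,
# never inline.

#' Default run configuration
#'
#' nRuns 30 ICA restarts; component threshold Z = 1 (alternates 0.5 /
#' 1.5 in the robustness scan); row-scope z-scoring of the FC matrix;
#' knee-point order unless `order` overrides; band-pass 0.01-0.08 Hz with
#' global-signal regression; overlay fractions 70/80/90%; VLSM
#' eligibility 25-75% with FDR alpha 0.05; LNM corrected alpha 1e-6.
#'
#' @param ... overrides.
#' @return named list
#' @export
defaultRunConfig <- function(...) {
  utils::modifyList(
    list(nRuns = 30L, icThreshold = 1, zscoreScope = "row", order = NULL,
         band = c(0.01, 0.08), globalSignal = TRUE,
         overlayFractions = c(0.7, 0.8, 0.9), vlsmFracs = c(0.25, 0.75),
         alpha = 0.05, lnmAlphaCorrected = 1e-6, seed = 1L),
    list(...))
}

#' Core run from per-patient averaged FC vectors
#'
#' Assembly, decomposition, identification and (when behavior is given)
#' damage scoring — the stages downstream of connectivity, shared by the
#' full run and the validation harnesses.
#'
#' @param averaged named list of per-patient averaged [FCVector-class].
#' @param brain [BrainMask-class].
#' @param refs list of [ReferenceNetwork-class] (may be empty: the first
#'   component is then "selected" without identification).
#' @param lesions [LesionCohort-class] (needed for damage scoring).
#' @param behavior optional data.frame with patient_id, aq, subtests.
#' @param config list from [defaultRunConfig()].
#' @return list: fcMatrix, decomposition, similarity, selectedIC,
#'   networkMap, damage, correlations
#' @export
runFromVectors <- function(averaged, brain, refs = list(),
                           lesions = NULL, behavior = NULL,
                           config = defaultRunConfig()) {
  grid <- brain@grid
  fcm <- assembleFCMatrix(averaged, grid, brain, standardize = TRUE,
                          zscoreScope = config$zscoreScope)
  decomp <- runDecomposition(fcm, brain, seed = config$seed,
                             nRuns = config$nRuns, q = config$order)
  similarity <- NULL
  selectedIC <- 1L
  if (length(refs)) {
    similarity <- rankComponents(decomp, refs, z = config$icThreshold)
    selectedIC <- attr(similarity, "selectedIC")
  }
  networkMap <- componentNetworkMap(decomp, selectedIC,
                                    z = config$icThreshold)
  damage <- NULL; correlations <- NULL
  if (!is.null(behavior) && !is.null(lesions)) {
    behavior <- behavior[match(names(lesions@lesions),
                               behavior$patient_id), ]
    damage <- cohortDamage(networkMap, lesions)
    meas <- intersect(c("aq", "naming", "comprehension", "fluency",
                        "repetition"), names(behavior))
    correlations <- do.call(rbind, lapply(meas, function(m) {
      bc <- behaviorCorrelation(damage$residual, behavior[[m]])
      data.frame(measure = m, r = bc$r, p = bc$p, n = bc$n)
    }))
  }
  list(fcMatrix = fcm, decomposition = decomp, similarity = similarity,
       selectedIC = selectedIC, networkMap = networkMap, damage = damage,
       correlations = correlations, config = config)
}

#' Full independent component-based lesion mapping run
#'
#' Preprocesses the normative scans (nuisance regression + band-pass),
#' builds the cohort brain mask, computes lesion-seeded FC per patient
#' averaged over the normative cohort, decomposes the union FC matrix,
#' identifies the symptom-related component against the references, and
#' scores per-patient network damage. All randomness flows from
#' `config$seed`; a rerun with the same config is bit-identical.
#'
#' @param lesions a [LesionCohort-class].
#' @param fmris list of [Fmri4D-class] normative scans (raw; set
#'   `preprocess = FALSE` if already cleaned).
#' @param refs list of [ReferenceNetwork-class].
#' @param behavior optional behavior data.frame.
#' @param config list from [defaultRunConfig()].
#' @param preprocess run [preprocessFmri()] first (default TRUE).
#' @param keepPerSubject keep unaveraged FC vectors (LNM baseline /
#'   HC-subset scans; default FALSE).
#' @param outDir optional artifact directory (see [writeRunArtifacts()]).
#' @return list as [runFromVectors()], plus brain, averaged, perSubject
#' @export
runICLM <- function(lesions, fmris, refs = list(), behavior = NULL,
                    config = defaultRunConfig(), preprocess = TRUE,
                    keepPerSubject = FALSE, outDir = NULL) {
  if (preprocess) {
    brain0 <- computeBrainMask(fmris)
    fmris <- lapply(fmris, preprocessFmri, band = config$band,
                    brain = if (isTRUE(config$globalSignal)) brain0)
  }
  brain <- computeBrainMask(fmris)
  fcv <- cohortFC(fmris, lesions, brain, keepPerSubject = keepPerSubject)
  res <- runFromVectors(fcv$averaged, brain, refs, lesions, behavior,
                        config)
  res$brain <- brain
  res$averaged <- fcv$averaged
  res$perSubject <- fcv$perSubject
  if (!is.null(outDir)) writeRunArtifacts(res, outDir)
  res
}

#' Write run artifacts to a directory
#'
#' Per-component z-maps (NIfTI), the patient mixing matrix and cross-ISI
#' matrix (CSV), similarity and damage tables (CSV), and a provenance
#' JSON (configuration, seed, selected component, run convergence,
#' package and R versions).
#'
#' @param res a [runICLM()] / [runFromVectors()] result.
#' @param outDir destination directory (created).
#' @return `outDir`, invisibly
#' @export
writeRunArtifacts <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  decomp <- res$decomposition
  for (i in seq_len(nComponents(decomp)))
    writeVolume(componentVolume(decomp, i),
                file.path(outDir, sprintf("ic%02d_zmap.nii.gz", i)))
  utils::write.csv(decomp@patientMixing,
                   file.path(outDir, "mixing.csv"), row.names = FALSE)
  utils::write.csv(decomp@crossISI,
                   file.path(outDir, "cross_isi.csv"), row.names = FALSE)
  if (!is.null(res$similarity))
    utils::write.csv(res$similarity,
                     file.path(outDir, "similarity.csv"), row.names = FALSE)
  if (!is.null(res$damage))
    utils::write.csv(res$damage, file.path(outDir, "damage.csv"),
                     row.names = FALSE)
  if (!is.null(res$correlations))
    utils::write.csv(res$correlations,
                     file.path(outDir, "correlations.csv"),
                     row.names = FALSE)
  prov <- list(
    config = res$config[setdiff(names(res$config), "order")],
    order = res$config$order %||% "knee-point",
    selected_ic = res$selectedIC,
    n_components = nComponents(decomp),
    selected_run = decomp@selectedRun,
    converged_runs = sum(vapply(decomp@runs, function(r) r@converged,
                                logical(1))),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("iclm")))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Split-half reproducibility of the identified network
#'
#' Per repeat: if the cohort is odd, one random patient is dropped; the
#' rest are split into two equal halves; the core run is executed per
#' half; the Dice coefficient between the two halves' identified positive
#' masks is recorded. Failed repeats (e.g. a half whose decomposition
#' does not converge) are excluded from the mean and reported.
#'
#' @param averaged named list of per-patient averaged [FCVector-class]
#'   (>= 6 patients).
#' @param brain,refs,config as in [runFromVectors()].
#' @param nRepeats number of random splits (default 10).
#' @param seed harness seed.
#' @return list(dice = per-repeat vector (NA = failed), meanDice)
#' @export
splitHalf <- function(averaged, brain, refs, nRepeats = 10L, seed = 1L,
                      config = defaultRunConfig()) {
  ids <- names(averaged)
  stopifnot(length(ids) >= 6)
  if (nRepeats == 0L)
    return(list(dice = numeric(0), meanDice = NA_real_))
  dice <- rep(NA_real_, nRepeats)
  for (rep in seq_len(nRepeats)) {
    set.seed(deriveSeed(seed, 500L + rep))
    use <- ids
    if (length(use) %% 2L == 1L) use <- setdiff(use, sample(use, 1))
    half1 <- sample(use, length(use) / 2)
    half2 <- setdiff(use, half1)
    dice[rep] <- tryCatch({
      m1 <- runFromVectors(averaged[half1], brain, refs,
                           config = config)$networkMap
      m2 <- runFromVectors(averaged[half2], brain, refs,
                           config = config)$networkMap
      diceCoefficient(m1@positiveMask, m2@positiveMask)
    }, error = function(e) NA_real_)
  }
  list(dice = dice, meanDice = mean(dice, na.rm = TRUE))
}

#' Subgroup reproducibility of the identified network
#'
#' Runs the core pipeline per labelled subgroup and reports the Dice
#' coefficient of each subgroup's identified positive mask against the
#' full-cohort map. Groups smaller than 3 are skipped with a warning.
#'
#' @param averaged named list of per-patient averaged [FCVector-class].
#' @param brain,refs,config as in [runFromVectors()].
#' @param labels named character vector mapping every patient to a group.
#' @param fullMap the full-cohort [NetworkMap-class].
#' @return data.frame: group, n, dice
#' @export
subgroupRuns <- function(averaged, brain, refs, labels, fullMap,
                         config = defaultRunConfig()) {
  ids <- names(averaged)
  if (!all(ids %in% names(labels)))
    stop("missing group label for: ",
         paste(setdiff(ids, names(labels)), collapse = ", "))
  rows <- list()
  for (g in unique(labels[ids])) {
    members <- ids[labels[ids] == g]
    if (length(members) < 3) {
      warning("subgroup '", g, "' has fewer than 3 patients; skipped")
      next
    }
    nm <- runFromVectors(averaged[members], brain, refs,
                         config = config)$networkMap
    rows[[g]] <- data.frame(group = g, n = length(members),
                            dice = diceCoefficient(nm@positiveMask,
                                                   fullMap@positiveMask))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Robustness to normative cohort size and component threshold
#'
#' Reruns averaging + decomposition + identification per normative-subset
#' size (subjects drawn without replacement under `seed`) and reports the
#' Dice of each identified map against the reference run; rethresholds
#' the reference run's selected component per threshold and reports
#' positive-mask size, Dice against the reference threshold's map and
#' (when behavior is given) the AQ correlation of residualized damage.
#'
#' @param perSubject named list (per patient) of lists of unaveraged
#'   [FCVector-class] (one per normative scan).
#' @param brain,refs,config as in [runFromVectors()].
#' @param lesions [LesionCohort-class]; behavior optional data.frame.
#' @param hcSubsets integer vector of normative-subset sizes.
#' @param thresholds numeric vector of component thresholds
#'   (default c(0.5, 1, 1.5)).
#' @param seed harness seed.
#' @return list(reference = full run, hcSubsets = data.frame,
#'   thresholds = data.frame)
#' @export
robustnessScan <- function(perSubject, brain, refs, lesions = NULL,
                           behavior = NULL, hcSubsets = integer(0),
                           thresholds = c(0.5, 1, 1.5), seed = 1L,
                           config = defaultRunConfig()) {
  nScan <- length(perSubject[[1]])
  stopifnot(all(hcSubsets >= 2), all(hcSubsets <= nScan))
  full <- runFromVectors(lapply(perSubject, averageFC), brain, refs,
                         lesions, behavior, config)
  subsetRows <- lapply(hcSubsets, function(s) {
    set.seed(deriveSeed(seed, 700L + s))
    pick <- sample.int(nScan, s)
    avg <- lapply(perSubject, function(vs) averageFC(vs[pick]))
    res <- runFromVectors(avg, brain, refs, config = config)
    data.frame(nHc = s, selectedIC = res$selectedIC,
               dice = diceCoefficient(res$networkMap@positiveMask,
                                      full$networkMap@positiveMask))
  })
  thrRows <- lapply(thresholds, function(z) {
    nm <- componentNetworkMap(full$decomposition, full$selectedIC, z)
    rAq <- NA_real_; pAq <- NA_real_
    if (!is.null(behavior) && !is.null(lesions)) {
      dmg <- cohortDamage(nm, lesions)
      b <- behavior[match(names(lesions@lesions),
                          behavior$patient_id), ]
      bc <- behaviorCorrelation(dmg$residual, b$aq)
      rAq <- bc$r; pAq <- bc$p
    }
    data.frame(threshold = z,
               nPositive = length(nm@positiveMask@voxelIdx),
               dice = diceCoefficient(nm@positiveMask,
                                      full$networkMap@positiveMask),
               rAq = rAq, pAq = pAq)
  })
  list(reference = full,
       hcSubsets = if (length(subsetRows)) do.call(rbind, subsetRows)
                   else data.frame(),
       thresholds = do.call(rbind, thrRows))
}

#' References emulating the canonical language networks, from ground truth
#'
#' For synthetic studies: the planted target network plays both reference
#' roles — its continuous map stands in for a meta-analytic z-map and its
#' binarized support for a parcel-style binary network.
#'
#' @param gt a [GroundTruth-class].
#' @param threshold support binarization level (default 0.05 of peak).
#' @return list of two [ReferenceNetwork-class]
#' @export
referencesFromGroundTruth <- function(gt, threshold = 0.05) {
  tgt <- gt@networks[[gt@targetIndex]]
  list(referenceNetwork(tgt, "target_continuous", "continuous"),
       referenceNetwork(binarize(tgt, threshold), "target_binary"))
}
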