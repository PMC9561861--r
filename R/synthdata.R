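# Synthetic cohorts with the statistical structure the decomposition
# assumes: near-orthogonal smooth spatial sources, temporally independent
# source time courses, heterogeneous lesions, behavior driven by damage to
# one designated network. All randomness flows from a master seed.

deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483629)
}

blobValues <- function(grid, center, sd) {
  dims <- grid@dims
  dx2 <- (seq_len(dims[1]) - center[1])^2
  dy2 <- (seq_len(dims[2]) - center[2])^2
  dz2 <- (seq_len(dims[3]) - center[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  v <- exp(-d2 / (2 * sd^2))
  v[d2 > (2 * sd)^2] <- 0  # truncate at 2 sd
  v
}

#' Plant k spatially independent distributed networks on a grid
#'
#' Each network is a set of `nBlobs` isotropic Gaussian blobs (sd
#' `radius` voxels, truncated at 2 sd) sharing one source time course —
#' the multi-regional structure real functional networks have, and the
#' structure lesion network mapping relies on: a lesion can destroy one
#' node while the network's remote nodes still carry its connectivity
#' signature. Blob centres are drawn with a minimum mutual distance and
#' rejected until all pairwise network map correlations are below 0.2,
#' giving the near-orthogonal source maps the decomposition premise
#' requires. A canonical set of temporally independent source time
#' courses is drawn alongside (fresh realizations are used per simulated
#' subject).
#'
#' @param grid a [VolumeGrid-class].
#' @param k number of networks (>= 2).
#' @param seed integer.
#' @param radius blob sd in voxels (default 2).
#' @param nBlobs regions per network (default 2).
#' @param nTimepoints length of the canonical source series (default 150).
#' @param targetIndex which network drives behavior (default 1).
#' @return a [GroundTruth-class]; `centers` has one row per blob with
#'   columns x, y, z, network
#' @export
makeNetworks <- function(grid, k, seed, radius = 2, nBlobs = 2L,
                         nTimepoints = 150, targetIndex = 1L) {
  stopifnot(k >= 2, nBlobs >= 1)
  dims <- grid@dims
  margin <- ceiling(2 * radius)
  if (any(dims - 2 * margin < 1))
    stop("grid too small to host ", k, " blobs of radius ", radius)
  minDist <- 2 * radius + 1   # blob cores never merge
  set.seed(deriveSeed(seed, 1L))
  total <- k * nBlobs
  netOf <- rep(seq_len(k), each = nBlobs)
  maps <- NULL
  for (placement in seq_len(200L)) {
    centers <- matrix(NA_real_, total, 3)
    placed <- 0L
    for (attempt in seq_len(200L * total)) {
      ctr <- vapply(seq_len(3), function(a)
        stats::runif(1, 1 + margin, dims[a] - margin), numeric(1))
      if (placed > 0L) {
        d <- sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                           matrix(ctr, placed, 3, byrow = TRUE))^2))
        if (min(d) < minDist) next
      }
      placed <- placed + 1L
      centers[placed, ] <- ctr
      if (placed == total) break
    }
    if (placed < total) next
    cand <- vector("list", k)
    flat <- matrix(0, prod(dims), k)
    for (j in seq_len(k)) {
      v <- array(0, dims)
      for (b in which(netOf == j))
        v <- pmax(v, blobValues(grid, centers[b, ], radius))
      cand[[j]] <- brainVolume(v, grid)
      flat[, j] <- as.vector(v)
    }
    cc <- abs(stats::cor(flat)); diag(cc) <- 0
    if (max(cc) < 0.2) { maps <- cand; break }
  }
  if (is.null(maps))
    stop("cannot place ", total, " separated blobs of radius ", radius,
         " on a ", paste(dims, collapse = "x"), " grid")
  src <- drawIndependentSources(nTimepoints, k, deriveSeed(seed, 2L))
  new("GroundTruth", networks = maps, targetIndex = as.integer(targetIndex),
      sourceSeries = src, centers = cbind(centers, network = netOf),
      seed = as.integer(seed))
}

# iid standard-normal columns, redrawn until pairwise |r| < 0.2
drawIndependentSources <- function(n, k, seed) {
  set.seed(seed)
  for (i in seq_len(100L)) {
    src <- matrix(stats::rnorm(n * k), n, k)
    cc <- abs(stats::cor(src)); diag(cc) <- 0
    if (max(cc) < 0.2) return(src)
  }
  stop("could not draw near-independent source series")
}

#' Simulate normative resting-state scans from planted networks
#'
#' Each subject's voxel time series is the sum over networks of
#' map_k(voxel) * source_k(t) plus white Gaussian noise, with fresh
#' independent source realizations per subject sharing the spatial maps.
#' `snr` is sd(signal)/sd(noise) at a network's peak voxel (map value 1,
#' unit-variance sources), so the noise sd is 1/snr; `snr = Inf` gives
#' noiseless scans.
#'
#' @param gt a [GroundTruth-class].
#' @param nSubjects,nTimepoints cohort size and scan length.
#' @param snr positive real (or Inf).
#' @param seed integer; per-subject seeds derived deterministically.
#' @param tr repetition time in seconds (default 2).
#' @return list of [Fmri4D-class]
#' @export
simulateFmri <- function(gt, nSubjects, nTimepoints, snr, seed, tr = 2) {
  stopifnot(nTimepoints >= 30, snr > 0)
  grid <- gt@networks[[1]]@grid
  nvox <- prod(grid@dims)
  k <- length(gt@networks)
  mapsFlat <- vapply(gt@networks, function(m) as.vector(m@data),
                     numeric(nvox))
  noiseSd <- if (is.finite(snr)) 1 / snr else 0
  lapply(seq_len(nSubjects), function(s) {
    src <- drawIndependentSources(nTimepoints, k, deriveSeed(seed, 100L + s))
    set.seed(deriveSeed(seed, 10000L + s))
    ts <- src %*% t(mapsFlat)  # t x voxels
    if (noiseSd > 0)
      ts <- ts + matrix(stats::rnorm(nTimepoints * nvox, sd = noiseSd),
                        nTimepoints, nvox)
    new("Fmri4D", grid = grid,
        series = array(t(ts), dim = c(grid@dims, nTimepoints)),
        tr = tr, subjectId = sprintf("hc%02d", s), sessionId = "1")
  })
}

# lesion of exactly `size` voxels: the `size` nearest voxels to a centre
lesionBlob <- function(grid, center, size) {
  dims <- grid@dims
  dx2 <- (seq_len(dims[1]) - center[1])^2
  dy2 <- (seq_len(dims[2]) - center[2])^2
  dz2 <- (seq_len(dims[3]) - center[3])^2
  d2 <- as.vector(outer(outer(dx2, dy2, "+"), dz2, "+"))
  idx <- order(d2, seq_along(d2))[seq_len(size)]
  arr <- array(0, dims); arr[idx] <- 1
  brainMask(arr, grid)
}

#' Simulate a heterogeneous lesion cohort
#'
#' Each lesion is a compact blob of uniformly drawn size whose centre is
#' jittered around the centre of a network sampled from `hitProfile`;
#' jitter disperses centres so pairwise lesion overlap stays low, the
#' regime in which overlay methods fail. The returned cohort's `meta`
#' records, per patient, the seeded network, the max ground-truth map
#' value of every network inside the lesion, and the true target-network
#' damage used by behavior generation.
#'
#' @param gt a [GroundTruth-class].
#' @param nPatients cohort size (0 allowed).
#' @param hitProfile numeric vector over networks, sampling probabilities
#'   (default uniform).
#' @param sizeRange integer pair, lesion size in voxels.
#' @param seed integer.
#' @param jitterSd centre jitter sd in voxels (default 2.5).
#' @return a [LesionCohort-class]
#' @export
simulateLesions <- function(gt, nPatients,
                            hitProfile = rep(1, length(gt@networks)),
                            sizeRange = c(30L, 150L), seed = 1L,
                            jitterSd = 2.5) {
  stopifnot(all(hitProfile >= 0), sum(hitProfile) > 0, all(sizeRange >= 1))
  grid <- gt@networks[[1]]@grid
  k <- length(gt@networks)
  if (nPatients == 0L)
    return(new("LesionCohort", grid = grid, lesions = list(),
               meta = data.frame()))
  set.seed(deriveSeed(seed, 3L))
  prob <- hitProfile / sum(hitProfile)
  lesions <- list()
  meta <- vector("list", nPatients)
  for (p in seq_len(nPatients)) {
    net <- sample.int(k, 1, prob = prob)
    size <- sample(seq.int(sizeRange[1], sizeRange[2]), 1)
    support <- which(gt@networks[[net]]@data > 0)
    blobs <- which(gt@centers[, "network"] == net)
    for (try in seq_len(200L)) {
      blob <- if (length(blobs) > 1L) sample(blobs, 1) else blobs
      ctr <- gt@centers[blob, 1:3] + stats::rnorm(3, sd = jitterSd)
      ctr <- pmin(pmax(ctr, 1), grid@dims)
      mask <- lesionBlob(grid, ctr, size)
      if (length(intersect(mask@voxelIdx, support)) >= 1L) break
    }
    lesions[[p]] <- mask
    maxima <- vapply(gt@networks, function(nw)
      max(nw@data[mask@voxelIdx]), numeric(1))
    meta[[p]] <- data.frame(
      patient_id = sprintf("pt%02d", p), size = size, seeded_network = net,
      true_damage = maxima[gt@targetIndex],
      t(stats::setNames(maxima, sprintf("max_net_%d", seq_len(k)))))
  }
  names(lesions) <- sprintf("pt%02d", seq_len(nPatients))
  new("LesionCohort", grid = grid, lesions = lesions,
      meta = do.call(rbind, meta))
}

wabRanges <- list(naming = c(0, 100), comprehension = c(0, 200),
                  fluency = c(0, 10), repetition = c(0, 100),
                  aq = c(0, 100))

#' Simulate WAB-like behavior driven by target-network damage
#'
#' The AQ-like severity score is an affine function of the true damage to
#' the designated network (max ground-truth map value inside the lesion)
#' plus Gaussian noise, clipped to the WAB range; subtests use per-subtest
#' slopes scaled to their ranges. Negative slope means damage lowers the
#' score. Generating slopes are stored as attributes for recovery tests.
#'
#' @param lesions a [LesionCohort-class] from [simulateLesions()].
#' @param gt the matching [GroundTruth-class].
#' @param slope AQ points per unit true damage, must be <= 0 (default -60).
#' @param noiseSd Gaussian noise sd on the AQ scale (default 5).
#' @param seed integer.
#' @param intercept AQ at zero damage (default 90).
#' @return data.frame: patient_id, naming, comprehension, fluency,
#'   repetition, aq, lesion_size
#' @export
simulateBehavior <- function(lesions, gt, slope = -60, noiseSd = 5,
                             seed = 1L, intercept = 90) {
  stopifnot(slope <= 0, noiseSd >= 0)
  meta <- lesions@meta
  ids <- names(lesions@lesions)
  if (is.null(meta$true_damage)) {
    tgt <- gt@networks[[gt@targetIndex]]
    dmg <- vapply(lesions@lesions, function(m) max(tgt@data[m@voxelIdx]),
                  numeric(1))
  } else dmg <- meta$true_damage
  n <- length(ids)
  set.seed(deriveSeed(seed, 4L))
  clip <- function(x, rng) pmin(pmax(x, rng[1]), rng[2])
  gen <- function(rng, sl, icpt) {
    clip(icpt + sl * dmg + stats::rnorm(n, sd = noiseSd * diff(rng) / 100),
         rng)
  }
  # subtest slopes proportional to each scale's range
  slopes <- list(naming = slope, comprehension = 2 * slope,
                 fluency = slope / 10, repetition = slope)
  out <- data.frame(
    patient_id = ids,
    naming = gen(wabRanges$naming, slopes$naming, 0.9 * 100),
    comprehension = gen(wabRanges$comprehension, slopes$comprehension,
                        0.9 * 200),
    fluency = gen(wabRanges$fluency, slopes$fluency, 0.9 * 10),
    repetition = gen(wabRanges$repetition, slopes$repetition, 0.9 * 100),
    aq = clip(intercept + slope * dmg +
                stats::rnorm(n, sd = noiseSd), wabRanges$aq),
    lesion_size = vapply(lesions@lesions, function(m)
      length(m@voxelIdx), integer(1)),
    row.names = NULL)
  attr(out, "generating") <- list(slope = slope, intercept = intercept,
                                  noiseSd = noiseSd, slopes = slopes,
                                  trueDamage = dmg)
  out
}

#' Default generator settings of a synthetic study
#'
#' The toy scale at which the full pipeline runs in minutes on one CPU:
#' an 18^3 grid, K = 4 planted networks, 20 normative subjects with one
#' 150-timepoint session each (TR 2 s), 24 patients with dispersed
#' lesions of 30-150 voxels, peak-voxel SNR 1, AQ slope -60 with noise
#' sd 5. The default hit profile weights the designated target network
#' threefold over each other network: the emulated cohort is recruited
#' for the target deficit (as an aphasia cohort is), so the symptom
#' network must be damaged throughout the cohort and in any random
#' subgroup, while the remaining networks keep enough representation to
#' make the decomposition a genuine multi-network problem.
#'
#' @return named list of generator parameters
#' @export
defaultCohortConfig <- function() {
  list(gridDims = c(18L, 18L, 18L), voxelSize = 4, k = 4L, radius = 2,
       nBlobs = 2L, nHc = 20L, nTimepoints = 150L, tr = 2, snr = 1,
       nPatients = 24L, sizeRange = c(30L, 150L), jitterSd = 2.5,
       hitProfile = NULL, slope = -60, noiseSd = 5, intercept = 90,
       targetIndex = 1L)
}

#' Generate a complete synthetic cohort
#'
#' Runs [makeNetworks()], [simulateFmri()], [simulateLesions()] and
#' [simulateBehavior()] under one master seed (all sub-seeds derived from
#' it), at the settings of [defaultCohortConfig()] unless overridden.
#'
#' @param seed master seed.
#' @param ... overrides of [defaultCohortConfig()] entries.
#' @return a [SyntheticCohort-class]
#' @export
simulateCohort <- function(seed = 1L, ...) {
  cfg <- utils::modifyList(defaultCohortConfig(), list(...))
  grid <- volumeGrid(cfg$gridDims, cfg$voxelSize)
  gt <- makeNetworks(grid, cfg$k, seed, radius = cfg$radius,
                     nBlobs = cfg$nBlobs,
                     nTimepoints = cfg$nTimepoints,
                     targetIndex = cfg$targetIndex)
  fmris <- simulateFmri(gt, cfg$nHc, cfg$nTimepoints, cfg$snr, seed,
                        tr = cfg$tr)
  hp <- cfg$hitProfile %||% {
    p <- rep(1, cfg$k)
    p[cfg$targetIndex] <- 3
    p
  }
  lesions <- simulateLesions(gt, cfg$nPatients, hitProfile = hp,
                             sizeRange = cfg$sizeRange, seed = seed,
                             jitterSd = cfg$jitterSd)
  behavior <- simulateBehavior(lesions, gt, slope = cfg$slope,
                               noiseSd = cfg$noiseSd, seed = seed,
                               intercept = cfg$intercept)
  cfg$seed <- as.integer(seed)
  new("SyntheticCohort", groundTruth = gt, hcFmris = fmris,
      lesions = lesions, behavior = behavior, config = cfg)
}

#' Write a synthetic cohort to disk
#'
#' NIfTI volumes for scans and lesions, a behavior CSV, and a ground-truth
#' JSON (network centres, target index, generating slopes).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created).
#' @return `dir`, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fmri"), showWarnings = FALSE)
  dir.create(file.path(dir, "lesions"), showWarnings = FALSE)
  dir.create(file.path(dir, "networks"), showWarnings = FALSE)
  for (f in cohort@hcFmris)
    writeVolume(f, file.path(dir, "fmri",
                             sprintf("%s_ses%s.nii.gz", f@subjectId,
                                     f@sessionId)))
  for (id in names(cohort@lesions@lesions))
    writeVolume(cohort@lesions@lesions[[id]],
                file.path(dir, "lesions", paste0(id, ".nii.gz")))
  gt <- cohort@groundTruth
  for (i in seq_along(gt@networks))
    writeVolume(gt@networks[[i]],
                file.path(dir, "networks", sprintf("net%02d.nii.gz", i)))
  utils::write.csv(cohort@behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  gen <- attr(cohort@behavior, "generating")
  jsonlite::write_json(
    list(target_index = gt@targetIndex, centers = gt@centers,
         seed = gt@seed, generating = gen[c("slope", "intercept", "noiseSd")],
         config = cohort@config[setdiff(names(cohort@config), "hitProfile")]),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
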