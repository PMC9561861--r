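# Shared fixture builders. Everything is generated in code at test time;
# the small cohort is memoised so several files can share one build.

tinyGrid <- function(n = 4) volumeGrid(c(n, n, n))

# an Fmri4D from a timepoints x voxels matrix (column-major voxel order)
fmriFromMatrix <- function(ts, dims, tr = 2, subjectId = "s1",
                           sessionId = "1") {
  new("Fmri4D", grid = volumeGrid(dims),
      series = array(t(ts), dim = c(dims, nrow(ts))), tr = tr,
      subjectId = subjectId, sessionId = sessionId)
}

maskFromIdx <- function(idx, grid) {
  arr <- array(0, grid@dims)
  arr[idx] <- 1
  brainMask(arr, grid)
}

fcVec <- function(values, lesionCols = integer(0), patientId = "p",
                  subjectId = "s") {
  values[lesionCols] <- 0
  new("FCVector", patientId = patientId, subjectId = subjectId,
      values = values, lesionCols = as.integer(lesionCols),
      nValid = length(values) - length(lesionCols))
}

.fixtureCache <- new.env(parent = emptyenv())

# small full cohort for pipeline-level unit tests (not the acceptance
# scale): 12^3 grid, 2 networks, 4 HC scans, 8 patients
smallCohort <- function() {
  if (is.null(.fixtureCache$small)) {
    .fixtureCache$small <- simulateCohort(
      seed = 42, gridDims = c(14L, 14L, 14L), k = 2L, radius = 1.5,
      nHc = 4L, nTimepoints = 60L, nPatients = 8L,
      sizeRange = c(10L, 40L))
  }
  .fixtureCache$small
}

smallRun <- function() {
  if (is.null(.fixtureCache$smallRun)) {
    co <- smallCohort()
    .fixtureCache$smallRun <- runICLM(
      co@lesions, co@hcFmris, referencesFromGroundTruth(co@groundTruth),
      co@behavior, config = defaultRunConfig(seed = 42, nRuns = 4,
                                globalSignal = FALSE),
      keepPerSubject = TRUE)
  }
  .fixtureCache$smallRun
}
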