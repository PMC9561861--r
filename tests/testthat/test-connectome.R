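test_that("preprocessing removes the mean and passes the stated band", {
  dims <- c(2, 2, 2)
  tr <- 2; nt <- 100
  t_s <- (0:(nt - 1)) * tr
  const <- fmriFromMatrix(matrix(5, nt, 8), dims, tr = tr)
  expect_equal(max(abs(preprocessFmri(const)@series)), 0)

  # DFT oracle: amplitude at the probe frequency before vs after
  dftAmp <- function(x, f, tr) {
    n <- length(x); k <- round(f * n * tr)
    Mod(fft(x))[k + 1] * 2 / n
  }
  inBand <- sin(2 * pi * 0.04 * t_s)     # 0.04 Hz, inside 0.01-0.08
  outBand <- sin(2 * pi * 0.2 * t_s)     # 0.2 Hz, outside
  f <- fmriFromMatrix(cbind(inBand, outBand,
                            matrix(rnorm(nt * 6), nt)), dims, tr = tr)
  g <- preprocessFmri(f)
  Y <- t(array(g@series, c(8, nt)))
  expect_equal(dftAmp(Y[, 1], 0.04, tr), dftAmp(inBand, 0.04, tr),
               tolerance = 0.05)
  expect_lt(dftAmp(Y[, 2], 0.2, tr), 0.1 * dftAmp(outBand, 0.2, tr))
})

test_that("confound regression is exact and rank checked", {
  dims <- c(2, 2, 2); nt <- 80
  conf <- cbind(drift = seq_len(nt), motion = rnorm(nt))
  # voxel = pure confound combination + nothing in band
  ts <- matrix(conf %*% c(0.3, -2), nt, 8)
  f <- fmriFromMatrix(ts, dims)
  out <- preprocessFmri(f, confounds = conf)
  expect_lt(max(abs(out@series)), 1e-8)
  expect_error(preprocessFmri(f, confounds = cbind(conf, drift2 = conf[, 1])),
               "collinear")
  expect_error(preprocessFmri(f, confounds = conf[1:10, ]), "rows")
  expect_error(preprocessFmri(f, band = c(0.01, 0.3)), "Nyquist")
})

test_that("seed FC matches the clamped Fisher-Z closed form", {
  dims <- c(3, 1, 1); nt <- 50
  set.seed(1)
  seedSeries <- rnorm(nt)
  resid <- residuals(lm(rnorm(nt) ~ seedSeries))  # exactly orthogonal
  ts <- cbind(seedSeries, seedSeries, resid)
  f <- fmriFromMatrix(ts, dims)
  brain <- maskFromIdx(1:3, volumeGrid(dims))
  lesion <- maskFromIdx(1, volumeGrid(dims))
  v <- seedFC(f, lesion, brain)
  # duplicated series: r clamps to 1 - 1e-7
  expect_equal(v@values[2], 0.5 * log((2 - 1e-7) / 1e-7), tolerance = 1e-9)
  expect_equal(v@values[3], 0, tolerance = 1e-10)  # arctanh(0) = 0
  expect_identical(v@values[1], 0)                 # lesion voxel zeroed
  expect_equal(v@nValid, 2L)
  # antisymmetry under sign flip of the target series
  f2 <- fmriFromMatrix(cbind(seedSeries, -seedSeries, resid), dims)
  v2 <- seedFC(f2, lesion, brain)
  expect_equal(v2@values[2], -v@values[2])
  # empty seed errors
  expect_error(seedFC(f, maskFromIdx(1, volumeGrid(dims)),
                      maskFromIdx(2:3, volumeGrid(dims))),
               "does not intersect")
})

test_that("averaging is two-stage: within subject then across subjects", {
  a1 <- fcVec(c(1, 7), patientId = "p1", subjectId = "A")
  a2 <- fcVec(c(3, 7), patientId = "p1", subjectId = "A")
  b1 <- fcVec(c(5, 7), patientId = "p1", subjectId = "B")
  avg <- averageFC(list(a1, a2, b1))
  expect_equal(avg@values[1], 3.5)  # (mean(1,3) + 5) / 2
  expect_equal(averageFC(list(a1))@values, a1@values)
  # symmetric pair cancels
  expect_equal(averageFC(list(fcVec(c(2, -1), subjectId = "A"),
                              fcVec(c(-2, 1), subjectId = "B")))@values,
               c(0, 0))
  # permutation invariance in subjects
  expect_equal(averageFC(list(b1, a2, a1))@values, avg@values)
  expect_error(averageFC(list(a1, fcVec(c(1, 0), lesionCols = 2L))),
               "zero-pattern")
})

test_that("FC matrix assembly standardizes rows and keeps lesion zeros", {
  grid <- volumeGrid(c(5, 1, 1))
  brain <- maskFromIdx(1:5, grid)
  v1 <- fcVec(c(1, 2, 3, 4, 5), patientId = "p1")
  v2 <- fcVec(c(2, 1, 0, 5, 3), lesionCols = 3L, patientId = "p2")
  fc <- assembleFCMatrix(list(p1 = v1, p2 = v2), grid, brain)
  expect_equal(mean(fc@values[1, ]), 0, tolerance = 1e-12)
  expect_equal(var(fc@values[1, ]), 1, tolerance = 1e-12)
  expect_identical(unname(fc@values[2, 3]), 0)  # zero-fill survives
  valid <- c(1, 2, 4, 5)
  expect_equal(mean(fc@values[2, valid]), 0, tolerance = 1e-12)
  expect_equal(var(fc@values[2, valid]), 1, tolerance = 1e-12)

  raw <- assembleFCMatrix(list(p1 = v1, p2 = v2), grid, brain,
                          standardize = FALSE)
  expect_equal(raw@values[1, ], v1@values, ignore_attr = TRUE)

  # idempotence: re-assembling from standardized rows changes nothing
  w1 <- fcVec(fc@values[1, ], patientId = "p1")
  w2 <- fcVec(fc@values[2, ], lesionCols = 3L, patientId = "p2")
  fc2 <- assembleFCMatrix(list(p1 = w1, p2 = w2), grid, brain)
  expect_equal(fc2@values, fc@values, tolerance = 1e-12)

  flatRow <- fcVec(rep(2, 5), patientId = "p2")
  expect_error(assembleFCMatrix(list(p1 = v1, p2 = flatRow), grid, brain),
               "p2")
})

test_that("global z-scoring scope standardizes the pooled matrix once", {
  grid <- volumeGrid(c(4, 1, 1))
  brain <- maskFromIdx(1:4, grid)
  v1 <- fcVec(c(1, 2, 3, 4), patientId = "p1")
  v2 <- fcVec(c(10, 0, 20, 5), lesionCols = 2L, patientId = "p2")
  fc <- assembleFCMatrix(list(p1 = v1, p2 = v2), grid, brain,
                         zscoreScope = "global")
  pooled <- c(fc@values[1, ], fc@values[2, c(1, 3, 4)])
  expect_equal(mean(pooled), 0, tolerance = 1e-12)
  expect_equal(sd(pooled), 1, tolerance = 1e-12)
  expect_identical(unname(fc@values[2, 2]), 0)
})

test_that("noiseless lesion seeding peaks inside the damaged network", {
  grid <- volumeGrid(c(16, 16, 16))
  gt <- makeNetworks(grid, k = 2, seed = 8)
  fs <- simulateFmri(gt, 3, 80, snr = Inf, seed = 8)
  brain <- computeBrainMask(fs)
  supp1 <- which(gt@networks[[1]]@data > 0)
  les <- maskFromIdx(supp1[seq_len(5)], grid)
  avg <- averageFC(lapply(fs, seedFC, lesion = les, brain = brain))
  # oracle: noiseless FC is maximal where only the damaged network lives
  best <- voxelIndex(brain)[which.max(avg@values)]
  expect_true(best %in% supp1)
  expect_equal(max(avg@values), 0.5 * log((2 - 1e-7) / 1e-7),
               tolerance = 1e-6)
})
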