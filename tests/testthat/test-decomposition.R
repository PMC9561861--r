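# independent oracle: perpendicular distance of each curve point to the
# chord joining the zero-component origin (0, 0) and the last point
kneeOracle <- function(cv) {
  n <- length(cv)
  d <- vapply(seq_len(n), function(i) {
    abs(cv[n] * i - n * cv[i]) / sqrt(cv[n]^2 + n^2)
  }, numeric(1))
  which.max(d)
}

test_that("knee point maximizes distance to the chord from the origin", {
  expect_identical(kneePoint(c(0.50, 0.80, 0.95, 0.99, 1.00)),
                   kneeOracle(c(0.50, 0.80, 0.95, 0.99, 1.00)))
  expect_identical(kneePoint(c(0.10, 0.90, 0.95, 1.00)), 2L)
  expect_identical(kneeOracle(c(0.10, 0.90, 0.95, 1.00)), 2L)
  # linear curve: every point on the chord, tie broken to index 1
  expect_identical(kneePoint(c(0.2, 0.4, 0.6, 0.8, 1.0)), 1L)
  expect_warning(flat <- kneePoint(c(0.5, 0.5, 0.5)), "flat")
  expect_identical(flat, 1L)
  # property: agrees with the oracle on random concave curves
  set.seed(20)
  for (i in 1:25) {
    cv <- cumsum(sort(runif(sample(3:12, 1)), decreasing = TRUE))
    cv <- cv / max(cv)
    expect_identical(kneePoint(cv), kneeOracle(cv))
  }
})

fcFromMatrix <- function(X) {
  grid <- volumeGrid(c(ncol(X), 1, 1))
  brain <- maskFromIdx(seq_len(ncol(X)), grid)
  vs <- lapply(seq_len(nrow(X)), function(i)
    fcVec(X[i, ], patientId = paste0("p", i)))
  names(vs) <- paste0("p", seq_len(nrow(X)))
  assembleFCMatrix(vs, grid, brain, standardize = FALSE)
}

test_that("PCA reduction whitens the signal subspace and reports rank", {
  set.seed(4)
  X <- matrix(rnorm(4 * 2), 4, 2) %*% matrix(rnorm(2 * 200), 2, 200)
  fc <- fcFromMatrix(X)
  p <- pcaReduce(fc, q = 2)
  expect_equal(p@cumVar[2], 1, tolerance = 1e-12)   # exact rank 2
  expect_lt(p@cumVar[1], 1)
  # whitened rows: uncorrelated, unit variance (population convention)
  expect_equal(tcrossprod(p@whitened) / ncol(X), diag(2),
               tolerance = 1e-10)
  # reconstruction through dewhitening recovers the rank-2 input
  expect_equal(p@dewhiten %*% p@whitened, X, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcaReduce(fc, q = 3), "rank")

  ident <- fcFromMatrix(matrix(rep(rnorm(50), 3), 3, byrow = TRUE))
  p1 <- pcaReduce(ident, q = 1)
  expect_equal(p1@cumVar[1], 1, tolerance = 1e-12)
})

test_that("Infomax separates a planted Laplacian mixture", {
  set.seed(12)
  n <- 5000
  S <- matrix(sample(c(-1, 1), 2 * n, TRUE) * rexp(2 * n), 2, n)
  A <- matrix(c(1.2, -0.4, 0.7, 1.5), 2, 2)
  X <- A %*% S
  sv <- svd(X)
  K <- diag(1 / sv$d) %*% t(sv$u)
  Xw <- sqrt(n) * (K %*% X)
  run <- infomaxICA(Xw, seed = 3)
  expect_true(run@converged)
  # recovered sources match truth up to permutation/sign
  cors <- abs(cor(t(run@sources), t(S)))
  expect_gte(max(cors[1, ]), 0.99)
  expect_gte(max(cors[2, ]), 0.99)
  # Amari-index oracle on the global gain matrix
  expect_lt(amariISI(run@demixing %*% (sqrt(n) * K %*% A)), 0.05)
  # exact mixing/demixing inverse pair and subspace reconstruction
  expect_equal(run@demixing %*% run@mixing, diag(2), tolerance = 1e-8)
  expect_lt(norm(run@mixing %*% run@sources - Xw, "F") / norm(Xw, "F"),
            1e-6)
  # determinism
  run2 <- infomaxICA(Xw, seed = 3)
  expect_identical(run2@demixing, run@demixing)
})

test_that("Amari ISI is zero exactly on scaled permutations", {
  expect_equal(amariISI(diag(4)), 0)
  P <- diag(4)[c(3, 1, 4, 2), ] %*% diag(c(2, -0.5, 1, 10))
  expect_equal(amariISI(P), 0)
  expect_equal(amariISI(matrix(1, 2, 2)), 1)  # hand evaluation
  set.seed(5)
  g <- matrix(rnorm(16), 4)
  expect_gt(amariISI(g), 0)
  # invariance under permutation, sign flips and global rescaling
  expect_equal(amariISI(3 * diag(c(-1, 1, 1, -1)) %*% g[c(2, 1, 3, 4), ]),
               amariISI(g), tolerance = 1e-12)
  expect_error(amariISI(rbind(c(0, 0), c(1, 2))), "all-zero")
})

icaRunFromW <- function(W, converged = TRUE) {
  X <- diag(nrow(W))  # sources unused by selection
  new("ICARun", demixing = W, mixing = solve(W), sources = W %*% X,
      seed = 1L, converged = converged, nIter = 1L)
}

test_that("cross-ISI selection favors consistent runs", {
  set.seed(6)
  W <- matrix(rnorm(9), 3)
  # three runs identical up to permutation and sign
  runs <- list(icaRunFromW(W),
               icaRunFromW(diag(c(-1, 1, 1)) %*% W[c(2, 1, 3), ]),
               icaRunFromW(diag(c(1, -1, -1)) %*% W[c(3, 2, 1), ]))
  sel <- crossISISelect(runs)
  expect_lt(max(sel$crossISI), 1e-10)
  expect_identical(sel$index, 1L)  # tie -> smallest index
  expect_equal(sel$crossISI, t(sel$crossISI))
  expect_equal(diag(sel$crossISI), rep(0, 3))

  # a corrupted run is never selected
  for (s in 1:5) {
    set.seed(s)
    bad <- icaRunFromW(matrix(rnorm(9), 3))
    sel2 <- crossISISelect(list(runs[[1]], runs[[2]], bad))
    expect_true(sel2$index %in% 1:2)
  }
  # non-converged runs stay in the matrix but are not candidates
  nc <- icaRunFromW(W, converged = FALSE)
  sel3 <- crossISISelect(list(nc, runs[[2]], runs[[3]]))
  expect_true(sel3$index %in% 2:3)
  expect_error(crossISISelect(list(runs[[1]])), "2 converged")
})

test_that("source maps are z-scored and skew-oriented", {
  set.seed(9)
  s <- rexp(500) - 0.3          # positively skewed
  z <- (s - mean(s)) / sd(s)
  out <- zscoreOrient(rbind(z, -z))
  expect_equal(out$sources[1, ], z, ignore_attr = TRUE)  # idempotent
  expect_equal(out$sources[2, ], z, ignore_attr = TRUE)  # sign-invariant
  expect_equal(out$flips, c(1, -1))
  expect_lt(abs(mean(out$sources[1, ])), 1e-10)
  expect_lt(abs(var(out$sources[1, ]) - 1), 1e-8)
  mix <- diag(2)
  expect_equal(zscoreOrient(rbind(z, -z), mix)$mixing,
               diag(c(1, -1)))
  expect_error(zscoreOrient(rbind(rep(2, 10))), "zero-variance")
})

test_that("thresholded maps follow Gaussian tails and nest", {
  grid <- volumeGrid(c(18, 18, 18))
  set.seed(14)
  z <- array(rnorm(prod(grid@dims)), grid@dims)
  nm <- thresholdMap(brainVolume(z, grid), 1)
  frac <- nVoxels(nm@positiveMask) / prod(grid@dims)
  expect_equal(frac, pnorm(-1), tolerance = 0.1)  # Gaussian tail oracle
  expect_length(intersect(voxelIndex(nm@positiveMask),
                          voxelIndex(nm@negativeMask)), 0)
  hi <- thresholdMap(brainVolume(z, grid), max(abs(z)) + 1)
  expect_equal(nVoxels(hi@positiveMask) + nVoxels(hi@negativeMask), 0)
  nm15 <- thresholdMap(brainVolume(z, grid), 1.5)
  expect_true(all(voxelIndex(nm15@positiveMask) %in%
                  voxelIndex(nm@positiveMask)))
})

test_that("full decomposition is reproducible and reconstructs", {
  res <- smallRun()
  d <- res$decomposition
  expect_true(all(vapply(seq_len(nComponents(d)), function(i) {
    s <- d@sources[i, ]
    abs(mean(s)) < 1e-10 && abs(var(s) - 1) < 1e-8
  }, logical(1))))
  best <- d@runs[[d@selectedRun]]
  expect_lt(norm(best@mixing %*% best@sources -
                 pcaReduce(res$fcMatrix)@whitened, "F") /
            norm(best@sources, "F"), 1e-6)
  d2 <- runDecomposition(res$fcMatrix, res$brain, seed = 42, nRuns = 4)
  expect_identical(d2@sources, d@sources)
  expect_identical(d2@selectedRun, d@selectedRun)
})
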