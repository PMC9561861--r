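test_that("overlap summary matches exhaustive enumeration", {
  grid <- volumeGrid(c(8, 1, 1))
  A <- maskFromIdx(1:2, grid); B <- maskFromIdx(2:3, grid)
  C <- maskFromIdx(2, grid)
  ov <- overlapSummary(lesionCohort(list(a = A, b = B, c = C)))
  # ever-lesioned voxels {1,2,3}; only v2 (count 3) is shared by >= 2
  expect_equal(ov$curve$proportion, c(1, 1 / 3, 1 / 3))
  # pairwise |int|/min: AB 1/2, AC 1, BC 1 -> mean 5/6
  expect_equal(sort(ov$pairwise), c(0.5, 1, 1))
  expect_equal(ov$pairwiseMean, 5 / 6)
  expect_equal(as.vector(ov$overlapMap@data)[1:4], c(1, 3, 1, 0))

  same <- overlapSummary(lesionCohort(list(a = A, b = A, c = A)))
  expect_equal(same$curve$proportion, c(1, 1, 1))
  expect_equal(same$pairwiseMean, 1)
  dis <- overlapSummary(lesionCohort(list(a = A, b = maskFromIdx(5:6,
                                                                 grid))))
  expect_equal(dis$curve$proportion, c(1, 0))
  expect_equal(dis$pairwiseMean, 0)
  # curve is nonincreasing; counts conserve total lesion volume
  expect_false(is.unsorted(rev(ov$curve$proportion)))
  expect_equal(sum(ov$overlapMap@data), 2 + 2 + 1)
  # alternative denominators stay in [0,1]
  expect_equal(overlapSummary(lesionCohort(list(a = A, b = B)),
                              pairwise = "dice")$pairwiseMean, 0.5)
  expect_equal(overlapSummary(lesionCohort(list(a = A, b = B)),
                              pairwise = "union")$pairwiseMean, 1 / 3)
})

test_that("VLSM reproduces the pooled-variance t and BH decisions", {
  grid <- volumeGrid(c(6, 1, 1))
  # voxel 2 lesioned in patients 1,2; voxel 3 in patients 1,2,3;
  # voxels 1 and 6 in a single patient (eligible at 25% of n=4, but the
  # lesioned group of one patient is dropped)
  coh <- lesionCohort(list(
    p1 = maskFromIdx(c(1, 2, 3), grid), p2 = maskFromIdx(c(2, 3), grid),
    p3 = maskFromIdx(3, grid),          p4 = maskFromIdx(6, grid)))
  aq <- c(10, 12, 20, 22)
  res <- vlsm(coh, aq, minFrac = 0.25, maxFrac = 0.75, alpha = 0.05)
  expect_identical(res$eligible, c(1L, 2L, 3L, 6L))
  # voxel 2: lesioned {10,12} vs not {20,22}; pooled t = -7.071..., df 2
  i2 <- which(res$eligible == 2L)
  expect_equal(res$t[i2], -10 / sqrt(2), tolerance = 1e-10)
  expect_equal(res$p[i2], 2 * pt(-abs(-10 / sqrt(2)), df = 2),
               tolerance = 1e-10)
  # voxels leaving a group of one patient -> dropped with NA statistics
  expect_identical(res$dropped, c(1L, 3L, 6L))
  expect_true(all(is.na(res$t[res$eligible %in% c(1L, 3L, 6L)])))

  # brute-force oracle over a random toy cohort
  set.seed(21)
  g2 <- volumeGrid(c(20, 1, 1))
  les <- lapply(1:10, function(i)
    maskFromIdx(sample(20, sample(3:9, 1)), g2))
  names(les) <- paste0("p", 1:10)
  beh <- rnorm(10, 50, 10)
  co2 <- lesionCohort(les)
  r2 <- vlsm(co2, beh, alpha = 0.1)
  lesMat <- vapply(les, function(m) as.vector(m@data), numeric(20))
  for (i in seq_along(r2$eligible)) {
    v <- r2$eligible[i]
    grp <- lesMat[v, ] > 0
    if (sum(grp) < 2 || sum(!grp) < 2) next
    m1 <- mean(beh[grp]); m2 <- mean(beh[!grp])
    n1 <- sum(grp); n2 <- sum(!grp)
    sp2 <- ((n1 - 1) * var(beh[grp]) + (n2 - 1) * var(beh[!grp])) /
      (n1 + n2 - 2)
    tOracle <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    expect_equal(r2$t[i], tOracle, tolerance = 1e-10)
  }
  # BH oracle: largest k with p_(k) <= k/m * alpha
  ps <- r2$p[!is.na(r2$p)]
  m <- length(ps); srt <- sort(ps)
  k <- max(c(0, which(srt <= seq_len(m) / m * 0.1)))
  rejOracle <- if (k == 0) numeric(0) else ps[ps <= srt[k]]
  expect_equal(sum(r2$pAdj < 0.1, na.rm = TRUE), length(rejOracle))
})

test_that("BH on the canonical p-vector rejects the first three", {
  p <- c(0.001, 0.01, 0.02, 0.9)
  m <- length(p); srt <- sort(p)
  k <- max(c(0, which(srt <= seq_len(m) / m * 0.05)))
  expect_equal(k, 3)                            # brute-force BH
  expect_identical(sum(p.adjust(p, "BH") < 0.05), 3L)
})

test_that("LNM per-patient maps use the one-sample t with Bonferroni", {
  grid <- volumeGrid(c(4, 1, 1))
  brain <- maskFromIdx(1:4, grid)
  mk <- function(vals, subj) fcVec(vals, lesionCols = 4L, patientId = "p",
                                   subjectId = subj)
  vals <- c(0.5, 0.5, 0.5, 0.5, 0.6)
  vecs <- lapply(1:5, function(s)
    mk(c(vals[s], -vals[s], 0, 0), paste0("s", s)))
  res <- lnmPatientMap(vecs, brain, alphaCorrected = 0.05)
  # closed form: mean .52, sd sqrt(0.002), n 5 -> t = 26
  expect_equal(res$t[1], 26, tolerance = 1e-10)
  expect_equal(res$t[2], -26, tolerance = 1e-10)
  expect_identical(res$excluded, 3L)        # zero-variance voxel
  expect_identical(res$nTested, 2L)
  p <- 2 * pt(-26, df = 4) * 2              # Bonferroni over 2 voxels
  expect_identical(voxelIndex(res$positiveMask),
                   if (p < 0.05) 1L else integer(0))
  # a threshold so strict nothing passes
  strict <- lnmPatientMap(vecs, brain, alphaCorrected = 1e-12)
  expect_length(voxelIndex(strict$positiveMask), 0)
})

test_that("LNM overlay thresholds follow ceiling arithmetic", {
  grid <- volumeGrid(c(3, 1, 1))
  masks <- c(lapply(1:7, function(i) maskFromIdx(1, grid)),
             lapply(1:3, function(i) maskFromIdx(2, grid)))
  ov <- lnmOverlay(masks, fractions = c(0.7, 0.8, 1.0))
  expect_equal(as.vector(ov$overlay@data), c(7, 3, 0))
  expect_identical(voxelIndex(ov$commonMaps[["70%"]]), 1L)  # 7 >= ceil(7)
  expect_length(voxelIndex(ov$commonMaps[["80%"]]), 0)      # 7 < ceil(8)
  expect_length(voxelIndex(ov$commonMaps[["100%"]]), 0)     # intersection
  ten <- lapply(1:10, function(i) maskFromIdx(c(1, 3), grid))
  ov2 <- lnmOverlay(ten, fractions = 0.9)
  expect_identical(voxelIndex(ov2$commonMaps[[1]]), c(1L, 3L))
})
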