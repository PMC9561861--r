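# PCA signal-subspace reduction with knee-point order selection,
# multi-restart natural-gradient Infomax ICA, cross-ISI run selection, and
# conversion of sources to thresholded z-maps.

#' Knee point of a cumulative explained-variance curve
#'
#' Maximum perpendicular distance to the chord, with the curve anchored at
#' the zero-component origin (0 components explain 0 variance): points
#' (0, 0), (1, y1), ..., (n, yn), chord from (0, 0) to (n, yn). Returns
#' the 1-based index of the curve point farthest from the chord; ties go
#' to the smallest index. A flat curve (all values equal) returns 1 with a
#' warning.
#'
#' @param cumvar nondecreasing numeric vector in (0, 1], length >= 3.
#' @return integer order
#' @export
kneePoint <- function(cumvar) {
  n <- length(cumvar)
  stopifnot(n >= 3, !is.unsorted(cumvar), all(cumvar >= 0 & cumvar <= 1))
  if (max(cumvar) == min(cumvar)) {
    warning("flat cumulative variance curve; returning order 1")
    return(1L)
  }
  # distance to chord (0,0)-(n, yn); denominator constant, compare numerators
  dist <- abs(cumvar[n] * seq_len(n) - n * cumvar)
  which.max(dist)
}

#' PCA reduction of the FC matrix to a signal subspace
#'
#' SVD of the (row-standardized) patients x voxels matrix; no additional
#' centring is applied (rows are already centred across voxels).
#' Cumulative explained variance comes from the squared singular values;
#' when `q` is absent the order is chosen by [kneePoint()] (floored at 2,
#' the smallest subspace ICA can rotate). The whitened q x voxels subspace
#' has uncorrelated unit-variance rows.
#'
#' @param fc an [FCMatrix-class] (>= 3 patients).
#' @param q optional order, <= patients - 1.
#' @return a [PCAResult-class]
#' @export
pcaReduce <- function(fc, q = NULL) {
  X <- fc@values
  M <- nrow(X); V <- ncol(X)
  stopifnot(M >= 3)
  sv <- svd(X)
  ev <- sv$d^2
  cumVar <- cumsum(ev) / sum(ev)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (is.null(q)) {
    q <- max(2L, kneePoint(pmin(cumVar, 1)))
  } else {
    stopifnot(q >= 1, q <= M - 1)
    q <- as.integer(q)
  }
  if (q > rank)
    stop(sprintf("requested order %d exceeds achievable rank %d", q, rank))
  d <- sv$d[seq_len(q)]
  whitened <- sqrt(V) * t(sv$v[, seq_len(q), drop = FALSE])
  dewhiten <- sv$u[, seq_len(q), drop = FALSE] %*% diag(d / sqrt(V),
                                                        q, q)
  new("PCAResult", basis = sv$u[, seq_len(q), drop = FALSE],
      singularValues = sv$d, whitened = whitened, dewhiten = dewhiten,
      cumVar = pmin(cumVar, 1), q = q)
}

#' Natural-gradient Infomax ICA (one restart)
#'
#' Bell-Sejnowski Infomax with the logistic nonlinearity
#' g(u) = 1/(1 + exp(-u)) and the natural-gradient update
#' dW = lrate * (I + (1 - 2 g(Y)) Y'/B) W over randomized mini-batches.
#' The learning rate anneals by 0.9 whenever the per-pass update
#' direction swings by more than 60 degrees (the update jitter near a
#' fixed point), and is halved with the pass restarted from the last
#' good weights whenever the update blows up. Convergence is declared
#' when the Frobenius norm of the per-pass weight change drops below
#' `tol`. Deterministic given `seed`.
#'
#' @param whitened q x V whitened matrix (rows uncorrelated, unit
#'   variance), V > q >= 2.
#' @param seed integer RNG seed (initial weights + batch order).
#' @param lrate initial learning rate; default 0.01/ln(q e).
#' @param maxIter maximum full passes (default 2048).
#' @param tol Frobenius weight-change tolerance (default 1e-6).
#' @param batchSize mini-batch size, default min(V, 256).
#' @return an [ICARun-class]
#' @export
infomaxICA <- function(whitened, seed, lrate = NULL, maxIter = 2048L,
                       tol = 1e-6, batchSize = NULL) {
  q <- nrow(whitened); V <- ncol(whitened)
  stopifnot(q >= 2, V > q)
  if (is.null(lrate)) lrate <- 0.01 / log(q * exp(1))
  if (is.null(batchSize)) batchSize <- min(V, 256L)
  set.seed(as.integer(seed))
  W <- qr.Q(qr(matrix(stats::rnorm(q * q), q, q)))
  I <- diag(q)
  converged <- FALSE
  iter <- 0L
  prevDelta <- NULL
  while (iter < maxIter) {
    iter <- iter + 1L
    Wprev <- W
    perm <- sample.int(V)
    ok <- TRUE
    for (start in seq(1L, V, by = batchSize)) {
      cols <- perm[start:min(start + batchSize - 1L, V)]
      Y <- W %*% whitened[, cols, drop = FALSE]
      G <- 1 / (1 + exp(-Y))
      W <- W + lrate * (I + ((1 - 2 * G) %*% t(Y)) / length(cols)) %*% W
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) { ok <- FALSE; break }
    }
    if (!ok) {
      lrate <- lrate * 0.5
      W <- Wprev
      prevDelta <- NULL
      next
    }
    delta <- as.vector(W - Wprev)
    nd <- sqrt(sum(delta^2))
    if (nd < tol) { converged <- TRUE; break }
    if (!is.null(prevDelta)) {
      cosang <- sum(delta * prevDelta) /
        (nd * sqrt(sum(prevDelta^2)))
      if (is.finite(cosang) && cosang < 0.5) lrate <- lrate * 0.9
    }
    prevDelta <- delta
  }
  new("ICARun", demixing = W, mixing = solve(W),
      sources = W %*% whitened, seed = as.integer(seed),
      converged = converged, nIter = iter)
}

#' Amari inter-symbol interference of a gain matrix
#'
#' For g = W1 %*% solve(W2) (or W %*% A_true), measures how far g is from
#' a scaled permutation:
#' ISI = (1/(2q(q-1))) * (sum_i(sum_j |g_ij| / max_k |g_ik| - 1) +
#' sum_j(sum_i |g_ij| / max_k |g_kj| - 1)). Lies in 0..1 and is 0 iff g
#' is a permutation times a nonzero diagonal.
#'
#' @param g square numeric matrix, no all-zero row or column.
#' @return real in 0..1
#' @export
amariISI <- function(g) {
  stopifnot(nrow(g) == ncol(g))
  a <- abs(g)
  q <- nrow(a)
  rowMax <- apply(a, 1, max)
  colMax <- apply(a, 2, max)
  if (any(rowMax == 0) || any(colMax == 0))
    stop("gain matrix has an all-zero row or column")
  (sum(rowSums(a / rowMax) - 1) + sum(colSums(t(t(a) / colMax)) - 1)) /
    (2 * q * (q - 1))
}

#' Select the most consistent of several ICA restarts
#'
#' Pairwise score(i, j) = amariISI(W_i %*% solve(W_j)); the selected run
#' minimizes the mean score against all other converged runs (ties to the
#' smallest index). Non-converged runs stay in the matrix but are never
#' candidates.
#'
#' @param runs list of [ICARun-class] (>= 2 converged).
#' @return list(index = integer, crossISI = symmetric matrix)
#' @export
crossISISelect <- function(runs) {
  n <- length(runs)
  conv <- which(vapply(runs, function(r) r@converged, logical(1)))
  if (length(conv) < 2L)
    stop("need >= 2 converged runs for cross-ISI selection, have ",
         length(conv))
  ci <- matrix(0, n, n)
  inv <- lapply(runs, function(r) r@mixing)  # solve(W) cached at run time
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      s <- (amariISI(runs[[i]]@demixing %*% inv[[j]]) +
            amariISI(runs[[j]]@demixing %*% inv[[i]])) / 2
      ci[i, j] <- s; ci[j, i] <- s
    }
  }
  means <- vapply(conv, function(i) mean(ci[i, setdiff(conv, i)]),
                  numeric(1))
  list(index = conv[which.min(means)], crossISI = ci)
}

#' Z-score and sign-orient source maps
#'
#' Each source row is standardized to mean 0, unit sample variance over
#' brain voxels, then sign-oriented so its skewness is positive (the
#' network side of a super-Gaussian spatial map is the heavy positive
#' tail); the matching mixing columns are flipped consistently.
#'
#' @param sources q x V source matrix.
#' @param mixing optional matrix whose columns correspond to sources.
#' @return list(sources = z-scored oriented matrix, mixing = flipped
#'   mixing or NULL, flips = +/-1 per component)
#' @export
zscoreOrient <- function(sources, mixing = NULL) {
  q <- nrow(sources)
  flips <- numeric(q)
  for (i in seq_len(q)) {
    s <- sources[i, ]
    sdev <- stats::sd(s)
    if (!is.finite(sdev) || sdev == 0)
      stop("zero-variance source ", i)
    z <- (s - mean(s)) / sdev
    flips[i] <- if (mean(z^3) < 0) -1 else 1
    sources[i, ] <- flips[i] * z
  }
  if (!is.null(mixing)) mixing <- sweep(mixing, 2, flips, `*`)
  list(sources = sources, mixing = mixing, flips = flips)
}

#' Threshold a z-map into a network map
#'
#' @param zmap a [BrainVolume-class] of z values (0 outside brain).
#' @param z positive threshold (default 1: the |Z| > 1 network
#'   definition).
#' @param label map name.
#' @return a [NetworkMap-class]
#' @export
thresholdMap <- function(zmap, z = 1, label = "component") {
  stopifnot(z > 0)
  new("NetworkMap", zmap = zmap, threshold = z,
      positiveMask = brainMask(zmap@data > z, zmap@grid),
      negativeMask = brainMask(zmap@data < -z, zmap@grid),
      label = label)
}

#' Multi-restart ICA decomposition of the FC matrix
#'
#' [pcaReduce()] to the signal subspace (knee-point order unless `q`
#' given), `nRuns` Infomax restarts with run seeds seed + 1..nRuns,
#' cross-ISI selection of the most consistent run, then z-scoring and
#' skew orientation of its sources. Patient loadings are mapped back
#' through the PCA dewhitening matrix.
#'
#' @param fc an [FCMatrix-class].
#' @param brain the [BrainMask-class] whose index orders the columns.
#' @param seed master seed.
#' @param nRuns number of restarts (default 30).
#' @param q optional subspace order override.
#' @param ... passed to [infomaxICA()].
#' @return a [Decomposition-class]
#' @export
runDecomposition <- function(fc, brain, seed = 1L, nRuns = 30L, q = NULL,
                             ...) {
  pca <- pcaReduce(fc, q)
  runs <- lapply(seq_len(nRuns), function(i)
    infomaxICA(pca@whitened, seed = deriveSeed(seed, i),
               ...))
  sel <- crossISISelect(runs)
  best <- runs[[sel$index]]
  zo <- zscoreOrient(best@sources, best@mixing)
  patientMixing <- pca@dewhiten %*% zo$mixing
  new("Decomposition", runs = runs, selectedRun = as.integer(sel$index),
      crossISI = sel$crossISI, sources = zo$sources,
      patientMixing = patientMixing, voxelIndex = brain@voxelIdx,
      grid = fc@grid, brainMask = brain)
}

#' Materialize one component as a volume
#'
#' @param decomp a [Decomposition-class].
#' @param i component index.
#' @return a [BrainVolume-class]: the z-map over brain voxels, 0 elsewhere
#' @export
componentVolume <- function(decomp, i) {
  arr <- array(0, decomp@grid@dims)
  arr[decomp@voxelIndex] <- decomp@sources[i, ]
  brainVolume(arr, decomp@grid)
}

#' Thresholded network map of one component
#'
#' @param decomp a [Decomposition-class].
#' @param i component index.
#' @param z threshold (default 1).
#' @return a [NetworkMap-class]
#' @export
componentNetworkMap <- function(decomp, i, z = 1) {
  thresholdMap(componentVolume(decomp, i), z, label = sprintf("IC%d", i))
}
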