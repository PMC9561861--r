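# Compare component maps with reference networks (Dice + spatial Pearson)
# and select the symptom-related component.

#' Dice coefficient of two binary masks
#'
#' 2|A cap B| / (|A| + |B|); symmetric, 1 iff the masks are equal and
#' nonempty. Both masks empty is undefined and errors.
#'
#' @param a,b [BrainMask-class] on one grid.
#' @return real in 0..1
#' @export
diceCoefficient <- function(a, b) {
  stopIfGridMismatch(a@grid, b@grid, "masks")
  na <- length(a@voxelIdx); nb <- length(b@voxelIdx)
  if (na + nb == 0L) stop("undefined Dice: both masks empty")
  2 * length(intersect(a@voxelIdx, b@voxelIdx)) / (na + nb)
}

#' Construct a reference network
#'
#' @param map [BrainVolume-class] or [BrainMask-class].
#' @param name label.
#' @param kind "binary" or "continuous"; inferred from the data when
#'   missing.
#' @return a [ReferenceNetwork-class]
#' @export
referenceNetwork <- function(map, name, kind = NULL) {
  if (is(map, "BrainMask")) {
    kind <- kind %||% "binary"
    map <- brainVolume(map@data, map@grid)
  }
  if (is.null(kind))
    kind <- if (all(map@data %in% c(0, 1))) "binary" else "continuous"
  new("ReferenceNetwork", name = name, map = map, kind = kind)
}

# binarize a reference for Dice: binary kinds as-is; continuous kinds
# z-scored over brain then thresholded at refZ (mirrors IC thresholding)
referenceMask <- function(ref, brain, refZ = 1) {
  if (ref@kind == "binary") return(binarize(ref@map, 0))
  v <- ref@map@data[brain@voxelIdx]
  z <- (v - mean(v)) / stats::sd(v)
  arr <- array(0, ref@map@grid@dims)
  arr[brain@voxelIdx] <- as.numeric(z > refZ)
  brainMask(arr, ref@map@grid)
}

#' Spatial correlation between a component and a reference
#'
#' Pearson r over brain voxels between the positive part of the IC z-map
#' (negative z set to 0) and the reference map (binary references as 0/1
#' vectors).
#'
#' @param icZmap [BrainVolume-class] component z-map.
#' @param ref a [ReferenceNetwork-class].
#' @param brain the [BrainMask-class].
#' @return real in -1..1
#' @export
mapCorrelation <- function(icZmap, ref, brain) {
  stopIfGridMismatch(icZmap@grid, ref@map@grid, "component and reference")
  idx <- brain@voxelIdx
  x <- pmax(icZmap@data[idx], 0)
  y <- ref@map@data[idx]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in component positive part or reference")
  stats::cor(x, y)
}

#' Rank components against reference networks and select one
#'
#' For every component and reference, computes the Dice coefficient of
#' the positive mask (threshold `z`) against the binarized reference and
#' the spatial correlation of the positive map against the reference.
#' The selected component has the best (smallest) mean rank across all
#' (criterion, reference) pairs; ties go to the smallest index. The trace
#' records per-criterion winners and whether they were unanimous.
#'
#' @param decomp a [Decomposition-class].
#' @param refs list of [ReferenceNetwork-class].
#' @param z component threshold (default 1).
#' @param refZ threshold for binarizing continuous references (default 1).
#' @return data.frame (ic, reference, dice, r, selected) with attributes
#'   `selectedIC` (integer) and `trace` (character)
#' @export
rankComponents <- function(decomp, refs, z = 1, refZ = 1) {
  stopifnot(length(refs) >= 1, z > 0)
  q <- nComponents(decomp)
  brain <- decomp@brainMask
  rows <- list()
  scores <- list()  # one numeric vector (per IC) per criterion
  for (r in seq_along(refs)) {
    ref <- refs[[r]]
    rmask <- referenceMask(ref, brain, refZ)
    dice <- numeric(q); pear <- numeric(q)
    for (i in seq_len(q)) {
      nm <- componentNetworkMap(decomp, i, z)
      dice[i] <- if (length(nm@positiveMask@voxelIdx) +
                     length(rmask@voxelIdx) == 0L) 0
                 else diceCoefficient(nm@positiveMask, rmask)
      pear[i] <- mapCorrelation(nm@zmap, ref, brain)
    }
    rows[[r]] <- data.frame(ic = seq_len(q), reference = ref@name,
                            dice = dice, r = pear)
    scores[[paste0("dice:", ref@name)]] <- dice
    scores[[paste0("r:", ref@name)]] <- pear
  }
  ranks <- vapply(scores, function(s) rank(-s, ties.method = "min"),
                  numeric(q))
  meanRank <- rowMeans(ranks)
  selected <- which.min(meanRank)  # ties -> smallest index
  winners <- vapply(scores, which.max, integer(1))
  unanimous <- length(unique(winners)) == 1L
  trace <- c(sprintf("criterion %s -> IC%d (%.4f)", names(scores),
                     winners, vapply(scores, max, numeric(1))),
             if (unanimous) sprintf("unanimous winner IC%d", selected)
             else sprintf("criteria disagree (%s); mean-rank winner IC%d",
                          paste(unique(winners), collapse = ","), selected))
  out <- do.call(rbind, rows)
  out$selected <- out$ic == selected
  attr(out, "selectedIC") <- as.integer(selected)
  attr(out, "trace") <- trace
  out
}
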