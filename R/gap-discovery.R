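#' Detect the barcode gap in ranked pairwise distances
#'
#' Implements the barcode-gap principle: within-species distances are small,
#' between-species distances are large, and the empty interval in between is
#' the delimitation threshold. The defined distances are sorted ascending as
#' `d(1..N)` with consecutive gaps `g_i = d(i+1) - d(i)`. The local gap
#' scale at rank `i` is the mean of the up-to-`window` gaps preceding `i`
#' (fewer near the start, at least one, so rank 1 is never a candidate).
#' The detected gap is the first `i` whose gap ends at or above the prior
#' (`d(i+1) >= prior`, so gaps lying entirely below the assumed
#' intraspecific range are never selected) with `g_i > x * scale_i`; the
#' partition threshold is the gap midpoint
#' `(d(i) + d(i+1)) / 2`. When no rank qualifies, `gapIndex` and `threshold`
#' are `NA`.
#'
#' The window-mean local scale and first-qualifying-gap rule are this
#' package's concretisation of the gap-significance criterion; both the
#' window and the relative width `x` are tunable.
#'
#' @param x a [GeneticDistances-class] with at least 3 defined pairs.
#' @param prior maximal prior intraspecific divergence P (>= 0); no gap is
#'   sought below it.
#' @param xRel relative gap width X (> 0): a candidate gap must exceed
#'   `xRel` times the local gap scale.
#' @param window smoothing window (number of preceding gaps averaged);
#'   default `max(10, ceiling(0.01 * N))` for `N` ranked distances.
#' @return a [GapScan-class].
#' @export
detectBarcodeGap <- function(x, prior, xRel = 1.5, window = NULL) {
  stopifnot(prior >= 0, xRel > 0)
  ranked <- sort(pairwiseDistances(x))
  N <- length(ranked)
  if (N < 3L)
    stop(insufficientDataError(sprintf(
      "gap detection needs at least 3 defined pairwise distances, got %d", N)))
  if (is.null(window)) window <- max(10L, as.integer(ceiling(0.01 * N)))
  window <- as.integer(window)

  g <- diff(ranked)
  ## mean of gaps g[max(1, i - window) .. i - 1] for each i = 2..N-1
  cs <- c(0, cumsum(g))
  i <- 2:(N - 1L)
  lo <- pmax(1L, i - window)
  localScale <- (cs[i] - cs[lo]) / (i - lo)
  qualifies <- ranked[i + 1L] >= prior & g[i] > xRel * localScale
  gapIndex <- if (any(qualifies)) i[which(qualifies)[1L]] else NA_integer_
  threshold <- if (is.na(gapIndex)) NA_real_
               else (ranked[gapIndex] + ranked[gapIndex + 1L]) / 2
  new("GapScan", prior = prior, x = xRel, ranked = ranked,
      gapIndex = as.integer(gapIndex), threshold = threshold,
      window = window)
}

insufficientDataError <- function(msg) {
  structure(class = c("barcodegap_insufficient_data", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Single-linkage partition at a distance threshold
#'
#' Groups sequences into the connected components of the graph with an edge
#' between two sequences iff their distance is defined and strictly below
#' the threshold. Undefined (saturated or non-overlapping) pairs contribute
#' no edge. Because thresholds produced by [detectBarcodeGap()] are gap
#' midpoints, no tie can straddle them and the strict inequality is
#' deterministic.
#'
#' @param x a [GeneticDistances-class].
#' @param threshold non-negative distance threshold.
#' @return an [OtuPartition-class] with `kind = "initial"`.
#' @export
partitionAtThreshold <- function(x, threshold) {
  stopifnot(threshold >= 0)
  adj <- x@defined & !is.na(x@d) & x@d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  newOtuPartition(stats::setNames(comp, x@ids), kind = "initial")
}

## canonical partition: groups renumbered by first appearance in id order
newOtuPartition <- function(assignment, kind) {
  lab <- as.integer(factor(assignment, levels = unique(assignment)))
  new("OtuPartition",
      assignment = stats::setNames(lab, names(assignment)), kind = kind)
}

#' @describeIn nOtus distinct groups in the partition.
#' @export
setMethod("nOtus", "OtuPartition", function(x) length(unique(x@assignment)))

#' Group assignment of a partition
#' @param x an [OtuPartition-class].
#' @return named integer vector mapping sequence id to group label.
#' @export
otuAssignment <- function(x) x@assignment

setMethod("show", "OtuPartition", function(object) {
  cat(sprintf("OtuPartition (%s): %d sequences in %d group%s\n",
              object@kind, length(object@assignment), nOtus(object),
              if (nOtus(object) == 1L) "" else "s"))
})

#' Initial barcode-gap partition
#'
#' One pass of [detectBarcodeGap()] followed by [partitionAtThreshold()] at
#' the detected threshold. When no gap qualifies, all sequences form a
#' single group.
#'
#' @inheritParams detectBarcodeGap
#' @return an [OtuPartition-class] with `kind = "initial"`.
#' @export
abgdInitial <- function(x, prior, xRel = 1.5, window = NULL) {
  scan <- detectBarcodeGap(x, prior, xRel, window)
  if (is.na(scan@gapIndex))
    return(newOtuPartition(stats::setNames(rep(1L, length(x@ids)), x@ids),
                           kind = "initial"))
  partitionAtThreshold(x, scan@threshold)
}

#' Recursive barcode-gap partition
#'
#' Starts from [abgdInitial()] and re-applies gap detection plus
#' partitioning inside every group of at least 3 sequences (with the same
#' prior and relative gap width), repeating until no group splits further.
#' Groups smaller than 3 sequences are structurally unsplittable by a gap
#' criterion (fewer than 3 pairwise distances) and are left intact. The
#' result is always a refinement of the initial partition.
#'
#' @inheritParams detectBarcodeGap
#' @return an [OtuPartition-class] with `kind = "recursive"`.
#' @export
abgdRecursive <- function(x, prior, xRel = 1.5, window = NULL) {
  part <- abgdInitial(x, prior, xRel, window)
  groups <- split(names(part@assignment), part@assignment)
  final <- list()
  queue <- groups
  while (length(queue)) {
    ids <- queue[[1L]]
    queue <- queue[-1L]
    sub <- trySplitGroup(x[ids], prior, xRel, window)
    if (is.null(sub)) {
      final[[length(final) + 1L]] <- ids
    } else {
      queue <- c(queue, sub)
    }
  }
  ## preserve the canonical id order of the matrix
  assignment <- integer(length(x@ids))
  names(assignment) <- x@ids
  for (k in seq_along(final)) assignment[final[[k]]] <- k
  newOtuPartition(assignment, kind = "recursive")
}

## returns list of >= 2 id groups when the group splits, NULL otherwise
trySplitGroup <- function(sub, prior, xRel, window) {
  if (length(sub@ids) < 3L) return(NULL)
  scan <- tryCatch(detectBarcodeGap(sub, prior, xRel, window),
                   barcodegap_insufficient_data = function(e) NULL)
  if (is.null(scan) || is.na(scan@gapIndex)) return(NULL)
  part <- partitionAtThreshold(sub, scan@threshold)
  if (nOtus(part) < 2L) return(NULL)
  unname(split(names(part@assignment), part@assignment))
}

#' Sweep of priors: initial and recursive OTU counts
#'
#' Runs gap detection and both partitions over a geometric grid of prior
#' intraspecific divergences,
#' `prior_k = pMin * (pMax / pMin)^(k / (steps - 1))`, `k = 0..steps-1`.
#' The defaults (`pMin = 0.001`, `pMax = 0.12`, `steps = 10`, consecutive
#' ratio about 1.70) span the range conventionally scanned in automatic
#' barcode-gap analyses of ITS data.
#'
#' @inheritParams detectBarcodeGap
#' @param pMin,pMax positive prior range, `pMin < pMax`.
#' @param steps number of grid points (>= 2).
#' @return `data.frame` with columns `prior`, `n_initial`, `n_recursive`.
#' @export
priorSweep <- function(x, pMin = 0.001, pMax = 0.12, steps = 10L,
                       xRel = 1.5, window = NULL) {
  if (!(pMin > 0 && pMin < pMax)) stop("require 0 < pMin < pMax")
  if (steps < 2L) stop("steps must be >= 2")
  priors <- priorGrid(pMin, pMax, steps)
  rows <- lapply(priors, function(p) {
    ini <- abgdInitial(x, p, xRel, window)
    rec <- abgdRecursive(x, p, xRel, window)
    data.frame(prior = p, n_initial = nOtus(ini), n_recursive = nOtus(rec))
  })
  do.call(rbind, rows)
}

#' Geometric prior grid
#' @inheritParams priorSweep
#' @return numeric vector of `steps` geometrically spaced priors.
#' @export
priorGrid <- function(pMin = 0.001, pMax = 0.12, steps = 10L) {
  pMin * (pMax / pMin)^((seq_len(steps) - 1) / (steps - 1))
}
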