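#' Build a pairwise genetic distance matrix from an alignment
#'
#' Fills every off-diagonal entry under pairwise deletion using the selected
#' correction. Pairs with no shared determinate sites, and pairs whose
#' correction saturates, become flagged-undefined entries (`NA` with
#' `defined = FALSE`) rather than errors: a single saturated pair must not
#' abort a whole analysis. The pair counting is vectorised through
#' indicator-matrix products, so a 290-sequence alignment (~42,000 pairs)
#' builds in seconds.
#'
#' @param aln a [BarcodeAlignment-class] with at least 2 sequences.
#' @param model a [DistanceModel-class] or a model name accepted by
#'   [distanceModel()].
#' @return a [GeneticDistances-class].
#' @examples
#' aln <- barcodeAlignment(c(a = "ACGTACGT", b = "ACGAACGT", c = "GCGAATGT"))
#' geneticDistances(aln, "K2P")
#' @export
geneticDistances <- function(aln, model = distanceModel("P")) {
  if (is.character(model)) model <- distanceModel(model)
  validObject(model)
  chars <- aln@chars
  n <- nrow(chars)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- rownames(chars)

  ind <- lapply(DETERMINATE_STATES, function(s) (chars == s) * 1)
  names(ind) <- DETERMINATE_STATES
  V <- ind$A + ind$C + ind$G + ind$T          # determinate indicator
  nValid <- tcrossprod(V)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  nDiff <- nValid - matches

  ok <- nValid > 0
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))

  if (model@model == "P") {
    d[ok] <- nDiff[ok] / nValid[ok]
  } else if (model@model == "K2P") {
    ag <- tcrossprod(ind$A, ind$G); ag <- ag + t(ag)
    ct <- tcrossprod(ind$C, ind$T); ct <- ct + t(ct)
    P <- Q <- matrix(NA_real_, n, n)
    P[ok] <- (ag[ok] + ct[ok]) / nValid[ok]
    Q[ok] <- (nDiff[ok] - ag[ok] - ct[ok]) / nValid[ok]
    d[ok] <- k2pCore(P[ok], Q[ok], model@alpha, model@pInv)
  } else if (model@model == "TN93") {
    ag <- tcrossprod(ind$A, ind$G); ag <- ag + t(ag)
    ct <- tcrossprod(ind$C, ind$T); ct <- ct + t(ct)
    p1 <- p2 <- q <- matrix(NA_real_, n, n)
    p1[ok] <- ag[ok] / nValid[ok]
    p2[ok] <- ct[ok] / nValid[ok]
    q[ok] <- (nDiff[ok] - ag[ok] - ct[ok]) / nValid[ok]
    if (model@freqMode == "global") {
      tot <- vapply(ind, sum, 0)
      gf <- tot / sum(tot)
      pA <- matrix(gf[1L], n, n); pC <- matrix(gf[2L], n, n)
      pG <- matrix(gf[3L], n, n); pT <- matrix(gf[4L], n, n)
    } else {
      pairFreq <- function(Is) {
        cnt <- tcrossprod(Is, V); cnt <- cnt + t(cnt)
        f <- matrix(NA_real_, n, n); f[ok] <- cnt[ok] / (2 * nValid[ok]); f
      }
      pA <- pairFreq(ind$A); pC <- pairFreq(ind$C)
      pG <- pairFreq(ind$G); pT <- pairFreq(ind$T)
    }
    degenerate <- ok & ((pA + pG) <= 0 | (pC + pT) <= 0)
    use <- ok & !degenerate
    d[use] <- tn93Core(p1[use], p2[use], q[use],
                       pA[use], pC[use], pG[use], pT[use],
                       model@alpha, model@pInv)
  } else {                                    # GTR
    cross <- lapply(ind, function(Ix)
      lapply(ind, function(Iy) tcrossprod(Ix, Iy)))
    idx <- which(ok & upper.tri(ok), arr.ind = TRUE)
    f <- matrix(0, 4L, 4L)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      for (x in 1:4) for (y in 1:4) f[x, y] <- cross[[x]][[y]][i, j]
      d[i, j] <- d[j, i] <- gtrCore(f / nValid[i, j],
                                    model@alpha, model@pInv)
    }
  }

  diag(d) <- 0
  defined <- !is.na(d)
  d[!defined] <- NA_real_
  new("GeneticDistances", ids = ids, d = d, defined = defined, model = model)
}

#' Assemble a GeneticDistances object from a plain matrix
#'
#' Entry point for distances computed elsewhere (for instance imported from
#' a PHYLIP file). `NA` entries are flagged undefined.
#'
#' @param m symmetric numeric matrix with zero diagonal; row names are the
#'   sequence ids (supplied via `ids` otherwise).
#' @param ids optional identifiers overriding `rownames(m)`.
#' @param model optional [DistanceModel-class] describing the provenance.
#' @return a [GeneticDistances-class].
#' @export
geneticDistancesFromMatrix <- function(m, ids = rownames(m),
                                       model = distanceModel("P")) {
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(m)))
  m <- (m + t(m)) / 2                          # enforce exact symmetry
  dimnames(m) <- list(ids, ids)
  diag(m) <- 0
  defined <- !is.na(m)
  new("GeneticDistances", ids = ids, d = m, defined = defined, model = model)
}

#' @describeIn nSequences sequences indexed by the distance matrix.
#' @export
setMethod("nSequences", "GeneticDistances", function(x) length(x@ids))

#' @describeIn alnIds identifiers of the distance matrix.
#' @export
setMethod("alnIds", "GeneticDistances", function(x) x@ids)

#' @describeIn definedMask mask of computable entries.
#' @export
setMethod("definedMask", "GeneticDistances", function(x) x@defined)

#' @export
setMethod("as.matrix", "GeneticDistances", function(x, ...) x@d)

setMethod("show", "GeneticDistances", function(object) {
  n <- length(object@ids)
  nUndef <- sum(!object@defined[upper.tri(object@defined)])
  cat(sprintf("GeneticDistances: %d sequences, model %s, %d undefined pair%s\n",
              n, object@model@model, nUndef, if (nUndef == 1L) "" else "s"))
})

#' Subset a distance matrix by sequence id or index
#' @param x a [GeneticDistances-class].
#' @param i character ids or numeric/logical index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "GeneticDistances", function(x, i, j, ..., drop = FALSE) {
  d <- x@d[i, i, drop = FALSE]
  new("GeneticDistances", ids = rownames(d), d = d,
      defined = x@defined[i, i, drop = FALSE], model = x@model)
})

#' Defined unordered pairwise distances
#'
#' @param x a [GeneticDistances-class].
#' @return numeric vector of the defined off-diagonal distances, each
#'   unordered pair once, unsorted.
#' @export
pairwiseDistances <- function(x) {
  ut <- upper.tri(x@d)
  x@d[ut & x@defined]
}

#' Histogram of pairwise distances
#'
#' Bins the defined off-diagonal distances (each unordered pair once) into
#' half-open bins `[k w, (k+1) w)` — the data behind
#' frequency-distribution-of-pairwise-comparisons plots.
#'
#' @param x a [GeneticDistances-class].
#' @param binWidth positive bin width.
#' @return `data.frame` with columns `lower`, `upper`, `count`, covering the
#'   contiguous bin range from 0 to the largest distance.
#' @export
distanceHistogram <- function(x, binWidth) {
  stopifnot(binWidth > 0)
  v <- pairwiseDistances(x)
  ## round before flooring so values sitting exactly on a bin edge are not
  ## pushed down a bin by floating-point representation (0.3/0.1 < 3)
  k <- floor(round(v / binWidth, 9L))
  kMax <- if (length(v)) max(k) else 0
  counts <- tabulate(k + 1L, nbins = kMax + 1L)
  data.frame(lower = (0:kMax) * binWidth,
             upper = (1:(kMax + 1L)) * binWidth,
             count = counts)
}

#' Write a distance matrix as a PHYLIP square matrix
#'
#' Undefined entries are written as `NA`.
#'
#' @param x a [GeneticDistances-class].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writePhylipDistances <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(x@ids)), con)
  rows <- vapply(seq_along(x@ids), function(i)
    paste(format(x@ids[i], width = 10L),
          paste(formatC(x@d[i, ], format = "g", digits = 10L),
                collapse = " ")),
    "")
  writeLines(rows, con)
  invisible(file)
}

#' Read a PHYLIP square distance matrix
#'
#' @param file path to a PHYLIP square matrix (as written by
#'   [writePhylipDistances()]); `NA` entries become undefined.
#' @param model optional [DistanceModel-class] describing the provenance.
#' @return a [GeneticDistances-class].
#' @export
readPhylipDistances <- function(file, model = distanceModel("P")) {
  lines <- readLines(file)
  n <- as.integer(trimws(lines[1L]))
  toks <- strsplit(trimws(lines[1L + seq_len(n)]), "\\s+")
  ids <- vapply(toks, `[`, "", 1L)
  m <- t(vapply(toks, function(tk) {
    v <- tk[-1L]
    v[v == "NA"] <- NA_character_    # undefined entries
    as.numeric(v)
  }, numeric(n)))
  geneticDistancesFromMatrix(m, ids = ids, model = model)
}

#' Export distances in long format
#'
#' @param x a [GeneticDistances-class].
#' @return `data.frame` with columns `id1`, `id2`, `model`, `distance`,
#'   `defined` (one row per unordered pair).
#' @export
distancesToLongFormat <- function(x) {
  ut <- which(upper.tri(x@d), arr.ind = TRUE)
  data.frame(id1 = x@ids[ut[, 1L]], id2 = x@ids[ut[, 2L]],
             model = x@model@model,
             distance = x@d[ut], defined = x@defined[ut])
}
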