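#' Count distinct ungapped sequences
#'
#' Removes `-` and `?` from every row and counts the distinct resulting
#' strings (exact, case-normalised equality). Two records that differ only
#' in their gapping are counted once.
#'
#' @param aln a [BarcodeAlignment-class].
#' @return integer; the number of unique degapped sequences.
#' @export
degapUniqueCount <- function(aln) {
  degapped <- gsub("[-?]", "", alnStrings(aln))
  length(unique(degapped))
}

#' Per-alignment site (column) classification
#'
#' Classifies every alignment column under the gaps-as-missing convention:
#' determinate states are A/C/G/T while `-`, `?`, `N` and IUPAC ambiguity
#' codes are missing. A column is *parsimony-informative* iff at least two
#' distinct determinate states each occur in at least two rows; *constant*
#' iff exactly one determinate state occurs (necessarily in >= 2 rows);
#' *variable but uninformative* otherwise when >= 2 determinate states
#' occur; and *all-missing* when fewer than two determinate characters are
#' present at all. The four counts partition the alignment length.
#'
#' @param aln a [BarcodeAlignment-class].
#' @return a one-row `data.frame` with columns `length`, `constant`, `pu`
#'   (parsimony-uninformative variable), `pi` (parsimony-informative) and
#'   `all_missing`.
#' @examples
#' aln <- barcodeAlignment(c(a = "AAAA", b = "AAA-", c = "ACC-", d = "ACCC"))
#' siteSummary(aln)
#' @export
siteSummary <- function(aln) {
  counts <- stateCounts(aln@chars)          # 4 x L determinate-state counts
  nDet <- colSums(counts)
  nDistinct <- colSums(counts > 0L)
  nInformativeStates <- colSums(counts >= 2L)

  allMissing <- nDet < 2L
  constant <- !allMissing & nDistinct == 1L
  informative <- !allMissing & nDistinct >= 2L & nInformativeStates >= 2L
  uninformative <- !allMissing & nDistinct >= 2L & !informative

  out <- data.frame(length = ncol(aln@chars),
                    constant = sum(constant),
                    pu = sum(uninformative),
                    pi = sum(informative),
                    all_missing = sum(allMissing))
  stopifnot(out$constant + out$pu + out$pi + out$all_missing == out$length)
  out
}

## 4 x L matrix of per-column counts of A, C, G, T.
stateCounts <- function(chars) {
  res <- vapply(DETERMINATE_STATES,
                function(s) colSums(chars == s),
                numeric(ncol(chars)))
  if (is.null(dim(res))) res <- matrix(res, nrow = 1L)  # single-column case
  t(res)
}

#' Site summaries for several alignments as one table
#'
#' Convenience wrapper collating [siteSummary()] rows for a named list of
#' alignments, suitable for TSV export.
#'
#' @param alignments named list of [BarcodeAlignment-class] objects.
#' @return `data.frame` with one row per alignment.
#' @export
siteSummaryTable <- function(alignments) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  rows <- lapply(alignments, siteSummary)
  cbind(data.frame(alignment = names(alignments)), do.call(rbind, rows),
        row.names = NULL)
}
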