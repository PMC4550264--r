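#' @import methods
NULL

## Alphabet accepted in aligned barcode sequences. Determinate states are
## A/C/G/T; everything else (N, IUPAC ambiguity codes, '-', '?') is treated
## as missing for site classification and distance counting.
ALN_ALPHABET <- c("A", "C", "G", "T", "N",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
                  "-", "?")
DETERMINATE_STATES <- c("A", "C", "G", "T")

#' Aligned DNA barcode matrix
#'
#' An S4 container for a rectangular multiple sequence alignment of DNA
#' barcodes. Rows are sequences, columns are alignment positions. Characters
#' are upper case with `U` normalised to `T`; the permitted alphabet is
#' A/C/G/T, N, the IUPAC ambiguity codes, `-` and `?`. Row names of the
#' matrix are the (unique, non-empty) sequence identifiers.
#'
#' @slot chars character matrix of single characters; rownames are sequence
#'   identifiers.
#' @slot descriptions named character vector of FASTA description suffixes
#'   (the header text after the first whitespace; `""` when absent).
#'
#' @seealso [barcodeAlignment()], [readFastaAlignment()], [siteSummary()]
#' @export
setClass("BarcodeAlignment",
  representation(chars = "matrix", descriptions = "character"))

setValidity("BarcodeAlignment", function(object) {
  m <- object@chars
  if (!is.character(m)) return("'chars' must be a character matrix")
  if (ncol(m) < 1L || nrow(m) < 1L) return("alignment must be non-empty")
  ids <- rownames(m)
  if (is.null(ids) || any(!nzchar(ids)))
    return("sequence identifiers must be non-empty")
  if (anyDuplicated(ids))
    return(paste0("duplicate sequence identifiers: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  bad <- !(m %in% ALN_ALPHABET)
  dim(bad) <- dim(m)              # %in% drops the matrix dimensions
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    return(sprintf("illegal character '%s' in record '%s' at column %d",
                   m[idx[1L], idx[2L]], ids[idx[1L]], idx[2L]))
  }
  if (length(object@descriptions) != nrow(m))
    return("'descriptions' must have one entry per sequence")
  TRUE
})

#' Evolutionary distance model specification
#'
#' Describes how pairwise distances are corrected: the substitution model
#' (`"P"`, `"K2P"`, `"TN93"` or `"GTR"`), an optional gamma rate-heterogeneity
#' shape `alpha` (> 0), an optional proportion of invariable sites `pInv`
#' (in \[0, 1)), and whether TN93 base frequencies are estimated per pair
#' from the pair's shared sites (`"pairwise"`, the default, matching
#' pairwise-deletion semantics) or once from the whole alignment
#' (`"global"`).
#'
#' @slot model character; one of `"P"`, `"K2P"`, `"TN93"`, `"GTR"`.
#' @slot alpha numeric; gamma shape parameter, `NA` for no gamma adjustment.
#' @slot pInv numeric; proportion of invariable sites, `NA` for none.
#' @slot freqMode character; `"pairwise"` or `"global"`.
#'
#' @seealso [distanceModel()], [geneticDistances()]
#' @export
setClass("DistanceModel",
  representation(model = "character", alpha = "numeric", pInv = "numeric",
                 freqMode = "character"))

setValidity("DistanceModel", function(object) {
  if (length(object@model) != 1L ||
      !object@model %in% c("P", "K2P", "TN93", "GTR"))
    return("model must be one of 'P', 'K2P', 'TN93', 'GTR'")
  if (length(object@alpha) != 1L ||
      (!is.na(object@alpha) && object@alpha <= 0))
    return("alpha must be NA or > 0")
  if (length(object@pInv) != 1L ||
      (!is.na(object@pInv) && (object@pInv < 0 || object@pInv >= 1)))
    return("pInv must be NA or in [0, 1)")
  if (length(object@freqMode) != 1L ||
      !object@freqMode %in% c("pairwise", "global"))
    return("freqMode must be 'pairwise' or 'global'")
  TRUE
})

#' Pairwise genetic distance matrix
#'
#' Symmetric matrix of pairwise evolutionary distances with an explicit
#' defined-entry mask. Entries where a correction is undefined (no shared
#' determinate sites, or saturation driving a logarithm/eigenvalue out of
#' domain) are flagged `FALSE` in `defined` and stored as `NA`, never as a
#' silent zero. Downstream gap discovery treats undefined entries as absent
#' pairs.
#'
#' @slot ids character; sequence identifiers (row/column names of `d`).
#' @slot d numeric matrix; distances, `NA` where undefined, zero diagonal.
#' @slot defined logical matrix; `TRUE` where the entry is computable.
#' @slot model the [DistanceModel-class] used (an unspecified model for
#'   matrices imported from file).
#'
#' @seealso [geneticDistances()], [detectBarcodeGap()], [njTree()]
#' @export
setClass("GeneticDistances",
  representation(ids = "character", d = "matrix", defined = "matrix",
                 model = "DistanceModel"))

setValidity("GeneticDistances", function(object) {
  n <- length(object@ids)
  d <- object@d; def <- object@defined
  if (!all(dim(d) == c(n, n)) || !all(dim(def) == c(n, n)))
    return("'d' and 'defined' must be n x n for n ids")
  if (anyDuplicated(object@ids)) return("ids must be unique")
  if (!isTRUE(all.equal(d, t(d)))) return("'d' must be symmetric")
  if (!identical(def, t(def))) return("'defined' must be symmetric")
  if (any(diag(d) != 0) || !all(diag(def)))
    return("diagonal must be zero and defined")
  if (anyNA(d[def])) return("defined entries must be non-missing")
  if (any(!is.na(d[!def]))) return("undefined entries must be NA")
  if (any(d[def] < 0)) return("defined distances must be non-negative")
  TRUE
})

#' Partition of sequences into hypothetical OTUs
#'
#' Assignment of every sequence to exactly one operational taxonomic unit.
#' Group labels are integers numbered by first appearance in the id order.
#' `kind` records how the partition arose: a single pass of gap detection
#' plus clustering (`"initial"`), the fixed point of within-group
#' re-partitioning (`"recursive"`), or the generating truth of a simulated
#' dataset (`"truth"`).
#'
#' @slot assignment named integer vector mapping sequence id to group label.
#' @slot kind character; `"initial"`, `"recursive"` or `"truth"`.
#'
#' @seealso [abgdInitial()], [abgdRecursive()], [nOtus()]
#' @export
setClass("OtuPartition",
  representation(assignment = "integer", kind = "character"))

setValidity("OtuPartition", function(object) {
  a <- object@assignment
  if (length(a) < 1L) return("empty partition")
  if (is.null(names(a)) || anyDuplicated(names(a)) || any(!nzchar(names(a))))
    return("assignment must be named by unique sequence ids")
  if (anyNA(a)) return("every id must be assigned")
  k <- length(unique(a))
  if (k < 1L || k > length(a)) return("invalid group count")
  if (length(object@kind) != 1L ||
      !object@kind %in% c("initial", "recursive", "truth"))
    return("kind must be 'initial', 'recursive' or 'truth'")
  TRUE
})

#' Ranked-distance barcode-gap scan result
#'
#' Diagnostics of one gap scan at a single prior intraspecific divergence:
#' the ranked defined pairwise distances, the rank of the detected gap (or
#' `NA` when no gap qualifies), the partition threshold (the midpoint of the
#' detected gap), the relative gap width used, and the smoothing window over
#' preceding gaps that sets the local gap scale.
#'
#' @slot prior numeric; maximal prior intraspecific divergence P.
#' @slot x numeric; relative gap width multiplier X.
#' @slot ranked numeric; sorted (non-decreasing) defined pairwise distances.
#' @slot gapIndex integer; rank i of the detected gap, `NA` if none.
#' @slot threshold numeric; `(ranked[i] + ranked[i+1]) / 2`, `NA` if none.
#' @slot window integer; smoothing window size used.
#'
#' @seealso [detectBarcodeGap()], [partitionAtThreshold()]
#' @export
setClass("GapScan",
  representation(prior = "numeric", x = "numeric", ranked = "numeric",
                 gapIndex = "integer", threshold = "numeric",
                 window = "integer"))

setValidity("GapScan", function(object) {
  if (is.unsorted(object@ranked)) return("'ranked' must be non-decreasing")
  i <- object@gapIndex
  if (!is.na(i)) {
    if (i < 1L || i >= length(object@ranked)) return("gapIndex out of range")
    if (object@ranked[i + 1L] < object@prior)
      return("detected gap must end at or above the prior")
    th <- object@threshold
    if (is.na(th) || th <= object@ranked[i] || th >= object@ranked[i + 1L])
      return("threshold must lie strictly inside the detected gap")
  } else if (!is.na(object@threshold)) {
    return("threshold must be NA when no gap was detected")
  }
  TRUE
})

#' Specification of a simulated barcode dataset
#'
#' Parameters of the two-scale simulator: species number and sizes, raw
#' sequence length, target mean within-species (`intraD`) and between-species
#' (`interD`) p-distances, the transition/transversion rate ratio `kappa`,
#' the per-site indel probability on a species-level branch (`indelRate`),
#' the equilibrium base composition and the RNG seed.
#'
#' @slot nSpecies integer.
#' @slot nPerSpecies integer vector (length 1, recycled, or one per species).
#' @slot seqLen integer; raw (ungapped) sequence length in nt.
#' @slot intraD numeric; target mean within-species p-distance.
#' @slot interD numeric; target mean between-species p-distance.
#' @slot kappa numeric; transition/transversion rate ratio (> 0).
#' @slot indelRate numeric in \[0, 0.2\].
#' @slot baseFreqs numeric length 4 (A, C, G, T), summing to 1.
#' @slot seed integer.
#'
#' @seealso [simulationSpec()], [simulateBarcodes()]
#' @export
setClass("SimulationSpec",
  representation(nSpecies = "integer", nPerSpecies = "integer",
                 seqLen = "integer", intraD = "numeric", interD = "numeric",
                 kappa = "numeric", indelRate = "numeric",
                 baseFreqs = "numeric", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  if (object@nSpecies < 1L) return("nSpecies must be >= 1")
  if (!length(object@nPerSpecies) %in% c(1L, object@nSpecies))
    return("nPerSpecies must have length 1 or nSpecies")
  if (any(object@nPerSpecies < 1L)) return("species sizes must be >= 1")
  if (object@seqLen < 1L) return("seqLen must be positive")
  if (object@intraD < 0 || object@interD <= object@intraD)
    return("require 0 <= intraD < interD")
  if (object@kappa <= 0) return("kappa must be > 0")
  if (object@indelRate < 0 || object@indelRate > 0.2)
    return("indelRate must be in [0, 0.2]")
  bf <- object@baseFreqs
  if (length(bf) != 4L || any(bf <= 0) || abs(sum(bf) - 1) > 1e-8)
    return("baseFreqs must be 4 positive values summing to 1")
  TRUE
})

#' Simulated barcode dataset with known truth
#'
#' A simulated aligned dataset bundling the true alignment (gaps arise only
#' from the simulated indel process, so homology is exact), the generating
#' species partition and the [SimulationSpec-class] that produced it.
#'
#' @slot alignment a [BarcodeAlignment-class].
#' @slot partition the true [OtuPartition-class] (`kind = "truth"`).
#' @slot spec the generating [SimulationSpec-class].
#'
#' @seealso [simulateBarcodes()], [studyEmulationPreset()]
#' @export
setClass("SimulatedBarcodes",
  representation(alignment = "BarcodeAlignment", partition = "OtuPartition",
                 spec = "SimulationSpec"))

setValidity("SimulatedBarcodes", function(object) {
  if (!setequal(names(object@partition@assignment),
                rownames(object@alignment@chars)))
    return("partition must cover exactly the alignment's ids")
  TRUE
})
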