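#' Construct a BarcodeAlignment from aligned sequence strings
#'
#' Normalises case (everything upper-cased) and RNA-style `U` to `T`, then
#' validates shape, identifiers and alphabet.
#'
#' @param sequences character vector of aligned sequences (equal length).
#' @param ids sequence identifiers; defaults to `names(sequences)`.
#' @param descriptions optional character vector of description suffixes.
#' @return a [BarcodeAlignment-class].
#' @examples
#' aln <- barcodeAlignment(c(s1 = "ACGT-", s2 = "ACGTT", s3 = "AC-TT"))
#' alnLength(aln)
#' @export
barcodeAlignment <- function(sequences, ids = names(sequences),
                             descriptions = NULL) {
  if (length(sequences) < 1L) stop("no sequences given")
  if (is.null(ids)) stop("sequence identifiers are required")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop(sprintf(
      "alignment is ragged: sequence lengths differ (e.g. '%s' has %d columns, '%s' has %d)",
      ids[1L], lens[1L], ids[which(lens != lens[1L])[1L]],
      lens[which(lens != lens[1L])[1L]]))
  }
  seqs <- chartr("u", "U", toupper(sequences))
  seqs <- chartr("U", "T", seqs)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- as.character(ids)
  if (is.null(descriptions)) descriptions <- rep("", nrow(m))
  names(descriptions) <- rownames(m)
  new("BarcodeAlignment", chars = m, descriptions = descriptions)
}

#' Read an aligned FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file and validates it
#' as a rectangular alignment. The identifier is the header token before the
#' first whitespace; the remainder of the header is retained as the record's
#' description.
#'
#' @param file path to an aligned FASTA file.
#' @return a [BarcodeAlignment-class].
#' @seealso [writeFastaAlignment()]
#' @export
readFastaAlignment <- function(file) {
  set <- Biostrings::readBStringSet(file)
  if (length(set) < 1L) stop("no FASTA records in ", file)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  barcodeAlignment(as.character(set), ids = ids, descriptions = desc)
}

#' Write an alignment as FASTA
#'
#' Writing then reading back with [readFastaAlignment()] returns an
#' identical object.
#'
#' @param aln a [BarcodeAlignment-class].
#' @param file output path.
#' @param width line width for sequence wrapping.
#' @return invisibly, `file`.
#' @export
writeFastaAlignment <- function(aln, file, width = 70L) {
  seqs <- alnStrings(aln)
  hdr <- ifelse(nzchar(aln@descriptions),
                paste(names(seqs), aln@descriptions), names(seqs))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = file, width = width)
  invisible(file)
}

#' Aligned sequences as strings
#'
#' @param aln a [BarcodeAlignment-class].
#' @return named character vector of aligned sequence strings.
#' @export
alnStrings <- function(aln) {
  out <- apply(aln@chars, 1L, paste, collapse = "")
  names(out) <- rownames(aln@chars)
  out
}

#' @describeIn nSequences rows of the alignment.
#' @export
setMethod("nSequences", "BarcodeAlignment", function(x) nrow(x@chars))

#' @describeIn alnIds identifiers of the aligned sequences.
#' @export
setMethod("alnIds", "BarcodeAlignment", function(x) rownames(x@chars))

#' @describeIn alnLength number of alignment columns.
#' @export
setMethod("alnLength", "BarcodeAlignment", function(x) ncol(x@chars))

#' @export
setMethod("as.matrix", "BarcodeAlignment", function(x, ...) x@chars)

setMethod("show", "BarcodeAlignment", function(object) {
  cat(sprintf("BarcodeAlignment: %d sequences x %d columns\n",
              nrow(object@chars), ncol(object@chars)))
  ids <- rownames(object@chars)
  shown <- utils::head(ids, 5L)
  cat("  ids:", paste(shown, collapse = ", "),
      if (length(ids) > 5L) sprintf("... (%d more)", length(ids) - 5L) else "",
      "\n")
})

#' Subset an alignment by sequence id or index
#' @param x a [BarcodeAlignment-class].
#' @param i character ids or numeric/logical row index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "BarcodeAlignment", function(x, i, j, ..., drop = FALSE) {
  m <- x@chars[i, , drop = FALSE]
  new("BarcodeAlignment", chars = m,
      descriptions = x@descriptions[rownames(m)])
})
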