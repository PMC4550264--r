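#' Number of sequences in an object
#' @param x an object holding sequences.
#' @return integer count of sequences.
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' Sequence identifiers of an object
#' @param x an object holding identified sequences.
#' @return character vector of identifiers.
#' @export
setGeneric("alnIds", function(x) standardGeneric("alnIds"))

#' Alignment length (number of columns)
#' @param x an alignment-like object.
#' @return integer column count.
#' @export
setGeneric("alnLength", function(x) standardGeneric("alnLength"))

#' Number of OTUs in a partition
#' @param x an [OtuPartition-class].
#' @return integer number of distinct groups.
#' @export
setGeneric("nOtus", function(x) standardGeneric("nOtus"))

#' Defined-entry mask of a distance matrix
#' @param x a [GeneticDistances-class].
#' @return logical matrix, `TRUE` where the pairwise distance is computable.
#' @export
setGeneric("definedMask", function(x) standardGeneric("definedMask"))
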