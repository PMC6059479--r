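#' @rdname BarcodeCounts-class
#' @param x a \linkS4class{BarcodeCounts} object.
#' @export
setGeneric("rejectedReads", function(x) standardGeneric("rejectedReads"))

#' @rdname BarcodeCounts-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname SyntheticTruth-class
#' @param x a \linkS4class{SyntheticTruth} object.
#' @export
setGeneric("strains", function(x) standardGeneric("strains"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("trueEffects", function(x) standardGeneric("trueEffects"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname BindingScorePanel-class
#' @param x a \linkS4class{BindingScorePanel} or \linkS4class{FactorCounts}
#'   object.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname FactorCounts-class
#' @param x an object with a locus label.
#' @export
setGeneric("locusLabel", function(x) standardGeneric("locusLabel"))

#' Count reads into a barcode x index matrix
#'
#' @param reads FASTQ file path(s) (plain or gzipped) or a
#'   [Biostrings::DNAStringSet] of reads.
#' @param design an \linkS4class{AmpliconDesign}.
#' @param ... passed to methods (`chunkSize` for file input).
#' @return a \linkS4class{BarcodeCounts}.
#' @seealso [extractReads()], [filterMinCount()]
#' @export
setGeneric("countBarcodes", function(reads, design, ...)
    standardGeneric("countBarcodes"))
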