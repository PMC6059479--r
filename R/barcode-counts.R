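#' @rdname BarcodeCounts-class
#' @param counts integer matrix, rows = barcode sequences, columns = sample
#'   indexes.
#' @param rejected named tally of rejected reads (`no_anchor`, `truncated`,
#'   `ambiguous_base`).
#' @param colData optional [S4Vectors::DataFrame] of per-sample annotation.
#' @export
BarcodeCounts <- function(counts,
                          rejected = c(no_anchor = 0L, truncated = 0L,
                                       ambiguous_base = 0L),
                          colData = NULL) {
    counts <- as.matrix(counts)
    if (is.null(colData))
        colData <- S4Vectors::DataFrame(row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = colData)
    md <- S4Vectors::metadata(se)
    md$rejected <- rejected
    md$totalReads <- sum(counts, na.rm = TRUE) + sum(rejected)
    S4Vectors::metadata(se) <- md
    new("BarcodeCounts", se)
}

#' @rdname BarcodeCounts-class
#' @param object a \linkS4class{BarcodeCounts}.
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "BarcodeCounts", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname FactorCounts-class
#' @param object a \linkS4class{FactorCounts}.
#' @export
setMethod("counts", "FactorCounts", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname BarcodeCounts-class
#' @export
setMethod("rejectedReads", "BarcodeCounts", function(x)
    S4Vectors::metadata(x)$rejected)

#' @rdname BarcodeCounts-class
#' @export
setMethod("totalReads", "BarcodeCounts", function(x)
    S4Vectors::metadata(x)$totalReads)

#' @rdname FactorCounts-class
#' @export
setMethod("locusLabel", "FactorCounts", function(x) x@locus)

#' @rdname BindingScorePanel-class
#' @export
setMethod("locusLabel", "BindingScorePanel", function(x) x@locus)

#' @rdname BindingScorePanel-class
#' @param object a \linkS4class{BindingScorePanel}.
#' @export
setMethod("scores", "BindingScorePanel", function(x)
    SummarizedExperiment::assay(x, "score"))

setMethod("show", "BarcodeCounts", function(object) {
    callNextMethod()
    rej <- rejectedReads(object)
    cat("rejected reads:", paste(names(rej), rej, sep = "=", collapse = " "),
        "\n")
})

#' Remove low counts from a barcode count matrix
#'
#' Entries below `threshold` are set to `NA` ("absent"); everything else is
#' untouched. The screen's preprocessing removes counts below 10 before any
#' further filtering or normalization, treating them as noise from sequencing
#' errors or index hopping.
#'
#' @param x a \linkS4class{BarcodeCounts} or \linkS4class{FactorCounts}.
#' @param threshold minimum count retained (default 10).
#' @return an object of the same class with sub-threshold entries absent.
#' @examples
#' m <- matrix(c(9L, 10L, 0L, 25L), 2,
#'             dimnames = list(c("b1", "b2"), c("i1", "i2")))
#' counts(filterMinCount(BarcodeCounts(m)))
#' @export
filterMinCount <- function(x, threshold = 10L) {
    stopifnot(threshold >= 0)
    m <- SummarizedExperiment::assay(x, "counts")
    m[!is.na(m) & m < threshold] <- NA
    SummarizedExperiment::assay(x, "counts") <- m
    x
}
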