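#' Construct an amplicon design
#'
#' @param name label for the design.
#' @param constantRegion anchor sequence (uppercase ACGT).
#' @param indexLength sample-index length (6 or 12).
#' @param indexSide,indexOffset side of the anchor the index sits on and the
#'   gap (bases) between them.
#' @param barcodeLength clone-barcode length (20 or 15).
#' @param barcodeSide,barcodeOffset side and gap for the barcode interval.
#' @param maxAnchorMismatches substitutions tolerated when locating the
#'   anchor (default 1; the barcode and index themselves are read off
#'   verbatim, without error correction).
#' @param searchWindow 0-based inclusive range of positions at which the
#'   anchor may start.
#' @return an \linkS4class{AmpliconDesign}.
#' @examples
#' d <- kanmxDesign()
#' d
#' @export
AmpliconDesign <- function(name, constantRegion,
                           indexLength = 6L, indexSide = "upstream",
                           indexOffset = 0L,
                           barcodeLength = 20L, barcodeSide = "downstream",
                           barcodeOffset = 0L,
                           maxAnchorMismatches = 1L,
                           searchWindow = c(0L, 12L)) {
    new("AmpliconDesign",
        name = as.character(name),
        constantRegion = toupper(as.character(constantRegion)),
        indexLength = as.integer(indexLength),
        indexSide = indexSide,
        indexOffset = as.integer(indexOffset),
        barcodeLength = as.integer(barcodeLength),
        barcodeSide = barcodeSide,
        barcodeOffset = as.integer(barcodeOffset),
        maxAnchorMismatches = as.integer(maxAnchorMismatches),
        searchWindow = as.integer(searchWindow))
}

#' Built-in amplicon designs
#'
#' `kanmxDesign()` models the barcoded marker-gene amplicon: a 6-bp sample
#' index immediately upstream of a cassette-flanking constant region, with a
#' 20-bp clone barcode immediately downstream. `ade2Design()` models the
#' second-locus amplicon with a 15-bp barcode. The constant-region sequences
#' shipped here are synthetic stand-ins with the geometry of the real
#' cassette linkers; supply your own `constantRegion` to match a concrete
#' primer design.
#'
#' @param constantRegion the anchor sequence to use.
#' @param ... further arguments passed to [AmpliconDesign()].
#' @return an \linkS4class{AmpliconDesign}.
#' @examples
#' ade2Design()
#' @export
kanmxDesign <- function(constantRegion = "CGTACGCTGCAGGTCGAC", ...) {
    AmpliconDesign(name = "kanmx-bc20", constantRegion = constantRegion,
                   indexLength = 6L, barcodeLength = 20L, ...)
}

#' @rdname kanmxDesign
#' @export
ade2Design <- function(constantRegion = "CTAGCTCGAGTCGACATG", ...) {
    AmpliconDesign(name = "ade2-bc15", constantRegion = constantRegion,
                   indexLength = 6L, barcodeLength = 15L, ...)
}

#' @rdname AmpliconDesign-class
#' @param x an \linkS4class{AmpliconDesign}.
#' @export
constantRegion <- function(x) x@constantRegion

#' @rdname AmpliconDesign-class
#' @export
barcodeLength <- function(x) x@barcodeLength

#' @rdname AmpliconDesign-class
#' @export
indexLength <- function(x) x@indexLength

setMethod("show", "AmpliconDesign", function(object) {
    cat("AmpliconDesign '", object@name, "'\n", sep = "")
    cat("  anchor: ", object@constantRegion,
        " (<=", object@maxAnchorMismatches, " mismatches, window ",
        object@searchWindow[1L], "-", object@searchWindow[2L], ")\n",
        sep = "")
    cat("  index: ", object@indexLength, " bp ", object@indexSide,
        " (offset ", object@indexOffset, ")\n", sep = "")
    cat("  barcode: ", object@barcodeLength, " bp ", object@barcodeSide,
        " (offset ", object@barcodeOffset, ")\n", sep = "")
})
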