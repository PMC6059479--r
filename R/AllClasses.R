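#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Amplicon design: the geometry used to parse a sequencing read
#'
#' An `AmpliconDesign` describes where the sample index and the clone barcode
#' sit relative to a constant anchor sequence (e.g. the cassette-flanking
#' constant region of a barcoded marker gene). Reads are parsed by locating
#' the anchor within a search window, then slicing the index and barcode
#' intervals at fixed offsets on either side of it. All coordinates are
#' 0-based, half-open.
#'
#' @slot name label for the design.
#' @slot constantRegion the anchor sequence (uppercase ACGT).
#' @slot indexLength sample-index length in bases (6 or 12).
#' @slot indexSide `"upstream"` or `"downstream"` of the anchor.
#' @slot indexOffset gap in bases between anchor and index interval.
#' @slot barcodeLength clone-barcode length in bases (20 or 15).
#' @slot barcodeSide `"upstream"` or `"downstream"` of the anchor.
#' @slot barcodeOffset gap in bases between anchor and barcode interval.
#' @slot maxAnchorMismatches substitutions tolerated when locating the anchor.
#' @slot searchWindow integer vector of length 2: the 0-based inclusive range
#'   of read positions at which the anchor may start.
#'
#' @seealso [kanmxDesign()], [ade2Design()], [locateAnchor()], [extractReads()]
#' @export
setClass("AmpliconDesign",
    slots = c(
        name = "character",
        constantRegion = "character",
        indexLength = "integer",
        indexSide = "character",
        indexOffset = "integer",
        barcodeLength = "integer",
        barcodeSide = "character",
        barcodeOffset = "integer",
        maxAnchorMismatches = "integer",
        searchWindow = "integer"
    )
)

setValidity("AmpliconDesign", function(object) {
    msg <- character()
    cr <- object@constantRegion
    if (length(cr) != 1L || !nzchar(cr) || grepl("[^ACGT]", cr))
        msg <- c(msg, "constantRegion must be a nonempty uppercase ACGT string")
    if (!object@indexLength %in% c(6L, 12L))
        msg <- c(msg, "indexLength must be 6 or 12")
    if (!object@barcodeLength %in% c(15L, 20L))
        msg <- c(msg, "barcodeLength must be 15 or 20")
    if (!object@indexSide %in% c("upstream", "downstream"))
        msg <- c(msg, "indexSide must be 'upstream' or 'downstream'")
    if (!object@barcodeSide %in% c("upstream", "downstream"))
        msg <- c(msg, "barcodeSide must be 'upstream' or 'downstream'")
    if (object@indexOffset < 0L || object@barcodeOffset < 0L)
        msg <- c(msg, "offsets must be nonnegative")
    if (object@indexSide == object@barcodeSide &&
        object@indexOffset == object@barcodeOffset)
        msg <- c(msg, "index and barcode intervals overlap")
    if (length(object@searchWindow) != 2L || any(object@searchWindow < 0L) ||
        object@searchWindow[1L] > object@searchWindow[2L])
        msg <- c(msg, "searchWindow must be an ordered nonnegative pair")
    if (object@maxAnchorMismatches < 0L)
        msg <- c(msg, "maxAnchorMismatches must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' Configuration of a simulated screen
#'
#' Holds the parameters of the synthetic-data generator: library size,
#' replication, sequencing depth, the negative-binomial overdispersion of the
#' count model, the per-base substitution error rate of read simulation, and
#' the distribution of true log2 binding effects.
#'
#' @slot nStrains number of barcoded clones in the library.
#' @slot nReplicates number of biological replicates (IP/input pairs).
#' @slot depth expected reads per sample.
#' @slot dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 reduces to Poisson.
#' @slot errorRate per-base substitution probability in simulated reads.
#' @slot fracBinders proportion of strains with a nonzero binding effect.
#' @slot effectMean,effectSd log2-scale effect distribution (Normal truncated
#'   at 0) for binders.
#' @slot seed integer seed making every downstream draw reproducible.
#'
#' @seealso [SimulationConfig()], [simulateLibrary()]
#' @export
setClass("SimulationConfig",
    slots = c(
        nStrains = "integer",
        nReplicates = "integer",
        depth = "numeric",
        dispersion = "numeric",
        errorRate = "numeric",
        fracBinders = "numeric",
        effectMean = "numeric",
        effectSd = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nStrains < 1L) msg <- c(msg, "nStrains must be >= 1")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (!is.finite(object@depth) || object@depth <= 0)
        msg <- c(msg, "depth must be > 0")
    if (!is.finite(object@dispersion) || object@dispersion < 0)
        msg <- c(msg, "dispersion must be >= 0")
    if (object@errorRate < 0 || object@errorRate >= 0.25)
        msg <- c(msg, "errorRate must be in [0, 0.25)")
    if (object@fracBinders < 0 || object@fracBinders > 1)
        msg <- c(msg, "fracBinders must be in [0, 1]")
    if (!is.finite(object@effectMean) || !is.finite(object@effectSd) ||
        object@effectSd < 0)
        msg <- c(msg, "effectMean/effectSd must be finite, effectSd >= 0")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated barcoded library
#'
#' The generator's record of what was simulated: the strain table (ids, ORF
#' names, barcode sequences and 384-well plate layout), the true per-locus
#' log2 binding effects, and the relative input abundance of every strain.
#' Downstream recovery tests compare pipeline output against this object.
#'
#' @slot strains a [S4Vectors::DataFrame] with columns `strain_id`, `orf`,
#'   `barcode`, `plate`, `row`, `col`.
#' @slot effects numeric matrix (strains x loci, columns `BC_UP`, `BC_DN`)
#'   of true log2 IP/input enrichments.
#' @slot abundance strictly positive relative input abundances.
#' @slot seed the seed the library was drawn with.
#'
#' @seealso [simulateLibrary()], [strains()], [trueEffects()], [abundances()]
#' @export
setClass("SyntheticTruth",
    slots = c(
        strains = "DataFrame",
        effects = "matrix",
        abundance = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    st <- object@strains
    need <- c("strain_id", "orf", "barcode", "plate", "row", "col")
    if (!all(need %in% colnames(st)))
        msg <- c(msg, paste("strains must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(st$barcode))
            msg <- c(msg, "barcode sequences must be unique")
        if (length(unique(nchar(st$barcode))) > 1L)
            msg <- c(msg, "barcodes must share one length")
    }
    if (nrow(object@effects) != nrow(st) ||
        length(object@abundance) != nrow(st))
        msg <- c(msg, "effects/abundance must match the strain table")
    if (!all(is.finite(object@effects)))
        msg <- c(msg, "effects must be finite")
    if (any(object@abundance <= 0))
        msg <- c(msg, "abundance must be strictly positive")
    if (length(msg)) msg else TRUE
})

#' Barcode x sample-index count matrix
#'
#' The pipeline's central table: integer read counts for every
#' (clone barcode, sample index) combination, held as a
#' [SummarizedExperiment::SummarizedExperiment] with assay `"counts"`
#' (rows = barcodes, columns = sample indexes). Rejected-read tallies from
#' extraction are kept in `metadata()`: a named vector with elements
#' `no_anchor`, `truncated` and `ambiguous_base`. Filtering
#' ([filterMinCount()]) replaces sub-threshold entries with `NA` ("absent").
#'
#' @seealso [countBarcodes()], [filterMinCount()], [rejectedReads()],
#'   [totalReads()]
#' @export
setClass("BarcodeCounts", contains = "SummarizedExperiment")

setValidity("BarcodeCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(m < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be nonnegative")
    }
    rej <- S4Vectors::metadata(object)$rejected
    if (is.null(rej) ||
        !all(c("no_anchor", "truncated", "ambiguous_base") %in% names(rej)))
        msg <- c(msg, "metadata()$rejected must tally no_anchor, truncated, ambiguous_base")
    if (length(msg)) msg else TRUE
})

#' Factor x sample counts at one barcoded locus
#'
#' A [BarcodeCounts]-like container after matching clone barcodes to ORF
#' (factor) names through a strain map: rows are factors, columns samples,
#' with the locus label (`BC_UP`, `BC_DN`, ...) carried along. Column
#' metadata holds the sample sheet fields (`fraction`, `condition`,
#' `replicate`, `plate`).
#'
#' @slot locus the locus label the counts refer to.
#' @seealso [factorCounts()], [medianNormalize()], [log2Scores()]
#' @export
setClass("FactorCounts",
    contains = "SummarizedExperiment",
    slots = c(locus = "character")
)

#' Per-factor, per-replicate binding scores
#'
#' Binding scores (log2 IP - log2 input) for one locus, rows = factors,
#' columns = replicates, held as a SummarizedExperiment with assay
#' `"score"`. Column metadata carries `condition` and `replicate`.
#'
#' @slot locus the locus label the scores refer to.
#' @seealso [log2Scores()], [quantileNormalize()], [moderatedOneSampleTest()]
#' @export
setClass("BindingScorePanel",
    contains = "SummarizedExperiment",
    slots = c(locus = "character")
)

setValidity("BindingScorePanel", function(object) {
    if (!"score" %in% SummarizedExperiment::assayNames(object))
        "assay 'score' is required"
    else TRUE
})

#' Empirical-Bayes variance prior
#'
#' The scaled inverse chi-square prior fitted across factors: prior degrees
#' of freedom `df` (may be `Inf`; 0 means no shrinkage) and prior variance
#' `s2`. Posterior (moderated) variances are the df-weighted average of the
#' prior and per-factor sample variances.
#'
#' @slot df prior degrees of freedom (>= 0 or `Inf`).
#' @slot s2 prior variance (> 0).
#' @seealso [estimatePrior()], [moderatedOneSampleTest()]
#' @export
setClass("ModeratedPrior", slots = c(df = "numeric", s2 = "numeric"))

setValidity("ModeratedPrior", function(object) {
    msg <- character()
    if (length(object@df) != 1L || is.na(object@df) || object@df < 0)
        msg <- c(msg, "df must be a single value >= 0 (Inf allowed)")
    if (length(object@s2) != 1L || !is.finite(object@s2) || object@s2 <= 0)
        msg <- c(msg, "s2 must be a single positive value")
    if (length(msg)) msg else TRUE
})

#' Running-sum enrichment result
#'
#' Result of the weighted Kolmogorov-Smirnov running-sum statistic over a
#' ranked factor list: the enrichment score `ES` (signed maximum deviation,
#' in \[-1, 1\]), a permutation p-value, the leading-edge positions, and the
#' full running-sum curve for plotting.
#'
#' @slot es the enrichment score.
#' @slot p permutation p-value.
#' @slot leadingEdge integer positions (in ranked order) of the set members
#'   driving the extreme deviation.
#' @slot runningSum the running-sum curve over the ranking.
#' @slot ranked the factor names in ranked order.
#' @seealso [runningSumEnrichment()]
#' @export
setClass("RunningSumResult",
    slots = c(
        es = "numeric",
        p = "numeric",
        leadingEdge = "integer",
        runningSum = "numeric",
        ranked = "character"
    )
)
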