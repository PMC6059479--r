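#' Read gene sets
#'
#' `readGMT()` parses GMT files (term, description, members...).
#' `readFactorTermTSV()` reads a two-column TSV (factor, term) into the same
#' named-list form.
#'
#' @param path file path.
#' @return named list of character vectors (term -> member factors), with a
#'   `description` attribute for GMT input.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[`, "", 1L)
    attr(sets, "description") <- vapply(parts, `[`, "", 2L)
    sets
}

#' @rdname readGMT
#' @param factorCol,termCol column names in the TSV.
#' @export
readFactorTermTSV <- function(path, factorCol = "factor",
                              termCol = "term") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c(factorCol, termCol) %in% colnames(df)))
    lapply(split(df[[factorCol]], df[[termCol]]), unique)
}

#' One-sided Fisher over-representation test per gene set
#'
#' For each term, the 2x2 table (binders in/out of the term vs non-binders
#' in/out) is tested for over-representation of binders in the term; the
#' one-sided p-value is the hypergeometric upper tail, identical to
#' `fisher.test(..., alternative = "greater")`. Terms disjoint from the
#' universe get p = 1 with a warning.
#'
#' @param binders character vector of called binders (subset of
#'   `universe`).
#' @param universe all tested factors.
#' @param sets named list of term -> member factors.
#' @return a [S4Vectors::DataFrame]: `term`, `overlap`, `setSize`,
#'   `nBinders`, `universe`, `p`, `FDR`.
#' @export
fisherEnrichment <- function(binders, universe, sets) {
    binders <- unique(binders); universe <- unique(universe)
    if (!all(binders %in% universe))
        stop("binders must be a subset of the universe")
    N <- length(universe); n <- length(binders)
    res <- lapply(names(sets), function(term) {
        inset <- intersect(sets[[term]], universe)
        K <- length(inset)
        k <- length(intersect(inset, binders))
        p <- if (K == 0L) {
            warning("term '", term, "' is disjoint from the universe")
            1
        } else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(term = term, overlap = k, setSize = K, stringsAsFactors = FALSE,
                   nBinders = n, universe = N, p = p)
    })
    out <- do.call(rbind, res)
    out$FDR <- bhAdjust(out$p)
    S4Vectors::DataFrame(out)
}

#' The built-in functional category scheme
#'
#' Loads the packaged mapping from coarse functional categories
#' (`DNA binding`, `RNA binding or processing`, `metabolism`) to GO-slim
#' process terms, in priority order. Factors matching no listed term fall
#' through to `other`.
#'
#' @return named list (category -> GO-slim term names), ordered by
#'   priority.
#' @export
goSlimCategoryScheme <- function() {
    path <- system.file("extdata", "go_slim_categories.tsv",
                        package = "barcodeChIP", mustWork = TRUE)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    cats <- unique(df$category)
    out <- lapply(cats, function(cc) df$term[df$category == cc])
    names(out) <- cats
    out
}

#' Assign factors to coarse functional categories
#'
#' Each factor is mapped to the highest-priority category whose GO-slim
#' terms contain it (priority: DNA binding > RNA binding or processing >
#' metabolism), otherwise `"other"`. Scheme terms missing from the GO-slim
#' collection are an error (they would silently empty a category).
#'
#' @param factors factor names to categorize.
#' @param goSlim named list, GO-slim term -> member factors.
#' @param scheme named list, category -> term names, in priority order
#'   (default: the packaged scheme).
#' @return named character vector, factor -> category.
#' @export
assignCategories <- function(factors, goSlim,
                             scheme = goSlimCategoryScheme()) {
    missing <- setdiff(unlist(scheme), names(goSlim))
    if (length(missing))
        stop("scheme term(s) absent from the GO-slim collection: ",
             paste(missing, collapse = "; "))
    out <- rep("other", length(factors))
    names(out) <- factors
    for (cc in rev(names(scheme))) {  # low priority first, high overwrites
        members <- unique(unlist(goSlim[scheme[[cc]]]))
        out[factors %in% members] <- cc
    }
    out
}

#' Running-sum (weighted Kolmogorov-Smirnov) set enrichment
#'
#' Walking down a ranked factor list, in-set positions add
#' `|metric|^exponent` (normalized by the in-set total) and out-of-set
#' positions subtract `1/(N - n_set)`; the enrichment score `ES` is the
#' signed maximum deviation of this running sum. Significance comes from
#' permuting set membership over the ranked factors:
#' `p = (1 + #(|ES*| >= |ES|)) / (nPerm + 1)`. Factors are ranked by
#' decreasing metric, ties broken by factor name for determinism.
#'
#' @param metric named numeric vector: the ranking metric per factor (e.g.
#'   the difference of the two loci's log fold-changes per binder).
#' @param geneSet character vector of set members; must intersect the
#'   ranked factors and must not cover them all.
#' @param exponent 0 (unweighted, symmetric steps) or 1 (weighted by the
#'   metric, the default of the classic scoring function).
#' @param nPerm number of membership permutations.
#' @param seed RNG seed for the permutation null.
#' @return a \linkS4class{RunningSumResult}.
#' @export
runningSumEnrichment <- function(metric, geneSet, exponent = 1,
                                 nPerm = 10000L, seed = 1L) {
    stopifnot(!is.null(names(metric)), exponent %in% c(0, 1))
    ord <- order(-metric, names(metric))
    metric <- metric[ord]
    ranked <- names(metric)
    N <- length(ranked)
    inSet <- ranked %in% geneSet
    nset <- sum(inSet)
    if (nset == 0L) stop("gene set does not intersect the ranked factors")
    if (nset == N) stop("gene set covers the entire ranking: the ",
                        "out-of-set step is undefined")
    w <- abs(metric)^exponent
    esOf <- function(hit) {
        hw <- w * hit
        denom <- sum(hw)
        if (denom == 0) stop("all in-set metric weights are zero")
        dev <- cumsum(hw) / denom - cumsum(!hit) / (N - nset)
        unname(dev[which.max(abs(dev))])
    }
    es <- esOf(inSet)
    dev <- unname(cumsum(w * inSet) / sum(w * inSet) -
                  cumsum(!inSet) / (N - nset))
    peak <- which.max(abs(dev))
    le <- if (es >= 0) which(inSet[seq_len(peak)])
          else peak - 1L + which(inSet[peak:N])
    set.seed(seed)
    hitsGE <- 0L
    for (b in seq_len(nPerm)) {
        hit <- logical(N)
        hit[sample.int(N, nset)] <- TRUE
        if (abs(esOf(hit)) >= abs(es)) hitsGE <- hitsGE + 1L
    }
    new("RunningSumResult",
        es = es, p = (1 + hitsGE) / (nPerm + 1),
        leadingEdge = as.integer(le), runningSum = dev, ranked = ranked)
}

setMethod("show", "RunningSumResult", function(object) {
    cat("RunningSumResult: ES =", format(object@es, digits = 4),
        ", p =", format(object@p, digits = 4),
        ",", length(object@leadingEdge), "leading-edge factors of",
        length(object@ranked), "ranked\n")
})

#' @rdname RunningSumResult-class
#' @param x a \linkS4class{RunningSumResult}.
#' @export
enrichmentScore <- function(x) x@es

#' @rdname RunningSumResult-class
#' @export
permutationP <- function(x) x@p

#' @rdname RunningSumResult-class
#' @export
leadingEdge <- function(x) x@ranked[x@leadingEdge]
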