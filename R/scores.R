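#' @rdname FactorCounts-class
#' @param counts factor x sample count matrix.
#' @param colData per-sample annotation (`fraction`, `condition`,
#'   `replicate`, `plate`).
#' @param locus locus label.
#' @export
FactorCounts <- function(counts, colData, locus = "BC_UP") {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = as.matrix(counts)),
        colData = S4Vectors::DataFrame(colData))
    new("FactorCounts", se, locus = locus)
}

#' @rdname BindingScorePanel-class
#' @param score factor x replicate score matrix.
#' @param colData optional per-replicate annotation (`condition`,
#'   `replicate`).
#' @param locus locus label.
#' @export
BindingScorePanel <- function(score, colData = NULL, locus = "BC_UP") {
    score <- as.matrix(score)
    if (is.null(colData))
        colData <- S4Vectors::DataFrame(
            condition = "untreated", replicate = seq_len(ncol(score)),
            row.names = colnames(score))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(score = score), colData = S4Vectors::DataFrame(colData))
    new("BindingScorePanel", se, locus = locus)
}

#' Match barcode counts to factors through a strain map
#'
#' Rows of the count matrix are matched to the strain map's `barcode`
#' column for one locus; matched rows are relabeled by ORF (factor) name.
#' Barcodes absent from the map (typically sequencing-error variants) are
#' dropped with a message. The map must be one-to-one between barcodes and
#' factors at the locus.
#'
#' @param x a \linkS4class{BarcodeCounts}.
#' @param strainMap data.frame/DataFrame with columns `barcode`, `orf` and
#'   optionally `locus`.
#' @param locus locus label; used to subset the map when it has a `locus`
#'   column.
#' @return a \linkS4class{FactorCounts}.
#' @export
factorCounts <- function(x, strainMap, locus = "BC_UP") {
    sm <- as.data.frame(strainMap)
    if ("locus" %in% colnames(sm)) sm <- sm[sm$locus == locus, ]
    if (anyDuplicated(sm$barcode) || anyDuplicated(sm$orf))
        stop("strain map must be one-to-one between barcodes and factors")
    m <- counts(x)
    hit <- match(rownames(m), sm$barcode)
    dropped <- sum(is.na(hit))
    if (dropped)
        message(dropped, " barcode(s) not in the strain map were dropped")
    keep <- !is.na(hit)
    m <- m[keep, , drop = FALSE]
    rd <- S4Vectors::DataFrame(orf = sm$orf[hit[keep]],
                               barcode = rownames(m))
    rownames(m) <- rd$orf
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m), rowData = rd,
        colData = SummarizedExperiment::colData(x))
    new("FactorCounts", se, locus = locus)
}

#' Median-normalize counts across samples
#'
#' Each sample (column) is scaled by `reference median / sample median`,
#' where the sample median is taken over present (non-`NA`) counts and the
#' reference is the median of the per-sample medians. This corrects
#' plate-to-plate (and IP/input) differences in sequencing depth
#' multiplicatively on raw counts, before the log transform. After the
#' operation all per-sample medians are equal.
#'
#' @param x a \linkS4class{FactorCounts} (or \linkS4class{BarcodeCounts}).
#' @return the same class, with scaled counts.
#' @export
medianNormalize <- function(x) {
    m <- SummarizedExperiment::assay(x, "counts")
    med <- apply(m, 2L, stats::median, na.rm = TRUE)
    bad <- !is.finite(med) | med <= 0
    if (any(bad))
        stop("sample(s) with no usable counts: ",
             paste(colnames(m)[bad], collapse = ", "))
    ref <- stats::median(med)
    m <- sweep(m, 2L, ref / med, "*")
    SummarizedExperiment::assay(x, "counts") <- m
    x
}

#' Remove factors with low input counts
#'
#' Factors whose raw input count fails `minInput` in more than
#' `n_replicates - minReplicates` input samples are removed entirely:
#' such factors are likely missing from the library or their barcode failed
#' to amplify. Apply to raw (unnormalized) counts. `NA` counts fail the
#' threshold.
#'
#' @param x a \linkS4class{FactorCounts} whose `colData()$fraction` marks
#'   input samples.
#' @param minInput minimum raw input count (default 10, the global count
#'   floor).
#' @param minReplicates number of input replicates that must reach
#'   `minInput` (default 4).
#' @return the filtered \linkS4class{FactorCounts}.
#' @export
removeLowInput <- function(x, minInput = 10L, minReplicates = 4L) {
    stopifnot(minInput >= 0)
    cd <- SummarizedExperiment::colData(x)
    inp <- which(cd$fraction == "input")
    if (!length(inp)) stop("no input samples in colData()$fraction")
    m <- SummarizedExperiment::assay(x, "counts")[, inp, drop = FALSE]
    nOK <- rowSums(!is.na(m) & m >= minInput)
    x[nOK >= minReplicates, ]
}

#' Per-replicate log2 IP/input binding scores
#'
#' Pairs IP and input samples by (plate, condition, replicate) and computes
#' `score = log2(IP) - log2(input)` on (normalized) counts. A score is
#' absent (`NA`) when either side is absent or nonpositive. Samples without
#' a partner are an error.
#'
#' @param x a \linkS4class{FactorCounts} with `colData()` columns
#'   `fraction` (`"IP"`/`"input"`), `condition`, `replicate`, `plate`.
#' @return a \linkS4class{BindingScorePanel}, columns named
#'   `<condition>_rep<replicate>`.
#' @export
log2Scores <- function(x) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    stopifnot(all(c("fraction", "condition", "replicate") %in% colnames(cd)))
    if (!"plate" %in% colnames(cd)) cd$plate <- 1L
    key <- paste(cd$plate, cd$condition, cd$replicate, sep = "|")
    m <- SummarizedExperiment::assay(x, "counts")
    ip <- which(cd$fraction == "IP")
    inp <- which(cd$fraction == "input")
    orphan <- c(setdiff(key[ip], key[inp]), setdiff(key[inp], key[ip]))
    dupes <- c(key[ip][duplicated(key[ip])], key[inp][duplicated(key[inp])])
    if (length(orphan) || length(dupes))
        stop("IP/input samples not pairable by (plate, condition, ",
             "replicate): ", paste(unique(c(orphan, dupes)), collapse = ", "))
    ord <- order(cd$condition[ip], cd$replicate[ip])
    ip <- ip[ord]
    inp <- inp[match(key[ip], key[inp])]
    sm <- log2(m[, ip, drop = FALSE]) - log2(m[, inp, drop = FALSE])
    sm[!is.finite(sm)] <- NA
    colnames(sm) <- paste0(cd$condition[ip], "_rep", cd$replicate[ip])
    cdout <- S4Vectors::DataFrame(condition = cd$condition[ip],
                                  replicate = cd$replicate[ip],
                                  plate = cd$plate[ip],
                                  row.names = colnames(sm))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(score = sm),
        rowData = SummarizedExperiment::rowData(x), colData = cdout)
    new("BindingScorePanel", se, locus = locusLabel(x))
}

## rank-mean quantile normalization of the columns of a matrix, honouring
## NAs (absent values stay absent and do not enter the reference)
quantileNormalizeMatrix <- function(m) {
    nPresent <- colSums(!is.na(m))
    if (any(nPresent < 1L)) stop("a column has no present values")
    nmax <- max(nPresent)
    grid <- if (nmax == 1L) 0.5 else (seq_len(nmax) - 1) / (nmax - 1)
    ## reference distribution: mean of the per-column quantile curves
    refs <- vapply(seq_len(ncol(m)), function(j) {
        v <- sort(m[!is.na(m[, j]), j])
        if (length(v) == 1L) rep(v, nmax)
        else stats::approx(seq(0, 1, length.out = length(v)), v,
                           xout = grid)$y
    }, numeric(nmax))
    ref <- rowMeans(refs)
    out <- m
    for (j in seq_len(ncol(m))) {
        ok <- !is.na(m[, j])
        v <- m[ok, j]
        nj <- length(v)
        target <- if (nj == nmax) ref
                  else stats::approx(grid, ref,
                                     xout = (seq_len(nj) - 1) / (nj - 1))$y
        ord <- order(v)
        grp <- cumsum(!duplicated(v[ord]))  # tie groups in sorted order
        val <- stats::ave(target, grp, FUN = mean)  # mean of tied positions
        res <- numeric(nj)
        res[ord] <- val
        out[ok, j] <- res
    }
    out
}

#' Quantile-normalize binding scores across replicates
#'
#' Classic rank-mean quantile normalization within one locus: each
#' replicate's values are ranked and the value at each rank is replaced by
#' the across-replicate mean of that rank, forcing all replicates onto one
#' distribution (replicates can differ slightly in dynamic range). Ties take
#' the mean of the tied positions; absent values stay absent and are
#' excluded from the reference. When all replicates observe the same
#' factors, each replicate's sorted values are identical afterwards, and the
#' operation is idempotent.
#'
#' @param x a \linkS4class{BindingScorePanel} (>= 2 replicates) or a plain
#'   matrix.
#' @return the same class, normalized.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
#' quantileNormalize(m)
#' @export
quantileNormalize <- function(x) {
    if (is.matrix(x)) return(quantileNormalizeMatrix(x))
    stopifnot(is(x, "BindingScorePanel"), ncol(x) >= 2L)
    m <- SummarizedExperiment::assay(x, "score")
    SummarizedExperiment::assay(x, "score") <- quantileNormalizeMatrix(m)
    x
}

#' Subset a score panel to one condition
#'
#' @param x a \linkS4class{BindingScorePanel}.
#' @param condition condition label to keep.
#' @return the subsetted panel.
#' @export
conditionPanel <- function(x, condition) {
    keep <- SummarizedExperiment::colData(x)$condition == condition
    if (!any(keep)) stop("no replicates with condition '", condition, "'")
    x[, keep]
}
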