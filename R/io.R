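#' Read and write barcode count tables as long-format TSV
#'
#' The interchange format is a three-column TSV (`barcode`, `index`,
#' `count`); the rejection tally travels as comment header lines
#' (`# rejected <reason> <n>`).
#'
#' @param x a \linkS4class{BarcodeCounts}.
#' @param path file path.
#' @return `writeCountsTSV()` returns `path` invisibly; `readCountsTSV()`
#'   returns a \linkS4class{BarcodeCounts}.
#' @export
writeCountsTSV <- function(x, path) {
    m <- counts(x)
    rej <- rejectedReads(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# rejected %s %d", names(rej), as.integer(rej)),
               con)
    idx <- which(!is.na(m) & m > 0, arr.ind = TRUE)
    df <- data.frame(barcode = rownames(m)[idx[, 1L]],
                     index = colnames(m)[idx[, 2L]],
                     count = m[idx])
    df <- df[order(df$barcode, df$index), ]
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountsTSV
#' @export
readCountsTSV <- function(path) {
    hdr <- readLines(path, n = 50L)
    rejLines <- grep("^# rejected ", hdr, value = TRUE)
    rej <- c(no_anchor = 0L, truncated = 0L, ambiguous_base = 0L)
    for (l in rejLines) {
        p <- strsplit(sub("^# rejected ", "", l), " ")[[1L]]
        rej[p[1L]] <- as.integer(p[2L])
    }
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    ubc <- sort(unique(df$barcode)); uix <- sort(unique(df$index))
    m <- matrix(0L, length(ubc), length(uix), dimnames = list(ubc, uix))
    m[cbind(match(df$barcode, ubc), match(df$index, uix))] <-
        as.integer(df$count)
    BarcodeCounts(m, rejected = rej)
}

#' Read a sample sheet
#'
#' TSV with columns `index`, `plate`, `fraction` (`IP`/`input`),
#' `condition`, `replicate`; every (plate, fraction, condition, replicate)
#' combination must be unique.
#'
#' @param path file path.
#' @return a [S4Vectors::DataFrame], row names = indexes.
#' @export
readSampleSheet <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("index", "plate", "fraction", "condition", "replicate")
    stopifnot(all(need %in% colnames(df)))
    if (!all(df$fraction %in% c("IP", "input")))
        stop("fraction must be 'IP' or 'input'")
    key <- do.call(paste, df[c("plate", "fraction", "condition",
                               "replicate")])
    if (anyDuplicated(key))
        stop("duplicate (plate, fraction, condition, replicate) entries")
    S4Vectors::DataFrame(df, row.names = df$index)
}

#' Attach a sample sheet to barcode counts
#'
#' Subsets the count matrix to the sheet's indexes (in sheet order) and
#' installs the sheet as `colData()`.
#'
#' @param x a \linkS4class{BarcodeCounts}.
#' @param sheet result of [readSampleSheet()].
#' @return the annotated \linkS4class{BarcodeCounts}.
#' @export
applySampleSheet <- function(x, sheet) {
    hit <- match(rownames(sheet), colnames(x))
    if (anyNA(hit))
        stop("indexes absent from the counts: ",
             paste(rownames(sheet)[is.na(hit)], collapse = ", "))
    out <- x[, hit]
    SummarizedExperiment::colData(out) <- sheet
    out
}

#' Read a strain (barcode to factor) map
#'
#' TSV with columns `barcode`, `orf` and optionally `locus`.
#'
#' @param path file path.
#' @return a [S4Vectors::DataFrame].
#' @export
readStrainMap <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("barcode", "orf") %in% colnames(df)))
    S4Vectors::DataFrame(df)
}

#' Read a pool map
#'
#' TSV with columns `pool`, `plate`, `axis` (`row`/`column`), `label` and
#' optionally `index` (the pool's sample index).
#'
#' @param path file path.
#' @return a [S4Vectors::DataFrame].
#' @export
readPoolMap <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("pool", "plate", "axis", "label") %in% colnames(df)))
    if (!all(df$axis %in% c("row", "column")))
        stop("axis must be 'row' or 'column'")
    S4Vectors::DataFrame(df)
}

#' Write a simulated truth table as TSV
#'
#' Columns: `strain_id`, `orf`, `barcode`, `plate`, `row`, `col`,
#' `effect_UP`, `effect_DN`, `abundance`.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeTruthTSV <- function(truth, path) {
    st <- as.data.frame(strains(truth))
    eff <- trueEffects(truth)
    st$effect_UP <- eff[, "BC_UP"]
    st$effect_DN <- eff[, "BC_DN"]
    st$abundance <- abundances(truth)
    utils::write.table(st, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a decode plate map as TSV
#'
#' @param report result of [decodeReport()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writePlateMap <- function(report, path) {
    utils::write.table(report$plateMap, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
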