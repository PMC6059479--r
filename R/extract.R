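#' Locate the constant-region anchor in reads
#'
#' Returns, per read, the leftmost 0-based position inside the design's
#' search window at which the constant region matches with at most
#' `maxAnchorMismatches` substitutions, or `NA` when no window position
#' matches. Ties (several admissible positions) resolve to the leftmost for
#' determinism.
#'
#' @param reads character vector or [Biostrings::DNAStringSet] of reads.
#' @param design an \linkS4class{AmpliconDesign}.
#' @return integer vector of 0-based anchor start positions (`NA` = absent).
#' @examples
#' d <- kanmxDesign(maxAnchorMismatches = 0)
#' locateAnchor(constantRegion(d), d)  # anchor verbatim at position 0
#' @export
locateAnchor <- function(reads, design) {
    dna <- if (is(reads, "DNAStringSet")) reads
           else Biostrings::DNAStringSet(reads)
    hits <- Biostrings::vmatchPattern(
        design@constantRegion, dna,
        max.mismatch = design@maxAnchorMismatches, fixed = TRUE)
    starts <- Biostrings::startIndex(hits)
    nhit <- S4Vectors::elementNROWS(hits)
    ul <- unlist(starts, use.names = FALSE)
    out <- rep(NA_integer_, length(dna))
    if (!length(ul)) return(out)
    idx <- rep(seq_along(dna), nhit)
    w <- design@searchWindow
    keep <- ul >= w[1L] + 1L & ul <= w[2L] + 1L
    idx <- idx[keep]; ul <- ul[keep]
    first <- !duplicated(idx)  # per-read starts are ascending: first = leftmost
    out[idx[first]] <- ul[first] - 1L
    out
}

#' Extract sample index and clone barcode from reads
#'
#' On an anchor hit, slices the index and barcode intervals at their
#' configured sides and offsets (0-based, half-open). A read is rejected as
#' `no_anchor` when the anchor is absent, `truncated` when either interval
#' runs off an end of the read, or `ambiguous_base` when a sliced interval
#' contains a non-ACGT character. Rejections are values, not errors.
#'
#' @param reads character vector or [Biostrings::DNAStringSet].
#' @param design an \linkS4class{AmpliconDesign}.
#' @param anchorStart optional precomputed result of [locateAnchor()].
#' @return a [S4Vectors::DataFrame] with columns `index`, `barcode` (both
#'   `NA` unless accepted) and `status` (one of `accepted`, `no_anchor`,
#'   `truncated`, `ambiguous_base`).
#' @examples
#' d <- kanmxDesign()
#' rd <- paste0("ACGTAC", constantRegion(d), strrep("GATC", 5))
#' extractReads(rd, d)
#' @export
extractReads <- function(reads, design, anchorStart = NULL) {
    if (is(reads, "DNAStringSet")) reads <- as.character(reads)
    if (is.null(anchorStart)) anchorStart <- locateAnchor(reads, design)
    n <- length(reads)
    len <- nchar(reads)
    aStart <- anchorStart
    aEnd <- aStart + nchar(design@constantRegion)
    interval <- function(side, offset, width) {
        s <- if (side == "upstream") aStart - offset - width
             else aEnd + offset
        cbind(start = s, end = s + width)
    }
    iv <- interval(design@indexSide, design@indexOffset, design@indexLength)
    bv <- interval(design@barcodeSide, design@barcodeOffset,
                   design@barcodeLength)
    status <- rep("accepted", n)
    status[is.na(aStart)] <- "no_anchor"
    trunc <- !is.na(aStart) &
        (iv[, 1L] < 0L | bv[, 1L] < 0L | iv[, 2L] > len | bv[, 2L] > len)
    status[trunc] <- "truncated"
    ok <- status == "accepted"
    index <- barcode <- rep(NA_character_, n)
    if (any(ok)) {
        index[ok] <- substr(reads[ok], iv[ok, 1L] + 1L, iv[ok, 2L])
        barcode[ok] <- substr(reads[ok], bv[ok, 1L] + 1L, bv[ok, 2L])
        amb <- ok & (grepl("[^ACGT]", index) | grepl("[^ACGT]", barcode))
        status[amb] <- "ambiguous_base"
        index[amb] <- NA_character_
        barcode[amb] <- NA_character_
    }
    S4Vectors::DataFrame(index = index, barcode = barcode, status = status)
}

## tally one batch of extractions into a long data.frame + rejection vector
tallyExtraction <- function(ext) {
    rej <- c(no_anchor = sum(ext$status == "no_anchor"),
             truncated = sum(ext$status == "truncated"),
             ambiguous_base = sum(ext$status == "ambiguous_base"))
    ok <- ext$status == "accepted"
    if (!any(ok))
        return(list(long = data.frame(barcode = character(),
                                      index = character(),
                                      count = integer()),
                    rejected = rej))
    tab <- table(barcode = ext$barcode[ok], index = ext$index[ok])
    long <- as.data.frame(tab, stringsAsFactors = FALSE,
                          responseName = "count")
    list(long = long[long$count > 0L, ], rejected = rej)
}

## combine long (barcode, index, count) frames into a BarcodeCounts
longToCounts <- function(long, rejected) {
    if (is.null(long) || !nrow(long)) {
        m <- matrix(0L, 0L, 0L, dimnames = list(character(), character()))
        return(BarcodeCounts(m, rejected = rejected))
    }
    key <- paste(long$barcode, long$index, sep = "\r")
    agg <- rowsum(long$count, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    bc <- vapply(parts, `[`, "", 1L)
    ix <- vapply(parts, `[`, "", 2L)
    ubc <- sort(unique(bc)); uix <- sort(unique(ix))
    m <- matrix(0L, length(ubc), length(uix),
                dimnames = list(ubc, uix))
    m[cbind(match(bc, ubc), match(ix, uix))] <- as.integer(agg[, 1L])
    BarcodeCounts(m, rejected = rejected)
}

## structural FASTQ check: 4-line records, '@' header, '+' separator,
## sequence and quality of equal length; errors name the offending record
validateFastq <- function(path, chunkLines = 2e6) {
    con <- if (endsWith(path, ".gz")) gzfile(path, "r") else file(path, "r")
    on.exit(close(con))
    rec <- 0L
    repeat {
        lines <- readLines(con, n = chunkLines)
        if (!length(lines)) break
        if (length(lines) %% 4L != 0L)
            stop("malformed FASTQ near record ", rec + length(lines) %/% 4L +
                 1L, " in '", path, "': truncated record", call. = FALSE)
        i <- seq(1L, length(lines), by = 4L)
        badHdr <- !startsWith(lines[i], "@")
        badSep <- !startsWith(lines[i + 2L], "+")
        badLen <- nchar(lines[i + 1L]) != nchar(lines[i + 3L]) |
            nchar(lines[i + 1L]) == 0L
        bad <- badHdr | badSep | badLen
        if (any(bad))
            stop("malformed FASTQ near record ", rec + which(bad)[1L],
                 " in '", path, "'", call. = FALSE)
        rec <- rec + length(i)
    }
    invisible(rec)
}

#' @rdname countBarcodes
#' @param chunkSize FASTQ records read per chunk (file input); memory use is
#'   bounded by the chunk, not the file.
#' @export
setMethod("countBarcodes", c("character", "AmpliconDesign"),
    function(reads, design, chunkSize = 5e5) {
        for (f in reads) validateFastq(f)
        longs <- list()
        rej <- c(no_anchor = 0L, truncated = 0L, ambiguous_base = 0L)
        for (f in reads) {
            skip <- 0
            repeat {
                chunk <- tryCatch(
                    Biostrings::readDNAStringSet(f, format = "fastq",
                                                 nrec = chunkSize,
                                                 skip = skip),
                    error = function(e) stop(
                        "malformed FASTQ near record ", skip + 1L,
                        " in '", f, "': ", conditionMessage(e),
                        call. = FALSE))
                if (!length(chunk)) break
                tl <- tallyExtraction(extractReads(chunk, design))
                longs[[length(longs) + 1L]] <- tl$long
                rej <- rej + tl$rejected
                if (length(chunk) < chunkSize) break
                skip <- skip + chunkSize
            }
        }
        longToCounts(do.call(rbind, longs), rej)
    })

#' @rdname countBarcodes
#' @export
setMethod("countBarcodes", c("DNAStringSet", "AmpliconDesign"),
    function(reads, design, ...) {
        tl <- tallyExtraction(extractReads(reads, design))
        longToCounts(tl$long, tl$rejected)
    })
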