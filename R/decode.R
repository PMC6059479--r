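#' Call barcodes present in each sequencing pool
#'
#' A barcode is called in a pool when its read count with that pool's index
#' reaches `minReads`. The decoding protocol uses thresholds of 50 (default)
#' or 100 reads.
#'
#' @param x a \linkS4class{BarcodeCounts} (columns = pool indexes or pool
#'   ids) or a plain count matrix.
#' @param minReads minimum supporting reads (>= 1).
#' @return named list: per pool, the character vector of called barcodes.
#' @examples
#' m <- matrix(c(49L, 50L), 2, dimnames = list(c("b1", "b2"), "pool1"))
#' callPoolBarcodes(m)  # only b2 reaches the default threshold
#' @export
callPoolBarcodes <- function(x, minReads = 50L) {
    stopifnot(minReads >= 1)
    m <- if (is(x, "BarcodeCounts")) counts(x) else as.matrix(x)
    out <- lapply(seq_len(ncol(m)), function(j)
        rownames(m)[!is.na(m[, j]) & m[, j] >= minReads])
    names(out) <- colnames(m)
    out
}

#' Decode well coordinates from row- and column-pool calls
#'
#' For every barcode, all (row, column) pairs in which it is called in both
#' the row pool and the column pool of the same plate are enumerated.
#' Exactly one pair makes a tentative assignment; more than one pair rejects
#' the barcode (`rejected-multimatch`); support in some pool but no complete
#' pair leaves it `unassigned`. Finally, any well tentatively holding more
#' than one barcode rejects all of its barcodes (`rejected-collision`).
#'
#' @param calls named list of per-pool barcode calls
#'   (from [callPoolBarcodes()]); names must be pool ids or pool indexes
#'   present in `poolMap`.
#' @param poolMap a data.frame/DataFrame with columns `pool`, `plate`,
#'   `axis` (`"row"`/`"column"`), `label`, and optionally `index`; call
#'   names are matched against `pool`, falling back to `index`.
#' @param counts optional \linkS4class{BarcodeCounts} used to report
#'   supporting reads for assigned barcodes.
#' @return a [S4Vectors::DataFrame] (one row per barcode) with columns
#'   `barcode`, `status`, `plate`, `row`, `col`, `row_reads`, `col_reads`.
#' @export
decodeCoordinates <- function(calls, poolMap, counts = NULL) {
    pm <- as.data.frame(poolMap)
    key <- names(calls)
    poolOf <- pm$pool[match(key, pm$pool)]
    if (anyNA(poolOf) && "index" %in% colnames(pm)) {
        alt <- pm$pool[match(key, pm$index)]
        poolOf[is.na(poolOf)] <- alt[is.na(poolOf)]
    }
    unknown <- is.na(poolOf)
    if (any(unknown))
        warning(sum(unknown), " pool(s) in the calls are absent from the ",
                "pool map and were skipped: ",
                paste(utils::head(key[unknown], 5L), collapse = ", "))
    long <- data.frame(
        barcode = unlist(calls[!unknown], use.names = FALSE),
        pool = rep(poolOf[!unknown],
                   lengths(calls[!unknown])))
    long <- cbind(long, pm[match(long$pool, pm$pool),
                           c("plate", "axis", "label")])
    rows <- long[long$axis == "row", ]
    cols <- long[long$axis == "column", ]
    pairs <- merge(rows[, c("barcode", "plate", "label", "pool")],
                   cols[, c("barcode", "plate", "label", "pool")],
                   by = c("barcode", "plate"),
                   suffixes = c("_row", "_col"))
    allbc <- unique(long$barcode)
    npairs <- as.vector(table(factor(pairs$barcode, levels = allbc)))
    status <- ifelse(npairs == 1L, "assigned",
                     ifelse(npairs > 1L, "rejected-multimatch",
                            "unassigned"))
    names(status) <- allbc
    out <- S4Vectors::DataFrame(
        barcode = allbc,
        status = unname(status[allbc]),
        plate = NA_integer_, row = NA_character_, col = NA_integer_,
        row_reads = NA_integer_, col_reads = NA_integer_)
    one <- pairs[pairs$barcode %in% allbc[status == "assigned"], ]
    i <- match(one$barcode, out$barcode)
    out$plate[i] <- as.integer(one$plate)
    out$row[i] <- one$label_row
    out$col[i] <- as.integer(one$label_col)
    ## well collisions: >1 tentative barcode at one coordinate
    wells <- paste(one$plate, one$label_row, one$label_col)
    clash <- wells %in% wells[duplicated(wells)]
    if (any(clash)) {
        j <- i[clash]
        out$status[j] <- "rejected-collision"
        out$plate[j] <- NA_integer_
        out$row[j] <- NA_character_
        out$col[j] <- NA_integer_
    }
    if (!is.null(counts)) {
        m <- counts(counts)
        colkey <- colnames(m)
        cd <- as.data.frame(SummarizedExperiment::colData(counts))
        poolcol <- if ("pool" %in% colnames(cd)) cd$pool else colkey
        lookup <- function(bc, pool) {
            jj <- match(pool, poolcol)
            ii <- match(bc, rownames(m))
            val <- rep(NA_integer_, length(bc))
            okk <- !is.na(jj) & !is.na(ii)
            val[okk] <- m[cbind(ii[okk], jj[okk])]
            val
        }
        asg <- out$status == "assigned"
        k <- match(out$barcode[asg], one$barcode)
        out$row_reads[asg] <- lookup(out$barcode[asg], one$pool_row[k])
        out$col_reads[asg] <- lookup(out$barcode[asg], one$pool_col[k])
    }
    out
}

#' Summarize a plate decode
#'
#' @param assignment result of [decodeCoordinates()].
#' @param plates plates to lay out in the plate map; defaults to the plates
#'   seen among assigned barcodes.
#' @return a list with `summary` (per-status barcode counts, plus assigned
#'   per plate) and `plateMap` (one row per well: `plate`, `row`, `col`,
#'   `barcode`, `status` of `assigned` or `empty`).
#' @export
decodeReport <- function(assignment, plates = NULL) {
    a <- as.data.frame(assignment)
    statuses <- c("assigned", "rejected-multimatch", "rejected-collision",
                  "unassigned")
    summary <- data.frame(
        status = statuses,
        n = vapply(statuses, function(s) sum(a$status == s), 0L))
    if (is.null(plates))
        plates <- sort(unique(a$plate[!is.na(a$plate)]))
    pmap <- do.call(rbind, lapply(plates, function(p)
        data.frame(plate = p,
                   row = rep(LETTERS[1:16], each = 24L),
                   col = rep(1:24, times = 16L))))
    if (is.null(pmap))
        pmap <- data.frame(plate = integer(), row = character(),
                           col = integer())
    hit <- match(paste(pmap$plate, pmap$row, pmap$col),
                 paste(a$plate, a$row, a$col))
    pmap$barcode <- a$barcode[hit]
    pmap$status <- ifelse(is.na(hit), "empty", "assigned")
    list(summary = summary, plateMap = pmap)
}
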