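#' @rdname SimulationConfig-class
#' @param nStrains,nReplicates,depth,dispersion,errorRate,fracBinders,effectMean,effectSd,seed
#'   see the class slots. Defaults emulate the screen's design: ~4,000
#'   clones, 6 biological replicates, a million reads per sample, mild
#'   overdispersion, and roughly 12% of factors bound with effects around
#'   1 log2 unit.
#' @export
SimulationConfig <- function(nStrains = 4000L, nReplicates = 6L,
                             depth = 1e6, dispersion = 0.05,
                             errorRate = 0.001, fracBinders = 0.12,
                             effectMean = 1.0, effectSd = 0.5,
                             seed = 1L) {
    new("SimulationConfig",
        nStrains = as.integer(nStrains),
        nReplicates = as.integer(nReplicates),
        depth = as.numeric(depth),
        dispersion = as.numeric(dispersion),
        errorRate = as.numeric(errorRate),
        fracBinders = as.numeric(fracBinders),
        effectMean = as.numeric(effectMean),
        effectSd = as.numeric(effectSd),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nStrains, "strains x",
        object@nReplicates, "replicates, depth", format(object@depth),
        "\n  dispersion", object@dispersion, "| errorRate", object@errorRate,
        "| fracBinders", object@fracBinders,
        "| effects ~ N(", object@effectMean, ",", object@effectSd,
        ") truncated >= 0 | seed", object@seed, "\n")
})

#' @rdname SyntheticTruth-class
#' @export
setMethod("strains", "SyntheticTruth", function(x) x@strains)

#' @rdname SyntheticTruth-class
#' @export
setMethod("trueEffects", "SyntheticTruth", function(x) x@effects)

#' @rdname SyntheticTruth-class
#' @export
setMethod("abundances", "SyntheticTruth", function(x) x@abundance)

setMethod("show", "SyntheticTruth", function(object) {
    st <- object@strains
    cat("SyntheticTruth:", nrow(st), "strains on",
        length(unique(st$plate)), "plate(s), barcode length",
        nchar(st$barcode[1L]), "\n")
    for (l in colnames(object@effects))
        cat("  ", l, ": ", sum(object@effects[, l] > 0), " true binders\n",
            sep = "")
})

## distinct random k-mers; redraws collisions, erroring after maxRedraws
## rounds (a persistent collision signals the barcode length is too short)
randomKmers <- function(n, k, avoid = character(), maxRedraws = 100L) {
    draw <- function(m) {
        m0 <- matrix(sample(c("A", "C", "G", "T"), m * k, replace = TRUE),
                     nrow = m)
        apply(m0, 1L, paste, collapse = "")
    }
    out <- draw(n)
    for (i in seq_len(maxRedraws)) {
        bad <- duplicated(out) | out %in% avoid
        if (!any(bad)) return(out)
        out[bad] <- draw(sum(bad))
    }
    stop("could not draw ", n, " distinct ", k,
         "-mers after ", maxRedraws, " redraws; barcode length too short")
}

## Normal(mean, sd) truncated at 0, drawn by inverse CDF so the number of
## RNG draws is fixed
rtruncnorm0 <- function(n, mean, sd) {
    if (sd == 0) return(rep(max(mean, 0), n))
    lo <- stats::pnorm(0, mean, sd)
    stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Simulate a barcoded strain library with ground truth
#'
#' Draws a library of `nStrains` clones with unique random barcodes of the
#' design's barcode length, lays them out row-major across 384-well plates
#' (rows A-P, columns 1-24), assigns each strain a log-normal relative input
#' abundance, and draws true per-locus log2 binding effects: with
#' probability `fracBinders` a Normal(`effectMean`, `effectSd`) truncated at
#' 0, otherwise exactly 0. Effects at the two flanking loci (`BC_UP`,
#' `BC_DN`) are drawn independently. Deterministic given `config@seed`.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param design an \linkS4class{AmpliconDesign}; sets the barcode length.
#' @return a \linkS4class{SyntheticTruth}.
#' @examples
#' truth <- simulateLibrary(SimulationConfig(nStrains = 384, seed = 1))
#' truth
#' @export
simulateLibrary <- function(config, design = kanmxDesign()) {
    stopifnot(is(config, "SimulationConfig"), is(design, "AmpliconDesign"))
    n <- config@nStrains
    set.seed(config@seed)
    barcodes <- randomKmers(n, design@barcodeLength)
    i <- seq_len(n) - 1L
    well <- i %% 384L
    st <- S4Vectors::DataFrame(
        strain_id = sprintf("S%05d", seq_len(n)),
        orf = sprintf("ORF%05d", seq_len(n)),
        barcode = barcodes,
        plate = i %/% 384L + 1L,
        row = LETTERS[well %/% 24L + 1L],
        col = well %% 24L + 1L)
    abundance <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
    eff <- vapply(c(BC_UP = 1L, BC_DN = 2L), function(...) {
        isB <- stats::runif(n) < config@fracBinders
        e <- numeric(n)
        e[isB] <- rtruncnorm0(sum(isB), config@effectMean, config@effectSd)
        e
    }, numeric(n))
    rownames(eff) <- st$strain_id
    new("SyntheticTruth", strains = st, effects = eff,
        abundance = abundance, seed = config@seed)
}

#' Simulate IP and input barcode counts
#'
#' For each replicate, input counts are drawn negative-binomially with mean
#' `depth * abundance / sum(abundance)` and the configured overdispersion
#' (`dispersion = 0` reduces to Poisson); IP counts have mean
#' `input mean * 2^effect * scale_r`, where `scale_r` is a per-IP-sample
#' scale drawn log-uniformly in \[0.5, 2\] to exercise normalization.
#' Samples get unique random 6-bp indexes; the sample sheet (fraction,
#' condition, replicate, plate) is carried in `colData()`.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param locus which locus' effects apply (`"BC_UP"` or `"BC_DN"`).
#' @param condition condition label recorded in the sample sheet.
#' @param seed seed for this draw; defaults to `config@seed`.
#' @return a \linkS4class{BarcodeCounts} (rows = barcodes, columns = sample
#'   indexes).
#' @examples
#' cfg <- SimulationConfig(nStrains = 50, nReplicates = 2, depth = 5e3,
#'                         seed = 3)
#' bc <- simulateCounts(simulateLibrary(cfg), cfg)
#' SummarizedExperiment::colData(bc)
#' @export
simulateCounts <- function(truth, config, locus = c("BC_UP", "BC_DN"),
                           condition = "untreated", seed = config@seed) {
    stopifnot(is(truth, "SyntheticTruth"), is(config, "SimulationConfig"))
    locus <- match.arg(locus)
    n <- nrow(truth@strains)
    stopifnot(n == config@nStrains)
    nr <- config@nReplicates
    set.seed(seed)
    idx <- randomKmers(2L * nr, 6L)
    scale_r <- exp(stats::runif(nr, log(0.5), log(2)))
    inputMean <- config@depth * truth@abundance / sum(truth@abundance)
    effect <- truth@effects[, locus]
    rcount <- function(mu) {
        as.integer(if (config@dispersion == 0) stats::rpois(n, mu)
                   else stats::rnbinom(n, mu = mu,
                                       size = 1 / config@dispersion))
    }
    m <- matrix(0L, n, 2L * nr,
                dimnames = list(truth@strains$barcode, idx))
    fraction <- rep(c("input", "IP"), nr)
    replicate <- rep(seq_len(nr), each = 2L)
    for (r in seq_len(nr)) {
        m[, 2L * r - 1L] <- rcount(inputMean)
        m[, 2L * r] <- rcount(inputMean * 2^effect * scale_r[r])
    }
    cd <- S4Vectors::DataFrame(
        index = idx, plate = 1L, fraction = fraction,
        condition = condition, replicate = replicate,
        row.names = idx)
    BarcodeCounts(m, colData = cd)
}

## Lay out index/barcode segments around the anchor as the design dictates;
## gaps introduced by nonzero offsets are filled with 'A'.
assembleReads <- function(design, index, barcode) {
    pieces <- list(index = index, barcode = barcode)
    sides <- c(index = design@indexSide, barcode = design@barcodeSide)
    offs <- c(index = design@indexOffset, barcode = design@barcodeOffset)
    lens <- c(index = design@indexLength, barcode = design@barcodeLength)
    sideStr <- function(side) {
        nm <- names(sides)[sides == side]
        if (!length(nm)) return("")
        tot <- max(offs[nm] + lens[nm])
        ## token list from the far end toward the anchor (upstream) or from
        ## the anchor outward (downstream); both reduce to position filling
        chunks <- character(0)
        pos <- 0L  # bases filled, counting from the anchor outward
        for (p in nm[order(offs[nm])]) {
            gap <- offs[[p]] - pos
            chunks <- c(chunks, if (gap > 0L) strrep("A", gap) else NULL,
                        p)
            pos <- offs[[p]] + lens[[p]]
        }
        if (side == "upstream") rev(chunks) else chunks
    }
    cat1 <- function(tokens) {
        if (!length(tokens) || identical(tokens, "")) return("")
        parts <- lapply(tokens, function(tk)
            if (tk %in% names(pieces)) pieces[[tk]] else tk)
        do.call(paste0, parts)
    }
    paste0(cat1(sideStr("upstream")), design@constantRegion,
           cat1(sideStr("downstream")))
}

## i.i.d. per-base substitution errors at rate `errorRate`
injectErrors <- function(reads, errorRate) {
    if (errorRate == 0 || !length(reads)) return(reads)
    L <- nchar(reads[1L])
    nerr <- stats::rbinom(length(reads), L, errorRate)
    subst <- function(x, pos) {
        old <- substr(x, pos, pos)
        pick <- ceiling(stats::runif(length(x)) * 3)
        alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))
        newb <- alt[cbind(match(old, rownames(alt)), pick)]
        paste0(substr(x, 1L, pos - 1L), newb,
               substr(x, pos + 1L, L))
    }
    one <- which(nerr == 1L)
    if (length(one)) {
        pos <- ceiling(stats::runif(length(one)) * L)
        reads[one] <- subst(reads[one], pos)
    }
    multi <- which(nerr >= 2L)
    for (i in multi) {
        for (p in sample.int(L, nerr[i]))
            reads[i] <- subst(reads[i], p)
    }
    reads
}

#' Simulate amplicon reads from a count matrix
#'
#' Emits exactly one read per count unit, assembled as the design dictates
#' (sample index, constant region, clone barcode), with i.i.d. substitution
#' errors at `errorRate` and a constant quality string (`"I"`); extraction
#' never uses base qualities. Deterministic given `seed`: reads are emitted
#' column by column, barcode by barcode.
#'
#' @param x a \linkS4class{BarcodeCounts} (columns named by index sequence)
#'   or a plain count matrix with barcode rownames and index colnames.
#' @param design an \linkS4class{AmpliconDesign}.
#' @param errorRate per-base substitution probability.
#' @param seed RNG seed for the error process.
#' @param filepath if non-`NULL`, a FASTQ file (gzip if the name ends in
#'   `.gz`) is written and the path returned invisibly.
#' @return a [Biostrings::DNAStringSet] of reads (invisibly, if written to
#'   file).
#' @export
simulateReads <- function(x, design, errorRate = 0, seed = 1L,
                          filepath = NULL) {
    m <- if (is(x, "BarcodeCounts")) counts(x) else as.matrix(x)
    m[is.na(m)] <- 0L
    set.seed(seed)
    reads <- character(0)
    for (j in seq_len(ncol(m))) {
        cnt <- m[, j]
        keep <- cnt > 0
        if (!any(keep)) next
        bcs <- rep(rownames(m)[keep], cnt[keep])
        reads <- c(reads,
                   assembleReads(design, colnames(m)[j], bcs))
    }
    reads <- injectErrors(reads, errorRate)
    dna <- Biostrings::DNAStringSet(reads)
    if (length(dna))
        names(dna) <- sprintf("read%07d", seq_along(dna))
    if (!is.null(filepath)) {
        qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(dna)))
        Biostrings::writeXStringSet(
            dna, filepath, format = "fastq", qualities = qual,
            compress = endsWith(filepath, ".gz"))
        return(invisible(filepath))
    }
    dna
}

#' Simulate row- and column-pool sequencing of an arrayed library
#'
#' For every plate in the layout, emits one pool per row (16) and one per
#' column (24). Each strain contributes reads to the pools of its well with
#' expected per-strain depth `depthPerPool` (Poisson); with probability
#' `dropout` a strain is silently omitted from a pool (independently per
#' pool), exercising the decoder's rejection logic. Pools carry unique 6-bp
#' indexes recorded in the pool map.
#'
#' @param truth a \linkS4class{SyntheticTruth} with a plate layout.
#' @param depthPerPool expected reads per strain per pool.
#' @param dropout probability a strain is missing from one pool.
#' @param seed RNG seed.
#' @param design amplicon design used when writing pool reads.
#' @param dir if non-`NULL`, per-pool FASTQ files (`<pool>.fastq`) are
#'   written there.
#' @param errorRate per-base substitution rate for written reads.
#' @return a list with `counts` (a \linkS4class{BarcodeCounts}, columns =
#'   pool indexes), `poolMap` (pool, plate, axis, label, index), and
#'   `dropped` (strain_id, pool pairs omitted).
#' @examples
#' truth <- simulateLibrary(SimulationConfig(nStrains = 384, seed = 1),
#'                          ade2Design())
#' pools <- simulatePools(truth, depthPerPool = 100, seed = 2)
#' nrow(pools$poolMap)  # 16 row + 24 column pools
#' @export
simulatePools <- function(truth, depthPerPool = 500, dropout = 0,
                          seed = 1L, design = ade2Design(), dir = NULL,
                          errorRate = 0) {
    stopifnot(is(truth, "SyntheticTruth"), depthPerPool > 0,
              dropout >= 0, dropout < 1)
    st <- truth@strains
    set.seed(seed)
    plates <- sort(unique(st$plate))
    pm <- do.call(rbind, lapply(plates, function(p) rbind(
        data.frame(pool = sprintf("P%02d_row%s", p, LETTERS[1:16]),
                   plate = p, axis = "row", label = LETTERS[1:16]),
        data.frame(pool = sprintf("P%02d_col%02d", p, 1:24),
                   plate = p, axis = "column", label = as.character(1:24)))))
    pm$index <- randomKmers(nrow(pm), 6L)
    rowPool <- sprintf("P%02d_row%s", st$plate, st$row)
    colPool <- sprintf("P%02d_col%02d", st$plate, st$col)
    member <- data.frame(
        strain = rep(st$strain_id, 2L),
        barcode = rep(st$barcode, 2L),
        pool = c(rowPool, colPool))
    drop <- stats::runif(nrow(member)) < dropout
    dropped <- S4Vectors::DataFrame(strain_id = member$strain[drop],
                                    pool = member$pool[drop])
    member <- member[!drop, ]
    m <- matrix(0L, nrow(st), nrow(pm),
                dimnames = list(st$barcode, pm$index))
    cnt <- stats::rpois(nrow(member), depthPerPool)
    m[cbind(match(member$barcode, rownames(m)),
            match(member$pool, pm$pool))] <- cnt
    cd <- S4Vectors::DataFrame(pm, row.names = pm$index)
    bc <- BarcodeCounts(m, colData = cd)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        for (k in seq_len(nrow(pm))) {
            simulateReads(m[, k, drop = FALSE], design,
                          errorRate = errorRate, seed = seed + k,
                          filepath = file.path(dir,
                                               paste0(pm$pool[k], ".fastq")))
        }
    }
    list(counts = bc, poolMap = S4Vectors::DataFrame(pm), dropped = dropped)
}

#' Strain map (barcode to factor) derived from a simulated truth
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param locus locus label recorded in the map.
#' @return a [S4Vectors::DataFrame] with columns `barcode`, `orf`, `locus`,
#'   the format expected by [factorCounts()].
#' @export
truthStrainMap <- function(truth, locus = "BC_UP") {
    st <- strains(truth)
    S4Vectors::DataFrame(barcode = st$barcode, orf = st$orf, locus = locus)
}
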