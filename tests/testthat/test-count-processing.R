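## a hand-built FactorCounts: nf factors x (nr input + nr IP) samples
makeFC <- function(m, fraction, replicate, condition = "untreated",
                   locus = "BC_UP") {
    cd <- S4Vectors::DataFrame(fraction = fraction, replicate = replicate,
                               condition = condition, plate = 1L,
                               row.names = colnames(m))
    FactorCounts(m, cd, locus = locus)
}

test_that("factorCounts maps barcodes to factors one-to-one and drops strangers", {
    tp <- toyPipeline(nStrains = 30, seed = 51)
    sm <- truthStrainMap(tp$truth)
    fc <- factorCounts(tp$counts, sm)
    expect_s4_class(fc, "FactorCounts")
    expect_equal(rownames(fc), as.character(sm$orf))
    expect_equal(locusLabel(fc), "BC_UP")
    ## unknown barcodes (e.g. sequencing-error variants) are dropped
    m <- counts(tp$counts)
    extra <- rbind(m, ERRBC = rep(1L, ncol(m)))
    rownames(extra)[nrow(extra)] <- strrep("A", 20)
    bc2 <- BarcodeCounts(extra,
                         colData = SummarizedExperiment::colData(tp$counts))
    expect_message(fc2 <- factorCounts(bc2, sm), "1 barcode")
    expect_equal(nrow(fc2), 30)
    ## a duplicated barcode in the map is an error
    smBad <- rbind(sm, sm[1, ])
    expect_error(factorCounts(tp$counts, smBad), "one-to-one")
})

test_that("medianNormalize equalizes per-sample medians multiplicatively", {
    m <- matrix(rpois(40, 100) + 1, 10, 4,
                dimnames = list(sprintf("f%02d", 1:10), sprintf("s%d", 1:4)))
    fc <- makeFC(m, rep(c("input", "IP"), 2), rep(1:2, each = 2))
    ## identical samples are left unchanged
    same <- makeFC(cbind(s1 = m[, 1], s2 = m[, 1]),
                   c("input", "IP"), c(1L, 1L))
    expect_equal(counts(medianNormalize(same)), counts(same) * 1.0)
    ## a doubled sample is scaled back onto the original
    doubled <- makeFC(cbind(s1 = m[, 1], s2 = 2L * m[, 1]),
                      c("input", "IP"), c(1L, 1L))
    nm <- counts(medianNormalize(doubled))
    expect_equal(unname(nm[, 1]), unname(nm[, 2]))
    ## random table: all medians equal afterwards
    nm <- counts(medianNormalize(fc))
    med <- apply(nm, 2, median)
    expect_true(max(med) - min(med) < 1e-9)
    ## an all-absent sample fails loudly
    m2 <- m; m2[, 3] <- NA
    expect_error(medianNormalize(makeFC(m2, rep(c("input", "IP"), 2),
                                        rep(1:2, each = 2))), "s3")
})

test_that("removeLowInput drops factors failing the input floor in too many replicates", {
    set.seed(52)
    nf <- 40; nr <- 6
    m <- matrix(rpois(nf * 2 * nr, 30), nf,
                dimnames = list(sprintf("f%02d", 1:nf), NULL))
    colnames(m) <- sprintf("s%02d", seq_len(2 * nr))
    fraction <- rep(c("input", "IP"), nr)
    replicate <- rep(seq_len(nr), each = 2)
    ## a factor absent from every input is removed
    m["f01", fraction == "input"] <- NA
    ## a factor above threshold everywhere is retained
    m["f02", fraction == "input"] <- 50L
    ## scatter low values elsewhere
    low <- sample(which(rep(fraction == "input", each = nf)), 40)
    m[low] <- sample(0:9, 40, replace = TRUE)
    fc <- makeFC(m, fraction, replicate)
    kept <- rownames(removeLowInput(fc, minInput = 10, minReplicates = 4))
    expect_false("f01" %in% kept)
    expect_true("f02" %in% kept)
    ## brute-force application of the rule
    inp <- m[, fraction == "input"]
    want <- rownames(m)[vapply(seq_len(nf), function(i)
        sum(!is.na(inp[i, ]) & inp[i, ] >= 10) >= 4, NA)]
    expect_identical(kept, want)
})

test_that("log2Scores pairs IP with input and computes log ratios", {
    m <- cbind(in1 = c(10, 20, 40), ip1 = c(10, 80, 20))
    rownames(m) <- c("f1", "f2", "f3")
    fc <- makeFC(m, c("input", "IP"), c(1L, 1L))
    p <- log2Scores(fc)
    expect_s4_class(p, "BindingScorePanel")
    expect_equal(unname(scores(p)[, 1]), c(0, 2, -1))  # IP=input, IP=4x, IP=x/2
    expect_equal(locusLabel(p), "BC_UP")
    ## unpaired samples are an error listing the orphan
    bad <- makeFC(m, c("input", "IP"), c(1L, 2L))
    expect_error(log2Scores(bad), "not pairable")
    ## Poisson counts at effect 1 without scale jitter: scores ~ 1
    set.seed(53)
    depth <- 1e5
    mu <- rep(depth / 200, 200)
    mm <- cbind(in1 = rpois(200, mu), ip1 = rpois(200, 2 * mu),
                in2 = rpois(200, mu), ip2 = rpois(200, 2 * mu))
    rownames(mm) <- sprintf("f%03d", 1:200)
    p <- log2Scores(makeFC(mm, rep(c("input", "IP"), 2), rep(1:2, each = 2)))
    expect_equal(mean(scores(p)), 1, tolerance = 3 / sqrt(depth))
    ## absent on either side stays absent
    mm[1, 1] <- NA
    p <- log2Scores(makeFC(mm, rep(c("input", "IP"), 2), rep(1:2, each = 2)))
    expect_true(is.na(scores(p)[1, 1]))
    expect_false(is.na(scores(p)[1, 2]))
})

test_that("quantileNormalize implements rank-mean with average ties and is idempotent", {
    ## the textbook two-replicate case
    m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
    q <- quantileNormalize(m)
    expect_equal(unname(q[, "a"]), c(1.5, 3.0, 4.5))
    expect_equal(unname(q[, "b"]), c(1.5, 3.0, 4.5))
    ## identical replicates are a fixed point
    same <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
    expect_equal(quantileNormalize(same), same)
    ## any input: sorted columns identical afterwards; idempotent
    set.seed(54)
    r <- matrix(rnorm(300), 100, 3)
    q <- quantileNormalize(r)
    expect_equal(sort(q[, 1]), sort(q[, 2]))
    expect_equal(sort(q[, 2]), sort(q[, 3]))
    expect_equal(quantileNormalize(q), q)
    ## ties take the mean of the tied positions
    t1 <- cbind(a = c(1, 1, 5), b = c(2, 4, 6))
    qt <- quantileNormalize(t1)
    ## reference ranks are (1.5, 2.5, 5.5); the tie spans ranks 1-2 -> 2.0
    expect_equal(unname(qt[, "a"]), c(2, 2, 5.5))
    expect_equal(unname(qt[, "b"]), c(1.5, 2.5, 5.5))
    ## agrees with the classic implementation on tie-free complete data
    skip_if_not_installed("limma")
    expect_equal(unname(quantileNormalize(r)),
                 unname(limma::normalizeQuantiles(r)))
    ## absent values stay absent
    rna <- r; rna[5, 2] <- NA
    qna <- quantileNormalize(rna)
    expect_true(is.na(qna[5, 2]))
    expect_equal(sum(is.na(qna)), 1L)
})

test_that("the preprocessing chain commutes and is permutation-equivariant", {
    set.seed(55)
    m <- matrix(rpois(120, 200) + 1, 20, 6,
                dimnames = list(sprintf("f%02d", 1:20), sprintf("s%d", 1:6)))
    fraction <- rep(c("input", "IP"), 3)
    replicate <- rep(1:3, each = 2)
    fc <- makeFC(m, fraction, replicate)
    ## median normalization then log2 = log2 then per-sample additive shift
    lhs <- log2(counts(medianNormalize(fc)))
    med <- apply(m, 2, median)
    shift <- log2(median(med) / med)
    rhs <- sweep(log2(m), 2, shift, "+")
    expect_equal(lhs, rhs)
    ## permuting factor order permutes the output identically
    perm <- sample(nrow(m))
    chain <- function(x) scores(quantileNormalize(log2Scores(medianNormalize(x))))
    out <- chain(fc)
    outPerm <- chain(makeFC(m[perm, ], fraction, replicate))
    expect_equal(outPerm, out[perm, ])
})
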