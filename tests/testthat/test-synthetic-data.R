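test_that("simulateLibrary draws unique barcodes and a row-major plate layout", {
    cfg <- SimulationConfig(nStrains = 384, seed = 1)
    truth <- simulateLibrary(cfg)
    st <- strains(truth)
    expect_equal(nrow(st), 384)
    expect_false(anyDuplicated(st$barcode) > 0)
    expect_true(all(nchar(st$barcode) == 20))
    expect_true(all(st$plate == 1))                 # exactly one full plate
    expect_equal(sort(unique(st$row)), LETTERS[1:16])
    expect_equal(sort(unique(st$col)), 1:24)
    ## row-major fill: first 24 strains are row A, columns 1..24
    expect_equal(st$row[1:24], rep("A", 24))
    expect_equal(st$col[1:24], 1:24)
    ## two plates when the library exceeds 384
    st2 <- strains(simulateLibrary(SimulationConfig(nStrains = 500, seed = 1)))
    expect_equal(unique(st2$plate), c(1L, 2L))
})

test_that("effects honour fracBinders and the truncated-normal model", {
    truth0 <- simulateLibrary(SimulationConfig(nStrains = 200,
                                               fracBinders = 0, seed = 2))
    expect_true(all(trueEffects(truth0) == 0))
    truth1 <- simulateLibrary(SimulationConfig(nStrains = 2000,
                                               fracBinders = 1,
                                               effectMean = 1, effectSd = 0.5,
                                               seed = 3))
    e <- trueEffects(truth1)
    expect_true(all(e >= 0))
    expect_gt(min(e), 0)                 # truncated at 0, prob(0) = 0
    expect_equal(mean(e[, "BC_UP"]), 1.05, tolerance = 0.05)
    expect_true(all(abundances(truth1) > 0))
})

test_that("the library draw is deterministic given the seed", {
    cfg <- SimulationConfig(nStrains = 4000, seed = 7)
    t1 <- simulateLibrary(cfg)
    t2 <- simulateLibrary(cfg)
    expect_identical(strains(t1), strains(t2))
    expect_identical(trueEffects(t1), trueEffects(t2))
    expect_identical(abundances(t1), abundances(t2))
    ## and a different seed gives a different library
    t3 <- simulateLibrary(SimulationConfig(nStrains = 4000, seed = 8))
    expect_false(identical(strains(t1)$barcode, strains(t3)$barcode))
})

test_that("null counts (no effect, no dispersion) have IP ~ input up to the sample scale", {
    cfg <- SimulationConfig(nStrains = 100, nReplicates = 4, depth = 1e6,
                            dispersion = 0, fracBinders = 0, seed = 4)
    bc <- simulateCounts(simulateLibrary(cfg), cfg)
    cd <- SummarizedExperiment::colData(bc)
    m <- counts(bc)
    for (r in unique(cd$replicate)) {
        ip <- m[, cd$replicate == r & cd$fraction == "IP"]
        inp <- m[, cd$replicate == r & cd$fraction == "input"]
        scale <- sum(ip) / sum(inp)
        expect_gt(scale, 0.45); expect_lt(scale, 2.2)  # log-uniform [0.5, 2]
        ratio <- ip / (inp * scale)
        expect_lt(sd(ratio) / mean(ratio), 0.05)  # Poisson at depth 1e4/strain
        expect_equal(mean(ratio), 1, tolerance = 0.02)
    }
})

test_that("a uniform log2 effect of 1 doubles the IP/input ratio", {
    cfg <- SimulationConfig(nStrains = 100, nReplicates = 2, depth = 1e6,
                            dispersion = 0, fracBinders = 1,
                            effectMean = 1, effectSd = 0, seed = 5)
    bc <- simulateCounts(simulateLibrary(cfg), cfg)
    cd <- SummarizedExperiment::colData(bc)
    m <- counts(bc)
    for (r in unique(cd$replicate)) {
        ip <- m[, cd$replicate == r & cd$fraction == "IP"]
        inp <- m[, cd$replicate == r & cd$fraction == "input"]
        ## per-strain ratio, relative to the (scale-confounded) column ratio
        colratio <- sum(ip) / sum(inp)
        expect_gt(colratio, 2 * 0.45); expect_lt(colratio, 2 * 2.2)
        expect_equal(mean(ip / inp) / colratio, 1, tolerance = 0.02)
    }
})

test_that("input column sums match the negative-binomial sum distribution", {
    cfg <- SimulationConfig(nStrains = 100, nReplicates = 6, depth = 1e5,
                            dispersion = 0.05, fracBinders = 0, seed = 6)
    truth <- simulateLibrary(cfg)
    bc <- simulateCounts(truth, cfg)
    cd <- SummarizedExperiment::colData(bc)
    mu <- cfg@depth * abundances(truth) / sum(abundances(truth))
    sdSum <- sqrt(sum(mu + cfg@dispersion * mu^2))
    inputSums <- colSums(counts(bc)[, cd$fraction == "input"])
    expect_true(all(abs(inputSums - cfg@depth) < 3 * sdSum * sqrt(6)))
    expect_lt(abs(mean(inputSums) - cfg@depth), 3 * sdSum / sqrt(6))
})

test_that("simulateReads emits one read per count unit and is seed-deterministic", {
    m <- matrix(c(5L, 2L, 0L, 3L), 2,
                dimnames = list(c(strrep("A", 20), strrep("C", 20)),
                                c("AAAAAA", "CCCCCC")))
    d <- kanmxDesign()
    rd <- simulateReads(m, d, errorRate = 0, seed = 1)
    expect_length(rd, 10)
    expect_equal(sum(grepl(strrep("A", 20), as.character(rd), fixed = TRUE)), 5)
    ## byte-identical FASTQ under the same seed, even with errors
    f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
    big <- matrix(500L, 1, dimnames = list(strrep("ACGT", 5), "GGGGGG"))
    simulateReads(big, d, errorRate = 0.05, seed = 9, filepath = f1)
    simulateReads(big, d, errorRate = 0.05, seed = 9, filepath = f2)
    expect_identical(readLines(f1), readLines(f2))
    ## and different under another seed
    simulateReads(big, d, errorRate = 0.05, seed = 10, filepath = f2)
    expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("substitution errors hit a 20-bp barcode at the binomial closed-form rate", {
    n <- 10000L
    bcseq <- strrep("ACGTG", 4)
    m <- matrix(n, 1, dimnames = list(bcseq, "AAAAAA"))
    d <- kanmxDesign()
    rate <- 0.01
    rd <- as.character(simulateReads(m, d, errorRate = rate, seed = 11))
    ## barcode occupies the last 20 bases of the assembled read
    obs <- substr(rd, nchar(rd[1]) - 19L, nchar(rd[1]))
    pExp <- 1 - (1 - rate)^20
    frac <- mean(obs != bcseq)
    expect_lt(abs(frac - pExp), 3 * sqrt(pExp * (1 - pExp) / n))
})

test_that("pooling covers each strain once per axis with the 384-well geometry", {
    truth <- simulateLibrary(SimulationConfig(nStrains = 384, seed = 1),
                             ade2Design())
    pools <- simulatePools(truth, depthPerPool = 100, dropout = 0, seed = 2)
    pm <- as.data.frame(pools$poolMap)
    expect_equal(sum(pm$axis == "row"), 16)
    expect_equal(sum(pm$axis == "column"), 24)
    m <- counts(pools$counts)
    present <- m > 0
    rowPools <- pm$index[pm$axis == "row"]
    colPools <- pm$index[pm$axis == "column"]
    expect_true(all(rowSums(present[, rowPools]) == 1))
    expect_true(all(rowSums(present[, colPools]) == 1))
    expect_true(all(colSums(present[, rowPools]) == 24))  # a row holds 24 wells
    expect_true(all(colSums(present[, colPools]) == 16))  # a column holds 16
    expect_equal(nrow(pools$dropped), 0)
})

test_that("pool dropout is reproducible under a fixed seed", {
    truth <- simulateLibrary(SimulationConfig(nStrains = 384, seed = 1),
                             ade2Design())
    p1 <- simulatePools(truth, depthPerPool = 100, dropout = 0.1, seed = 3)
    p2 <- simulatePools(truth, depthPerPool = 100, dropout = 0.1, seed = 3)
    expect_gt(nrow(p1$dropped), 0)
    expect_identical(p1$dropped, p2$dropped)
    expect_identical(counts(p1$counts), counts(p2$counts))
})

test_that("config and truth objects enforce their invariants", {
    expect_error(SimulationConfig(depth = 0), "depth")
    expect_error(SimulationConfig(errorRate = 0.3), "errorRate")
    expect_error(SimulationConfig(fracBinders = 1.2), "fracBinders")
    expect_error(SimulationConfig(dispersion = -1), "dispersion")
    truth <- simulateLibrary(SimulationConfig(nStrains = 10, seed = 1))
    expect_error({
        bad <- truth
        bad@abundance[1] <- -1
        validObject(bad)
    }, "positive")
})
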