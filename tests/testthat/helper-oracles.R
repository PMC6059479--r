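## Independent brute-force oracles used to cross-check the implementation.

## exhaustive anchor scan: try every position, count mismatches literally
scanAnchorOracle <- function(read, anchor, maxMismatch, window) {
    L <- nchar(anchor)
    a <- strsplit(anchor, "")[[1L]]
    for (k in window[1L]:window[2L]) {
        sub <- substr(read, k + 1L, k + L)
        if (nchar(sub) < L) next
        if (sum(strsplit(sub, "")[[1L]] != a) <= maxMismatch) return(k)
    }
    NA_integer_
}

## literal BH step-up: sort, q_(i) = min_{j>=i} m p_(j)/j, clip at 1
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- pmin(1, m * p[o] / seq_len(m))
    q <- rev(cummin(rev(q)))
    out <- numeric(m)
    out[o] <- q
    out
}

## hypergeometric upper tail by explicit binomial-coefficient summation
bruteHyperTail <- function(k, K, N, n) {
    js <- max(0L, n + K - N):min(n, K)
    js <- js[js >= k]
    if (!length(js)) return(0)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## running-sum ES by direct evaluation of every prefix deviation
bruteRunningSum <- function(metric, inSet, exponent) {
    N <- length(metric)
    w <- abs(metric)^exponent
    dev <- numeric(N)
    for (i in seq_len(N)) {
        hit <- sum(w[seq_len(i)][inSet[seq_len(i)]]) / sum(w[inSet])
        miss <- sum(!inSet[seq_len(i)]) / (N - sum(inSet))
        dev[i] <- hit - miss
    }
    dev[which.max(abs(dev))]
}

## small random library + counts for pipeline tests
toyPipeline <- function(nStrains = 100, nReplicates = 3, depth = 2e4,
                        dispersion = 0.05, fracBinders = 0.1, seed = 1,
                        effectMean = 1, effectSd = 0.5) {
    cfg <- SimulationConfig(nStrains = nStrains, nReplicates = nReplicates,
                            depth = depth, dispersion = dispersion,
                            errorRate = 0, fracBinders = fracBinders,
                            effectMean = effectMean, effectSd = effectSd,
                            seed = seed)
    truth <- simulateLibrary(cfg)
    list(cfg = cfg, truth = truth, counts = simulateCounts(truth, cfg))
}

## align an extracted count matrix onto the simulated one (missing cells = 0)
alignCounts <- function(extracted, simulated) {
    m <- matrix(0L, nrow(simulated), ncol(simulated),
                dimnames = dimnames(simulated))
    e <- counts(extracted)
    keepr <- intersect(rownames(e), rownames(m))
    keepc <- intersect(colnames(e), colnames(m))
    m[keepr, keepc] <- e[keepr, keepc]
    m
}
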