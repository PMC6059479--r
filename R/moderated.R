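#' @rdname ModeratedPrior-class
#' @param df,s2 prior degrees of freedom and prior variance.
#' @export
ModeratedPrior <- function(df, s2) new("ModeratedPrior", df = df, s2 = s2)

#' @rdname ModeratedPrior-class
#' @param x a \linkS4class{ModeratedPrior}.
#' @export
priorDf <- function(x) x@df

#' @rdname ModeratedPrior-class
#' @export
priorVar <- function(x) x@s2

setMethod("show", "ModeratedPrior", function(object) {
    cat("ModeratedPrior: d0 =", format(object@df),
        ", s0^2 =", format(object@s2), "\n")
})

## inverse of trigamma(d0/2) in d0, by bisection; trigamma is strictly
## decreasing so bisection is safe. d0 outside [1e-4, 1e6] -> Inf / clamp.
invTrigammaHalf <- function(target, lower = 1e-4, upper = 1e6,
                            tol = 1e-8) {
    if (target <= trigamma(upper / 2)) return(Inf)
    if (target >= trigamma(lower / 2)) return(lower)
    lo <- lower; hi <- upper
    while (hi - lo > tol * max(1, lo)) {
        mid <- (lo + hi) / 2
        if (trigamma(mid / 2) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

#' Fit the empirical-Bayes variance prior
#'
#' Method-of-moments fit of a scaled inverse chi-square prior to per-factor
#' sample variances on the log scale. With
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`, the prior degrees of
#' freedom `d0` solve
#' `trigamma(d0/2) = mean((e - mean(e))^2 * G/(G-1) - trigamma(d_g/2))`
#' (infinite when the right-hand side is nonpositive: no excess spread
#' beyond sampling noise), and the prior variance is
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`.
#'
#' @param s2 per-factor sample variances.
#' @param df residual degrees of freedom (recycled).
#' @return a \linkS4class{ModeratedPrior}.
#' @export
estimatePrior <- function(s2, df) {
    df <- rep_len(df, length(s2))
    if (all(!is.na(s2) & s2 == 0))
        stop("all sample variances are zero: degenerate data")
    ok <- is.finite(s2) & s2 > 0 & df >= 1
    if (sum(ok) < length(s2))
        warning(length(s2) - sum(ok),
                " variance(s) unusable (zero, nonfinite, or df < 1) were ",
                "excluded from the prior fit")
    if (sum(ok) < 10L)
        stop("need at least 10 factors with positive variance and df >= 1")
    s2 <- s2[ok]; df <- df[ok]
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    G <- length(e)
    ebar <- mean(e)
    rhs <- mean((e - ebar)^2 * G / (G - 1) - trigamma(df / 2))
    if (rhs <= 0) {
        d0 <- Inf
        s02 <- exp(ebar)
    } else {
        d0 <- invTrigammaHalf(rhs)
        s02 <- if (is.infinite(d0)) exp(ebar)
               else exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    }
    ModeratedPrior(d0, s02)
}

## moderated t machinery shared by the one- and two-sample tests
moderatedT <- function(est, s2, df, n_eff, prior) {
    d0 <- prior@df; s02 <- prior@s2
    stilde2 <- if (is.infinite(d0)) rep(s02, length(s2))
               else (d0 * s02 + df * s2) / (d0 + df)
    t <- est / sqrt(stilde2 / n_eff)
    dfTot <- d0 + df
    p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t))
         else 2 * stats::pt(-abs(t), dfTot)
    list(t = t, p = p, stilde2 = stilde2, dfTotal = dfTot)
}

#' Moderated one-sample test for binding
#'
#' Per factor, the mean binding score `M_g` over replicates is tested
#' against 0 with an empirical-Bayes moderated t-statistic: the sample
#' variance `s_g^2` (df `d_g = n_g - 1`) is shrunk to the posterior
#' `s~_g^2 = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)` under the prior fitted
#' across factors, and `t_g = M_g / (s~_g / sqrt(n_g))` is referred to a t
#' distribution with `d0 + d_g` degrees of freedom (normal when `d0` is
#' infinite). Two-sided p-values; BH FDR across factors.
#'
#' @param panel a \linkS4class{BindingScorePanel} or a score matrix
#'   (factors x replicates). Factors need >= 2 finite scores; others are
#'   dropped with a message.
#' @param prior optional \linkS4class{ModeratedPrior}; fitted from the
#'   panel when `NULL`. `ModeratedPrior(0, s2)` gives the ordinary t-test.
#' @return a [S4Vectors::DataFrame]: `factor`, `logFC` (mean score), `s2`,
#'   `df`, `t`, `p`, `FDR`, and `locus` when known.
#' @seealso [callBinders()], [estimatePrior()]
#' @export
moderatedOneSampleTest <- function(panel, prior = NULL) {
    locus <- NA_character_
    if (is(panel, "BindingScorePanel")) {
        locus <- locusLabel(panel)
        m <- SummarizedExperiment::assay(panel, "score")
    } else m <- as.matrix(panel)
    n <- rowSums(is.finite(m))
    drop <- n < 2L
    if (any(drop))
        message(sum(drop), " factor(s) with fewer than 2 finite scores ",
                "were dropped")
    m <- m[!drop, , drop = FALSE]
    n <- n[!drop]
    M <- rowMeans(m, na.rm = TRUE)
    s2 <- apply(m, 1L, stats::var, na.rm = TRUE)
    d <- n - 1
    if (is.null(prior)) prior <- estimatePrior(s2, d)
    mt <- moderatedT(M, s2, d, n, prior)
    S4Vectors::DataFrame(
        factor = rownames(m), logFC = unname(M), s2 = unname(s2),
        df = unname(d), t = unname(mt$t), p = unname(mt$p),
        FDR = bhAdjust(unname(mt$p)), locus = locus)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} min(1, m * p_(j) / j)`, returned in input order.
#'
#' @param p p-values in \[0, 1\].
#' @return the adjusted values (FDRs).
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 1.0))
#' @export
bhAdjust <- function(p) {
    if (any(!is.na(p) & (p < 0 | p > 1)))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Flag significant binders
#'
#' A factor is a binder when its fold-change is strictly positive and its
#' FDR is below the cutoff (default 0.01).
#'
#' @param table result of [moderatedOneSampleTest()].
#' @param fdrCut FDR cutoff.
#' @return the table with a logical `binder` column.
#' @export
callBinders <- function(table, fdrCut = 0.01) {
    table$binder <- table$logFC > 0 & table$FDR < fdrCut
    table
}

#' Condition contrast with a moderated two-sample test
#'
#' Restricts to factors that are significant binders (positive fold-change,
#' FDR < `binderUnionCut`) in at least one condition, then tests the
#' between-condition difference of mean binding scores with a moderated
#' two-sample t: pooled within-condition variance
#' (df `d_g = n_A + n_B - 2`) shrunk under a prior estimated on this
#' restricted set, BH adjustment within the set, significance at FDR <
#' `diffFdrCut`. The reported `logFC` is `mean(A) - mean(B)`; pass the
#' treated condition as `panelA` to report treated/untreated fold-changes.
#'
#' @param panelA,panelB \linkS4class{BindingScorePanel}s (or score
#'   matrices) for the two conditions at the same locus, >= 2 replicates
#'   each.
#' @param binderUnionCut FDR cutoff defining the binder union (default
#'   0.05).
#' @param diffFdrCut FDR cutoff for a significant difference (default
#'   0.05).
#' @return a [S4Vectors::DataFrame]: `factor`, `logFC`, `t`, `p`, `FDR`,
#'   `significant`, `binderA`, `binderB`.
#' @export
differentialBinding <- function(panelA, panelB, binderUnionCut = 0.05,
                                diffFdrCut = 0.05) {
    getm <- function(x)
        if (is(x, "BindingScorePanel"))
            SummarizedExperiment::assay(x, "score") else as.matrix(x)
    if (is(panelA, "BindingScorePanel") && is(panelB, "BindingScorePanel") &&
        !identical(locusLabel(panelA), locusLabel(panelB)))
        stop("panels must share a locus")
    mA <- getm(panelA); mB <- getm(panelB)
    tA <- callBinders(moderatedOneSampleTest(panelA), binderUnionCut)
    tB <- callBinders(moderatedOneSampleTest(panelB), binderUnionCut)
    union <- base::union(tA$factor[tA$binder], tB$factor[tB$binder])
    union <- intersect(intersect(union, rownames(mA)), rownames(mB))
    if (!length(union)) {
        warning("no significant binders in either condition; empty contrast")
        return(S4Vectors::DataFrame(
            factor = character(), logFC = numeric(), t = numeric(),
            p = numeric(), FDR = numeric(), significant = logical(),
            binderA = logical(), binderB = logical()))
    }
    mA <- mA[union, , drop = FALSE]
    mB <- mB[union, , drop = FALSE]
    nA <- rowSums(is.finite(mA)); nB <- rowSums(is.finite(mB))
    ok <- nA >= 2L & nB >= 2L
    if (any(!ok))
        message(sum(!ok), " factor(s) with fewer than 2 finite scores in a ",
                "condition were dropped from the contrast")
    mA <- mA[ok, , drop = FALSE]; mB <- mB[ok, , drop = FALSE]
    nA <- nA[ok]; nB <- nB[ok]
    union <- union[ok]
    diff <- rowMeans(mA, na.rm = TRUE) - rowMeans(mB, na.rm = TRUE)
    s2A <- apply(mA, 1L, stats::var, na.rm = TRUE)
    s2B <- apply(mB, 1L, stats::var, na.rm = TRUE)
    dA <- nA - 1; dB <- nB - 1
    s2 <- (dA * s2A + dB * s2B) / (dA + dB)
    d <- dA + dB
    prior <- estimatePrior(s2, d)
    mt <- moderatedT(diff, s2, d, 1 / (1 / nA + 1 / nB), prior)
    fdr <- bhAdjust(unname(mt$p))
    S4Vectors::DataFrame(
        factor = union, logFC = unname(diff), t = unname(mt$t),
        p = unname(mt$p), FDR = fdr, significant = fdr < diffFdrCut,
        binderA = union %in% tA$factor[tA$binder],
        binderB = union %in% tB$factor[tB$binder])
}
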