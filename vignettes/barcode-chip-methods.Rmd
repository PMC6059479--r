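---
title: "Methods: decoding and quantifying protein-DNA binding from barcoded clone pools"
author: "barcodeChIP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding and quantifying protein-DNA binding from barcoded clone pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeChIP)
```

# The experimental readout this package models

The screen this package analyzes couples two genomic elements in every cell
of a pooled yeast culture: a TAP-tagged protein (one per clone) and a short
DNA barcode (15 or 20 bp) integrated at one fixed locus, flanking a reporter
cassette. Because all clones share one antibody epitope, a single chromatin
immunoprecipitation (ChIP) of the pool enriches, clone by clone, the barcode
DNA in proportion to how strongly that clone's tagged protein crosslinks to
the barcoded locus. Sequencing the barcode amplicon in the IP and the input
fraction turns locus-specific protein binding for thousands of proteins into
a pair of count vectors:

$$\text{binding score}_{g,r} = \log_2 \mathrm{IP}_{g,r} - \log_2 \mathrm{IN}_{g,r}$$

for factor $g$ in replicate $r$. Everything downstream - normalization,
moderated statistics, set enrichment - works on this table.

# Pipeline stages and their assumptions

## Read parsing (`locateAnchor`, `extractReads`, `countBarcodes`)

Amplicon reads are parsed geometrically, not by alignment: a constant
cassette-flanking sequence (the *anchor*) is located within a configurable
search window allowing up to `maxAnchorMismatches` substitutions (default 1),
and the 6-bp sample index and the clone barcode are read off verbatim at
fixed offsets on either side. Choices worth knowing:

* **No barcode error correction.** Library barcodes are known and well
  separated; correcting single-base errors would move counts between
  barcodes in a depth-dependent way. Reads whose barcode acquired a
  sequencing error simply fail to match any library barcode and are dropped
  at the strain-map join (`factorCounts()`), where they are counted and
  reported.
* **Leftmost-match tie-break.** If several window positions admit the
  anchor within tolerance, the leftmost wins, making extraction
  deterministic.
* **Rejections are data.** Reads are tallied as `no_anchor`, `truncated`
  (an interval runs off the read) or `ambiguous_base` (non-ACGT in a sliced
  interval); accepted + rejected always equals the reads processed.
* **Coordinates are 0-based, half-open** throughout the design geometry.
* The grammatical ambiguity in which element sits on which side of the
  anchor is resolved by making both sides configurable in
  `AmpliconDesign`; the shipped presets put the index immediately upstream
  and the barcode immediately downstream.

Counts below 10 are removed before preprocessing (`filterMinCount()`):
at typical depths such entries are dominated by index hopping and
PCR/sequencing artifacts rather than real library members.

## Arrayed-library decoding (`callPoolBarcodes`, `decodeCoordinates`)

The arrayed collection is decoded by sequencing one pool per plate row (16)
and one per column (24): a barcode called (>= `minReads`, default 50;
100 is the conservative preset) in exactly one row pool and one column pool
of a plate is assigned that well. Two rejection rules keep the map honest:
a barcode matching more than one row-column combination is
`rejected-multimatch`, and if several barcodes converge on one well all of
them become `rejected-collision`. Row-column pairs are only formed within
one plate's pools, since pools are made per plate. A barcode supported on
only one axis (dropout) stays `unassigned` rather than erroring - the
symmetric treatment of row-side and column-side dropout. With per-pool
dropout probability $d$, the expected unassigned fraction is
$1-(1-d)^2$, which the tests verify on simulated plates.

## Normalization chain (`medianNormalize`, `removeLowInput`, `log2Scores`, `quantileNormalize`)

1. **Plate median scaling.** Each sample is multiplied by
   (reference median / sample median), the reference being the median of
   per-sample medians; this removes plate- and fraction-level depth
   differences multiplicatively on raw counts, before the log transform.
   Numerically, normalize-then-log equals log-then-additive-shift, which the
   tests check.
2. **Low-input filtering.** A factor must reach a raw input count of
   `minInput` (default 10, reusing the global count floor) in at least
   `minReplicates` (default 4) of the input replicates, otherwise it is
   removed whole: such factors are likely missing from the library or
   failed to amplify, and their ratios would be noise.
3. **Scores.** IP and input are paired by (plate, condition, replicate);
   the score is the difference of log2 counts, absent whenever either side
   is absent.
4. **Quantile normalization across replicates**, separately per locus,
   forces the replicate score vectors onto one common distribution (the
   rank-wise mean), compensating small dynamic-range differences between
   biological replicates. Ties take the mean of the tied positions
   (average-rank convention); absent values stay absent and do not enter
   the reference; with unequal numbers of present values the rank is mapped
   through an interpolated mean quantile curve, which reduces exactly to
   rank-mean when the panels are complete. The operation is idempotent.

A genuinely open design point is whether quantile normalization acts on log
counts or on the IP/input score vectors. This package applies it to the
per-replicate score vectors: the motivation for the step is the replicate
dynamic range of the *binding* readout, and normalizing the ratio scale
cancels the per-sample scale factors directly. The stage can equally be run
on any matrix (the function accepts one), so the alternative placement
remains available to the user.

## Moderated statistics (`estimatePrior`, `moderatedOneSampleTest`, `differentialBinding`)

With few replicates (6 untreated; 3 + 3 in the drug contrast), per-factor
variances are noisy; the binder test therefore shrinks them with the
standard empirical-Bayes machinery. The prior is a scaled inverse
chi-square with parameters $(d_0, s_0^2)$ fitted by method of moments on
the log scale: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$,

$$\psi'(d_0/2) = \max\!\Big(0,\ \mathrm{mean}_g\big[(e_g-\bar e)^2\tfrac{G}{G-1} - \psi'(d_g/2)\big]\Big),$$

solved for $d_0$ by monotone bisection over $[10^{-4}, 10^{6}]$ at
tolerance $10^{-8}$ ($\psi'$ is strictly decreasing, so bisection is safe;
a right-hand side at or below the attainable range gives $d_0 = \infty$,
i.e. no excess spread beyond sampling noise), and
$s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$. The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ feeds the moderated
statistic $t_g = M_g / (\tilde s_g/\sqrt{n_g})$ with $d_0 + d_g$ degrees of
freedom (normal when $d_0 = \infty$). The tests verify this fit and test
agree with the reference implementation (limma) to numerical precision, and
that $d_0 = 0$ recovers the ordinary t-test.

Model form: the binder call is a **one-sample moderated t on per-replicate
log-ratios** (equivalent to a paired IP-vs-input contrast), and the drug
contrast is a **two-sample moderated t** on the difference of condition
means with pooled within-condition variance, restricted to factors that are
significant binders (positive fold-change, FDR < 0.05) in at least one
condition, with the prior refitted on that restricted set. This is the
formulation with the fewest assumptions that reproduces the reported
outputs (log fold-change of ChIP/input; log fold-change of
treated/untreated). P-values are two-sided - significant depletions are
informative even if unexpected. Multiple testing uses Benjamini-Hochberg
FDR; binders require strictly positive fold-change and FDR < 0.01.

## Set enrichment (`fisherEnrichment`, `assignCategories`, `runningSumEnrichment`)

Over-representation of categories among binders uses the one-sided Fisher
test (hypergeometric upper tail). The packaged category scheme maps coarse
classes (DNA binding, RNA binding or processing, metabolism) to GO-slim
process terms with priority DNA > RNA > metabolism; anything unlisted is
"other".

For locus preference, binders ranked by the difference of the two loci's
fold-changes are scanned with the weighted Kolmogorov-Smirnov running sum:
in-set steps add $|m_i|^{p}$ (normalized by the in-set total,
exponent $p \in \{0, 1\}$, default 1, matching the common default of the
classic scoring function), out-of-set steps subtract $1/(N-n)$; the
enrichment score is the signed maximum deviation. Significance permutes
set membership over the ranked factors ($10^4$ permutations by default,
fixed seed), so $p \ge 1/(n_\mathrm{perm}+1)$ by construction; the original
analysis did not state its permutation scheme, so this null is a documented
choice of the package. Ranking ties break by factor name.

# The synthetic-data generator

The generator is first-class, tested code: it is how the pipeline is
validated offline, end to end, against a known truth.

* **Library**: `nStrains` clones with unique random barcodes (collisions
  are redrawn, erroring after 100 rounds - a sign the barcode is too
  short), laid out row-major on 384-well plates (rows A-P, columns 1-24).
* **Effects**: with probability `fracBinders` a clone is a true binder
  with log2 effect drawn from Normal(`effectMean`, `effectSd`) truncated
  at 0; otherwise exactly 0. Effects at the two flanking loci are drawn
  independently, so UP-specific, DN-specific and shared binders all occur.
* **Abundance** is a separate log-normal draw (sdlog 0.5): input
  representation and binding are distinct quantities, and the pipeline must
  not confuse them.
* **Counts**: negative binomial; input mean
  `depth * abundance / sum(abundance)`, IP mean multiplied by
  `2^effect` and by a per-IP-sample scale drawn log-uniformly in
  $[0.5, 2]$ to exercise normalization. The variance is
  $\mu + \phi\mu^2$; $\phi = 0$ reduces to Poisson. The original work
  states no count noise model, so the negative binomial - the standard
  overdispersed model for sequencing counts - is an explicit stand-in.
* **Reads**: one read per count unit, assembled index + anchor + barcode,
  i.i.d. substitution errors at `errorRate`, constant quality string
  (`"I"`) since extraction never reads qualities. Byte-identical FASTQ
  under a fixed seed.
* **Pools**: 16 row + 24 column pools per plate, per-strain Poisson depth
  `depthPerPool`, and a `dropout` probability that silently removes a
  strain from a pool to exercise the decoder's rejection paths.

Defaults (`SimulationConfig()`) emulate the screen's conditions: ~4,000
clones, 6 replicates, $10^6$ reads per sample, dispersion 0.05 (a typical
mild overdispersion for amplicon counts), error rate $10^{-3}$, 12% binders
with effects around 1 log2 unit - the binder fraction and effect scale a
screen of this design would consider realistic.

What the generator does **not** emulate - and what passing tests therefore
do not show about real data: PCR jackpots and chimeras, quality-score error
profiles, paired-end reads, index hopping between samples, growth-rate
competition within the pool, and tag effects on protein function. The
simulator validates the *computational* chain, not the assay chemistry.

# Validation problem sizes

The shipped test suite and the acceptance script size their simulations so
the whole suite runs in well under an hour on one core while keeping
Monte-Carlo error small relative to every asserted margin: the error-free
round trip uses 1,000 strains x 6 replicates at depth $2\times10^4$ per
sample; decode recovery uses full 384-well plates at 500 reads per strain
per pool; calibration and power use 4,000 factors x 6 replicates at depth
$10^6$ over 20 null screens; prior recovery uses 5,000 factors; the drug
contrast uses 2,000 factors with 3 + 3 replicates and 100 injected shifts
of -1.5 log2 units.

# Known limitations

* Barcode extraction trusts the read orientation implied by the sequencing
  primer; no reverse-complement scan is attempted.
* No UMI handling, paired-end merging, or quality trimming; amplicons are
  assumed short and single-read.
* No between-locus normalization: the two flanking loci are processed
  separately by design, so cross-locus comparisons of absolute scores
  inherit any locus-specific amplification bias.
* The decoder supports only row/column pooling, not higher-dimensional or
  compressed-sensing designs.
* GO-slim categories are used flat; no GO-graph propagation.
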