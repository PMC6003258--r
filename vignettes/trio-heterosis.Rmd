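---
title: "Trio heterosis analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio heterosis analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterex)
```

# The experimental design

The package analyses a *trio*: two inbred parents (P1, P2) and their F1
hybrid, each measured with at least two biological replicates — for traits
(replicated field measurements) and for expression (RNA-seq counts). All
containers are Bioconductor-native: counts live in a `TrioExperiment`
(a `SummarizedExperiment` whose `colData` records line and replicate),
gene models and QTL intervals are `GRanges`.

# Models and procedures

## Phenotypic heterosis

For each trait, mid-parent heterosis MPH = (F1 − MP)/MP and high-parent
heterosis HPH = (F1 − BP)/BP are computed from line means and reported in
percent. The better parent is the higher-mean parent by default; a
per-trait flag handles traits where lower is better. Significance uses a
two-sided Welch t-test of the F1 replicates against per-replicate
mid-parent values (P1~k~ + P2~k~)/2 paired by replicate index (for MPH) or
against the better parent's replicates (for HPH). The choice of Welch's
test on per-replicate mid-parent values is a design decision: a paired or
one-sample variant would also be defensible, but the Welch form makes no
assumption about equal variances between the hybrid and the synthetic
mid-parent sample and degrades gracefully when replicate pairing is
arbitrary. At the degenerate zero-variance boundary the p-value is defined
as 1 when the means agree and 0 otherwise.

Some published heterosis tables contain cells that cannot be reproduced
from the printed line means (they were evidently computed at replicate
level before rounding); only cells that are arithmetically consistent with
the printed means are used as reference values in the tests.

## Quantification

FPKM~gs~ = 10^9^ · c~gs~ / (L~g~ · N~s~) uses the supplied count matrix's
column totals as "million mapped fragments" — self-contained and
monotone-equivalent to using genome-wide mapped totals, which a
counts-first pipeline does not see. Gene length is the annotated gene
length from the gene-model file. Replicate agreement is the squared
Pearson correlation of log2(FPKM + 1) between within-line sample pairs
(pseudocount fixed at 1). A gene is *expressed* — and thus part of the
default enrichment universe — when its FPKM reaches 1 in at least one
sample; both knobs are configurable.

Size factors are plain median-of-ratios: the median across
everywhere-nonzero genes of the ratio to the per-gene geometric mean,
rescaled to geometric mean exactly 1. Note they are used for DE
normalization and normalized-count output, but *not* for effect
estimation (below).

## Differential expression

The DE engine is an exact conditional negative-binomial test written for
this package. Counts of the two lines are scaled to the geometric-mean
library size and rounded; per-gene dispersions are method-of-moments
estimates on these pseudo-counts (variance = mu + phi·mu^2), floored at 0
and shrunk with weight 0.5 toward a 20%-trimmed-mean common dispersion —
three replicates give very unstable raw moments, and the even-weight
shrinkage is the simplest stabilizer with a configurable knob.
Conditional on a gene's grand total T, the group-1 sum under the null is
distributed as the convolution ratio of two NB sums with sizes n~1~/phi
and n~2~/phi; the two-sided p-value sums the probabilities of all splits
no more likely than the observed one (the "sum of small probabilities"
convention, not tail doubling). phi = 0 degenerates to the exact
Binomial(T, n~1~/(n~1~+n~2~)) split. p-values are exactly 1 for T = 0 and
never 0. log2 fold changes use normalized group means with pseudocount
0.5 on both sides so zero groups stay finite. Genes are called at
FDR ≤ 0.05 (Benjamini–Hochberg within contrast) and |log2FC| ≥ 1, both
boundaries inclusive.

DG_HP is the union of the F1-vs-P1 and F1-vs-P2 DEG sets; DG_PP is the
P1-vs-P2 set; the seven Venn regions are reported alongside.

## Inheritance modes

Per gene, the randomized-block model y = u + line + block + e is fitted by
least squares (closed form in the balanced design; the test suite checks
it against `lm()`), giving the composite additive effect
\[a\] = (P̄1 − P̄2)/2, the dominance effect \[d\] = F̄1 − (P̄1 + P̄2)/2, and
a residual variance on (3−1)(r−1) degrees of freedom. The dominance ratio
Hp = \[d\]/|\[a\]| carries dominance direction in its sign and is invariant
to parent labelling. The bands: additive −0.2 < Hp ≤ 0.2, partial dominance
−0.8 < Hp ≤ −0.2 or 0.2 < Hp ≤ 0.8, dominance −1.2 < Hp ≤ −0.8 or
0.8 < Hp ≤ 1.2, over-dominance Hp ≤ −1.2 or Hp > 1.2. The bands partition
the extended reals; ±infinity (degenerate parents, |a| ≤ eps = 1e-8, with
a real dominance effect) is over-dominance by definition, and Hp = 0 when
both effects are below eps.

The classification is backed by a 99.8% t-interval for \[d\] − \[a\] when
d > 0 and \[d\] + \[a\] when d < 0 (at d = 0 exactly, the d − a form). In
a balanced trio these contrasts reduce to F̄1 minus the higher (resp.
lower) parent mean, with standard error sqrt(2·sigma²/r). The interval is
reported as a `confident` flag and does not override the band assignment
— how a hard band rule and an interval-based rule should interact is left
open in the method's source description, so the package reports both.

**Expression scale.** Effects are estimated on the linear FPKM scale
(counts per million when no gene lengths are available), with a
log2(FPKM+1) option. Two reasons: Hp is a ratio of linear-scale
quantitative-genetic effects, and column-total scaling is robust when a
large fraction of the transcriptome is differential — median-of-ratios
factors assume most genes are non-differential and are visibly biased on
the simulator's strong-effect genomes, which the linear library-size
scale is not (effect signs are symmetric, so column totals stay
comparable).

By default only DG_HP genes are classified (mirroring how such trios are
analysed); `classifyAll` lifts the restriction — the simulator recovery
tests use it, because restricting to DEGs would deplete the additive class
and distort the recovered composition.

## Enrichment and QTL colocalization

Enrichment is an upper-tail hypergeometric test of a gene set against each
term of a user-supplied GMT map (at least 3 universe members per term by
default), BH-adjusted across terms; the universe defaults to the expressed
genes. No GO DAG propagation is attempted — the term map is taken as
given, which is what working from deposited annotation files looks like
without live database access.

Colocalization treats all coordinates as 1-based inclusive (BED input is
converted on read); a gene and a QTL colocalize when they share at least
one base on the same chromosome, so touching endpoints count with overlap
length 1. The production path uses `GenomicRanges::findOverlaps`; the
tests pin it to a brute-force all-pairs scan. QTL panels must carry
physical coordinates; flanking marker names are annotation only, since
marker-to-coordinate resolution is a genetics problem outside this
package.

# The simulator

`simulateTrioCounts()` plants, per gene, a mid-parent mean m (uniform in
[0.5, 1.5]·`baseMean`), a mode drawn from `modeFractions` (default: the
over-dominance-heavy composition 63.1/17.3/15.6/4.0% observed in
hybrid-rice panicle transcriptomes), a true Hp uniform inside that mode's
band, and line means mu~P1~ = m + a, mu~P2~ = m − a,
mu~F1~ = m + Hp·|a| — so true Hp is exact by construction on the linear
scale. Counts are NB(mean, phi) with variance mu + phi·mu² (Poisson at
phi = 0), multiplied by a per-sample library-size factor and a log-normal
block factor shared by all genes of a sample (the simplest structure that
makes the replication term of the ANOVA identifiable). Effect magnitudes
are drawn around `effectScale` and capped at 0.8·m/max(1, |Hp|), which
keeps every line mean strictly positive and the planted Hp exact; the
default `effectScale` (2·`baseMean`) makes the cap bind, i.e. parents
diverge strongly at every gene.

Band sampling keeps a margin (`bandMargin`, default 0.05) from the band
edges so that recovery tests measure classification, not boundary
coin-flips. The additive and dominance bands are only 0.4 wide, so the
margin is clamped per band to 45% of the band width: asking for a margin
of 0.3 concentrates those bands near their centres (Hp ≈ 0 and ≈ ±1.0)
while honouring 0.3 where the band allows it. Over-dominant |Hp| is capped
at `hpMax` = 2.5.

**What the simulator does not emulate:** sequencing reads and mapping
artifacts, per-gene dispersion trends (phi is common to all genes),
correlated effects between neighbouring genes, partially differential
transcriptomes (every gene carries an effect), or GO-DAG structure in term
maps. Passing recovery tests therefore demonstrates the estimators'
correctness under the stated generative model, not performance on any
particular real data set.

`simulateTraits()` draws normal replicates around per-line trait means;
its default specification is the published panicle-trait table of the
WFYT025 combination (means ± SD for ten yield-related traits).
`simulateGenomeFeatures()` lays non-overlapping gene intervals round-robin
over 12 chromosomes (the rice karyotype) and places each QTL over a
contiguous run of genes, recording exactly which genes fall inside —
the construction oracle for the colocalization tests.

# Test problem sizes and statistical tolerances

The suite checks, among others: mode recovery on a 2000-gene trio with
r = 3, base mean 500, phi = 0.02 and band margin 0.3, requiring ≥90%
correct modes and planted fractions within ±0.05 — the dispersion sits in
the low-noise regime a delta-method power analysis identifies as the one
where band-centre recovery is expected to clear 90%
(sd(Hp) ≈ sqrt(1.5·phi/r)·(m/|a|) ≈ 0.13 against narrow-band margins of
0.18); FDR control as the mean fraction of null genes at FDR ≤ 0.05 over
50 simulated null trios of 2000 genes; 99.8% CI coverage within
[0.99, 1.0] over 10,000 simulated genes; and exact agreement of BH,
hypergeometric, phi = 0 exact-test, least-squares and interval-overlap
routines with brute-force oracles (1000 random p-vectors, every
hypergeometric instance with N ≤ 12, enumerated binomial splits, `lm()`
refits, all-pairs scans). Monte-Carlo checks (trait-level power, planted
enrichment ranking) run 200 seeded replicates each.

# Known limitations

* The exact test assumes a common dispersion per gene across groups and
  ignores uncertainty in the dispersion estimate; with 3 replicates the
  shrunk estimator is serviceable but approximate, and the test is mildly
  conservative due to discreteness.
* Effect estimation assumes a balanced trio; unbalanced designs are
  rejected rather than approximated.
* The dominance-ratio classification is a hard banding of a noisy ratio;
  near band edges the calls are uncertain by construction, and the
  `confident` flag (CI excluding zero) is the honest companion signal.
* FPKM from column totals differs from FPKM on genome-wide mapped totals
  by a per-sample constant; any analysis in this package is invariant to
  that constant, but exported FPKM values are not comparable across
  differently filtered matrices.
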