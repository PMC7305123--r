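---
title: "Methods: quantifying activity-dependent Pol II occupancy and its loss"
author: "nadtseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying activity-dependent Pol II occupancy and its loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadtseq)
```

## The problem

Neurons respond to salient stimuli (here, fear conditioning, FC) with a
rapid transcriptional burst at early-response genes such as *Arc*, *Fos*,
*Egr1* and *Npas4*.  RNA polymerase II ChIP-seq occupancy at transcription
start sites and exons is a direct proxy for that transcription, and the
question the pipeline answers is factorial: does a knock-out genotype
attenuate the FC-induced occupancy gain, gene by gene and genome-wide?
`nadtseq` implements that analysis as composable, tested functions, from
aligned reads to classified genes, islands, and gene-set enrichments.

## From alignments to signals

**Multimapper weighting.** A read matching $n$ genomic loci is kept only if
$n \le 3$ and contributes weight $1/n$ at each locus; reads with more
matches are discarded.  Total weight per sequenced fragment is therefore 1
(or 0), so multimapping neither inflates nor deletes coverage mass.  The
match count comes from the SAM `NH` tag when present, from the BED score
column otherwise, and defaults to 1 with a warning when neither exists —
input dialects vary and silent failure would be worse than an optimistic
assumption the log records.

**Duplicate capping.** At most 5 read records per identical
(chrom, start, end) key are retained per sample, a pragmatic PCR-bias guard
that leaves true saturated coverage mostly intact at realistic depths.  The
cap counts records, not weights, because amplification duplicates a
molecule regardless of where else it maps.  Retention is made deterministic
by a stable sort on (chrom, start, end, weight).  Strand is ignored in the
key by default (a config flag enables strand-aware keying); capping runs
after weighting, and `cap = Inf` recovers raw weighted counts for audits.

**FPKM.** Signal per gene is the weighted fragment count over a region —
the TSS window of 700 bp each side of the start site (1400 bp total), or
the union of the gene's exons — per kilobase of region per million library
fragments.  The library is the summed weight of retained reads overlapping
any annotated gene body ("reads in transcripts"); a flag switches to
all-retained-reads for comparisons.  A read counts once per gene even when
it touches two exons, and any-overlap (≥ 1 shared base) is the counting
rule, the common convention for short fragments.  Multi-transcript genes
are collapsed to one model per gene — the exon union and the
strand-outermost TSS — since quantification is per gene.

Internally all coordinates live in `GenomicRanges` (1-based, closed), the
Bioconductor convention; GTF is native and BED is shifted on read.  Windows
are clipped at chromosome bounds, never extended.

## The differential model

Signals are first normalized per gene to the untreated wild-type baseline:
each value (plus pseudocount $\varepsilon$) is divided by the geometric
mean of the untreated-WT samples (plus $\varepsilon$), per batch when batch
ids are present and globally otherwise, so the baseline cells have
geometric mean exactly 1.  The default $\varepsilon$ = 0.1 FPKM keeps
zero-coverage cells finite on the log scale while perturbing typical
signals (FPKM of order 1-100) by little; it is exposed in every function
that logs or ratios.

Each gene's $\log_2(\text{signal} + \varepsilon)$ values are then fit with
a genotype × treatment two-way ANOVA.  The reference design is unbalanced —
4 untreated and 5 FC-treated pairs per genotype — so main effects use Type
II sums of squares (each main effect adjusted for the other; with no
a-priori ordering of factors this is the standard choice).  The assumptions
are the usual ones: approximately normal log-scale noise with common
within-cell variance; the synthetic calibration below probes how far
Poisson counting noise bends them.

The four reported comparisons (FC effect in WT, FC effect in KO, KO vs WT
untreated, KO vs WT under FC) are pairwise contrasts of cell means tested
Fisher-LSD style against the pooled residual mean square with its residual
degrees of freedom — the most literal reading of "pairwise comparison of
means using the mean square error".  No within-gene multiplicity correction
is applied; instead each comparison family is Benjamini-Hochberg adjusted
across genes, mirroring how each comparison is reported separately.  The
contrast estimate on the log2 scale is the log2 ratio of geometric means,
which is also what the reporting uses.  Classification is `up` when the
ratio reaches $\log_2 1.5$ with $p < 0.05$, `down` symmetrically, else
`no_change`; both thresholds are parameters.

Degenerate genes are flagged rather than guessed at: zero residual degrees
of freedom is an error, a zero-MSE gene with equal means gets $t = 0$, and
an all-zero baseline with $\varepsilon = 0$ is excluded with a warning.

## Binding islands

The island caller reimplements the SICER idea at desk scale: tile each
chromosome into 100 bp windows, count weighted fragments by midpoint, and
call a window eligible when $P(X \ge \text{count}) \le 0.05$ under
Poisson($\lambda$) with $\lambda$ = total weighted reads × window width /
effective genome length (the annotated chromosome lengths in the toy
setting; mappability correction is out of scope).  Weighted counts are
rounded up inside the tail, which is exact for integer counts and
conservative otherwise.  Eligible windows at most 600 bp apart merge into
islands; the island score is $\sum -\ln P(X \ge c_i)$ over eligible member
windows, its p-value the product of those tails ($e^{-\text{score}}$), with
BH across islands.  This reproduces the published tool's ranking behaviour
without its convolution-based score distribution, which is a non-goal.
Input chromatin is subtracted per member window after scaling by the
library ratio, then islands are rescored.  "Binding islands" pass
$p \le 0.05$, score ≥ 200 and FDR ≤ 0.05 jointly.  The absolute score
cutoff is depth-dependent; at the synthetic depths used here a planted
8-fold, 5 kb block scores in the hundreds while homogeneous noise scores
in single digits, so the published cutoff separates cleanly.  A "bound
gene" is one whose TSS window or body overlaps a significant island —
the definition is recorded in output rather than assumed.

## Gene-set enrichment

PAGE computes, for each set of $m$ scored genes with mean log2 ratio
$S_m$, $Z = (S_m - \mu)\sqrt{m}/\delta$ against the mean and SD of all
scored genes — not only genes appearing in some set — with two-sided normal
p and BH q.  Genes without a finite ratio are dropped from background and
sets alike.  $Z$ is invariant to shifting all ratios and to positive
rescaling, so ranked term lists are stable to global normalization choices;
"top negative" lists take the $k$ most negative $Z$ with name tie-breaks.

## What the synthetic study emulates — and what it does not

`sim_config()` defaults define the validation conditions: 2000 genes with
1-5 exons on 3 toy chromosomes; log-normal baselines (sdlog 1, a realistic
ChIP dynamic range); the 4 + 5 pair design; 10% of genes responsive at
2-fold in WT with total attenuation in KO; 2e5 fragments per sample of
fixed 300 bp length (the midpoint of a 200-400 bp sonication range);
multiplicative log-normal replicate noise (sdlog 0.25, biological CV of
roughly 25%); 5% multimappers with $n \in \{2,3,4\}$ (the $n = 4$ plants
exercise the discard rule); 1% PCR bursts of 7 extra copies (exceeding the
cap); and a placement kernel putting 60% of a gene's fragments in its TSS
window and 40% on its exons.  TDRD3 samples share the Pol II baselines with
independent log-normal distortion sized for a gene-level log correlation of
0.9.

The kernel is a pragmatic stand-in for promoter-proximal Pol II enrichment,
not a mechanistic model: there is no sequence, no chromatin state, no
fragment-length variation, no mappability structure, and decoy multimapper
placements are uniform.  Passing tests therefore demonstrate that the
*computational* chain is correct and calibrated under a plausible noise
model — not that any biological claim holds in real tissue.

## Numerical choices and problem sizes

Ties in duplicate capping break by input order after a stable sort;
window assignment uses integer fragment midpoints (even-length fragments
floor the half-base); profile bins tile $[-\text{span}, +\text{span})$ so
the mirror of offset $x$ is $-x-1$; percentage reporting rounds half away
from zero at the stated precision (base R's half-even rounding would turn
12.5% into 12%).  Hierarchical clustering uses 1 − Pearson distance with
average linkage on row-wise Z-scores, constant rows excluded, and no
leaf-order optimization so results are deterministic in the input order.

The validation suite runs at deliberately modest sizes chosen once: the
null-calibration study uses the full 2000-gene default (type-I error of the
complete pipeline is checked against a three-sigma binomial band),
recovery-monotonicity studies use 600 genes at two depths and two replicate
counts, island null and plant use a 10 Mb and 2 Mb toy chromosome, PAGE
calibration uses 1000 random sets of 50 over 10,000 genes, and the ANOVA is
checked against an `lm()`/`car::Anova()` oracle on 100 random instances.

## Known limitations

Transcript-level quantification, alternative TSS handling, spike-in or
input scaling at the FPKM stage, negative-binomial count models, and
mixed-effects designs are out of scope.  The duplicate cap biases truly
saturated short regions downward at high depth — visible in the synthetic
convergence checks, and the reason audits can set `cap = Inf`.  The pseudocount and
the Type II sums of squares are design choices where a published analysis
could have differed; the suite perturbs the pseudocount and checks that
desk-scale classifications barely move, while the SS flavour only matters
for the unbalanced main effects and is fixed here as the standard choice.
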