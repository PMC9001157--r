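---
title: "Methods: building and evaluating a multi-locus chloroplast reference database"
author: "refkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating a multi-locus chloroplast reference database}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refkit)
```

## The problem

Plant metabarcoding lacks a single universal locus: chloroplast regions such
as *matK*, *rbcL* and *trnH-psbA* each discriminate some groups well and
others poorly. One answer is a *multi-locus* reference database built by
hybridization capture: a probe panel enriches sequencing libraries for many
(here, twenty) chloroplast gene regions at once, consensus sequences are
called per sample and gene, and the resulting database is evaluated for how
well it identifies its own members and separates taxa by genetic distance.

`refkit` implements that whole desk-side workflow as testable components:

1. **Probe panel design** — cluster candidate targets at 95% identity,
   keep the longest sequence per cluster, tile 120-mers at 2X.
2. **Consensus calling** — quality-filter pileup observations, call a
   haploid majority base per position, mask low-depth positions to `N`,
   annotate gene regions by local alignment.
3. **Database accounting** — FASTA + taxonomy I/O and the gene-recovery
   matrix (which genes yielded usable sequence for which samples).
4. **Leave-one-out evaluation** — search each record against the database
   minus itself; classify the best hit by the lowest shared taxonomic rank.
5. **Distance analyses** — Kimura two-parameter (K2P) distances per gene
   and over gene concatenations: baseline profiles, an all-genes UPGMA
   dendrogram, and iterative-concatenation curves for comparison groups.
6. **Synthetic data** — a generator with known truth for all of the above.

## Alignment substrate

Real capture studies delegate comparisons to external tools (an MSA program
for alignments, a local-search tool for database hits, a greedy clusterer
for probe design). `refkit` instead rests on one explicit primitive: exact
pairwise alignment by dynamic programming, global (Needleman–Wunsch/Gotoh)
and local (Smith–Waterman), with affine gaps.

Fixed conventions, chosen once and tested:

* default scores match +1, mismatch −1, gap open −2, gap extend −1; a gap
  of length $k$ costs $\mathrm{open} + (k-1)\,\mathrm{extend}$; a linear
  mode (every gap column at the open cost) exists because the test-suite
  enumeration oracle is linear-gap;
* `N` is scored as a mismatch against everything, including `N` — masked
  positions are not evidence of similarity;
* traceback ties prefer the diagonal, then the vertical, then the
  horizontal move, so every alignment is deterministic;
* batch comparisons align each pair in a canonical orientation
  (lexicographically smaller sequence first), making pair statistics
  orientation-free; database searches therefore do not depend on which
  member is called "query";
* two identity denominators: per alignment column (used for annotation and
  top-hit ranking) and per shorter ungapped sequence (the CD-HIT-style
  clustering criterion).

A consequence worth knowing: identity-over-the-shorter can be high between
unrelated sequences of very different lengths, because a short sequence
embeds almost entirely into a long one. Greedy clustering shares this
behaviour with its inspiration and, as there, representatives of different
clusters are not guaranteed to be mutually below the threshold.

## Probe design

Within each gene region, sequences are visited longest-first (ties broken
by id) and greedily attached to the first existing cluster whose
representative they match at identity-over-shorter ≥ 0.95 (configurable).
Representatives are tiled with 120-mer probes at a 60 bp step ("2X tiling":
each probe overlaps half its length). If the final regular probe ends short
of the sequence, one extra probe is anchored at the 3′ end so every base is
covered; the tiling boundary rule is otherwise unstated in common practice,
so this choice is ours. Sequences shorter than one probe are skipped with a
warning. For $L \ge 120$ every base is covered; for $L \ge 180$ every base
more than 60 bp from either end is covered at least twice.

Target extraction from a reference genome is by local alignment with two
acceptance thresholds, identity ≥ 0.70 and reference coverage ≥ 0.50 by
default. These stand in for an E-value cut-off: E-value calibration would
require score statistics out of proportion to the decision being made, and
the downstream clustering is robust to the exact threshold.

## Consensus calling

The pileup model is deliberately simple: one observation per row with a
base, base quality and mapping quality. An observation counts only if both
qualities are ≥ 30. Per position the caller is haploid: the single majority
base among quality-passing observations, masked to `N` when

* depth (quality-passing observations) is below 50, or
* the maximum count is tied — a haploid caller should not invent certainty,
  so ties are ambiguity, not a priority call.

Raising the depth threshold can only grow the masked set (tested as a
monotonicity property). Indels are out of scope; coordinates are ungapped.

Gene annotation aligns each reference gene locally against the consensus
(optionally restricted to a hinted window widened by 100 bp on either side)
and accepts a hit when column identity ≥ 0.25 **and** the footprint covers
≥ 50% of the reference. The identity floor alone is not usable with local
alignment: an optimal local alignment is by construction high-identity,
however short, so chance 8–10 bp hits on unrelated sequence would pass any
identity test. The coverage requirement is what makes "similarity 25%"
meaningful; a fully masked gene region is then correctly reported absent
(`N` runs score as mismatches and cannot anchor a credible footprint).

## Recovery accounting

A gene counts as recovered for a sample when a sequence exists and at least
50% of its bases are unambiguous (configurable). Presence/absence is what a
recovery figure shows; the 50% floor keeps husks of `N`s from counting.
Lowering the floor can only add recoveries (tested).

## Leave-one-out evaluation

Each sample carrying a gene is ranked against all other carriers by global
alignment column identity; ties break by more aligned matches, then sample
id. The best hit's taxonomy is compared with the query's and classified by
the lowest shared rank (species → genus → family → order → class, else
none). All-`N` sequences cannot be informatively searched and are excluded
from evaluation (they remain harmless candidates).

"Matched at family level or below across all genes" admits two readings, so
both are computed: the percentage of all (sample, gene) assignments at
species/genus/family rank (the pooled headline) and the percentage of
samples whose best assignment over genes reaches family or below.

## K2P distances

With $P$ and $Q$ the transition and transversion proportions over
comparable sites,

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q). $$

Columns with a gap or `N` in either sequence are excluded (pairwise
deletion). Outside the formula's domain the distance is **undefined** and
propagates as `NA` with a reason — never silently 0 or a maximum. The one
documented exception: before UPGMA clustering, undefined entries are
imputed at the matrix maximum (with a message), since an agglomeration
needs a complete matrix and incomparable pairs are at least as divergent as
anything observed.

Multi-gene distances are computed per gene and pooled by site counts.
Pooling counts is *exactly* the concatenated-alignment computation — the
pooled $P$ and $Q$ equal those of the concatenation — while aligning genes
separately respects their boundaries and reuses per-pair work. This is also
how missing genes behave under "gaps for missing data": an absent gene is
an all-gap block, pairwise deletion removes it, and the distance is over
the genes both samples share. Pairwise alignment replaces a multiple
alignment throughout; pairwise-deletion K2P from a pairwise alignment is a
well-defined quantity, though column-level results can differ from any
particular MSA.

The dendrogram uses UPGMA (average linkage) by default because the distance
matrix is built from roughly clock-like divergence; complete and single
linkage are available. Iterative concatenation orders genes with the
standard barcodes first (*matK*, *rbcL*, *trnH-psbA*) and the rest shuffled
by a seed, then reports the distance of every comparison-group member to
the baseline at each prefix length $k$. Comparison groups default to four
strata relative to the baseline's taxonomy: within species, within genus,
within family, and between families of the same order.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, with
exact known truth:

* **Taxonomy**: a nested grid (classes × orders × families × genera ×
  species × samples) with deterministic names and cyclic location labels.
  The default grid (2 × 2 × 2 × 2 × 2 × 3) yields 96 samples; study-scale
  runs trim to 93, the size of the motivating application. Counts may be
  vectors for uneven designs.
* **Sequences**: per gene, a uniform-composition root evolves down the
  ultrametric rank tree under continuous-time K2P with transition/
  transversion ratio $\kappa$ (default 3, a typical plastid value) and a
  per-gene lognormal rate multiplier (sdlog 0.3). Branch depths are set so
  the expected distance between two samples equals the divergence
  configured for their most recent common rank: species 0.001, genus 0.02,
  family 0.08, order 0.15, class 0.25, between classes 0.35. Star-like
  rank trees (rather than general birth–death trees) give exact expected
  distances per comparison category, which is what stratified distance
  curves need.
* **Gene lengths**: drawn uniformly on 180–900 bp, the length range typical
  of capture-targeted chloroplast regions.
* **Dropout**: each (sample, gene) drops independently at rate 0.1 by
  default — Binomial(20, 0.9) puts the mean recovered genes at 18 of 20 —
  with at least one gene guaranteed per sample (bounded redraws).
* **Pileups**: per-position depth is a rounded truncated normal (default
  mean 120, sd 30); each observation is the true base with probability
  0.99; base and mapping qualities are two-point mixtures so a controllable
  fraction fails the quality-30 filter.

Everything is reproducible byte-identically from (config, seed); every
generator stage draws from its own derived seed, so stages can be re-run
independently.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no indels (simulated homologs are column-true, so
distance-estimator tests are isolated from aligner error; indel-bearing
cases are exercised separately in the alignment tests), no chloroplast
genome structure, no base-composition bias, no among-site rate variation,
no mapping or duplication artifacts upstream of the pileup, and taxonomy
trees are star-like within ranks rather than realistically imbalanced.

One measurable consequence: rank-structured truth ties many true distances,
which caps rank-correlation statistics between estimated and true distances
below 1 even for a perfect estimator; recovery tests therefore compare
against the attainable ceiling rather than an absolute correlation.

## Numerical and design choices

* Consensus ties → `N`; annotation needs identity **and** coverage;
  undefined distances propagate as `NA` (imputation only at the dendrogram,
  logged).
* Alignment tie-breaks and canonical pair orientation make every search and
  distance deterministic; re-running any stage on the same inputs gives
  identical bytes.
* The K2P estimator is validated by simulation: at 10 kb sites and true
  distances 0.01/0.05/0.20 the mean estimate over 200 replicate pairs lies
  within three standard errors of truth.
* Problem sizes: unit tests run on databases of 8–32 samples and genes of
  150–900 bp; the end-to-end study analogue uses 93 samples × 20 genes with
  10% dropout, matching the scale of the motivating application.

## Limitations

The local-search ranking is alignment-identity based, not score/E-value
based, so results on real data may differ from a BLAST-derived workflow in
edge cases (highly partial sequences, compositionally biased regions). The
greedy clusterer has no word filter and is quadratic; it is meant for
panels of thousands of representatives, not millions of reads. The caller
is strictly haploid and indel-free. The generator's ultrametric strata are
a deliberate idealization: they make expected distances exact at the cost
of realistic tree shape.
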