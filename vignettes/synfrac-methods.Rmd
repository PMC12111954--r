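---
title: "Methods: synteny-based fractionation analysis and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny-based fractionation analysis and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Grass genomes share an ancient whole-genome duplication (a tetraploidization
roughly 100 Mya, here called the GCT after the field's usage). Most duplicate
gene copies have since been lost — *fractionation* — and the rate and bias of
those losses is a readable record of genome stability: which chromosomes,
which subgenomes, and which evolutionary periods shed genes fastest.
`synfrac` reconstructs that record from gene collinearity. Its inputs are the
ordinary products of a comparative-genomics workflow: gene positions (GFF3 or
BED), coding sequences (FASTA), an all-vs-all protein homology table (BLAST
tabular), and a dated species tree (Newick, branch lengths in My). One genome
serves as the reference (in the motivating system, *Leersia perrieri*, an
outgroup to *Oryza* that shares the GCT).

The package treats absence of a *collinear* ortholog as the operational
definition of gene loss. A gene that survives but has moved out of its
ancestral context counts as lost under this definition; that is a property of
the collinearity-based method, and all loss statistics inherit it.

## Collinear block detection

Blocks are chained in gene-rank coordinates (the order index of genes along a
chromosome), the standard dot-plot coordinate for synteny: base-pair
distances vary with intergenic expansion, while rank gaps directly count
intervening gene placements. Filtered homology hits become anchors (best bit
score per unordered gene pair; the self-comparison diagonal is excluded), and
for each chromosome pair the highest-scoring chain that is strictly monotone
in both ranks (ascending for `+`, descending for `-`) is extracted by dynamic
programming, its anchors are removed, and the extraction repeats. Anchors
therefore belong to at most one block, which keeps "collinear gene" counts
free of double counting.

Scoring is the one genuinely open design in this module, and we diverge
deliberately from penalizing raw rank gaps. A chain's score is the sum of
anchor scores (default 10 per anchor) minus a penalty (default 6) for every
anchor of the chromosome pair that the chain skips over — anchors of the
original set whose rank falls strictly inside a gap between consecutive chain
anchors, on either axis. The reasoning: after heavy fractionation, lost genes
leave long rank gaps that carry *no conflicting homology signal*, and a
rank-gap penalty would shred exactly the blocks the analysis needs intact;
skipped anchors, in contrast, are positive evidence of a conflicting
arrangement (an inversion, a translocated segment), and leapfrogging them
should be expensive. With the default anchor score 10 and skip penalty 6,
closing a chain at an inverted segment beats bridging it, so a collinear run
with an internal inversion resolves into `+`/`-`/`+` blocks rather than one
block that swallows a corner of the inversion. A hard cap (`max_gap`, default
25 ranks on either axis) bounds bridges across genuinely empty space, and
blocks need at least `min_anchors = 5` anchors.

Block significance uses a closed approximation: with `m` anchors in an
envelope covering fraction `p_cell` of the chromosome pair's rank grid, and
`n` anchors total on the pair, the expected number of co-monotone `m`-subsets
in the envelope is `lambda = C(n, m) p_cell^m 2/m!`, and
`p = 1 - exp(-lambda)`. Monte-Carlo experiments (in the test suite) show this
is conservative by a small factor (roughly 2 in the regimes probed); it is
meant for ranking and flagging, not for calibrated inference.

## Ks estimation and homology classes

Synonymous distances use the Nei–Gojobori (1986) pathway-counting method:
per-codon synonymous site fractions from the universal genetic code
(mutations to stop codons count as nonsynonymous, so `S + N = 3 x`
codons exactly), multi-hit codons averaged over all orderings of single-step
pathways excluding those through stops, and Jukes–Cantor correction
`dS = -(3/4) log(1 - (4/3) pS)`. A distance saturates at `pS >= 3/4`.
A block's Ks is the *median* of its defined anchor values — robust to the
occasional anchor that pairs a tandem copy rather than the positional
ortholog.

Blocks are classified by Ks: below 0.3, orthologous (cross-species
divergence in this clade); in 0.4–0.9, paralogs from the shared
tetraploidization (the Ks-0.6 peak); anything else, including saturated
blocks, unclassified. The 0.4–0.9 window is deliberately wider than the
ortholog cutoff to absorb lineage rate variation. Ks-to-time conversion
`T = Ks / (2 r)` is provided with the clock rate `r` as an explicit
parameter; the pipeline default (6.5e-9 substitutions/site/year) is an
arbitrary placeholder that real analyses must calibrate. Rate correction
across species rescales each Ks distribution by the ratio of kernel-density
modes of a shared event; when two modes are within 10% density of each other
the larger is used, with a warning.

## The alignment table and loss accounting

The reference-anchored table has one row per reference gene and one column
per (species, class): each species' ortholog column, the reference's two
paralog-copy columns (from its own GCT blocks), and each species' two
paralog-copy columns (from GCT-class blocks against the reference). Cells
hold the partner gene id or are absent (a dot on disk). All filling is
block-level: a cell is claimed by the highest-scoring covering block, ties
broken by anchor count then block id, and within a column a partner id is
used at most once. When a gene has two surviving paralog partners, copy 1 is
the one on the lower-ordinal chromosome; a single surviving partner occupies
copy 1.

From the table follow, without further inference:

* **Per-chromosome loss fractions** (absent ortholog cells over reference
  genes) and retention in half-open 1-Mb windows on reference coordinates
  (step = width).
* **The ordinal trend**: Spearman correlation between chromosome ordinal and
  loss fraction with a seeded permutation p-value (10,000 shuffles by
  default). This statistic is this package's explicit form of the
  qualitative claim that smaller-numbered chromosomes are more stable; it is
  labelled as such in output.
* **Subgenome partition**: each reference GCT block pairs two homoeologous
  regions; per species, the side with more retained orthologs is
  `subgenome_more`, ties going to the lower-ordinal chromosome; regions with
  both sides fully lost are excluded and counted.
* **Dollo branch assignment**: each reference-attested gene is presumed
  ancestrally present (the reference acts as an always-present outgroup);
  one loss is placed on the stem of every maximal all-absent clade. Branch
  rates are losses over branch duration (genes/My).

A caveat documented here because it shapes validation: Dollo parsimony maps
two *independent* losses of one gene in sister lineages to a single loss on
their stem branch. The Dollo estimate is therefore not an unbiased estimate
of per-branch loss *events*; it estimates the Dollo projection of the
presence patterns. Parameter-recovery checks accordingly compare the
pipeline's Dollo counts to the same Dollo operator applied to the true
simulated patterns, which isolates detection error from the parsimony
convention.

## Tandem clusters and enrichment

Two genes are tandem-linked when homologous, on one chromosome, and
separated by at most `max_gap` intervening genes (default 5 — there is no
field-standard definition, so the knob is echoed in every report header);
clusters are connected components of the link graph, singletons dropped.
Summary densities divide the tandem count by a *caller-declared* genome
length so that published ratio arithmetic can be reproduced whatever units
the source table used.

Association between two gene properties (tandem membership and family
membership, say) uses the Yates-corrected chi-squared on the 2x2 table, with
the upper-tail probability computed by `pchisq` in the far-tail regime
(p-values near 1e-300 remain representable). The continuity-corrected form
is the reference behaviour because recomputing published p-values from their
printed counts matches only the corrected statistic; an uncorrected option
and a Fisher variant exist. Over-representation analysis applies the same
2x2 machinery per category with Benjamini–Hochberg correction. Family calls
from two evidence lines (a domain scan and a homology search) are their set
intersection.

## The simulator

The generator produces the statistical structure the analysis assumes, plus
complete ground truth: a 7-chromosome ancestor; whole-genome duplication;
nested fusions (by default `c6a` into `c2a` and `c7b` into `c3b`, 14 to 12
chromosomes, with chromosomes then relabelled 1..12 by descending gene count
so the fused neo-chromosomes get the small ordinals, as in the grass
karyotype); branch-specific losses (Poisson with mean rate x duration,
90% drawn from families still carrying both WGD copies, weighted by a
per-chromosome multiplier and optionally by a copy-b subgenome bias);
inversions reversing random rank intervals; tandem bursts inserting adjacent
near-copies; and sequence divergence.

Default study conditions: 360 genes per ancestral chromosome (5040 genes in
the post-WGD root genome), 100 codons per gene (500 in the sequence-accuracy
experiments), a 4-species tree `(((spA:2,spB:2):28,spC:30):5,ref:35)` in My
with per-branch loss rates (150, 30, 30, 270, 150, 25 genes/My for the
ingroup stem, the spA-spB stem, spC, spA, spB and ref respectively) chosen
to land leaf lineages at roughly 35-50% loss of reference-attested genes —
the regime the motivating system reports. The chromosome multiplier ramps
linearly 0.7 to 1.4 across ordinals 1..12 (configurable to flat for null
experiments); one inversion and ten tandem events per branch in expectation;
5% of families are tagged as a tandem-prone "resistance-like" family
(8x weight as tandem parents), which gives the enrichment stage a true
association to find.

Sequence evolution is built so that realized dS tracks its target exactly
rather than approximately: ancestral CDS are drawn from fourfold-degenerate
codon families (Val, Ala, Gly, Thr, Pro, Ser), making every third position
fully synonymous (one synonymous site per codon); third positions then
evolve under Jukes–Cantor at the branch's synonymous distance
(clock rate 3.5e-9/site/year by default, so reference-vs-ingroup orthologs
sit near Ks 0.245, inside the sub-0.3 ortholog regime) and first/second
positions at `omega_n/omega_s` (default 0.1/0.9) of it, with stop-creating
draws reverted. The WGD copies receive an initial offset so surviving
paralog pairs reach Ks 0.6 at the leaves. This is a deliberate
simplification: amino-acid composition is unrealistic (six residues), there
is no transition/transversion bias, no rate variation among sites or genes,
and no gene conversion. Passing recovery tests therefore demonstrates that
the estimators are correct under their own model assumptions, not that real
genomes satisfy those assumptions. Likewise the homology table is
synthesized from true families (with optional noise rows), so hit-filtering
robustness to real BLAST artefacts is exercised only lightly.

True pairwise synonymous distances are additive along the tree (plus WGD
and tandem birth offsets); for tandem-involved pairs the bookkeeping is an
additive approximation, documented in `true_ds()`.

## Validation design and problem sizes

The test suite validates each estimator against an independent oracle:
exhaustive chain enumeration on anchor sets of up to 15; brute-force
minimal-branch-cover search over all 256 presence patterns on an 8-leaf tree
(plus outgroup) for Dollo; exact enumeration of the 120 orderings for the
5-chromosome permutation test; a Monte-Carlo placement experiment for block
significance; a hand-computed NG86 example (100 GGT codons with 10 GGC
substitutions: S = 100, N = 200, dS = 0.10733); and `chisq.test` as a
cross-check of the corrected chi-squared. Published worked examples whose
inputs are printed alongside them (contingency counts, branch loss counts
and durations, genes-per-block and tandem-density ratios) are recomputed
exactly.

End-to-end parameter recovery runs the full pipeline on the default
5040-gene simulation (chosen so each analysis completes in tens of seconds
on one core while leaving per-branch loss counts in the hundreds): anchor
F1 against true collinear pairs is ~0.999; per-branch Dollo counts are
within ~1% of the truth projection (the acceptance bound is 15%); the
ordinal trend is recovered with Spearman rho well above 0.7; NG86 mean bias
at dS targets 0.1/0.3/0.6 with 500-codon genes is below 0.01. The
subgenome-partition experiment uses the 2x biased scenario with *flat*
chromosome multipliers: with the ordinal ramp active, a region that pairs a
low-ordinal fused chromosome (low multiplier, biased copy) with a
high-ordinal one can have near-identical expected loss on both copies, so
"the biased copy" is not a recoverable quantity there; under the flat
design the partition recovers the biased homoeolog in 100% of regions with
at least 10 genes.

## Known limitations

* Loss is collinearity-based; movement out of context counts as loss.
* Block counts are parameter-sensitive (no merging of adjacent broken
  blocks is attempted), so cross-study comparisons of block numbers should
  fix the chaining parameters first.
* The significance approximation is conservative and uncalibrated in the
  tails; use it for ranking.
* The clock rate, the tandem `max_gap`, and the Ks class windows are
  conventions, surfaced as parameters and echoed in outputs, not inferred
  from data.
* Hit symmetrization: the hit set is treated as undirected after filtering;
  directional asymmetries in the input search are collapsed by keeping the
  best score.
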