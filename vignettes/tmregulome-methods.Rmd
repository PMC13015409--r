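---
title: "Methods: integrating chromatin dynamics, loops and GWAS variants in the steroid-treated trabecular meshwork"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating chromatin dynamics, loops and GWAS variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`tmregulome` integrates processed regulatory-genomics data from a
two-condition design (vehicle control versus glucocorticoid treatment of
trabecular meshwork cells) across six layers — peaks, enhancer chromatin
states, super-enhancers, enhancer RNAs, promoter-capture Hi-C loops and
A/B compartments — and maps GWAS variants for intraocular pressure and
primary open-angle glaucoma onto target genes through those layers. The
pipeline starts from *called* features: peak calling, loop scoring,
compartment eigenvectors, transcript quantification and differential
expression are upstream tools' jobs and arrive as inputs.

All internal coordinates are 0-based half-open (BED-native). GTF records
and variant positions, which are 1-based inclusive by convention, are
converted on read, and conversion is lossless on a write/read round
trip. Chromosome names match as exact strings; interval sets sharing no
chromosome produce zero overlaps plus a warning naming the unshared
chromosomes, never silent aliasing.

# Procedures and their assumptions

## Consensus and differential features

Replicate consensus uses merge-then-count: candidate regions are the
union-merge of all replicate peaks, and a candidate is kept when at
least *k* replicates touch it (any overlap, at least 1 bp). The
alternative idiom — pairwise intersection — yields fragmented regions
and is sensitive to replicate order; merge-then-count keeps regions
contiguous and is symmetric in the replicates. It is also monotone in
*k*, which the tests assert. Whether a study's own replicate filter used
one idiom or the other is rarely stated; the choice is isolated in
`consensus_peaks()` and shared by SE consensus.

Condition differences (`diff_peaks()`, `se_diff()`) label a feature
stable when it overlaps any feature on the other side by at least 1 bp
— the bedtools-intersect default. Reciprocal-overlap variants were
considered and deliberately left out of the default path: every
downstream count in the pipeline inherits the 1 bp rule, so a single
overlap criterion keeps all layers commensurable.

## Enhancer states and switches

The state scheme is the standard three-mark convention: H3K4me1 with
H3K27me3 is poised, H3K27ac without H3K27me3 is active, H3K4me1 alone is
primed, anything else inactive, with precedence poised > active >
primed > inactive. Two points are genuinely open and resolved here as
package policy: H3K4me1 is *not* required for the active call (H3K27ac
alone suffices), and the H3K27ac ∧ H3K27me3 ∧ ¬H3K4me1 corner resolves
to inactive rather than poised because poised is defined on the
H3K4me1 + H3K27me3 pair. The truth table is exhaustively tested on all
2³ mark subsets and can be overridden by classifying with custom peak
sets.

A switch is a transition between active and the non-active pool in
either direction; transitions inside the non-active pool (e.g. primed to
poised) are `stays_nonactive`, since the biological readout of interest
is activation.

## Super-enhancers

`stitch_and_rank()` follows the ROSE geometry with its canonical
defaults: stitch gap 12,500 bp (inclusive: a 12,500 bp gap merges, a
12,501 bp gap does not) and TSS exclusion ±2,500 bp, applied by dropping
constituents *fully inside* an exclusion window before stitching. Region
signal is the sum of overlapping H3K27ac peak signals prorated by the
overlapped fraction of each peak, which is deterministic and independent
of peak order. `se_cutoff()` scales rank and signal to [0, 1] and takes
the argmax of (scaled rank − scaled signal); ties break toward the
larger index so that ambiguity yields *fewer* super-enhancers, and a
curve whose maximum gap is below 10⁻⁹ (constant or effectively linear)
yields none, with a warning. The cutoff is invariant to affine
rescaling of the signals by construction.

Tissue specificity against an external SE catalog counts a catalog
sample when a *single* catalog SE covers at least 70% of the query SE's
length. The wording "overlapping at least 70% of a TM SE" fixes the
coverage direction (fraction of the query, not of the catalog SE) but
not whether multiple catalog SEs may stack; single-SE coverage is the
default and a `stacked = TRUE` variant unions the sample's SEs first.

## Enhancer RNAs

The cascade merges enhancer segments within 50 bp, then rejects merged
regions with any gene-body overlap, regions nearer than 3,000 bp to a
TSS, and regions nearer than 3,000 bp to an H3K4me3 peak. Distances are
edge-to-edge gaps (overlap means distance zero) measured from the region
edge, not its midpoint, and "within 3 kb" is strict: a region exactly
3,000 bp away survives. The filters are conjunctive, so their order
cannot change the outcome — a property test permutes them. Expression
retention is `CPM > min_cpm` (strictly) in at least `min_samples`
samples; the boundary rows [1.0, 1.2, 0.5] (dropped) and [1.1, 1.1, 0]
(kept) are frozen in the tests. CPM is plain library-size normalization;
TMM-scaled libraries can be supplied instead by pre-scaling the counts,
since the retention rule only consumes the matrix.

## Loops and compartments

Two loops match when both anchors overlap, in either anchor pairing;
anchors are canonicalized on read so the match is symmetric. Sample
consensus clusters loops by single linkage over this relation and keeps
clusters spanning at least *k* distinct samples, with the anchor-wise
union span as representative — deterministic and order-independent.
Anchor padding is exposed (`padding`) and defaults to 0.

Compartment windows are classified by score sign; an exact zero takes
the flanking-window majority and otherwise defaults to B with a warning
(B is the conservative call for a vanishing eigenvector). Shift
detection consumes external per-window significance flags by default,
emulating a dedicated differential-compartment caller, whose statistical
model this package deliberately does not re-implement; a z-scaled delta
threshold (default 0.3) is available when no flags exist. The package's
own statistical step is downstream: a one-sample two-sided t-test of
per-window signal changes against zero within each shift direction,
erroring on fewer than two windows or zero variance rather than
emitting unstable statistics.

## Variants and integration

LD expansion keeps proxies with r² at or above the threshold within
1 Mb of their lead. No r² threshold is printed in typical LDproxy
workflows' reports; 0.8 is the default here and every output records the
threshold used. The peri-SNP window "within 5 kb" reads as SNP ± 5 kb
(a 10 kb window); the variant-loop rule requires variant and promoter in
*opposite* anchors; the SE rule requires both inside one SE interval.
Closest genes report every gene tied at the minimum body distance.

For the 16 gene sets, a gene overlaps a feature when the feature touches
the union of gene body and promoter — requiring the promoter alone would
silently drop body-internal enhancers, and the body alone would drop
upstream elements; the union is the permissive, symmetric choice and is
a single knob in `genes_overlapping()`. The promoter window itself
(−2,000/+500 around the TSS, strand-aware, clipped at zero) is a
configuration default, not a literature constant: no annotation version
or window is canonical for promoter-capture panels, so every
promoter-dependent result is parameterized on it. Repressor anchors are
H3K27me3/H3K9me3-marked segments supplied as their own input track.
Over-representation uses the one-sided hypergeometric tail with BH
correction per set, against the universe of all genes in the gene-model
file — the most conservative universe available without asserting an
annotation coverage that the inputs do not carry.

## Chromatin-state model selection

Given emission matrices for increasing state counts, each model's score
is the mean, over its states, of the best Pearson correlation against
the next-larger model's states; constant emission rows correlate as 0
with a warning. The selected count is the state count of the last model
*before* the first score gain below epsilon (default 0.01): the curve
has plateaued once an extra state stops adding correlation structure, so
the plateau's first member — not its successor — is the chosen model.

# The synthetic-data generator

`generate_dataset()` lays the genome out in fixed-width gene slots (one
gene per slot, default 150 slots of ~67 kb per 10 Mb chromosome) cycling
through six roles: enhancer clusters, eRNA loci, filter decoys,
super-enhancers, loop-distal anchors, and background. The slot geometry
guarantees that planted features are spatially isolated — no decoy
accidentally rescues a candidate, no variant accidentally lands in a
loop anchor — which is what makes exact planted-truth recovery a
meaningful contract rather than a statistical hope. Placement of
variants additionally resamples against an avoid-list of all anchors and
SEs (with a 500 bp margin for consensus-span growth under jitter).

What it emulates: per-replicate peak files with Gaussian boundary jitter
(sd 25 bp) and 10% peak dropout, so k-of-n consensus is non-trivial;
per-sample loops present in 2 or 3 of 3 replicates with ±30 bp anchor
jitter plus sample-private noise loops that consensus must discard;
negative-binomial counts (dispersion 0.1) with planted log2
fold-changes; eRNA count libraries fixed at one million so planted CPM
boundaries are exact; an external SE catalog in which planted
TM-specific SEs appear in 2.5% of samples and ubiquitous ones in 95%;
tissue loop catalogs that omit TM-specific loops; and emission matrices
whose consecutive-model correlation curve rises in controlled 0.015
steps to exactly 1 at 13 states (the construction uses exact-correlation
vectors and verifies its own curve, redrawing from derived sub-seeds if
a random cross-correlation intrudes).

What it does not emulate: read-level noise, mappability and GC structure
in peaks; CHiCAGO score distributions and distance decay in loops;
eigenvector estimation noise in compartment scores; realistic LD block
structure (proxies are placed uniformly around their leads). Passing the
recovery tests therefore demonstrates that the *integration logic* is
correct under the stated geometric contracts — it does not certify
behavior under upstream-caller artifacts, which is exactly the division
of labor the pipeline assumes.

`synthetic_config(noise = FALSE)` zeroes jitter, dropout and anchor
jitter; on this noiseless placement every layer's planted truth is
recovered with precision = recall = 1, and the test suite asserts it
end-to-end. With default noise the loop, variant and eRNA layers remain
exact (their geometry tolerates the perturbations by design margin),
while peak-derived layers degrade gracefully; the enhancer-switch
recovery test runs with dropout disabled because 2-of-3 consensus loses
a truth peak with probability ~2.8% per mark and condition under 10%
dropout, a generator property that would otherwise be mistaken for
classifier error.

The default scale — 2 chromosomes × 10 Mb, 300 genes, ~130 enhancer
elements, ~50 SEs, ~170 planted loops plus 240 noise loops, 400
compartment windows, ~45 lead variants with ~4 proxies each — was chosen
so a full generate-and-run cycle completes in well under a minute on a
single core while every layer still has enough planted events (tens per
class) for precision and recall to be informative.

# Numerical choices and degenerate inputs

* Overlap is always at least 1 bp; book-ended intervals do not overlap
  but do merge in union-merge operations.
* `se_cutoff()` requires at least 3 regions, demands a sorted input, and
  treats max-gap ≤ 10⁻⁹ as degenerate (no SEs).
* The top-loop-change quantile is type-7 (R's default) over genes with
  at least one change, ties at the threshold included.
* t-tests refuse n < 2 and zero variance; hypergeometric terms with no
  universe genes are skipped rather than scored at p = 1.
* A variant position equal to a window's exclusive end belongs to the
  next window (half-open semantics, tested at the boundary).
* Loop anchors are canonicalized lexicographically by (chrom, start,
  end); inter-chromosomal BEDPE records are skipped with a counted
  warning since the pipeline consumes intra-chromosomal loops only.

# Known limitations

Loop clustering is single-linkage, so dense loop fields can chain into
one consensus cluster; the paper-scale alternative (pairwise matching per
condition) is recoverable by calling `loop_match_pairs()` directly.
Enhancer-state calls are binary per mark with no signal weighting.
The delta-threshold compartment mode is a convenience, not a calibrated
test — external significance flags are the intended path. ORA assumes
exchangeable genes (no length or GC bias correction), which is adequate
for the toy GMT fixtures and for ranking sets, less so for absolute
enrichment claims on real annotations.
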