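---
title: "Methods: integrating timecourse expression, binding and knockout evidence for direct target inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating timecourse expression, binding and knockout evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference problem

A lineage-determining transcription factor that switches on midway
through a developmental timecourse leaves three distinct genome-scale
footprints: genes whose expression tracks (or mirrors) the regulator's
rise across sorted cell populations; genomic regions the factor
physically binds; and genes whose expression collapses (or rises) when
the factor is knocked out. Each footprint alone is noisy and heavily
contaminated by indirect effects — correlation captures whole downstream
programmes, binding includes non-functional events, and knockout
profiling mixes direct and cascade responses. `regonset` operationalises
the classical remedy: a gene is called a *directly controlled target*
only when all three lines of evidence agree,

$$\text{positively controlled} \;=\;
  \{r \ge r^+\} \;\cap\; \{\text{down in null}\} \;\cap\; \{\text{bound}\},$$

with the negative mirror image defined analogously.

# Stage-by-stage model

## Dynamic-gene filter

A gene is *dynamic* when the sample standard deviation (n−1 denominator)
of its four log2(value+1) intensities exceeds `sd_threshold` (default 1)
**and** its maximum linear intensity exceeds `min_expression` (default
100). The variability criterion lives on the log scale — an SD threshold
of 1 is only meaningful there for array intensities spanning orders of
magnitude — while the intensity floor is a linear detection limit. The
choice of scale for the SD is a genuine design decision: applied to
linear values the same threshold would pass essentially every expressed
gene.

## Correlation classes and two-platform consensus

Each dynamic gene's four-point profile is Pearson-correlated with the
regulator's profile on the log2(value+1) scale — the scale on which the
filter already operates and on which array fold structure is additive. A
planted log2-mirror profile anti-correlates at exactly −1 on this scale
but only at about −0.55 on the linear scale, which is a property of the
scale, not of the biology; using the log scale keeps the negative cutoff
meaningful. Labels are assigned inclusively: positive iff r ≥ 0.8,
negative iff r ≤ −0.6 (figure-legend cutoffs come without strictness, so
the inclusive reading is the testable one). Zero-variance genes receive
no correlation and stay unclassified. A gene keeps a label only when
both array platforms agree on it; disagreement or absence from either
platform yields `unclassified`. Four-point correlations are extremely
heavy-tailed under the null (see the permutation control below), and the
two-platform consensus is the principal false-positive guard.

## Permutation control

The observed coherence of the dynamic transcriptome with the regulator
is validated by independently permuting the four population values of
every gene and recomputing the correlation to the unshuffled regulator.
Shuffling within genes preserves each gene's value multiset and thereby
targets exactly the correlation structure. The pooled null is centred at
zero; its |r| ≥ 0.8 tail is non-negligible (roughly a fifth of
permutations for four points), which is why the null comparison is made
within the same gene set and why single-platform correlation alone would
be unusable.

## SOM mosaic

Expression dynamics are visualised with a batch self-organizing map on
z-scored four-point profiles: tiles on an r × c grid (pipeline default
6 × 6 for the synthetic scale; `som_mosaic()` defaults to 10 × 10),
Gaussian neighbourhood whose radius decays linearly from max(r, c)/2 to
0.5 over 50 epochs, codebooks initialised from seeded sampled profiles.
Batch updates make the fit independent of gene order, and a learning
rate — a concept of the online algorithm — is not needed. Each gene maps
to its best-matching tile (ties to the lowest index); per-tile mean
profiles rendered per population give the mosaic. Grid size and schedule
are visualisation choices, not inference parameters.

## Peak processing

*Repeat filter.* A peak is excluded when the fraction of its bases
covered by the merged repeat mask exceeds `repeat_fraction` (0.6). The
same threshold serves for peaks and for motif cores; the filter
operationalises "peaks in repeat regions" as a base-fraction rule, the
only self-consistent reading that also covers partial overlaps.

*Partition.* Peaks called in population 2 or 3 form the early-shared
"2,3,4" class; peaks called only in population 4 form "4 only". The two
classes are a disjoint cover of the retained peaks. Pairwise peak-height
correlations are reported per class; the tight population-2/3
correlation (> 0.80) is the empirical justification for merging the
early populations.

*Density matrices.* For heatmap rendering, mean coverage is computed per
bin (default 100 bp) over ±5 kb around each summit, rows ordered by
descending population-4 height so the dominant late-binding block is
visible. Bin width must divide the window exactly.

*Saturation.* Depth sufficiency is assessed by binomial thinning of
per-peak counts: at depth fraction f each count is thinned
Binomial(count, f) and the fraction of peaks still reaching the
detection threshold is averaged over replicates, with Monte-Carlo
standard errors. Thinning replaces re-calling peaks from subsampled
reads (peak calling is outside this package) while preserving the
statistic the curve is meant to show.

## Peak-to-gene assignment

The anchor is the peak summit — the best point estimate of the binding
site, and the only anchor under which the category priority is
unambiguous. Priority: **promoter** (|summit − TSS| ≤ 500 bp; the window
is symmetric, the minimal assumption when no side is specified) >
**intragenic** (summit within [start, end), introns included) >
**intergenic** (nearest gene left and nearest gene right of the summit
in chromosome coordinates, each linked only when its nearest boundary is
within 50 kb; "5′/3′" is read in chromosome orientation to avoid double
counting under gene-strand readings). All genes tied at the qualifying
distance are linked; a (peak, gene) pair is linked at most once. The TSS
of a −-strand gene is end − 1 under the package-wide 0-based half-open
convention — a single convention everywhere avoids off-by-one drift.

## Motif analysis

Scanning uses the central 200 bp core of each peak (whole sequence if
shorter), excluding cores > 60 % repeat-masked. The scanner matches
IUPAC consensus strings position by position on both strands, reporting
every (offset, strand) including overlaps; `N` in the subject matches no
code. Three consensi are scanned by default: the regulator's own
`TGYGGT`, the GATA-family `WGATAA`, and a novel promoter-associated
element operationalised as the `TGTAGT` box planted with a `TGGGA` box
within 10 bp 5′ (the two conserved boxes of a longer degenerate
consensus). The extended-consensus statistic counts, strand-aware, how
many `WGATA` matches are immediately followed by `A`; under a uniform
background the expectation is n/4 — rounded half-up, so 1138 matches
give 285 — deliberately *not* composition-adjusted, because the
uniform-background expectation is the published reference point. The
expectation uses total matches while the binomial p-value uses the
eligible matches (those with a 3′ base), an explicit choice for
edge-of-sequence matches.

The binary peak-annotation table (partition membership, promoter status,
three motif flags) is clustered with Jaccard distance (two all-zero rows
are defined as distance 0) and average linkage, rows pre-sorted by peak
id for order-independence. Promoter × novel-motif association is a
two-sided Fisher exact test.

## Knockout differential calls

Technical replicates are averaged (linear scale) into biological
replicates; the fold change is mean(het)/mean(null) on the linear scale;
and the p-value defaults to limma's moderated t on the log2
biological-replicate means. With two biological replicates per genotype,
a per-gene Welch test has at most ~2 degrees of freedom and a critical
t above 4, giving it under 50 % power even for two-fold effects — the
moderated statistic, which borrows variance information across the whole
array, is both the field standard for this design and the only variant
with usable power; the per-gene Welch test remains available as
`method = "ttest"`. Thresholds follow the array convention: fold ≥ 1.5
or ≤ 1/1.5, p < 0.05, applied to raw p-values (no multiple-testing
correction, matching the convention under which the thresholds were
defined; overlap p-values downstream are likewise reported raw).

## Set integration

The hypergeometric overlap of two gene sets is the upper-tail
probability P(X ≥ k) with X ~ Hypergeometric(N, |A|, |B|). The universe
is the set of genes observable by all evidence types — present in both
expression platforms and in the gene-model table — since membership
probabilities are only defined where an observation was possible.
Bound-gene fractions per correlation class are reported over the whole
gene complement (genes outside the dynamic sets count as unclassified),
and an empty class yields an undefined (NA) fraction rather than 0.

# The synthetic study

`simulate_dataset()` generates the full input complement with recorded
truth. Design choices, fixed once:

* **Genome and scale.** Two 5 Mb chromosomes, 200 genes, 100 peaks —
  seconds-scale everywhere while leaving room for > 50 kb intergenic
  space. Genes are non-nested, 3–10 kb long, with a 4:1 mixture of short
  (1–10 kb) and long (55–80 kb) gaps so that linkable and unlinkable
  intergenic peaks both exist.
* **Expression.** The regulator follows the fixed log2 profile
  (3, 6, 8, 10) — strictly increasing, spanning the detection floor to
  ~1000 linear. Planted positives copy it, planted negatives carry its
  affine mirror (so their log-scale correlation is exactly −1), all
  remaining genes are flat baselines; everything except the regulator
  receives additive log2 noise (default SD 0.25, a mid-range array
  noise level) independently per platform. Defaults plant 15 % positive
  and 10 % negative targets.
* **Peaks.** Early-shared peaks get tightly correlated heights across
  populations (r > 0.9 by construction); late-only peaks are called only
  in population 4 with heights at least five-fold above populations 2/3
  — the two signatures the partition is meant to detect. Location
  fractions default to 20/30/30/20 % promoter / intragenic / near- /
  far-intergenic. Promoter and intragenic peaks sit preferentially
  (70 %) on planted targets so binding evidence concentrates where
  expression evidence is planted; near-intergenic peaks avoid planted
  genes entirely so the truth of "which planted gene is bound" stays
  unambiguous for validation. Ten per cent of peaks are constructed to
  overlap the repeat mask by 70 % of their length.
* **Knockout effects.** Planted per-gene true folds are
  ko_fold × 2^U(0, 1) (nominal ko_fold 1.5): a continuum of effect sizes
  of which the detection threshold is the weakest, emulating the fact
  that real knockout responses form a distribution of which a threshold
  captures the tail. An effect planted *exactly* at an inclusive
  detection boundary is recovered with probability ~1/2 under any
  symmetric noise, so a zero-spread generator cannot support recovery
  claims; with the default spread, genes within ~0.1 log2 of the
  boundary are still individually missed at an appreciable rate, which
  is why recovery is assessed as a seed-averaged quantity. Replicate
  noise is 0.1 (biological) and 0.05 (technical) log2.
* **Motifs.** Concrete instantiations of the consensi are planted at
  uniform strands and non-overlapping offsets inside the scanned core
  (probabilities 0.6 regulator, 0.4 GATA; the novel cassette at 0.8 in
  promoter peaks vs 0.05 elsewhere, powering the promoter-association
  test). Recorded (offset, motif, strand) triples are recoverable by
  scanning.

What the generator does **not** emulate: probe-level array structure and
normalisation artefacts, read-level sequencing (peaks and heights are
primitives, not called from reads), correlated noise between platforms,
repeat-family sequence composition, and any genome-scale correlation
between binding and chromatin context. Passing tests therefore validate
the pipeline's logic, thresholds and statistics — not its robustness to
upstream preprocessing of real data.

# Determinism and numerics

Every stochastic stage derives its own seed from the run seed via a
fixed affine map, so stages are independently reproducible and a whole
run is byte-identical for identical configuration. Emitted numbers are
written with fixed precision (and generated values rounded to the same
precision), so files round-trip losslessly. Rounding of the analytic
expectation n/4 is half-up (284.5 → 285), not banker's. Degenerate
inputs are defined rather than accidental: zero-variance genes are
unclassified; empty classes give NA fractions; a single-row annotation
matrix returns a trivial order; constant peak heights give NA
correlations; a Fisher table with an empty margin gives p = 1.

# Problem sizes

Unit tests run the generator at 60-gene/40-peak scale; invariant and
recovery checks use the 200-gene/100-peak defaults, ten seeds for the
recovery metrics, 100 permutations for the null, and 10^5 draws for the
Monte-Carlo cross-check of the hypergeometric tail. These sizes were
chosen to exercise every code path at comfortable interactive speed.

# Known limitations

* The three consensus strings are scanned as hard IUPAC matches; no
  position-weight scoring, discovery, or conservation filtering.
* The knockout test assumes the 2 × 2 replicate design; unbalanced
  designs work but inherit limma's behaviour rather than a bespoke one.
* Overlap p-values depend on the universe definition; with a different
  observable-gene universe the p-values (not the set memberships)
  change.
* The intergenic "nearest gene per side" rule ignores gene strand by
  design; regulatory assignments in gene-dense regions are
  correspondingly conservative.
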