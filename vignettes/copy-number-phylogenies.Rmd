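---
title: "Distance-based copy-number phylogenies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based copy-number phylogenies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-cell whole-genome sequencing of tumors yields, per cell, a *copy-number
profile* (CNP): a vector of non-negative integers over fixed-size genomic bins
(typically 0.5–5 Mbp), one or two vectors per chromosome depending on whether
copy numbers are total or allele-specific. Because copy-number alterations
(CNAs) accumulate along cell divisions, the profiles of a sampled cell
population carry phylogenetic signal: cells that diverged recently share more
alterations. `cnphylo` reconstructs the *cell lineage tree* — an unrooted
binary tree whose leaves are the sequenced cells — from these profiles, and
provides the simulation and evaluation machinery needed to study how well
such reconstruction works under realistic noise.

The package deliberately uses simple, per-bin distance functions rather than
explicit evolutionary models of CNA events (minimum-event distances). The
motivating observations are that (i) event-model distances are expensive and
brittle when profiles contain calling error, and (ii) a well-chosen elementwise
distance retains most of the signal while being linear-time per pair.

## Distance functions

For two genomes $s,t$ with per-chromosome profiles $C^k=(c_1,\dots,c_{n_k})$,
the *standard* distances sum over all bins of all $K$ chromosome (and allele)
vectors; writing $\Delta_i = c^k_{s,i} - c^k_{t,i}$:

* Manhattan: $\sum |\Delta_i|$
* Euclidean: $\sqrt{\sum \Delta_i^2}$ (a single radical over the grand total)
* Root: $\sum \sqrt{|\Delta_i|}$
* Log: $\sum \log(1+|\Delta_i|)$

The *breakpoint* space applies the same four forms to breakpoint profiles
$b_i = c_{i+1}-c_i$, computed independently within each chromosome (no
cross-chromosome differences). Nonzero $b_i$ mark segment boundaries, so
breakpoint distances count *where profiles change* rather than *by how much
they differ*, which removes the length-weighting of long events and the
cancellation of overlapping gains and losses.

The root form is the methodologically interesting one: a single amplification
can add several copies at once, so a copy-number jump of magnitude $m$ is
weak evidence for $m$ separate events. Taking $\sqrt{|\Delta|}$ per bin
discounts large jumps while keeping the function a metric ($\sqrt{|\cdot|}$
is subadditive coordinatewise, so the triangle inequality survives summation;
the test suite property-checks all eight variants). The log form is
implemented as $\log(1+|\Delta|)$: the bare $\log|\Delta|$ sometimes written
for this family is $-\infty$ at $\Delta=0$ and $0$ at $|\Delta|=1$, so the
offset version is the only metric interpretation; this is a deliberate
package choice and is flagged here because other implementations may differ.

The two headline method variants are `standard` space with the `root` form
(most robust when profiles are noisy) and `breakpoint` space with the `root`
form (most accurate on clean profiles); both reconstruct with balanced
minimum evolution.

## Tree reconstruction

Given the cell-by-cell distance matrix, `infer_lineage()` reconstructs an
unrooted binary tree by *balanced minimum evolution* (BME): the criterion
scores a topology by the Pauplin length
$\sum_{i<j} 2^{1-p_{ij}} D_{ij}$, where $p_{ij}$ is the topological path
length between leaves $i$ and $j$; on a matrix additive over a tree the
criterion equals the tree's total branch length. The search is the standard
Desper–Gascuel scheme — greedy taxon insertion followed by an SPR hill climb
— as implemented in `ape::fastme.bal`; `cnphylo` additionally evaluates the
neighbor-joining topology under the same criterion and returns whichever is
better, so the BME result is never worse than the NJ baseline under its own
objective. Neighbor joining itself (`ape::nj`) is exposed as the baseline
method. `balanced_length()` is implemented natively and is the package's
single source of truth for the criterion; the tests verify that the search
attains the exhaustive-enumeration optimum for up to six taxa and that both
methods exactly recover random additive trees up to ten taxa.

Branch lengths on the returned tree are the search's estimates with negative
values clamped to zero; every evaluation metric in the package is
topology-only, so branch lengths are cosmetic.

## The simulator

`simulate_dataset()` emulates the standard generative pipeline for benchmark
CNP data: a ground-truth tree, genome evolution along it, binning, then
noise. It is first-class, tested code — the study conditions, not a fixture.

**Tree.** `sample_tree()` draws a rooted binary topology from the neutral
Kingman coalescent (uniformly random pair merges), the usual model for an
exponentially growing tumor population. A `growth` rate is exposed but only
rescales node times; events are drawn per edge, so the parameter is
documented as cosmetic.

**Genome representation.** Each chromosome copy is an ordered sequence of
reference *regions* of $M = 1{,}000$ bp — the minimum CNA unit, following
the convention that variants above 1 kbp count as CNAs. Sequences are stored
as run lists of reference intervals rather than explicit arrays, so
hg38-scale genomes (about 2.9M regions per allele) cost almost nothing; the
semantics are identical to the explicit array model, and duplications insert
tandem copies while deletions may remove the last copy of a region.

**Events.** The founder (root) receives `Poisson(founder_multiplier * lambda)`
segmental CNAs — the initiating mutation burst — and optionally a
whole-genome duplication (only the founder can undergo WGD). Every other
node inherits its parent's genome plus `Poisson(lambda)` segmental CNAs.
Per event: the allele is Bernoulli(`alpha`); the chromosome is chosen with
probability proportional to its current length; gain vs deletion is
Bernoulli(`p_gain`); the length is exponential with mean `beta`, rounded up
to whole regions and truncated at the chromosome end; the start is uniform
over feasible positions; gains insert a geometric number of extra copies
(support 1, 2, ...; success probability `1/delta`, hence mean `delta`).
Events drawn for a fully deleted chromosome are redrawn with bounded
retries.

**Clones.** With `n_clones > 0`, that many disjoint ancestral clades are
selected — preferring clade sizes closest to `n_cells / n_clones` and within
`[n_cells/(4 n_clones), n_cells/n_clones]`, which yields balanced,
well-separated clones — and each selected ancestor receives
`Poisson(clonal_events_mean)` (minimum 1) chromosomal events: arm-level with
probability `p_arm` (the arm boundary defaults to half the chromosome, as no
centromere table is assumed), whole-chromosome otherwise; deletion with
probability `p_chrom_del`, which defaults to 0.8 under WGD (post-WGD tumors
trend back toward triploidy) and 0.5 otherwise. Clone labels are exactly the
leaf sets of the selected clades.

**Binning.** A bin's copy number is the mean copy count of the reference
regions it covers, rounded half-up; an unmutated diploid genome reads 1 in
every allele bin. Rounding half-up (rather than R's banker's rounding) makes
a region gain covering exactly half a bin visible, which matters for the
noise calibration below.

**Defaults.** 250 cells, 22 hg38 autosomes (about 5,764 allele bins at 1 Mbp),
`lambda = 2`, `founder_multiplier = 10`, `alpha = 0.5`, `p_gain = 0.5`,
`beta = 5` Mbp, `delta = 2`, no WGD, no clones. These are the baseline study
conditions; tens of segmental CNAs accumulate on a root-to-leaf path, within
the ranges reported by pan-cancer surveys.

## Noise models

Real CNPs inherit two kinds of error from the calling pipeline, and the
simulator models both.

**Jitter** mimics read-count fluctuation: each bin with copy number $c$ is
redrawn from $\mathcal N(c, (c\,r_j)^2)$, rounded, and clamped at zero. The
probability that a bin changes is the two-sided tail
$2(1-\Phi(0.5/(c\,r_j)))$ — at $r_j = 0.1$ about $9.56\%$ for $c=3$,
$1.24\%$ for $c=2$, and effectively never ($5.7\times10^{-7}$, a fraction)
for $c=1$ — so noise concentrates in amplified regions, as in real data.

**Boundary error** mimics the caller's imprecision at segment edges. Within
each chromosome and allele, maximal equal-copy runs are found; the length of
each segment (scanning left to right) is redrawn from
$\mathcal N(L, (r_b L)^2)$ rounded to whole bins, and the segment's boundary
with its right neighbor moves accordingly, the neighbor absorbing the
residual. Boundary displacements therefore do not accumulate along a
chromosome: each internal boundary is displaced by an independent rounded
Gaussian around its true position. Displaced boundaries are kept in order,
so a small segment overrun from both sides can vanish, much as callers miss
small segments. Single-segment chromosomes are never altered, and the total
bin count per chromosome is always conserved (a property the tests assert).

Jitter is applied before boundary error: fluctuation exists in the raw
counts, segmentation error on top of it.

The exact boundary mechanics of the reference pipelines are not published,
so this model was *calibrated*, not copied: candidate schemes (cumulative
left-to-right resampling, centered segment growth, independent boundary
displacement) were scored against the published breakpoint-detection
statistics for the two standard noise presets — `low` ($r_b=0.02$,
$r_j=0.1$) and `high` ($r_b=0.04$, $r_j=0.1$), with pooled precision/recall
computed from the informative-breakpoint sets of clean vs noisy profiles —
and the independent-displacement scheme above reproduces them; the
acceptance script recomputes these quantities. One published figure is
worth flagging: the low-preset altered-bin fraction reported alongside
those precision/recall values (0.064%) is not jointly attainable with them
under *any* bin-level mechanism, because destroying a quarter of a cell's
~95 informative breakpoints necessarily alters at least ~20 bins (~0.4%).
The package reports what its model actually does rather than fitting an
inconsistent statistic.

What the generator does not emulate: read-level effects (GC bias, coverage
waves beyond the jitter abstraction), phasing error in allele-specific
calls (alleles are assumed consistently ordered across cells, as simulated
data guarantees), doublets, replicating cells, and focal complex events
(translocations, inversions, chromothripsis). Conclusions from passing
tests therefore concern segmentation-level error, not raw-read artifacts.

## Numerical and reproducibility choices

* Coordinates are 1-based inclusive in files and converted internally; the
  last bin of a chromosome may be short.
* Bins with missing values are rejected, not imputed; no imputation rule is
  defensible without a data model.
* All randomness in `simulate_dataset()` flows from one seed through three
  derived sub-streams (tree, events, noise), so any stage can be reproduced
  in isolation; `run_benchmark()` derives per-replicate seeds the same way.
* Tie-breaks in reconstruction are inherited from the deterministic C
  implementations (first-improvement orderings fixed by input order); a
  `seed` argument to `bme_tree()` optionally randomizes the insertion order
  for robustness studies.
* Degenerate inputs: fewer than 3 cells refuse to form a tree; a 3-cell
  matrix returns the unique unrooted topology without searching; empty
  clones and mismatched leaf sets are hard errors.

## Problem sizes used by the test suite

The packaged checks run the full default condition (250 cells, hg38 layout)
with 3 replicates for the noise-calibration statistics, 5 replicates for
the reconstruction-error benchmark, and 3 replicates for the four-clone
detection benchmark; property-style tests use small synthetic layouts (2–5
chromosomes, tens of bins) where exhaustive oracles are feasible. Replicate
counts are the package's choice of desk-scale defaults; larger runs via
`run_benchmark()` simply extend `n_replicates`.

## Known limitations

* The boundary-error model is a calibrated stand-in for unpublished
  reference mechanics; statistics outside the calibrated presets (very high
  $r_b$) should be interpreted cautiously.
* `clade_induced_ari()` enumerates cluster orderings and is factorial in
  the number of clusters (capped at 8; a greedy fallback is provided).
* Distance computation is dense and quadratic in cells; thousands of cells
  are fine, hundreds of thousands are not the target.
* The simulator evolves copy numbers only; it does not emit reads or BAMs.
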