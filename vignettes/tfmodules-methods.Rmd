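---
title: "Methods: summit colocalization statistics, conditional module tests and motif arrangement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summit colocalization statistics, conditional module tests and motif arrangement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfmodules)
```

## The problem

ChIP-Seq peak regions are wide — often several hundred base pairs — while
the protein–DNA contact they report is nearly point-like. Calling two
factors "cobound" whenever their peak regions intersect therefore lumps
together true joint binding and loci where the actual binding sites are
hundreds of base pairs apart. `tfmodules` instead works from **peak
summits**, the positions of maximum local enrichment, which track the
underlying binding site to within a few dozen base pairs. Two peaks from
different experiments are *cobinding* when their summits lie within
`d_s` bp on the same chromosome; the default `d_s = 150` matches the width
of nucleosome-free accessible regions mapped by digital genomic
footprinting, so a cobinding event can be read as "two summits in the same
accessible slot".

## The null model and its parameters

The significance model treats the genome as `N` accessible slots of width
`d_s` and each experiment as throwing its summits uniformly into them. For
experiments with `n` and `m` peaks the expected number of shared slots is
`lambda = n * m / N`, and the observed cobinding count `k` is tested with a
Poisson tail — `P(X >= k)` when `k` is at or above `lambda` (enrichment),
`P(X <= k)` otherwise (depletion, i.e. mutual avoidance). An exact
hypergeometric tail (`N` slots, `n` marked, `m` drawn) is available via
`model = "hypergeom"`.

Parameters that matter:

* `d_s` (bp, default 150): the summit-distance threshold and slot width.
* `N`: 250,000 for somatic mammalian cells; 500,000 for embryonic stem
  cells, whose nucleosome occupancy is roughly halved; or counted from a
  user-supplied accessible-regions BED (one row per slot,
  `estimate_N("counted_from_bed")`). Smaller genomes (fly, Arabidopsis)
  scale `N` down proportionally; supplying the BED is then the right route.
* `T`: the Bonferroni family. All-pairs scans over `T` experiments test
  `T x T` ordered pairs, so raw p-values are multiplied by `T^2` (108,241
  for T = 329) and capped at 1. The unordered count `T(T-1)/2` is available
  behind `bonferroni(..., method = "pairs")`.

The Poisson default is deliberately the more conservative of the two tails
in the regime where enrichment calls are made. This ordering is *not*
universal: at `k = 1` or `k` within a standard deviation of `lambda` the
two tails cross by tiny margins. The property suite therefore asserts
Poisson >= hypergeometric only for `k >= max(2, 2*lambda)`, which covers
every call a user would act on.

### Counting convention

`count_cobinding(a, b)` counts peaks of the *first* experiment having at
least one qualifying summit of the second, pairing each with its nearest
partner (ties to the lower coordinate). Many-to-one matches make the count
asymmetric by at most the number of such collisions; `k` is capped at
`min(n, m)` so it never leaves the hypergeometric support. The score matrix
averages the two orientations before clustering. This convention is
reproducible, bounded, and matches what a windowed-intersect implementation
produces.

## Scores, clustering

Each pair gets a signed coassociation score: `-log10 p` when enrichment,
`+log10 p` (hence negative) when depletion, with p floored at 1e-300 so
scores stay finite. Experiments are clustered on `1 - Pearson r` distances
between score-matrix rows (average linkage by default; the linkage is
exposed because nothing in the method pins it down). A constant row has no
defined correlation; its distance to everything is set to 1 and the id is
flagged rather than silently dropped.

## Conditional (base-TF) tests

Choosing a base factor TF_b restricts the universe to its `k_b` peaks.
With `k_i`, `k_j` the base peaks cobound by factors i and j, and `k_ij`
those cobound by both, the null expectation is `lambda = k_i * k_j / k_b` —
two independent subsets of the base's peaks intersecting at random — and
the Poisson tail is applied as before. The statistic is symmetric in i and
j. `conditional_heatmap()` pre-filters partners to those whose pairwise
cobinding with the base is significant (corrected p below `theta`, default
1e-10; 1e-100 is a sensible stricter choice for heavily connected anchors)
and Bonferroni-corrects the conditional tests over the number of (i, j)
pairs actually tested. The correction family for conditional scans is a
design choice of this package: the method itself prints only the pre-filter
threshold.

`iterate_module()` extends a module by one factor at a time. The current
cobinding-region set (base peaks cobound by every member) plays the role of
factor i against the original base: with `k_r` its size, `k_c` the
candidate's cobinding count with the base, and `k_obs` the regions the
candidate cobinds, `lambda = k_r * k_c / k_b`. At the first iteration this
is exactly the triplet formula; under a null candidate placed uniformly
over the accessible slots it is calibrated (the candidate's hits in the
base are then a uniform subset, and `k_obs` is binomial with mean
`k_c * k_r / k_b`), which is why this reading of "iterate with the region
set as the new base" was chosen over re-normalizing by `N`.

## Motif layer

Windows of 150 bp centered on summits are scanned with position weight
matrices. Counts become frequencies after adding a pseudocount of 1% of
the column total, split evenly over the four bases. An instance score is
the sum over positions of the frequency of the observed base, normalized by
the per-position minima and maxima so the consensus scores exactly 1 and
the anti-consensus exactly 0; `N` bases contribute the column mean. Three
enrichment measures are reported per motif:

* **global**: one-tailed two-sample z-test of mean best-instance score,
  input regions versus background regions sampled from the accessible
  genome (default 5,000 windows from a user-supplied BED; >= 200 needed for
  the normal approximation to be honest);
* **local**: paired one-tailed z-test of the summit window against the mean
  of the two adjacent flanking windows;
* **positional bias**: chi-square goodness-of-fit of best-instance center
  positions against uniform over the achievable center range, 15 bins by
  default (reduced to `max(5, n/10)` and flagged for small inputs).

These three statistics are this package's concrete choices standing in for
the corresponding read-outs of summit-centered motif enrichment tools; the
published tool this layer emulates does not print its internal formulas, so
no numerical replication of it is claimed — the contracts tested here are
the z- and chi-square constructions above.

**Motif-centered rescan**: regions whose anchor best score falls below the
quality threshold (default 0.8 on the [0, 1] scale; the cutoff is exposed
because "low quality" is not quantified anywhere authoritative) are
discarded, the rest are re-centered on the anchor instance center and
strand-flipped so the anchor reads on +. Partner motifs are then rescanned;
signed center-to-center distances (negative = upstream of the anchor),
partner strands, per-strand histograms, modal distances and a recomputed
positional-bias p are reported. Instance centers are taken at
`start + floor((L-1)/2)`, so distances are integers; even-length motifs
carry a half-base truncation that is identical for all regions and cancels
out of the histogram shape.

For a two-TF module the report is read three ways: both motifs globally
enriched — both factors contact DNA (and the spacing histogram indicates
whether their sites are arranged); one enriched — that factor recruits the
other (tethering); neither — wrong motif models or a third recruiting
factor. `interpret_motif_roles()` applies these labels at a corrected
global-p threshold of 0.01.

## The synthetic fixture generator

`fixture_spec()`/`generate_fixture()` build everything the pipeline
consumes: a uniform-ACGT genome, an accessible-slot map, per-experiment
narrowPeak files, a JASPAR motif library and a truth table. Design choices,
fixed once:

* Slots sit on a deterministic grid with a gap of at least one slot width
  between consecutive slots (pitch 300 bp by default). Distinct slots are
  therefore always farther apart than `d_s`, making "cobinding iff same
  slot" exact in fixtures — the cleanest realization of the null the
  statistics assume, and a fair cartoon of nucleosomal spacers separating
  accessible regions.
* Null experiments occupy uniformly drawn slots without replacement, one
  summit per slot, jittered ±30 bp around the slot center — reflecting how
  closely summits track binding sites in practice.
* Planted relations: `cobind` copies a fraction of one experiment's summits
  next to another's; `tether` gives two or more partners a shared subset of
  base peaks while placing their remaining peaks outside the base and
  disjointly from each other, so partners co-occur *only* inside the base;
  `spacing` writes anchor and partner consensus strings into the sequence
  at an exact center-to-center distance.
* The genome background is i.i.d. uniform ACGT. No statistic in the
  package models sequence composition beyond the PWM layer's own
  background sampling, so dinucleotide structure, repeats, GC skew and
  mappability — all present in real genomes — are deliberately absent.

What passing tests on these fixtures shows: the statistics are calibrated
and powerful *under their own null*, the counting and scanning primitives
are exact against brute force, and planted structure of realistic effect
size is recovered. What they do not show: robustness to peak-width
heterogeneity, to clumped accessibility, to sequence composition bias, or
to antibodies of different efficiency — on real data the null is an
approximation and corrected thresholds should be read accordingly.

## Numerical choices and degenerate inputs

* Tail probabilities are computed with R's `ppois`/`phyper` (verified
  against term-by-term and combinatorial summations to < 1e-9 relative
  error over the tested grid) and floored at 1e-300.
* Direction ties (`k == lambda`) count as enrichment, so `P(X >= 0) = 1`
  for empty experiments rather than an undefined lower tail.
* Scanner ties: strand ties resolve to +, offset ties to the lower forward
  offset; a PWM whose min and max scores coincide (fully uniform columns)
  scores 0 everywhere rather than dividing by zero.
* Empty inputs error early with named messages (empty base experiment,
  empty region set after iteration, no anchor above threshold, fewer than
  2 partners passing `theta`), never returning partial statistics.

## Problem sizes used by the validation suite

The null-calibration simulations use 2,000 replicates at `N = 10,000`
slots with 500-peak experiments (pairwise) and a 500-peak base with two
300-peak factors placed inside it (conditional); recovery simulations use
200 replicates of 30% planted cobinding at `n = m = 1,000`,
`N = 250,000`, and 50 replicates of a planted tethered triplet at the same
`N`; the motif layer is validated on 1,000 random scan fixtures against an
exhaustive oracle and 100 replicates of a 17-bp planted spacing at 500
regions. These sizes give binomial standard errors comfortably below the
margins being asserted while keeping the whole suite runnable on a laptop
in about a minute.

## Known limitations

* The null ignores peak signal strength, width and GC/mappability
  covariates; `N` is a single genome-wide constant (promoter/enhancer
  stratification is possible only by supplying a restricted BED).
* The counting convention resolves many-to-one summit matches
  asymmetrically; the symmetrized score matrix absorbs this, but raw `k`
  values for the two orientations can differ slightly.
* The motif statistics use normal approximations for the two enrichment
  tests; they are accurate at the region counts the pipeline produces
  (hundreds and above) but should not be trusted for a handful of regions.
* De novo motif discovery, dinucleotide background models and segmentation
  integration are out of scope.
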