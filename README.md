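# tfmodules

Discovery of transcription-factor (TF) regulatory modules from ChIP-Seq
peak summits: summit-proximity cobinding statistics against an
accessible-chromatin null, conditional (base-TF) tests that extend pairs to
triplets and beyond, coassociation-score clustering, and a PWM motif layer
that turns cobinding regions into DNA recruitment rules (which factors touch
DNA, at what spacing and strand arrangement).

## Who this is for

Computational biologists holding a collection of ChIP-Seq peak files
(ENCODE narrowPeak or BED summit format) for TFs and cofactors assayed in
one cell type, who want to know which factors bind DNA together, which
factor tethers which, and whether the underlying binding sites obey a fixed
spacing — without re-running anything upstream of peak calling.

## The model

Two peaks from different experiments are **cobinding** when their summits —
the base-pair proxies for the protein–DNA contact point — lie within
`d_s = 150` bp on the same chromosome. The genome offers `N` accessible
slots of width `d_s` for TF binding (defaults: `N = 250,000` for somatic
mammalian cells, `N = 500,000` for embryonic stem cells, or `N` counted
from a DNase digital-genomic-footprinting BED). If experiments with `n` and
`m` peaks place their summits at random into those slots, the cobinding
count `k` is approximately Poisson with

```
lambda = n * m / N,        p(k) = exp(-lambda) * lambda^k / k!
```

and the reported p-value is the tail on the observed side (enriched
`P(X >= k)` or depleted `P(X <= k)`); an exact hypergeometric tail is
available as an alternative, the Poisson being the more conservative choice
in the enrichment regime. All-pairs scans over `T` experiments are
Bonferroni-corrected by `T^2` (for T = 329, the factor is 108,241). Signed
coassociation scores `-log10 p` (enriched) / `+log10 p` (depleted) are
clustered with `1 - Pearson r` distances to expose candidate modules.

For modules beyond pairs, a **base TF** restricts the universe to its `k_b`
peaks: with `k_i`, `k_j` the base peaks cobound by factors i and j and
`k_ij` the base peaks cobound by both, the conditional expectation is
`lambda = k_i * k_j / k_b`, tested with the same Poisson tail and iterable
to quadruplets and beyond.

The **motif layer** scans the 150-bp window centered on each summit with
position frequency matrices (JASPAR text format), scoring each instance as
a min/max-normalized frequency sum in [0, 1], and reports global enrichment
(vs accessible-genome background), local enrichment (vs flanking windows)
and positional bias (chi-square vs uniform). Re-anchoring regions on the
best instance of a chosen motif (discarding low-quality anchors,
normalizing anchor strand) yields signed, strand-resolved distance
histograms between binding sites — the spacing signatures that indicate
direct cooperative binding versus tethering.

## Worked example

```r
library(tfmodules)

# a synthetic study: 2,000 accessible slots, a base TF, two partners
# (one cobinding, both tethered), an unrelated factor, and a CCAAT-box
# anchor with an E-box planted 17 bp downstream in the base TF's summits
bundle <- generate_fixture(demo_fixture_spec(11))
null   <- estimate_N("user", N = bundle$N)
e      <- bundle$experiments

pairwise_cobinding(e$baseTF, e$partnerA, null, T = 4)
#> <tf_cobinding> baseTF vs partnerA: k=422 (n=800, m=500, lambda=200),
#>   enriched, p=1.35e-42 (corrected 2.17e-41), score=41.87

conditional_cobinding(e$baseTF, e$partnerA, e$partnerB)
#> <tf_conditional> partnerA + partnerB | base baseTF: k_ij=360 (k_i=422,
#>   k_j=360, k_b=800, lambda=190), enriched, p=3.3e-28, score=27.48

motifs <- bundle$motifs
motif_centered_rescan(summit_regions(e$baseTF), bundle$genome,
                      motifs$CCAAT_box, motifs["E_box"])$E_box
#> <tf_arrangement> E_box anchored on CCAAT_box: 640 regions (160 discarded),
#>   modal distance 17, positional bias p = 1e-300
```

Reading the output: 422 of the base TF's 800 peaks carry a partnerA summit
within 150 bp where 200 were expected, so the pair colocalizes genome-wide
far beyond chance. Conditioning on the base, partnerA and partnerB co-occur
in 360 base peaks against an expectation of 190 — a tethered triplet. The
motif-centered rescan keeps the 640 regions with a high-quality CCAAT-box
anchor and finds the E-box concentrated 17 bp downstream of it on the same
strand: a fixed spacing rule implying both factors contact DNA as an
arranged pair.

A command-line wrapper for the pipeline steps (filter, pairwise,
conditional, motifs, simulate) is in `inst/scripts/tfmodules-cli.R`:

```sh
Rscript inst/scripts/tfmodules-cli.R simulate --seed 11 --out fix
Rscript inst/scripts/tfmodules-cli.R pairwise fix/metadata.tsv fix \
    --accessible fix/slots.bed --out pw
```

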