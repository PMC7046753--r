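Package: tfmodules
Title: Discovery of Transcription-Factor Regulatory Modules from ChIP-Seq
    Summit Colocalization and Motif Arrangement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies groups of transcription factors (TFs) and cofactors
    that bind DNA together, starting from ChIP-Seq peak summits. Two peaks
    from different experiments are called cobinding when their summits lie
    within a fixed distance (default 150 bp), and the significance of the
    genome-wide cobinding count is assessed with Poisson or hypergeometric
    tail probabilities against a null of random placement into the genome's
    accessible-chromatin slots. Pairwise coassociation scores are clustered
    into candidate modules; a conditional test anchored on a base TF extends
    pairs to triplets and beyond. A motif layer scans summit-centered windows
    with position weight matrices, measures global, local and positional
    enrichment, and re-anchors regions on a chosen motif to reveal preferred
    spacing and strand arrangements of partner binding sites. A seeded
    synthetic-fixture generator produces genomes, accessible-slot maps and
    peak sets with planted cobinding, tethering and motif-spacing structure
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
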