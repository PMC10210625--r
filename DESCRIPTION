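Package: repeatscape
Title: Satellite Arrays, Centromeres, Recombination Hotspots and
    Self-Alignment for Repeat-Dense Chromosome-Scale Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing repeat-dense chromosome-scale assemblies
    of the kind produced by long-read sequencing of rodent genomes rich in
    centromeric satellite DNA. Provides sliding-window sequence-complexity
    tracks (GC, gene density, Shannon entropy, linguistic complexity),
    trough-based centromere localization, tandem-repeat periodicity spectra
    with monomer consensus extraction, satellite monomer mapping and array
    segmentation up to a centromere classification (simple, asymmetric,
    symmetric), telomere-motif array scanning including interstitial sites,
    Marey-map recombination-rate estimation with fold-over-average hotspot
    calling, permutation tests for the spatial clustering of flagged gene
    sets, and suffix-array self-alignment with a duplicated-base fraction
    statistic. A synthetic-genome simulator plants centromeric satellite
    arrays, orientation blocks, array expansions, breakage-fusion-bridge
    duplications, telomere arrays, genes and genetic maps with
    machine-readable ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
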