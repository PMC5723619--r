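Package: broodscan
Title: Temporal Selection Scans for Multi-Generation Broodline SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting loci under directional selection across a few
    generations of reproductively isolated hatchery broodlines, as arise in
    salmonid reintroduction programs. Provides a quality-control cascade for
    RAD-seq SNP panels (minor allele frequency, call rates, exact
    Hardy-Weinberg test with Benjamini-Yekutieli correction), principal
    coordinate analysis of Smouse-Peakall genotypic distances, a per-locus
    regression / Q-Q linearity outlier scan of allele-frequency trajectories,
    an FST-heterozygosity outlier scan against a simulated temporal-drift
    neutral envelope, cross-method consensus tiers with nearest-gene
    annotation, and a Wright-Fisher broodline simulator with known truth for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vcfR,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
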