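Package: regscout
Title: Prioritisation of Remotely Acting Gene-Regulatory Regions from
    Chromatin Contact Maps and Enhancer Signal
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nominates candidate distal regulatory regions for a gene of
    interest by ranking the partner bins of the gene-containing bin in
    binned, pre-normalised chromatin-contact (Hi-C) maps, locating the
    highest H3K27ac-enrichment region within each top partner bin, and
    screening patient cohort variant calls against the nominated regions
    with novelty annotation against a known-variant catalog and overlap
    with transcription-factor binding sites. Includes seeded simulators
    for contact maps with power-law distance decay, enrichment signal
    tracks with planted peaks, and cohort variant tables with planted
    carriers, plus a packaged worked example at the NF1 locus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
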