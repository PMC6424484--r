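Package: hapgeo
Title: Functional Phylogeography of Crop Domestication Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic tools for tracing the geographic origin of
    causal domestication mutations from resequencing data. Implements window
    diversity statistics (pi, Watterson's theta, Tajima's D), Hudson Fst,
    pi-ratio selective-sweep scans, LD decay, the four-population f4 test,
    silhouette-score core-population curation, read-depth genotyping of
    whole-gene deletions, four-gamete screening of non-recombining regions,
    hamming-distance minimum-spanning-tree haplotype networks, and
    ancestral/derived haplotype range-overlap inference of mutation origins.
    Ships a synthetic-data generator that emulates a structured
    wild/domesticate/feral metapopulation with region-seeded causal mutations
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
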