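Package: germpanel
Title: Germplasm Genotype-Panel Verification, LD Decay and SNP Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for verifying germplasm collections from resequencing- and
    array-derived SNP genotype panels: VCF import with hard filtering on INFO
    annotations (QD, FS, MQ), merging of panels on common positions with
    allele harmonization, identity-by-state similarity with accession
    verification verdicts (confirmed, drifted, redundant, mis-assigned,
    unique), linkage-disequilibrium decay fitted with the Hill-Weir expected
    r-squared curve, neighbor-joining trees from concatenated SNP alignments
    rooted between species groups, binned SNP-difference profiles against a
    reference accession, and a seeded simulator of structured inbred panels
    with planted mislabels and duplicates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    graphics,
    vcfR,
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
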