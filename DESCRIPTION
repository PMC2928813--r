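Package: autozyg
Title: Homozygosity Mapping and Shared-Haplotype Scanning in Consanguineous Pedigrees
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping autosomal recessive disease loci in
    consanguineous pedigrees from SNP-array genotypes. Implements a
    homozygous-haplotype (HH) linkage scan with known-locus exclusion
    testing, a shared identical-by-state run-of-homozygosity scan with
    false-heterozygote bridging and unaffected-sample contrast, repair
    and interpolation of centimorgan map positions from physical
    coordinates, a splice-acceptor disruption annotator that locates
    cryptic acceptors and computes frameshift/truncation consequences,
    and a gene-dropping simulator that implants autozygous tracts in
    synthetic pedigrees with a one-directional genotyping-error model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
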