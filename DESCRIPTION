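Package: homsift
Title: Homozygosity Mapping and Recessive Variant Prioritization in
    Consanguineous Pedigrees
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for gene discovery in consanguineous families with
    autosomal-recessive disease: pedigree kinship and inbreeding
    arithmetic, identity-by-descent trio filtering of exome variant calls,
    frequency and functional exclusion cascades, cross-family candidate
    intersection, runs-of-homozygosity calling with shared-region mapping,
    STR-based founder-haplotype delineation, and coding-consequence
    checking of cDNA substitutions. Includes a gene-dropping simulator of
    consanguineous-pedigree exomes with a planted founder mutation so the
    whole pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    optparse,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
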