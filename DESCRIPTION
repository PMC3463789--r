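Package: ccstatus
Title: Inbreeding Status and Founder Haplotype Mosaics for Multiparental
    Recombinant Inbred Lines
Version: 0.1.0
Authors@R: person("UNC", "Systems Genetics Tools", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for declaring multiparental recombinant inbred lines
    distributable or complete from pedigrees and dense SNP genotypes.
    Determines obligate ancestors of the extant animals of a line from its
    pedigree, reconstructs each genotyped ancestor's genome as a mosaic of
    the eight founder haplotypes with a diplotype hidden Markov model,
    places recombination breakpoints at midpoints of ambiguous intervals,
    merges the ancestors' mosaics into line-level fixed and segregating
    regions, computes the maximum residual heterozygosity, and classifies
    the line against the 90% (distributable) and 98% (complete)
    homozygosity thresholds. A forward-in-time simulator of the eight-way
    funnel breeding design provides pedigrees, true mosaics, and noisy
    genotype calls for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
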