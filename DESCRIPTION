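Package: retrocnv
Title: Detection, Genotyping, and Selection Testing of Retrotransposed
    Gene Copy-Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers gene copy-number variants created by
    retrotransposition (retroCNVs) from paired-end and exon-exon
    junction sequencing evidence, genotypes them across population
    cohorts, estimates allele frequencies under Hardy-Weinberg
    equilibrium, contrasts polymorphic against fixed retrocopy
    insertion patterns, and tests candidate insertions for positive
    selection with a coalescent-calibrated ratio of nucleotide
    diversity between derived and ancestral haplotype classes and an
    iHS extreme-score density test. Includes a seeded synthetic-data
    generator (toy references with injected retrocopies, diploid
    cohorts with paired-end reads, neutral and sweep coalescent
    haplotypes) so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    rtracklayer
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
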