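Package: halopop
Title: Population-Genomic Evidence for Recombination in Clonal Haploid Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess (sexual) recombination in haploid microbial
    populations from multi-strain genome resequencing data: linkage
    disequilibrium statistics (D, D', r2) with a half-maximum LD-decay
    estimator, SNP-distance clonal lineage detection and minimum spanning
    networks, principal component ordination of SNP genotypes, gene-tree
    concordance via majority-rule consensus, core-genome counting,
    mating-type-locus synteny comparison (inversion and indel detection)
    and CAAX prenylation motif scanning. Includes a forward-time haploid
    Wright-Fisher simulator with recombination and planted clonal lineages
    so that every analysis stage can be exercised and validated end to end
    without access to raw sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    vcfR,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
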