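#!/usr/bin/env Rscript

## Stage 6: mating-type locus comparison and pheromone motif scan.
##
## Compares the mating-locus sequence of a reference-orientation strain with
## an inverted-orientation strain: maximal unique exact-match anchors,
## colinear chaining, inversion/indel intervals, and per-region divergence.
## Scans the two pheromone-precursor proteins for the C-terminal CAAX
## prenylation motif.

suppressPackageStartupMessages(library(halopop))

loci <- Biostrings::readDNAStringSet("results/dataset/mat_locus.fasta")
loci <- setNames(as.character(loci), names(loci))
truth <- utils::read.delim("results/dataset/truth.tsv")

ref_strain <- truth$sample[!truth$inverted][1]
inv_strain <- truth$sample[truth$inverted][1]
message(sprintf("comparing %s (reference orientation) vs %s (inverted)",
                ref_strain, inv_strain))

anc <- find_anchors(loci[[ref_strain]], loci[[inv_strain]], k = 20)
utils::write.table(anc, "results/matlocus_anchors.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
syn <- chain_anchors(anc)
print(syn)
print(syn$inversion_intervals)
if (nrow(syn$indel_intervals)) print(syn$indel_intervals)

## divergence of the locus between two same-orientation strains from
## different lineages (the sequences are substitution-only, so equal-length
## pairs are aligned)
ref_only <- truth[!truth$inverted, ]
same <- ref_only$sample[!duplicated(ref_only$lineage)][1:2]
message(sprintf("aligned divergence between %s and %s: %.4f",
                same[1], same[2],
                aligned_divergence(loci[[same[1]]], loci[[same[2]]])))

hits <- caax_scan(system.file("extdata", "pheromone_precursors.faa",
                              package = "halopop"))
print(hits)
utils::write.table(hits, "results/caax_hits.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf("%d of %d precursor proteins end in a CAAX box",
                sum(hits$is_caax), nrow(hits)))
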