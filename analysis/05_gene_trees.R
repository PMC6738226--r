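#!/usr/bin/env Rscript

## Stage 5: gene-tree concordance.
##
## Filters the per-window alignments (longer than 200 columns, mean pairwise
## difference larger than 15), builds a K2P neighbor-joining tree per
## surviving window, and counts the internal nodes shared by more than half
## of the trees. Low concordance between gene trees is the phylogenetic
## signature of recombination.

suppressPackageStartupMessages(library(halopop))

alns <- read_gene_alignments("results/dataset/genes")
message(sprintf("%d candidate gene alignments", length(alns)))

kept <- Filter(filter_alignment, alns)
message(sprintf("%d pass the length/divergence filter", length(kept)))

trees <- lapply(kept, function(a) nj_tree(alignment_distances(a, "K2P")))
dir.create("results/gene_trees", showWarnings = FALSE, recursive = TRUE)
for (g in names(trees))
  ape::write.tree(trees[[g]], sprintf("results/gene_trees/%s.nwk", g))

cons <- majority_consensus(trees)
print(cons)
ape::write.tree(cons$consensus_tree, "results/consensus.nwk")
utils::write.table(
  data.frame(split = names(cons$split_frequencies),
             frequency = cons$split_frequencies),
  "results/split_frequencies.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
message(sprintf("%d of %d possible internal nodes present in more than half of the trees",
                length(cons$majority_splits),
                length(trees[[1]]$tip.label) - 3L))
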