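#!/usr/bin/env Rscript

## Stage 4: ordination of strains.
##
## Principal component analysis of the SNP genotype matrix: the planted
## clonal lineages appear as tight clusters, divergent singleton strains
## scatter. Writes scores and percent variance explained.

suppressPackageStartupMessages(library(halopop))

gm <- read_vcf("results/dataset/variants.vcf")
p <- snp_pca(gm, n_axes = 2)
print(p)

truth <- utils::read.delim("results/dataset/truth.tsv")
scores <- data.frame(sample = rownames(p$scores), p$scores,
                     lineage = truth$lineage[match(rownames(p$scores),
                                                   truth$sample)])
utils::write.table(scores, "results/pca_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(axis = seq_along(p$percent_variance),
                              percent_variance = p$percent_variance),
                   "results/pca_variance.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf("PC1 %.1f%%, PC2 %.1f%% of variance",
                p$percent_variance[1], p$percent_variance[2]))
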