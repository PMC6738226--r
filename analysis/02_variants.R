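#!/usr/bin/env Rscript

## Stage 2: variant-based summaries.
##
## Reads the haploid VCF written by 01_simulate.R, computes SNP density,
## pairwise SNP differences, clonal clusters (single linkage, d < 200) and
## the clone-collapsed minimum spanning network, and compares the clusters
## with the simulator's truth labels. Tables go under results/.

suppressPackageStartupMessages(library(halopop))

gm <- read_vcf("results/dataset/variants.vcf")
print(gm)
genome_bp <- 9550000
message(sprintf("SNP density: %.3f%% of %.2f Mbp", snp_density(gm, genome_bp),
                genome_bp / 1e6))

d <- pairwise_differences(gm)
print(d)
utils::write.table(d$d, "results/pairwise_snps.tsv", sep = "\t", quote = FALSE)

truth <- utils::read.delim("results/dataset/truth.tsv")

cl <- clonal_clusters(d, threshold = 200)
print(cl)
within <- outer(truth$lineage, truth$lineage, "==")
message(sprintf("max within-lineage difference: %d SNPs; min between-lineage: %d SNPs",
                max(d$d[upper.tri(d$d) & within]),
                min(d$d[upper.tri(d$d) & !within])))
truth_parts <- unname(split(truth$sample, truth$lineage))
message(sprintf("clusters match planted lineages: %s",
                setequal(lapply(cl$partition, sort), lapply(truth_parts, sort))))
utils::write.table(data.frame(sample = names(cl$membership),
                              cluster = cl$membership),
                   "results/clusters.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

msn <- minimum_spanning_network(d, collapse_threshold = 200)
print(msn)
utils::write.table(msn$edges, "results/msn_edges.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
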