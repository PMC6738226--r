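#!/usr/bin/env Rscript

## Stage 3: linkage disequilibrium decay.
##
## Computes D' and r2 for every biallelic locus pair within 10 kb on the same
## contig, bins the statistics by distance, applies the half-maximum rule for
## the decay interval, and fits the LOESS decay curve whose half-maximum
## crossing is the LD decay distance. A finite, short decay distance is the
## LD-based evidence for recombination.

suppressPackageStartupMessages(library(halopop))

gm <- biallelic_loci(read_vcf("results/dataset/variants.vcf"))
message(sprintf("%d biallelic loci", nrow(gm$loci)))

prs <- enumerate_pairs(gm, max_distance = 10000)
message(sprintf("%d same-contig pairs within 10 kb (%d undefined pairs skipped)",
                nrow(prs), attr(prs, "n_skipped")))
## the per-pair table runs to hundreds of thousands of rows; only the binned
## summaries are written

for (stat in c("r2", "D_prime")) {
  binned <- bin_means(prs, stat, bin_width = 100)
  di <- decay_interval(binned)
  fit <- fit_decay_curve(prs, stat)
  message(sprintf("%s: max bin mean %.4f, half-max %.4f, decay interval %s-%s bp",
                  stat, di$M, di$H, format(di$left_border),
                  format(di$right_border)))
  print(fit)
  utils::write.table(binned, sprintf("results/ld_binned_%s.tsv", stat),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
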