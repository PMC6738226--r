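vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=c1,length=10000>",
  "##contig=<ID=c2,length=10000>",
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sA", "sB", "sC"), collapse = "\t"))

write_vcf_lines <- function(records) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(vcf_header, records), path)
  path
}

test_that("haploid VCF records parse with missing calls preserved", {
  path <- write_vcf_lines(c(
    "c1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0\t1\t.",
    "c1\t250\t.\tG\tC\t.\tPASS\t.\tGT\t1\t1\t0"))
  gm <- read_vcf(path)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(dim(gm$calls), c(3L, 2L))
  expect_equal(sum(is.na(gm$calls)), 1L)
  expect_equal(unname(gm$calls[, 1L]), c(0L, 1L, NA))
  expect_equal(gm$loci$ref, c("A", "G"))
})

test_that("diploid genotypes and duplicate records are rejected", {
  bad_ploidy <- write_vcf_lines(c("c1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0\t0/1\t1"))
  expect_error(read_vcf(bad_ploidy), "ploidy error.*c1:100")
  dup <- write_vcf_lines(c("c1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0\t1\t1",
                           "c1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0\t0\t1"))
  expect_error(read_vcf(dup), "duplicate")
})

test_that("SNP density is the locus count over genome length, in percent", {
  gm0 <- gm_from_calls(matrix(integer(0), nrow = 3, ncol = 0))
  expect_equal(snp_density(gm0, 9.55e6), 0)
  gm1 <- random_biallelic_gm(4, 32)
  expect_equal(snp_density(gm1, 10000), 0.32)
  ## linear in locus count
  gm2 <- random_biallelic_gm(4, 13)
  expect_equal(snp_density(gm2, 10000), 0.13)
  expect_error(snp_density(gm1, 0), "positive")
})

test_that("pairwise differences count mismatching complete calls", {
  calls <- rbind(c(0L, 0L, 1L, 1L, 0L),
                 c(1L, 0L, 1L, 0L, 0L))
  d <- pairwise_differences(gm_from_calls(calls))
  expect_equal(d$d[1, 2], 2L)
  expect_equal(d$n_compared[1, 2], 5L)
  same <- pairwise_differences(gm_from_calls(rbind(c(0L, 1L), c(0L, 1L))))
  expect_true(all(same$d == 0L))
})

test_that("missing calls are excluded pairwise, matching a per-locus recount", {
  set.seed(41)
  for (rep in 1:20) {
    gm <- random_biallelic_gm(6, 15, miss_prob = 0.2)
    d <- pairwise_differences(gm)
    x <- gm$calls
    for (i in 1:5) {
      for (j in (i + 1):6) {
        manual_d <- 0L
        manual_n <- 0L
        for (l in seq_len(ncol(x))) {
          if (!is.na(x[i, l]) && !is.na(x[j, l])) {
            manual_n <- manual_n + 1L
            if (x[i, l] != x[j, l]) manual_d <- manual_d + 1L
          }
        }
        expect_equal(d$d[i, j], manual_d)
        expect_equal(d$n_compared[i, j], manual_n)
      }
    }
  }
})

test_that("distances are invariant under ref/alt relabelling at any locus", {
  set.seed(77)
  gm <- random_biallelic_gm(5, 12, miss_prob = 0.1)
  d1 <- pairwise_differences(gm)$d
  flipped <- gm$calls
  flip_at <- c(2L, 7L, 11L)
  flipped[, flip_at] <- 1L - flipped[, flip_at]
  d2 <- pairwise_differences(gm_from_calls(flipped))$d
  expect_equal(unname(d1), unname(d2))
})

test_that("clonal clusters are single-linkage components below the threshold", {
  d <- matrix(c(0, 150, 300,
                150, 0, 150,
                300, 150, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- clonal_clusters(d, 200)
  expect_equal(length(cl$partition), 1L)
  expect_setequal(cl$partition[[1L]], c("A", "B", "C"))
  ## no pair below the threshold: all singletons
  far <- matrix(200, 4, 4) - diag(200, 4)
  rownames(far) <- colnames(far) <- letters[1:4]
  expect_equal(lengths(clonal_clusters(far, 200)$partition), rep(1L, 4))
  expect_error(clonal_clusters(d, 0), "positive")
})

test_that("clusters agree with a brute-force union-find on random inputs", {
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    d <- matrix(sample(0:400, n * n, replace = TRUE), n, n)
    d <- d + t(d)
    diag(d) <- 0
    rownames(d) <- colnames(d) <- sprintf("x%02d", seq_len(n))
    thr <- sample(50:350, 1)
    got <- clonal_clusters(d, thr)$membership
    want <- oracle_union_find(d, thr)
    ## same partition up to label permutation
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(want, levels = unique(want))))
  }
})

test_that("tied minimum-spanning edges are all retained", {
  d3 <- matrix(10, 3, 3) - diag(10, 3)
  rownames(d3) <- colnames(d3) <- c("A", "B", "C")
  msn <- minimum_spanning_network(d3, collapse_threshold = 1)
  expect_equal(length(msn$nodes), 3L)
  expect_equal(nrow(msn$edges), 3L)
  expect_equal(sum(msn$edges$in_mst), 2L)
  ## unique MST: chain 1,1,10 keeps only the two short edges
  dc <- matrix(c(0, 1, 11, 1, 0, 1, 11, 1, 0), 3, 3)
  dc[1, 3] <- dc[3, 1] <- 10
  rownames(dc) <- colnames(dc) <- c("A", "B", "C")
  msn2 <- minimum_spanning_network(dc, collapse_threshold = 0.5)
  expect_equal(sort(msn2$edges$weight), c(1, 1))
})

test_that("any spanning tree inside the MSN has the independent MST weight", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(4:9, 1)
    d <- matrix(sample(1:40, n * n, replace = TRUE), n, n)
    d <- pmin(d, t(d))
    diag(d) <- 0
    rownames(d) <- colnames(d) <- sprintf("x%d", seq_len(n))
    msn <- minimum_spanning_network(d, collapse_threshold = 0.5)
    expect_equal(sum(msn$edges$weight[msn$edges$in_mst]),
                 oracle_prim_weight(d))
    expect_equal(sum(msn$edges$in_mst), n - 1L)
  }
})

test_that("planted clones collapse to single network nodes", {
  ds <- simulate_population(small_sim(seed = 8))
  d <- pairwise_differences(ds$genotypes)
  cl <- clonal_clusters(d, 200)
  truth_parts <- unname(split(ds$truth$sample, ds$truth$lineage))
  got_parts <- cl$partition
  expect_setequal(lapply(got_parts, sort), lapply(truth_parts, sort))
  msn <- minimum_spanning_network(d, 200)
  expect_equal(length(msn$nodes), length(truth_parts))
})

test_that("core and soft-core counts follow the presence table", {
  ## saturated: every cluster in all genomes
  m <- matrix(1L, 10, 22)
  cg <- core_genome_counts(m, soft_min = 20)
  expect_equal(cg$n_core, 10L)
  expect_equal(cg$n_soft_core, 10L)
  ## planted mixture: 5 universal, 3 missing in one, 2 missing in three
  pm <- rbind(matrix(1L, 5, 22),
              t(sapply(1:3, function(i) {
                r <- rep(1L, 22)
                r[i] <- 0L
                r
              })),
              t(sapply(1:2, function(i) {
                r <- rep(1L, 22)
                r[i + c(0, 5, 9)] <- 0L
                r
              })))
  cg2 <- core_genome_counts(pm, soft_min = 20)
  expect_equal(cg2$n_core, 5L)
  expect_equal(cg2$n_soft_core, 8L)
  expect_equal(cg2$n_clusters_total, 10L)
  ## threshold collapse: soft_min = n_genomes
  cg3 <- core_genome_counts(pm, soft_min = 22)
  expect_equal(cg3$n_soft_core, cg3$n_core)
  expect_error(core_genome_counts(pm[0, , drop = FALSE]), "empty")
})
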