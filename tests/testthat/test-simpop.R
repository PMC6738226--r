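test_that("no mutation yields a monomorphic sample", {
  cfg <- small_sim(seed = 5, mu = 0, generations = 40,
                   clone_spec = data.frame(n_copies = c(3L, 2L), lambda = 0))
  ds <- simulate_population(cfg)
  expect_equal(nrow(ds$genotypes$loci), 0L)
  expect_equal(ncol(ds$genotypes$calls), 0L)
  ## alignments exist but are identical across strains
  expect_true(all(vapply(ds$gene_alignments,
                         function(a) length(unique(a)) == 1L, logical(1))))
})

test_that("identical configuration and seed give bit-identical datasets", {
  cfg <- small_sim(seed = 33, generations = 60)
  d1 <- simulate_population(cfg)
  d2 <- simulate_population(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_population(small_sim(seed = 34, generations = 60))
  expect_false(identical(d1$genotypes$calls, d3$genotypes$calls))
})

test_that("planted clones sit within 200 SNPs of each other", {
  for (seed in c(2, 7, 19)) {
    ds <- simulate_population(small_sim(seed = seed))
    d <- pairwise_differences(ds$genotypes)$d
    for (lin in unique(ds$truth$lineage[duplicated(ds$truth$lineage)])) {
      members <- ds$truth$sample[ds$truth$lineage == lin]
      within <- d[members, members][upper.tri(diag(length(members)))]
      expect_true(all(within < 200),
                  label = sprintf("within-lineage %s, seed %d", lin, seed))
    }
  }
})

test_that("inversion labels hit the configured fraction when achievable", {
  ## singleton-only sampling: every count is achievable
  cfg <- small_sim(seed = 9, sample_size = 10,
                   clone_spec = data.frame(n_copies = integer(0),
                                           lambda = numeric(0)),
                   mat_locus = list(contig = 5, start = 60001, end = 90000,
                                    fraction_inverted = 0.3))
  ds <- simulate_population(cfg)
  expect_equal(sum(ds$truth$inverted), 3L)
  ## clonal lineages flip as one unit
  ds2 <- simulate_population(small_sim(seed = 9))
  by_lineage <- tapply(ds2$truth$inverted, ds2$truth$lineage,
                       function(v) length(unique(v)))
  expect_true(all(by_lineage == 1L))
})

test_that("gene alignments match their window dimensions", {
  cfg <- small_sim(seed = 21, gene_windows = data.frame(contig = c(1, 2),
                                                        start = c(101, 501),
                                                        end = c(400, 1500)))
  ds <- simulate_population(cfg)
  expect_named(ds$gene_alignments, c("gene_01", "gene_02"))
  expect_equal(unique(nchar(ds$gene_alignments$gene_01)), 300L)
  expect_equal(unique(nchar(ds$gene_alignments$gene_02)), 1000L)
  expect_equal(length(ds$gene_alignments$gene_01), cfg$sample_size)
})

test_that("genotype positions are strictly increasing within contigs", {
  ds <- simulate_population(small_sim(seed = 13))
  loci <- ds$genotypes$loci
  for (ctg in unique(loci$contig)) {
    expect_true(all(diff(loci$pos[loci$contig == ctg]) > 0))
  }
})

test_that("segregating-site count matches the replicate sampling distribution", {
  ## oracle: the sampling distribution of S from independent replicate runs
  ## of the same process, not a closed form
  base <- function(seed) sim_config(
    population_size = 50, genome = 1000000L, mu = 1e-7, rho = 1e-8,
    generations = 500, sample_size = 20,
    clone_spec = data.frame(n_copies = integer(0), lambda = numeric(0)),
    gene_windows = data.frame(contig = integer(0), start = integer(0),
                              end = integer(0)),
    mat_locus = NULL, seed = seed)
  s_obs <- nrow(simulate_population(base(7))$genotypes$loci)
  reps <- vapply(101:150, function(sd)
    nrow(simulate_population(base(sd))$genotypes$loci), numeric(1))
  expect_gt(s_obs, mean(reps) - 3 * stats::sd(reps))
  expect_lt(s_obs, mean(reps) + 3 * stats::sd(reps))
})

test_that("datasets round-trip through VCF and FASTA writers", {
  ds <- simulate_population(small_sim(seed = 4))
  td <- withr::local_tempdir()
  paths <- write_dataset(ds, td)
  gm <- read_vcf(paths$vcf)
  expect_equal(gm$sample_ids, ds$genotypes$sample_ids)
  expect_equal(gm$loci$pos, ds$genotypes$loci$pos)
  expect_equal(gm$loci$contig, ds$genotypes$loci$contig)
  expect_equal(unname(gm$calls), unname(ds$genotypes$calls))
  alns <- read_gene_alignments(file.path(td, "genes"))
  expect_identical(alns$gene_01, ds$gene_alignments$gene_01)
  truth <- read.delim(paths$truth)
  expect_equal(truth$sample, ds$truth$sample)
  expect_equal(truth$inverted, ds$truth$inverted)
})

test_that("a dataset without SNPs writes a valid header-only VCF", {
  ds <- simulate_population(small_sim(seed = 5, mu = 0, generations = 30,
                                      clone_spec = data.frame(n_copies = 2L,
                                                              lambda = 0)))
  td <- withr::local_tempdir()
  paths <- write_dataset(ds, td)
  lines <- readLines(paths$vcf)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  expect_equal(sum(!grepl("^#", lines)), 0L)
  gm <- read_vcf(paths$vcf)
  expect_equal(nrow(gm$loci), 0L)
  expect_equal(gm$sample_ids, ds$genotypes$sample_ids)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(genome = integer(0)), "contig")
  expect_error(sim_config(mu = 1.5), "rates")
  expect_error(sim_config(population_size = 5, sample_size = 30,
                          clone_spec = NULL), "exceeds")
  expect_error(sim_config(gene_windows = data.frame(contig = 1, start = 10,
                                                    end = 10^9)), "bounds")
  expect_error(sim_config(gene_windows = data.frame(contig = c(1, 1),
                                                    start = c(100, 150),
                                                    end = c(200, 250))),
               "overlap")
})

test_that("gene-tree topology diversity does not decrease with recombination", {
  ## stochastic ordering, fixed seeds: mean count of distinct topologies
  ## across replicates is non-decreasing in rho
  n_topologies <- function(rho, seed) {
    cfg <- small_sim(seed = seed, rho = rho, N = 30, generations = 120,
                     sample_size = 8,
                     clone_spec = data.frame(n_copies = integer(0),
                                             lambda = numeric(0)),
                     contigs = rep(50000L, 4),
                     gene_windows = data.frame(contig = 1:4, start = 10001,
                                               end = 22000),
                     mat_locus = NULL)
    ds <- simulate_population(cfg)
    trees <- lapply(ds$gene_alignments, function(a)
      nj_tree(alignment_distances(a, "raw")))
    keys <- vapply(trees, function(tr)
      paste(sort(tree_bipartitions(tr)), collapse = ";"), character(1))
    length(unique(keys))
  }
  seeds <- 301:310
  m0 <- mean(vapply(seeds, function(s) n_topologies(0, s), numeric(1)))
  m2 <- mean(vapply(seeds, function(s) n_topologies(2e-5, s), numeric(1)))
  expect_lte(m0, m2)
})
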