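#' Configure the full analysis pipeline
#'
#' Bundles either a simulator configuration or paths to input files with the
#' per-stage parameters of the analysis chain (variant summaries, LD decay,
#' PCA, gene trees, mating-locus synteny, motif scan, core genome). Every
#' block is validated before any stage runs.
#'
#' @param sim A [sim_config()] (simulate inputs) or `NULL`.
#' @param vcf Path to a haploid VCF (used when `sim` is `NULL`).
#' @param alignments Directory or files of aligned gene FASTAs (when `sim`
#'   is `NULL`).
#' @param loci FASTA of per-sample mating-locus sequences (when `sim` is
#'   `NULL`).
#' @param proteins Protein FASTA for the CAAX scan, or `NULL` to use the
#'   packaged pheromone-precursor sequences.
#' @param presence Gene presence/absence matrix (clusters x genomes), a path
#'   to such a TSV, or `NULL` to synthesize one with
#'   [simulate_presence_table()].
#' @param genome_length Total genome length in bp (for SNP density); taken
#'   from `sim` when available.
#' @param clone_threshold SNP cutoff for clonal clusters and MSN collapsing.
#' @param max_distance,bin_width,span LD stage parameters.
#' @param ld_fit_bin_width Binning used inside [fit_decay_curve()].
#' @param n_axes PCA axes to report.
#' @param min_length,min_mean_diff Gene-alignment filter bounds.
#' @param tree_model Distance model for gene trees.
#' @param anchor_k Anchor length for the mating-locus comparison.
#' @param min_indel,max_gap Chaining parameters.
#' @param soft_min Soft-core threshold (`NULL`: all genomes minus two).
#' @param seed Global seed (overrides `sim$seed` when `sim` is given).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), vcf = NULL, alignments = NULL,
                            loci = NULL, proteins = NULL, presence = NULL,
                            genome_length = NULL, clone_threshold = 200,
                            max_distance = 10000, bin_width = 100,
                            span = 0.2, ld_fit_bin_width = 25, n_axes = 2L,
                            min_length = 200, min_mean_diff = 15,
                            tree_model = "K2P", anchor_k = 20,
                            min_indel = 50, max_gap = 500, soft_min = NULL,
                            seed = 1L) {
  if (is.null(sim) && is.null(vcf))
    stop("config validation error: either `sim` or `vcf` must be given")
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- as.integer(seed)
    genome_length <- sum(as.numeric(sim$genome))
  }
  if (is.null(genome_length) || genome_length <= 0)
    stop("config validation error: genome_length must be positive")
  if (clone_threshold <= 0) stop("config validation error: clone_threshold")
  if (max_distance < 1 || bin_width < 1 || ld_fit_bin_width < 1)
    stop("config validation error: LD window/bin parameters")
  if (anchor_k < 8) stop("config validation error: anchor_k must be >= 8")
  tree_model <- match.arg(tree_model, c("raw", "JC69", "K2P"))
  structure(list(sim = sim, vcf = vcf, alignments = alignments, loci = loci,
                 proteins = proteins, presence = presence,
                 genome_length = genome_length,
                 clone_threshold = clone_threshold,
                 max_distance = max_distance, bin_width = bin_width,
                 span = span, ld_fit_bin_width = ld_fit_bin_width,
                 n_axes = as.integer(n_axes), min_length = min_length,
                 min_mean_diff = min_mean_diff, tree_model = tree_model,
                 anchor_k = anchor_k, min_indel = min_indel,
                 max_gap = max_gap, soft_min = soft_min,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: input acquisition (simulation or file
#' loading), variant summaries (SNP density, pairwise differences, clonal
#' clusters, minimum spanning network), LD decay, PCA, gene-tree concordance,
#' mating-locus synteny, CAAX motif scan and core-genome counting, and
#' returns a consolidated report. Stages whose inputs carry no information
#' (e.g. no segregating SNPs) are marked skipped rather than failing; the
#' report schema is identical either way. Identical configuration and seed
#' give an identical report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when given, per-stage tables and the
#'   JSON report are written beneath it.
#' @return Object of class `pipeline_report` (a named list): elements
#'   `n_snps`, `snp_density_percent`, `clusters`, `n_clusters`, `msn`,
#'   `ld`, `pca`, `genetrees`, `matlocus`, `caax`, `coregenome`, `skipped`
#'   (character vector) and `seed`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  skipped <- character(0)

  ## --- inputs ---------------------------------------------------------
  if (!is.null(config$sim)) {
    dataset <- simulate_population(config$sim)
    gm <- dataset$genotypes
    alignments <- dataset$gene_alignments
    loci_seqs <- dataset$locus_sequences
  } else {
    dataset <- NULL
    gm <- read_vcf(config$vcf)
    alignments <- if (!is.null(config$alignments))
      read_gene_alignments(config$alignments) else list()
    loci_seqs <- if (!is.null(config$loci)) {
      ss <- Biostrings::readDNAStringSet(config$loci)
      stats::setNames(as.character(ss), names(ss))
    } else NULL
  }

  report <- list(n_snps = nrow(gm$loci),
                 snp_density_percent = snp_density(gm, config$genome_length),
                 clusters = NULL, n_clusters = NA_integer_, msn = NULL,
                 ld = NULL, pca = NULL, genetrees = NULL, matlocus = NULL,
                 caax = NULL, coregenome = NULL, skipped = character(0),
                 seed = config$seed)

  has_variation <- nrow(gm$loci) > 0L

  ## --- variant summaries ----------------------------------------------
  if (has_variation) {
    dst <- pairwise_differences(gm)
    cl <- clonal_clusters(dst, config$clone_threshold)
    msn <- minimum_spanning_network(dst, config$clone_threshold)
    report$clusters <- cl
    report$n_clusters <- length(cl$partition)
    report$msn <- list(n_nodes = length(msn$nodes), n_edges = nrow(msn$edges),
                       graph = msn)
    report$distances <- dst
  } else {
    skipped <- c(skipped, "clusters: no variation", "msn: no variation")
  }

  ## --- linkage disequilibrium ------------------------------------------
  if (has_variation) {
    bi <- biallelic_loci(gm)
    prs <- enumerate_pairs(bi, config$max_distance)
    if (nrow(prs) >= 20L) {
      fit <- fit_decay_curve(prs, "r2", span = config$span,
                             bin_width = config$ld_fit_bin_width)
      report$ld <- list(n_pairs = nrow(prs),
                        binned = bin_means(prs, "r2", config$bin_width),
                        decay = fit,
                        decay_distance = fit$decay_distance,
                        censored = fit$censored)
    } else {
      skipped <- c(skipped, "ld: fewer than 20 informative pairs")
    }
  } else {
    skipped <- c(skipped, "ld: no variation")
  }

  ## --- ordination -------------------------------------------------------
  if (has_variation) {
    pc <- snp_pca(gm, config$n_axes)
    report$pca <- list(percent_variance = pc$percent_variance[seq_len(pc$n_axes)],
                       scores = pc$scores, result = pc)
  } else {
    skipped <- c(skipped, "pca: no variation")
  }

  ## --- gene trees -------------------------------------------------------
  if (length(alignments)) {
    kept <- Filter(function(a) filter_alignment(a, config$min_length,
                                                config$min_mean_diff),
                   alignments)
    if (length(kept) >= 2L) {
      trees <- lapply(kept, function(a)
        nj_tree(alignment_distances(a, config$tree_model)))
      cons <- majority_consensus(trees)
      report$genetrees <- list(n_candidate = length(alignments),
                               n_filtered = length(kept),
                               n_majority_splits = length(cons$majority_splits),
                               consensus = cons)
    } else {
      skipped <- c(skipped, "genetrees: fewer than 2 alignments pass the filter")
    }
  } else {
    skipped <- c(skipped, "genetrees: no alignments")
  }

  ## --- mating locus ----------------------------------------------------
  if (!is.null(loci_seqs) && length(loci_seqs) >= 2L) {
    pick <- pick_locus_pair(loci_seqs, dataset)
    anc <- find_anchors(loci_seqs[[pick[1L]]], loci_seqs[[pick[2L]]],
                        config$anchor_k)
    syn <- chain_anchors(anc, config$min_indel, config$max_gap)
    report$matlocus <- list(query = pick[1L], subject = pick[2L],
                            n_anchors = nrow(anc),
                            n_inversions = nrow(syn$inversion_intervals),
                            n_indels = nrow(syn$indel_intervals),
                            report = syn)
  } else {
    skipped <- c(skipped, "matlocus: no locus sequences")
  }

  ## --- motif scan -------------------------------------------------------
  prot <- config$proteins
  if (is.null(prot)) {
    prot <- system.file("extdata", "pheromone_precursors.faa",
                        package = "halopop")
  }
  if (nzchar(prot) && file.exists(prot)) {
    hits <- caax_scan(prot)
    report$caax <- list(n_sequences = nrow(hits),
                        n_caax = sum(hits$is_caax), hits = hits)
  } else {
    skipped <- c(skipped, "caax: no protein sequences")
  }

  ## --- core genome -----------------------------------------------------
  presence <- config$presence
  if (is.null(presence)) {
    presence <- simulate_presence_table()
  } else if (is.character(presence)) {
    presence <- as.matrix(utils::read.table(presence, header = TRUE,
                                            sep = "\t", row.names = 1L))
  }
  soft_min <- if (is.null(config$soft_min)) ncol(presence) - 2L else
    config$soft_min
  report$coregenome <- core_genome_counts(presence, soft_min)

  report$skipped <- skipped
  report$truth <- if (!is.null(dataset)) dataset$truth else NULL
  class(report) <- "pipeline_report"

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

## choose a query/subject pair for the locus comparison: one reference-
## orientation and one inverted strain when truth is available, otherwise the
## first two sequences
pick_locus_pair <- function(loci_seqs, dataset) {
  ids <- names(loci_seqs)
  if (!is.null(dataset) && any(dataset$truth$inverted) &&
      any(!dataset$truth$inverted)) {
    q <- dataset$truth$sample[!dataset$truth$inverted][1L]
    s <- dataset$truth$sample[dataset$truth$inverted][1L]
    return(c(q, s))
  }
  ids[1:2]
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  SNPs: %d (density %.3f%%)\n", x$n_snps,
              x$snp_density_percent))
  if (!is.null(x$clusters))
    cat(sprintf("  clonal clusters: %d (MSN: %d nodes, %d edges)\n",
                x$n_clusters, x$msn$n_nodes, x$msn$n_edges))
  if (!is.null(x$ld))
    cat(sprintf("  LD decay distance: %s bp (%d pairs)\n",
                if (x$ld$censored) "censored" else
                  sprintf("%.0f", x$ld$decay_distance), x$ld$n_pairs))
  if (!is.null(x$pca))
    cat(sprintf("  PCA: PC1 %.1f%%, PC2 %.1f%%\n",
                x$pca$percent_variance[1L],
                if (length(x$pca$percent_variance) > 1L)
                  x$pca$percent_variance[2L] else NA))
  if (!is.null(x$genetrees))
    cat(sprintf("  gene trees: %d/%d pass filter; %d majority splits\n",
                x$genetrees$n_filtered, x$genetrees$n_candidate,
                x$genetrees$n_majority_splits))
  if (!is.null(x$matlocus))
    cat(sprintf("  mating locus (%s vs %s): %d inversion, %d indel interval(s)\n",
                x$matlocus$query, x$matlocus$subject,
                x$matlocus$n_inversions, x$matlocus$n_indels))
  if (!is.null(x$caax))
    cat(sprintf("  CAAX: %d/%d proteins positive\n", x$caax$n_caax,
                x$caax$n_sequences))
  if (!is.null(x$coregenome))
    cat(sprintf("  core genome: %d core / %d soft-core of %d clusters\n",
                x$coregenome$n_core, x$coregenome$n_soft_core,
                x$coregenome$n_clusters_total))
  if (length(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

## machine-readable report: flat JSON of the headline numbers plus TSV tables
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- list(
    n_snps = report$n_snps,
    snp_density_percent = report$snp_density_percent,
    n_clusters = report$n_clusters,
    msn_nodes = if (is.null(report$msn)) NA else report$msn$n_nodes,
    msn_edges = if (is.null(report$msn)) NA else report$msn$n_edges,
    ld_n_pairs = if (is.null(report$ld)) NA else report$ld$n_pairs,
    ld_decay_distance = if (is.null(report$ld) || report$ld$censored) NA else
      report$ld$decay_distance,
    ld_censored = if (is.null(report$ld)) NA else report$ld$censored,
    pc1_percent = if (is.null(report$pca)) NA else
      report$pca$percent_variance[1L],
    pc2_percent = if (is.null(report$pca) ||
                      length(report$pca$percent_variance) < 2L) NA else
      report$pca$percent_variance[2L],
    genetrees_filtered = if (is.null(report$genetrees)) NA else
      report$genetrees$n_filtered,
    majority_splits = if (is.null(report$genetrees)) NA else
      report$genetrees$n_majority_splits,
    inversion_intervals = if (is.null(report$matlocus)) NA else
      report$matlocus$n_inversions,
    indel_intervals = if (is.null(report$matlocus)) NA else
      report$matlocus$n_indels,
    caax_positive = if (is.null(report$caax)) NA else report$caax$n_caax,
    core_genes = report$coregenome$n_core,
    soft_core_genes = report$coregenome$n_soft_core,
    skipped = report$skipped,
    seed = report$seed)
  jsonlite::write_json(flat, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(report$clusters)) {
    utils::write.table(
      data.frame(sample = names(report$clusters$membership),
                 cluster = report$clusters$membership),
      file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (!is.null(report$msn))
    utils::write.table(report$msn$graph$edges, file.path(out_dir, "msn_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$ld))
    utils::write.table(report$ld$binned, file.path(out_dir, "ld_binned.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$pca))
    utils::write.table(cbind(sample = rownames(report$pca$scores),
                             as.data.frame(report$pca$scores)),
                       file.path(out_dir, "pca_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$caax))
    utils::write.table(report$caax$hits, file.path(out_dir, "caax_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file.path(out_dir, "report.json"))
}
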