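#' Configure a haploid Wright-Fisher simulation
#'
#' Builds and validates the full parameterization of the forward-time haploid
#' Wright-Fisher simulator used to emulate a multi-strain resequencing study:
#' a multi-contig genome, recurrent biallelic mutation, crossover
#' recombination, planted clonal lineages, designated gene windows for tree
#' building, and a two-orientation mating-type locus.
#'
#' The defaults emulate a survey of 21 haploid strains on a ~9.55 Mbp
#' multi-contig fungal genome: four planted clonal clusters (of 3, 4, 6 and 2
#' strains) whose members differ by well under 200 SNPs, divergent background
#' lineages separated by thousands of SNPs, 24 gene windows of 20 kb, and a
#' 30 kb mating-type locus inverted in 4 of the 21 sampled strains.
#'
#' @param population_size Number of haploid individuals per generation.
#' @param genome Integer vector of contig lengths (bp). Contigs are
#'   independent linkage groups.
#' @param mu Per-base, per-generation mutation probability. Mutation is
#'   finite-sites biallelic: a second hit at a site toggles the allele back.
#' @param rho Per-base, per-generation crossover probability. The number of
#'   crossovers per recombining birth is Poisson(rho * genome length).
#' @param generations Number of generations simulated from a monomorphic
#'   founder population (burn-in equals this value).
#' @param sample_size Number of strains sampled at the end of the run
#'   (clonal copies included).
#' @param clone_spec Data frame with columns `n_copies` and `lambda`: each row
#'   plants one clonal lineage of `n_copies` sampled strains, each strain
#'   carrying Poisson(`lambda`) private mutations on top of the lineage
#'   founder genotype. Use a 0-row data frame for no planted clones.
#' @param gene_windows Data frame with columns `contig`, `start`, `end`
#'   (1-based inclusive, non-overlapping, within contig bounds) marking the
#'   windows from which per-gene alignments are extracted.
#' @param mat_locus List with elements `contig`, `start`, `end`,
#'   `fraction_inverted` describing the mating-type locus and the fraction of
#'   sampled strains carrying the inverted orientation.
#' @param seed Integer RNG seed. Identical configurations (including seed)
#'   give bit-identical datasets.
#' @return An object of class `sim_config`.
#' @seealso [simulate_population()]
#' @export
sim_config <- function(population_size = 50,
                       genome = rep(477500L, 20),
                       mu = 8.9e-6,
                       rho = 8e-6,
                       generations = 250,
                       sample_size = 21,
                       clone_spec = data.frame(n_copies = c(3L, 4L, 6L, 2L),
                                               lambda = 30),
                       gene_windows = default_gene_windows(genome),
                       mat_locus = list(contig = length(genome),
                                        start = 300001L, end = 330000L,
                                        fraction_inverted = 4 / 21),
                       seed = 1L) {
  genome <- as.integer(genome)
  if (length(genome) < 1L || any(genome < 1L))
    stop("configuration error: genome must contain at least one contig of positive length")
  for (r in c(mu = mu, rho = rho)) {
    if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 1)
      stop("configuration error: rates must lie in [0, 1]")
  }
  if (population_size < 2L) stop("configuration error: population_size must be >= 2")
  if (generations < 1L) stop("configuration error: generations must be >= 1")
  if (is.null(clone_spec) || nrow(clone_spec) == 0L) {
    clone_spec <- data.frame(n_copies = integer(0), lambda = numeric(0))
  }
  if (!all(c("n_copies", "lambda") %in% names(clone_spec)))
    stop("configuration error: clone_spec needs columns n_copies and lambda")
  if (any(clone_spec$n_copies < 1L) || any(clone_spec$lambda < 0))
    stop("configuration error: invalid clone_spec")
  n_clone <- sum(clone_spec$n_copies)
  n_founders <- nrow(clone_spec) + max(0L, sample_size - n_clone)
  if (sample_size < n_clone)
    stop("configuration error: sample_size smaller than planted clone copies")
  if (n_founders > population_size)
    stop("configuration error: sample_size exceeds available individuals")
  gene_windows <- validate_windows(gene_windows, genome)
  if (!is.null(mat_locus)) {
    stopifnot(mat_locus$contig >= 1L, mat_locus$contig <= length(genome),
              mat_locus$start >= 1L, mat_locus$end <= genome[mat_locus$contig],
              mat_locus$start < mat_locus$end,
              mat_locus$fraction_inverted >= 0, mat_locus$fraction_inverted <= 1)
  }
  structure(list(population_size = as.integer(population_size),
                 genome = genome, mu = mu, rho = rho,
                 generations = as.integer(generations),
                 sample_size = as.integer(sample_size),
                 clone_spec = clone_spec, gene_windows = gene_windows,
                 mat_locus = mat_locus, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default gene windows for a given genome
#'
#' Lays out up to 24 non-overlapping 20 kb windows cycling over contigs,
#' skipping contigs too short to host a window.
#'
#' @param genome Integer vector of contig lengths.
#' @param n_windows Number of windows to place.
#' @param width Window width in bp.
#' @return Data frame with columns `contig`, `start`, `end`.
#' @export
default_gene_windows <- function(genome, n_windows = 24L, width = 20000L) {
  out <- list()
  pass <- 0L
  while (length(out) < n_windows && pass < 50L) {
    for (ctg in seq_along(genome)) {
      start <- 50000L + pass * (width + 30000L)
      if (start + width - 1L <= genome[ctg] - 1000L) {
        out[[length(out) + 1L]] <- data.frame(contig = ctg, start = start,
                                              end = start + width - 1L)
      }
      if (length(out) >= n_windows) break
    }
    pass <- pass + 1L
  }
  do.call(rbind, out)
}

validate_windows <- function(gene_windows, genome) {
  if (is.null(gene_windows) || nrow(gene_windows) == 0L)
    return(data.frame(contig = integer(0), start = integer(0), end = integer(0)))
  stopifnot(all(c("contig", "start", "end") %in% names(gene_windows)))
  gw <- gene_windows[order(gene_windows$contig, gene_windows$start), , drop = FALSE]
  if (any(gw$contig < 1L) || any(gw$contig > length(genome)) ||
      any(gw$start < 1L) || any(gw$end > genome[gw$contig]) ||
      any(gw$start > gw$end))
    stop("configuration error: gene windows outside contig bounds")
  same <- which(diff(gw$contig) == 0)
  if (any(gw$start[same + 1L] <= gw$end[same]))
    stop("configuration error: gene windows overlap")
  rownames(gw) <- NULL
  gw
}

## ---- internal engine ------------------------------------------------------

## Genotypes are sorted integer vectors of global 1-based positions carrying
## the derived allele relative to the current reference state. Finite-sites
## mutation toggles membership; sites fixed in the whole population are pruned
## periodically (a pure relabelling of the reference).

## Toggle derived state at `pos` (positions drawn with replacement: an even
## number of hits at one site cancels out).
toggle_sites <- function(v, pos) {
  if (length(pos) == 0L) return(v)
  r <- rle(sort(pos))
  odd <- r$values[r$lengths %% 2L == 1L]
  if (length(odd) == 0L) return(v)
  sort(c(v[!(v %in% odd)], odd[!(odd %in% v)]))
}

## Recombine two parental genotypes given crossover count k.
## Contigs are independent linkage groups: each contig starts from a randomly
## chosen parent; each crossover switches the source.
recombine_pair <- function(a, b, k, total_len, contig_starts) {
  breaks <- ceiling(stats::runif(k) * total_len)
  start_parents <- sample.int(2L, length(contig_starts), replace = TRUE)
  edges <- sort(unique(c(contig_starts, breaks + 1L)))
  edges <- edges[edges <= total_len]
  is_cstart <- edges %in% contig_starts
  src <- integer(length(edges))
  cur <- 0L
  ci <- 0L
  for (s in seq_along(edges)) {
    if (is_cstart[s]) {
      ci <- ci + 1L
      cur <- start_parents[ci]
    } else {
      cur <- 3L - cur
    }
    src[s] <- cur
  }
  keep_a <- a[src[findInterval(a, edges)] == 1L]
  keep_b <- b[src[findInterval(b, edges)] == 2L]
  sort(c(keep_a, keep_b))
}

prune_fixed <- function(pop) {
  common <- pop[[1L]]
  for (i in seq_along(pop)[-1L]) {
    if (length(common) == 0L) return(pop)
    common <- common[common %in% pop[[i]]]
  }
  if (length(common) == 0L) return(pop)
  lapply(pop, function(v) v[!(v %in% common)])
}

#' Run the haploid Wright-Fisher simulator
#'
#' Forward-time simulation from a monomorphic founder population. Each
#' generation every individual draws one parent, or two parents when at least
#' one crossover occurs (crossovers per birth ~ Poisson(rho * genome length),
#' placed uniformly; contigs recombine as independent linkage groups).
#' Mutations per birth ~ Poisson(mu * genome length), placed uniformly;
#' mutation is finite-sites biallelic, so a site hit twice flips back and
#' every segregating site has exactly two alleles. After the final
#' generation, clonal lineages are planted by copying distinct founder
#' individuals and adding Poisson(lambda) private mutations per copy; the
#' remaining strains are sampled from distinct individuals. The mating-type
#' locus orientation is assigned per lineage so that the configured fraction
#' of sampled strains (rounded to the nearest achievable count) carries the
#' inverted form.
#'
#' Draw order per generation (single seeded RNG stream): crossover counts,
#' mutation counts, first parents, second parents, then per individual (in
#' index order) crossover positions plus per-contig starting parents, then
#' mutation positions. After the final generation: founder indices, per-clone
#' private mutation counts and positions, inversion assignment order, window
#' reference sequences, locus reference sequence, per-locus ref/alt alleles.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `simulated_dataset`: a list with elements
#'   `genotypes` (a [genotype_matrix()] of segregating sites in the sample),
#'   `gene_alignments` (named list of equal-length per-window alignments,
#'   each a named character vector of sequences), `locus_sequences` (named
#'   character vector of per-sample mating-locus DNA), `truth` (data frame
#'   with `sample`, `lineage`, `inverted`, `clone_parent`, plus attributes),
#'   `genealogy` (an `ape::phylo` genealogy of the sample when `rho = 0`,
#'   otherwise `NULL`), `n_crossovers` (realized crossover events) and
#'   `config`.
#' @examples
#' cfg <- sim_config(population_size = 20, genome = 50000L, mu = 2e-5,
#'                   rho = 0, generations = 60, sample_size = 6,
#'                   clone_spec = data.frame(n_copies = 2L, lambda = 5),
#'                   gene_windows = data.frame(contig = 1, start = 1001,
#'                                             end = 3000),
#'                   mat_locus = list(contig = 1, start = 30001, end = 40000,
#'                                    fraction_inverted = 0.5),
#'                   seed = 42)
#' ds <- simulate_population(cfg)
#' dim(ds$genotypes$calls)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$population_size
  genome <- config$genome
  L <- sum(as.numeric(genome))
  contig_starts <- c(1, cumsum(as.numeric(genome))[-length(genome)] + 1)
  G <- config$generations

  pop <- rep(list(integer(0)), N)
  parents <- if (config$rho == 0) matrix(0L, nrow = G, ncol = N) else NULL
  n_crossovers <- 0

  for (g in seq_len(G)) {
    nx <- stats::rpois(N, config$rho * L)
    nm <- stats::rpois(N, config$mu * L)
    p1 <- sample.int(N, N, replace = TRUE)
    p2 <- sample.int(N, N, replace = TRUE)
    newpop <- pop[p1]
    for (i in which(nx > 0L)) {
      newpop[[i]] <- recombine_pair(pop[[p1[i]]], pop[[p2[i]]], nx[i],
                                    L, contig_starts)
      n_crossovers <- n_crossovers + nx[i]
    }
    for (i in which(nm > 0L)) {
      mpos <- ceiling(stats::runif(nm[i]) * L)
      newpop[[i]] <- toggle_sites(newpop[[i]], mpos)
    }
    pop <- newpop
    if (!is.null(parents)) parents[g, ] <- p1
    if (g %% 25L == 0L) pop <- prune_fixed(pop)
  }
  pop <- prune_fixed(pop)

  build_dataset(config, pop, parents, n_crossovers, L, contig_starts)
}

## Assemble the sampled dataset: clones, singletons, truth labels, sequences.
build_dataset <- function(config, pop, parents, n_crossovers, L, contig_starts) {
  N <- config$population_size
  cs <- config$clone_spec
  n_lineages <- nrow(cs)
  n_clone <- if (n_lineages) sum(cs$n_copies) else 0L
  n_single <- config$sample_size - n_clone
  founders <- sample.int(N, n_lineages + n_single)

  genotypes <- list()
  lineage <- character(0)
  clone_parent <- integer(0)
  for (j in seq_len(n_lineages)) {
    fg <- pop[[founders[j]]]
    for (cc in seq_len(cs$n_copies[j])) {
      k <- stats::rpois(1L, cs$lambda[j])
      g <- if (k > 0L) toggle_sites(fg, ceiling(stats::runif(k) * L)) else fg
      genotypes[[length(genotypes) + 1L]] <- g
      lineage <- c(lineage, sprintf("L%02d", j))
      clone_parent <- c(clone_parent, founders[j])
    }
  }
  for (s in seq_len(n_single)) {
    genotypes[[length(genotypes) + 1L]] <- pop[[founders[n_lineages + s]]]
    lineage <- c(lineage, sprintf("S%02d", s))
    clone_parent <- c(clone_parent, NA_integer_)
  }
  n <- config$sample_size
  sample_ids <- sprintf("strain_%02d", seq_len(n))

  ## mating-locus orientation: whole lineages flip together; greedy fill in
  ## random unit order toward round(fraction * n)
  inverted <- rep(FALSE, n)
  if (!is.null(config$mat_locus)) {
    units <- split(seq_len(n), lineage)
    target <- round(config$mat_locus$fraction_inverted * n)
    got <- 0L
    for (u in sample(units)) {
      if (got + length(u) <= target) {
        inverted[u] <- TRUE
        got <- got + length(u)
      }
      if (got == target) break
    }
  }

  ## reference letters: window sequences first, then the mating locus, then
  ## per-locus ref/alt for remaining segregating sites
  gw <- config$gene_windows
  window_ref <- list()
  if (nrow(gw)) {
    for (w in seq_len(nrow(gw))) {
      len <- gw$end[w] - gw$start[w] + 1L
      window_ref[[w]] <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    }
  }
  ml <- config$mat_locus
  locus_ref <- NULL
  if (!is.null(ml)) {
    locus_ref <- sample(c("A", "C", "G", "T"), ml$end - ml$start + 1L,
                        replace = TRUE)
  }

  ## segregating sites in the sample (present in >=1, absent in >=1 strain)
  all_sites <- sort(unique(unlist(genotypes)))
  if (length(all_sites)) {
    carrier_counts <- tabulate(match(unlist(genotypes), all_sites),
                               nbins = length(all_sites))
    seg <- all_sites[carrier_counts < n]
  } else {
    seg <- integer(0)
  }

  site_contig <- findInterval(seg, contig_starts)
  site_local <- seg - contig_starts[site_contig] + 1
  ref_allele <- ref_base_at(seg, site_contig, site_local, gw, window_ref,
                            ml, locus_ref)
  alt_allele <- vapply(ref_allele, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))

  calls <- matrix(0L, nrow = n, ncol = length(seg))
  for (i in seq_len(n)) {
    hit <- match(genotypes[[i]], seg)
    hit <- hit[!is.na(hit)]
    calls[i, hit] <- 1L
  }
  gm <- genotype_matrix(
    calls = calls,
    loci = data.frame(contig = sprintf("contig_%02d", site_contig),
                      pos = as.integer(site_local),
                      ref = unname(ref_allele), alt = unname(alt_allele),
                      stringsAsFactors = FALSE),
    sample_ids = sample_ids)

  ## per-window alignments: substitutions only, so alignment = extraction
  gene_alignments <- list()
  if (nrow(gw)) {
    for (w in seq_len(nrow(gw))) {
      g_start <- contig_starts[gw$contig[w]] + gw$start[w] - 1
      g_end <- contig_starts[gw$contig[w]] + gw$end[w] - 1
      aln <- character(n)
      for (i in seq_len(n)) {
        seqc <- window_ref[[w]]
        d <- genotypes[[i]]
        d <- d[d >= g_start & d <= g_end]
        if (length(d)) {
          off <- d - g_start + 1
          seqc[off] <- substitute_base(seqc[off], seg, ref_allele, alt_allele, d)
        }
        aln[i] <- paste(seqc, collapse = "")
      }
      names(aln) <- sample_ids
      gene_alignments[[sprintf("gene_%02d", w)]] <- aln
    }
  }

  ## per-sample mating-locus sequences; inverted strains carry the central
  ## 70% of the locus reverse-complemented
  locus_sequences <- NULL
  inv_region <- NULL
  if (!is.null(ml)) {
    len <- ml$end - ml$start + 1L
    flank <- floor(0.15 * len)
    inv_region <- c(flank + 1L, len - flank)
    g_start <- contig_starts[ml$contig] + ml$start - 1
    g_end <- contig_starts[ml$contig] + ml$end - 1
    locus_sequences <- character(n)
    for (i in seq_len(n)) {
      seqc <- locus_ref
      d <- genotypes[[i]]
      d <- d[d >= g_start & d <= g_end]
      if (length(d)) {
        off <- d - g_start + 1
        seqc[off] <- substitute_base(seqc[off], seg, ref_allele, alt_allele, d)
      }
      if (inverted[i]) {
        mid <- seqc[inv_region[1]:inv_region[2]]
        seqc[inv_region[1]:inv_region[2]] <- rev(dna_complement(mid))
      }
      locus_sequences[i] <- paste(seqc, collapse = "")
    }
    names(locus_sequences) <- sample_ids
  }

  genealogy <- NULL
  if (!is.null(parents)) {
    genealogy <- pedigree_genealogy(parents, founders, lineage, sample_ids,
                                    clone_parent)
  }

  truth <- data.frame(sample = sample_ids, lineage = lineage,
                      inverted = inverted, clone_parent = clone_parent,
                      stringsAsFactors = FALSE)

  structure(list(genotypes = gm, gene_alignments = gene_alignments,
                 locus_sequences = locus_sequences, truth = truth,
                 genealogy = genealogy, n_crossovers = n_crossovers,
                 inversion_region = inv_region, config = config),
            class = "simulated_dataset")
}

## Reference base at arbitrary segregating sites, honouring bases already
## fixed by window / locus reference sequences.
ref_base_at <- function(seg, site_contig, site_local, gw, window_ref,
                        ml, locus_ref) {
  refb <- character(length(seg))
  if (length(seg) == 0L) return(refb)
  unset <- rep(TRUE, length(seg))
  if (nrow(gw)) {
    for (w in seq_len(nrow(gw))) {
      inw <- unset & site_contig == gw$contig[w] &
        site_local >= gw$start[w] & site_local <= gw$end[w]
      if (any(inw)) {
        refb[inw] <- window_ref[[w]][site_local[inw] - gw$start[w] + 1L]
        unset[inw] <- FALSE
      }
    }
  }
  if (!is.null(ml)) {
    inl <- unset & site_contig == ml$contig &
      site_local >= ml$start & site_local <= ml$end
    if (any(inl)) {
      refb[inl] <- locus_ref[site_local[inl] - ml$start + 1L]
      unset[inl] <- FALSE
    }
  }
  if (any(unset))
    refb[unset] <- sample(c("A", "C", "G", "T"), sum(unset), replace = TRUE)
  refb
}

## Derived base for global positions `d`: the recorded alt allele for
## segregating sites, otherwise (sites fixed in the sample or toggled private
## sites) a deterministic complement-style substitution of the reference base.
substitute_base <- function(ref_here, seg, ref_allele, alt_allele, d) {
  idx <- match(d, seg)
  out <- character(length(d))
  known <- !is.na(idx)
  out[known] <- alt_allele[idx[known]]
  if (any(!known)) out[!known] <- dna_complement(ref_here[!known])
  out
}

dna_complement <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]
}

## Reconstruct the sample genealogy from the recorded pedigree (rho = 0 only):
## pairwise coalescent times between founder individuals, average-linkage
## clustering of the (ultrametric) times, clones attached at zero height,
## zero-length internal edges collapsed to multifurcations.
pedigree_genealogy <- function(parents, founders, lineage, sample_ids,
                               clone_parent) {
  G <- nrow(parents)
  nf <- length(founders)
  if (nf < 2L) return(NULL)
  anc <- matrix(0L, nrow = nf, ncol = G + 1L)
  anc[, G + 1L] <- founders
  for (g in G:1L) anc[, g] <- parents[g, anc[, g + 1L]]
  tmrca <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      eq <- which(anc[i, ] == anc[j, ])
      t_back <- if (length(eq)) G + 1L - max(eq) else G + 1L
      tmrca[i, j] <- tmrca[j, i] <- t_back
    }
  }
  ## founder index per sample: lineage founders first, then singletons in
  ## the order their founders were drawn
  n <- length(sample_ids)
  lin_f <- match(clone_parent, founders)
  single_ids <- which(is.na(clone_parent))
  if (length(single_ids)) {
    n_lin <- sum(!is.na(unique(clone_parent)))
    lin_f[single_ids] <- n_lin + seq_along(single_ids)
  }
  d <- matrix(0, n, n, dimnames = list(sample_ids, sample_ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <-
        if (lin_f[i] == lin_f[j]) 0 else 2 * tmrca[lin_f[i], lin_f[j]]
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  ape::di2multi(tr, tol = 1e-8)
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated haploid population sample\n")
  cat(sprintf("  strains: %d   segregating sites: %d   contigs: %d\n",
              length(x$genotypes$sample_ids), nrow(x$genotypes$loci),
              length(x$config$genome)))
  cat(sprintf("  gene windows: %d   mating locus: %s   crossovers: %d\n",
              length(x$gene_alignments),
              if (is.null(x$locus_sequences)) "none" else
                sprintf("%d strains inverted", sum(x$truth$inverted)),
              x$n_crossovers))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits a haploid VCF 4.2 file (`variants.vcf`), one aligned FASTA per gene
#' window (`genes/<gene_id>.fasta`), a per-sample mating-locus FASTA
#' (`mat_locus.fasta`) and a truth table (`truth.tsv`: sample, lineage,
#' inversion, clone_parent). Files round-trip through [read_vcf()] and
#' [read_gene_alignments()] without loss.
#'
#' @param dataset A `simulated_dataset` from [simulate_population()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list of the written paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(out_dir, "variants.vcf")
  write_haploid_vcf(dataset$genotypes, dataset$config$genome, vcf_path)
  paths <- list(vcf = vcf_path)

  if (length(dataset$gene_alignments)) {
    gdir <- file.path(out_dir, "genes")
    dir.create(gdir, showWarnings = FALSE)
    paths$genes <- character(0)
    for (gid in names(dataset$gene_alignments)) {
      p <- file.path(gdir, paste0(gid, ".fasta"))
      write_fasta(dataset$gene_alignments[[gid]], p)
      paths$genes <- c(paths$genes, p)
    }
  }
  if (!is.null(dataset$locus_sequences)) {
    paths$mat_locus <- file.path(out_dir, "mat_locus.fasta")
    write_fasta(dataset$locus_sequences, paths$mat_locus)
  }
  paths$truth <- file.path(out_dir, "truth.tsv")
  utils::write.table(dataset$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

## Minimal haploid VCF 4.2 writer (##contig headers, GT-only FORMAT).
write_haploid_vcf <- function(gm, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=halopop", con)
  writeLines(sprintf("##contig=<ID=contig_%02d,length=%d>",
                     seq_along(genome), genome), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$sample_ids), collapse = "\t"), con)
  if (nrow(gm$loci)) {
    gt <- t(gm$calls)
    gt_chr <- matrix(as.character(gt), nrow = nrow(gt))
    gt_chr[is.na(gt_chr)] <- "."
    body <- paste(gm$loci$contig, gm$loci$pos, ".", gm$loci$ref, gm$loci$alt,
                  ".", "PASS", ".", "GT",
                  apply(gt_chr, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
  invisible(path)
}

#' Generate a synthetic gene presence/absence table
#'
#' Produces a randomized gene-cluster-by-genome presence table of the kind
#' consumed by [core_genome_counts()], emulating a pangenome in which most
#' clusters are universal, a minority are missing from one or two genomes and
#' a tail is patchily distributed. Entirely synthetic: counts follow the
#' configured mixture, not any real annotation.
#'
#' @param n_genomes Number of genome columns.
#' @param n_clusters Number of gene-cluster rows.
#' @param p_core Probability that a cluster is universal.
#' @param p_near_core Probability that a cluster is missing from 1-2 genomes.
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @return Integer matrix (clusters x genomes) of copy counts (0/1).
#' @export
simulate_presence_table <- function(n_genomes = 22L, n_clusters = 4100L,
                                    p_core = 0.62, p_near_core = 0.15,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cls <- sample(c("core", "near", "cloud"), n_clusters, replace = TRUE,
                prob = c(p_core, p_near_core, 1 - p_core - p_near_core))
  m <- matrix(1L, nrow = n_clusters, ncol = n_genomes,
              dimnames = list(sprintf("cluster_%05d", seq_len(n_clusters)),
                              sprintf("genome_%02d", seq_len(n_genomes))))
  for (i in which(cls == "near")) {
    m[i, sample.int(n_genomes, sample(1:2, 1L))] <- 0L
  }
  for (i in which(cls == "cloud")) {
    n_missing <- 3L + stats::rbinom(1L, n_genomes - 4L, 0.35)
    m[i, sample.int(n_genomes, n_missing)] <- 0L
  }
  m
}
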