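#' Detect clonal lineages from pairwise SNP distances
#'
#' Groups strains into clonal clusters by single linkage: two strains belong
#' to the same cluster when they are connected by a chain of pairwise
#' distances strictly below the threshold. The default threshold of 200 SNPs
#' reflects the magnitude separating within-lineage from between-lineage
#' differences in compact haploid fungal genomes.
#'
#' @param dist A `snp_distance` from [pairwise_differences()], or any
#'   symmetric numeric matrix with dimnames.
#' @param threshold Positive SNP-difference cutoff (strict: edges at
#'   `d < threshold`).
#' @return Object of class `clonal_clusters`: list with `threshold`,
#'   `partition` (list of character vectors of strain names) and `membership`
#'   (named integer vector).
#' @export
clonal_clusters <- function(dist, threshold = 200) {
  if (threshold <= 0) stop("threshold must be positive")
  d <- dist_matrix_of(dist)
  ids <- rownames(d)
  g <- igraph::graph_from_adjacency_matrix(d < threshold, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  membership <- as.integer(comp)
  names(membership) <- ids
  partition <- split(ids, membership)
  names(partition) <- NULL
  structure(list(threshold = threshold, partition = partition,
                 membership = membership),
            class = "clonal_clusters")
}

#' @export
print.clonal_clusters <- function(x, ...) {
  sizes <- lengths(x$partition)
  cat(sprintf("Clonal clusters at d < %s: %d clusters (%d multi-strain, largest %d)\n",
              format(x$threshold), length(x$partition), sum(sizes > 1L),
              max(sizes)))
  invisible(x)
}

dist_matrix_of <- function(dist) {
  d <- if (inherits(dist, "snp_distance")) dist$d else as.matrix(dist)
  stopifnot(nrow(d) == ncol(d), isSymmetric(unname(d * 1.0)))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- sprintf("sample_%02d", seq_len(nrow(d)))
  }
  d
}

#' Minimum spanning network over clonal lineages
#'
#' Collapses strains into clonal lineages (single-linkage clusters below
#' `collapse_threshold`) and builds a minimum spanning network over the
#' collapsed nodes: Kruskal's algorithm on the minimum inter-lineage
#' distances, retaining, at each selected weight, every tied edge that joins
#' the same pair of components (so the result is a network rather than a
#' tree).
#'
#' @param dist A `snp_distance` or symmetric distance matrix.
#' @param collapse_threshold SNP cutoff for collapsing clones into one node.
#' @return Object of class `msn_graph`: list with `nodes` (list of strain
#'   groups), `node_ids`, `edges` (data frame `from`, `to`, `weight`,
#'   `in_mst`), and `clusters` (the `clonal_clusters` used).
#' @export
minimum_spanning_network <- function(dist, collapse_threshold = 200) {
  d <- dist_matrix_of(dist)
  cl <- clonal_clusters(dist, collapse_threshold)
  k <- length(cl$partition)
  node_ids <- vapply(cl$partition, function(g) g[[1L]], character(1))
  ## minimum inter-lineage distance
  nd <- matrix(Inf, k, k, dimnames = list(node_ids, node_ids))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j)
        nd[i, j] <- min(d[cl$partition[[i]], cl$partition[[j]], drop = FALSE])
    }
  }
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), in_mst = logical(0))
  if (k >= 2L) {
    comp <- seq_len(k)
    cand <- which(upper.tri(nd), arr.ind = TRUE)
    ew <- nd[cand]
    ord <- order(ew, cand[, 1L], cand[, 2L])
    cand <- cand[ord, , drop = FALSE]
    ew <- ew[ord]
    taken <- integer(0)
    mst_flag <- logical(0)
    u <- 1L
    while (u <= length(ew) && length(unique(comp)) > 1L) {
      w <- ew[u]
      at_w <- which(ew == w)
      at_w <- at_w[at_w >= u]
      ## evaluate all ties at this weight against the component state before
      ## any merge at this weight
      joins <- at_w[comp[cand[at_w, 1L]] != comp[cand[at_w, 2L]]]
      taken <- c(taken, joins)
      for (e in joins) {
        c1 <- comp[cand[e, 1L]]
        c2 <- comp[cand[e, 2L]]
        mst_flag <- c(mst_flag, c1 != c2)
        if (c1 != c2) comp[comp == c2] <- c1
      }
      u <- max(at_w) + 1L
    }
    if (length(taken)) {
      edges <- data.frame(from = node_ids[cand[taken, 1L]],
                          to = node_ids[cand[taken, 2L]],
                          weight = ew[taken], in_mst = mst_flag,
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$weight, edges$from, edges$to), ]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = cl$partition, node_ids = node_ids, edges = edges,
                 clusters = cl),
            class = "msn_graph")
}

#' @export
print.msn_graph <- function(x, ...) {
  cat(sprintf("Minimum spanning network: %d nodes (%d strains), %d edges (%d tie edges)\n",
              length(x$nodes), sum(lengths(x$nodes)), nrow(x$edges),
              sum(!x$edges$in_mst)))
  invisible(x)
}

#' Core and soft-core genome counts
#'
#' Summarizes a gene-cluster-by-genome presence table: core clusters are
#' present (count >= 1) in every genome; soft-core clusters are present in at
#' least `soft_min` genomes.
#'
#' @param presence Matrix or data frame of non-negative counts, rows = gene
#'   clusters, columns = genomes.
#' @param soft_min Minimum number of genomes for the soft core (default: all
#'   but two, the usual near-universal convention).
#' @return Object of class `core_genome_summary`: list with
#'   `n_clusters_total`, `n_core`, `n_soft_core`, `soft_min`, `n_genomes`.
#' @export
core_genome_counts <- function(presence, soft_min = ncol(presence) - 2L) {
  m <- as.matrix(presence)
  if (length(m) == 0L || nrow(m) == 0L) stop("empty presence table")
  if (any(m < 0)) stop("presence entries must be non-negative counts")
  if (soft_min > ncol(m)) stop("soft_min exceeds the number of genomes")
  present <- m >= 1L
  n_in <- rowSums(present)
  structure(list(n_clusters_total = nrow(m),
                 n_core = sum(n_in == ncol(m)),
                 n_soft_core = sum(n_in >= soft_min),
                 soft_min = as.integer(soft_min),
                 n_genomes = ncol(m)),
            class = "core_genome_summary")
}

#' @export
print.core_genome_summary <- function(x, ...) {
  cat(sprintf("Core genome: %d/%d clusters in all %d genomes; soft core (>= %d genomes): %d\n",
              x$n_core, x$n_clusters_total, x$n_genomes, x$soft_min,
              x$n_soft_core))
  invisible(x)
}
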