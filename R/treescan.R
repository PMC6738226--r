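#' Read aligned FASTA gene alignments
#'
#' Reads one or more aligned FASTA files (equal-length nucleotide sequences)
#' into named character vectors, the alignment representation used throughout
#' the gene-tree module.
#'
#' @param paths Character vector of FASTA paths, or a single directory (all
#'   `.fa`/`.fasta` files are read, sorted by name).
#' @return Named list (by file base name) of named character vectors.
#' @export
read_gene_alignments <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.(fa|fasta)$",
                             full.names = TRUE))
  }
  out <- lapply(paths, function(p) {
    ss <- Biostrings::readDNAStringSet(p)
    stats::setNames(as.character(ss), names(ss))
  })
  names(out) <- sub("\\.(fa|fasta)$", "", basename(paths))
  out
}

alignment_char_matrix <- function(aln) {
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L)
    stop("alignment sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Mean pairwise nucleotide differences of an alignment
#'
#' For every pair of sequences, counts the columns at which both carry an
#' unambiguous base (A/C/G/T) and the bases differ; returns the arithmetic
#' mean of these integer counts over all pairs.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @return Mean number of differing columns per sequence pair.
#' @export
mean_pairwise_diff <- function(aln) {
  m <- alignment_char_matrix(aln)
  n <- nrow(m)
  if (n < 2L) return(0)
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- valid[i, ] & valid[j, ]
      tot <- tot + sum(both & m[i, ] != m[j, ])
    }
  }
  tot / (n * (n - 1L) / 2L)
}

#' Gene-alignment filter for tree building
#'
#' Retains an alignment only when it is strictly longer than `min_length`
#' columns and its mean pairwise difference count is strictly larger than
#' `min_mean_diff` (both inequalities strict: alignments of exactly 200
#' columns or exactly 15.0 mean differences are rejected). Short or
#' near-invariant alignments carry too little signal for a resolved gene
#' tree.
#'
#' @param aln Named character vector of aligned sequences.
#' @param min_length Minimum alignment length (exclusive bound).
#' @param min_mean_diff Minimum mean pairwise difference (exclusive bound).
#' @return `TRUE` when the alignment passes.
#' @export
filter_alignment <- function(aln, min_length = 200, min_mean_diff = 15) {
  len <- unique(nchar(aln))
  stopifnot(length(len) == 1L)
  len > min_length && mean_pairwise_diff(aln) > min_mean_diff
}

#' Pairwise distances from a gene alignment
#'
#' Computes pairwise evolutionary distances over columns at which both
#' sequences carry an unambiguous base: `raw` mismatch proportion,
#' Jukes-Cantor (`JC69`) `-(3/4) ln(1 - 4p/3)`, or Kimura two-parameter
#' (`K2P`) from transition/transversion proportions
#' `-(1/2) ln(1 - 2P - Q) - (1/4) ln(1 - 2Q)`.
#'
#' @param aln Named character vector of >= 3 aligned sequences.
#' @param model One of `"raw"`, `"JC69"`, `"K2P"`.
#' @return Symmetric numeric matrix of distances with sequence names.
#' @export
alignment_distances <- function(aln, model = c("raw", "JC69", "K2P")) {
  model <- match.arg(model)
  m <- alignment_char_matrix(aln)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 sequences")
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  purine <- m %in% c("A", "G")
  dim(purine) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- valid[i, ] & valid[j, ]
      nb <- sum(both)
      if (nb == 0L) stop(sprintf("no comparable sites between %s and %s",
                                 rownames(m)[i], rownames(m)[j]))
      diff <- both & m[i, ] != m[j, ]
      p <- sum(diff) / nb
      d[i, j] <- d[j, i] <- switch(
        model,
        raw = p,
        JC69 = {
          arg <- 1 - 4 * p / 3
          if (arg <= 0)
            stop(sprintf("saturated-distance error between %s and %s",
                         rownames(m)[i], rownames(m)[j]))
          -0.75 * log(arg)
        },
        K2P = {
          transition <- diff & (purine[i, ] == purine[j, ])
          P <- sum(transition) / nb
          Q <- p - P
          a1 <- 1 - 2 * P - Q
          a2 <- 1 - 2 * Q
          if (a1 <= 0 || a2 <= 0)
            stop(sprintf("saturated-distance error between %s and %s",
                         rownames(m)[i], rownames(m)[j]))
          -0.5 * log(a1) - 0.25 * log(a2)
        })
    }
  }
  d
}

#' Neighbor-joining gene tree
#'
#' Builds an unrooted tree by neighbor joining on a pairwise distance matrix
#' and clamps negative branch lengths to zero. The tree builder is
#' deliberately pluggable: every downstream statistic (bipartitions,
#' consensus, concordance counts) consumes topologies from any builder.
#'
#' @param dist Symmetric numeric distance matrix with taxon dimnames
#'   (>= 3 taxa, finite entries).
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("distances must be finite")
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' Extracts, for every internal edge, the two-set split of the leaf set it
#' induces, in canonical form: each split is encoded as the sorted,
#' comma-joined members of the side that does not contain the reference leaf
#' (the alphabetically first tip). Trivial splits (one side a single leaf)
#' are excluded; a star tree yields an empty set.
#'
#' @param tree An `ape::phylo` tree with >= 4 uniquely labelled leaves.
#' @return Character vector of canonical split encodings (possibly empty).
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop("leaf labels must be unique")
  if (length(tips) < 4L) return(character(0))
  tree <- ape::unroot(tree)
  n <- length(tips)
  ## tip set below each node, by postorder accumulation
  tree <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", max(tree$edge))
  for (i in seq_len(n)) below[[i]] <- tips[i]
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]
    chd <- tree$edge[e, 2L]
    below[[par]] <- c(below[[par]], below[[chd]])
  }
  ref <- sort(tips)[1L]
  splits <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    chd <- tree$edge[e, 2L]
    if (chd <= n) next                     # pendant edge: trivial
    side <- below[[chd]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (ref %in% side) side <- setdiff(tips, side)
    splits <- c(splits, paste(sort(side), collapse = ","))
  }
  unique(splits)
}

#' Majority-rule consensus of gene trees
#'
#' Tallies the nontrivial bipartitions of a set of gene trees sharing one
#' leaf set, reports each split's frequency, and assembles the consensus tree
#' from the splits present in more than `threshold` of the trees (at
#' threshold >= 0.5 majority splits are always mutually compatible). The
#' number of majority splits is the concordance statistic: a recombining
#' population shows few internal nodes shared by more than half of the gene
#' trees, a clonal one shows many.
#'
#' @param trees List of `ape::phylo` trees on the identical leaf set.
#' @param threshold Split-frequency threshold (default 0.5, strict).
#' @return Object of class `consensus_result`: list with `split_frequencies`
#'   (named numeric), `majority_splits` (character), `consensus_tree`
#'   (`ape::phylo`), `n_trees`.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 2L)
  taxa <- sort(trees[[1L]]$tip.label)
  for (k in seq_along(trees)) {
    if (!identical(sort(trees[[k]]$tip.label), taxa))
      stop(sprintf("input error: tree %d has a different leaf set", k))
  }
  all_splits <- unlist(lapply(trees, tree_bipartitions))
  freq <- if (length(all_splits)) table(all_splits) / length(trees) else
    table(character(0))
  freq <- stats::setNames(as.numeric(freq), names(freq))
  majority <- names(freq)[freq > threshold]
  structure(list(split_frequencies = freq, majority_splits = majority,
                 consensus_tree = splits_to_tree(majority, taxa),
                 n_trees = length(trees)),
            class = "consensus_result")
}

## Assemble a (multifurcating) tree from mutually compatible splits. Splits
## are encoded as in tree_bipartitions(): the side not containing the
## reference leaf. Each such side is a nested cluster in the tree rooted at
## the reference leaf.
splits_to_tree <- function(splits, taxa) {
  clusters <- lapply(strsplit(splits, ",", fixed = TRUE), sort)
  nest <- function(members, clust) {
    inside <- clust[vapply(clust, function(cl) all(cl %in% members),
                           logical(1))]
    maximal <- inside[vapply(seq_along(inside), function(i) {
      !any(vapply(seq_along(inside), function(j) {
        j != i && length(inside[[j]]) > length(inside[[i]]) &&
          all(inside[[i]] %in% inside[[j]])
      }, logical(1)))
    }, logical(1))]
    covered <- unique(unlist(maximal))
    parts <- c(vapply(maximal, function(cl) {
      rest <- inside[vapply(inside, function(x)
        all(x %in% cl) && length(x) < length(cl), logical(1))]
      nest_str <- nest(cl, rest)
      nest_str
    }, character(1)), setdiff(members, covered))
    if (length(parts) == 1L) parts else
      paste0("(", paste(parts, collapse = ","), ")")
  }
  newick <- paste0(nest(taxa, clusters), ";")
  ## a bare leaf set (no splits) nests as (a,b,c); already valid newick
  ape::read.tree(text = newick)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Majority-rule consensus of %d gene trees: %d majority splits\n",
              x$n_trees, length(x$majority_splits)))
  invisible(x)
}
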