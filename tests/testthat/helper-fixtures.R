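## Shared fixtures and independent brute-force oracles for the test suite.

## small, fast simulator configuration used across tests
small_sim <- function(seed = 1L, mu = 2e-5, rho = 1e-5, N = 40L,
                      contigs = rep(100000L, 5), generations = 150L,
                      sample_size = 12L,
                      clone_spec = data.frame(n_copies = c(3L, 2L), lambda = 10),
                      gene_windows = data.frame(contig = seq_along(contigs),
                                                start = 20001L, end = 30000L),
                      mat_locus = list(contig = length(contigs), start = 60001L,
                                       end = 90000L, fraction_inverted = 1 / 3)) {
  sim_config(population_size = N, genome = contigs, mu = mu, rho = rho,
             generations = generations, sample_size = sample_size,
             clone_spec = clone_spec, gene_windows = gene_windows,
             mat_locus = mat_locus, seed = seed)
}

## genotype matrix from a bare call matrix, one locus per 100 bp on a contig
gm_from_calls <- function(calls, contig = "c1", spacing = 100L) {
  m <- ncol(calls)
  genotype_matrix(calls,
                  data.frame(contig = rep(contig, m), pos = spacing * seq_len(m),
                             ref = rep("A", m), alt = rep("T", m),
                             stringsAsFactors = FALSE),
                  sprintf("s%02d", seq_len(nrow(calls))))
}

## random biallelic genotype matrix; every locus carries both alleles
random_biallelic_gm <- function(n_samples, n_loci, miss_prob = 0) {
  calls <- matrix(0L, n_samples, n_loci)
  for (j in seq_len(n_loci)) {
    repeat {
      col <- stats::rbinom(n_samples, 1L, stats::runif(1, 0.2, 0.8))
      if (miss_prob > 0)
        col[stats::runif(n_samples) < miss_prob] <- NA_integer_
      obs <- col[!is.na(col)]
      if (length(unique(obs)) == 2L) break
    }
    calls[, j] <- col
  }
  gm_from_calls(calls)
}

## ---- oracles ---------------------------------------------------------------

## LD by explicit haplotype tabulation (complete 0/1 vectors)
oracle_ld <- function(a, b) {
  n <- length(a)
  n11 <- sum(a == 1 & b == 1)
  pA <- sum(a == 1) / n
  pB <- sum(b == 1) / n
  pAB <- n11 / n
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dp <- if (D == 0) 0 else abs(D) / dmax
  list(D = D, D_prime = dp, r2 = r2)
}

## single-linkage clusters by explicit union-find over all thresholded pairs
oracle_union_find <- function(d, threshold) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d[i, j] < threshold) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

## minimum-spanning-tree total weight by Prim's algorithm
oracle_prim_weight <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  total <- 0
  while (!all(in_tree)) {
    best <- Inf
    best_j <- NA_integer_
    for (i in which(in_tree)) {
      for (j in which(!in_tree)) {
        if (d[i, j] < best) {
          best <- d[i, j]
          best_j <- j
        }
      }
    }
    total <- total + best
    in_tree[best_j] <- TRUE
  }
  total
}

## all maximal exact matches >= k between two short strings, by direct
## character comparison along every diagonal, then two-way uniqueness by
## scanning every occurrence
oracle_anchors <- function(q, s, k) {
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  nq <- length(qc)
  ns <- length(sc)
  count_occ <- function(chars, pat) {
    m <- length(pat)
    n <- length(chars)
    if (m > n) return(0L)
    sum(vapply(seq_len(n - m + 1L), function(p)
      all(chars[p:(p + m - 1L)] == pat), logical(1)))
  }
  out <- list()
  for (dg in (1L - nq):(ns - 1L)) {
    i_range <- max(1L, 1L - dg):min(nq, ns - dg)
    eq <- qc[i_range] == sc[i_range + dg] & qc[i_range] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (u in which(r$values & r$lengths >= k)) {
      i0 <- i_range[starts[u]]
      len <- r$lengths[u]
      pat <- qc[i0:(i0 + len - 1L)]
      if (count_occ(qc, pat) == 1L && count_occ(sc, pat) == 1L) {
        out[[length(out) + 1L]] <-
          data.frame(q_start = i0, q_end = i0 + len - 1L, s_start = i0 + dg,
                     s_end = i0 + len - 1L + dg, length = len)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(q_start = integer(0), q_end = integer(0), s_start = integer(0),
               s_end = integer(0), length = integer(0))
  res[order(res$q_start, res$s_start), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

## mutate a DNA string at a given per-base substitution rate
mutate_dna <- function(x, rate) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

## alignment of `n` sequences in which sequence pairs differ at controlled
## columns: seq i differs from seq 1 at columns 1..d[i]
alignment_with_diffs <- function(len, d) {
  base <- strsplit(random_dna(len), "", fixed = TRUE)[[1L]]
  seqs <- vapply(seq_along(d), function(i) {
    chars <- base
    if (d[i] > 0) {
      idx <- seq_len(d[i])
      chars[idx] <- vapply(chars[idx], function(b)
        setdiff(c("A", "C", "G", "T"), b)[1L], character(1))
    }
    paste(chars, collapse = "")
  }, character(1))
  stats::setNames(c(paste(base, collapse = ""), seqs),
                  sprintf("t%02d", seq_len(length(d) + 1L)))
}
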