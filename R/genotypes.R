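#' Construct a haploid genotype matrix
#'
#' The central container for multi-strain haploid variant calls: an ordered
#' set of loci (contig, 1-based position, ref/alt alleles) and a strain-by-
#' locus matrix of haploid allele codes (0 = reference, k = k-th alternate,
#' `NA` = missing).
#'
#' @param calls Integer matrix, samples x loci; `NA` marks missing calls.
#' @param loci Data frame with columns `contig`, `pos`, `ref`, `alt` (multiple
#'   alternates comma-separated).
#' @param sample_ids Character vector of strain names, one per row of `calls`.
#' @return An object of class `genotype_matrix` with elements `sample_ids`,
#'   `loci` and `calls` (dimnames set from samples and contig:pos).
#' @export
genotype_matrix <- function(calls, loci, sample_ids) {
  calls <- as.matrix(calls)
  stopifnot(nrow(calls) == length(sample_ids), ncol(calls) == nrow(loci),
            all(c("contig", "pos", "ref", "alt") %in% names(loci)))
  ord <- order(loci$contig, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  key <- paste(loci$contig, loci$pos)
  if (anyDuplicated(key))
    stop("format error: duplicate locus ", key[duplicated(key)][1])
  n_alt <- ifelse(nchar(loci$alt) == 0, 0L,
                  lengths(strsplit(loci$alt, ",", fixed = TRUE)))
  mx <- suppressWarnings(apply(calls, 2L, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- 0L
  if (any(mx > n_alt))
    stop("format error: call indexes a non-existent allele")
  rownames(calls) <- sample_ids
  colnames(calls) <- if (nrow(loci)) paste0(loci$contig, ":", loci$pos) else
    character(0)
  rownames(loci) <- NULL
  structure(list(sample_ids = sample_ids, loci = loci, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Haploid genotype matrix: %d strains x %d loci (%d contigs, %d missing calls)\n",
              length(x$sample_ids), nrow(x$loci),
              length(unique(x$loci$contig)), sum(is.na(x$calls))))
  invisible(x)
}

#' Read haploid variant calls from a VCF file
#'
#' Parses a VCF 4.2 file of haploid genotypes into a [genotype_matrix()].
#' Every GT value must be haploid (`0`, `1`, ..., or `.` for missing); a
#' diploid genotype aborts with an error naming the record, as does a
#' duplicated (contig, position) pair.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @return A [genotype_matrix()] with loci sorted by (contig, pos).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(v@gt)
  sample_ids <- colnames(v@gt)[-1L]
  if (n_rec == 0L) {
    return(genotype_matrix(matrix(integer(0), nrow = length(sample_ids), ncol = 0),
                           data.frame(contig = character(0), pos = integer(0),
                                      ref = character(0), alt = character(0)),
                           sample_ids))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_rec)
  bad <- grepl("[/|]", gt)
  dim(bad) <- dim(gt)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("ploidy error: non-haploid genotype '%s' at %s:%s",
                 gt[w[1L], w[2L]], fix[w[1L], "CHROM"], fix[w[1L], "POS"]))
  }
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  if (anyDuplicated(key))
    stop("format error: duplicate record at ", key[duplicated(key)][1L])
  calls <- t(suppressWarnings(matrix(as.integer(gt), nrow = nrow(gt))))
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  genotype_matrix(calls,
                  data.frame(contig = fix[, "CHROM"],
                             pos = as.integer(fix[, "POS"]),
                             ref = fix[, "REF"], alt = alt,
                             stringsAsFactors = FALSE),
                  sample_ids)
}

#' SNP density as a percentage of genome size
#'
#' @param matrix A [genotype_matrix()].
#' @param genome_length Total genome size in bp.
#' @return `100 * n_loci / genome_length`.
#' @export
snp_density <- function(matrix, genome_length) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (!is.numeric(genome_length) || genome_length <= 0)
    stop("genome_length must be positive")
  100 * nrow(matrix$loci) / genome_length
}

#' Pairwise SNP differences between strains
#'
#' Counts, for every pair of strains, the loci at which both calls are
#' present and differ (missing calls excluded pairwise), together with the
#' number of loci compared.
#'
#' @param matrix A [genotype_matrix()].
#' @return An object of class `snp_distance`: list with `sample_ids`,
#'   `d` (symmetric integer matrix of mismatch counts) and `n_compared`.
#' @export
pairwise_differences <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  x <- matrix$calls
  n <- nrow(x)
  d <- matrix(0L, n, n, dimnames = list(matrix$sample_ids, matrix$sample_ids))
  nc <- d
  if (ncol(x) > 0L && n >= 2L) {
    obs <- !is.na(x)
    x0 <- x
    x0[!obs] <- -1L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        both <- obs[i, ] & obs[j, ]
        nc[i, j] <- nc[j, i] <- sum(both)
        d[i, j] <- d[j, i] <- sum(both & x0[i, ] != x0[j, ])
      }
    }
  } else if (n >= 2L) {
    nc[] <- 0L
  }
  structure(list(sample_ids = matrix$sample_ids, d = d, n_compared = nc),
            class = "snp_distance")
}

#' @export
print.snp_distance <- function(x, ...) {
  up <- x$d[upper.tri(x$d)]
  cat(sprintf("Pairwise SNP differences: %d strains; range %s-%s, mean %.1f\n",
              length(x$sample_ids),
              if (length(up)) min(up) else "-", if (length(up)) max(up) else "-",
              if (length(up)) mean(up) else NA))
  invisible(x)
}
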