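#' Reverse complement of a DNA string
#'
#' @param x Character scalar over A,C,G,T,N.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  paste(rev(dna_complement(chars)), collapse = "")
}

#' Find maximal unique exact-match anchors between two sequences
#'
#' Enumerates all maximal exact matches of length >= `k` between a query and
#' a subject sequence, in forward and reverse-complement orientation, keeping
#' only matches whose string occurs exactly once in each sequence (in the
#' match's orientation). `N` never matches. Anchors are the raw material for
#' dotplots and for colinear chaining; coordinates are 1-based inclusive,
#' with reverse-orientation anchors reported in query-forward coordinates.
#'
#' Matching is seeded on shared k-mers, merged along diagonals (a maximal
#' match of length M contributes exactly M - k + 1 consecutive seeds on one
#' diagonal), then filtered for two-way uniqueness.
#'
#' @param query,subject DNA strings (A,C,G,T,N).
#' @param k Minimum anchor length (>= 8).
#' @return Data frame with columns `q_start`, `q_end`, `s_start`, `s_end`,
#'   `length`, `orientation` (`"forward"`/`"reverse"`), sorted by `q_start`.
#' @export
find_anchors <- function(query, subject, k = 20) {
  if (nchar(query) == 0L || nchar(subject) == 0L)
    stop("empty sequence")
  if (k < 8L) stop("k must be >= 8")
  query <- toupper(query)
  subject <- toupper(subject)
  ns <- nchar(subject)
  fwd <- anchors_one_orientation(query, subject, k)
  rev_sub <- revcomp(subject)
  rv <- anchors_one_orientation(query, rev_sub, k)
  rows <- list()
  if (nrow(fwd)) {
    fwd$orientation <- "forward"
    rows[[1L]] <- fwd
  }
  if (nrow(rv)) {
    ## map reversed-subject coordinates back to subject-forward
    s_start <- ns - rv$s_end + 1L
    s_end <- ns - rv$s_start + 1L
    rv$s_start <- s_start
    rv$s_end <- s_end
    rv$orientation <- "reverse"
    rows[[length(rows) + 1L]] <- rv
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(q_start = integer(0), q_end = integer(0), s_start = integer(0),
               s_end = integer(0), length = integer(0),
               orientation = character(0))
  out <- out[order(out$q_start, out$s_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Maximal exact matches >= k between q and s (one orientation), unique in
## both. Returns q_start, q_end, s_start, s_end, length in the coordinates of
## the strings as given.
anchors_one_orientation <- function(q, s, k) {
  empty <- data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      length = integer(0))
  nq <- nchar(q)
  ns <- nchar(s)
  if (nq < k || ns < k) return(empty)
  qk <- substring(q, seq_len(nq - k + 1L), seq_len(nq - k + 1L) + k - 1L)
  sk <- substring(s, seq_len(ns - k + 1L), seq_len(ns - k + 1L) + k - 1L)
  q_ok <- !grepl("N", qk, fixed = TRUE)
  s_ok <- !grepl("N", sk, fixed = TRUE)
  smap <- split(which(s_ok), sk[s_ok])
  qpos <- which(q_ok & qk %in% names(smap))
  if (length(qpos) == 0L) return(empty)
  seeds_q <- rep(qpos, lengths(smap[qk[qpos]]))
  seeds_s <- unlist(smap[qk[qpos]], use.names = FALSE)
  diag_id <- seeds_s - seeds_q
  ord <- order(diag_id, seeds_q)
  seeds_q <- seeds_q[ord]
  diag_id <- diag_id[ord]
  ## runs of consecutive seeds on one diagonal = maximal matches
  new_run <- c(TRUE, diff(diag_id) != 0L | diff(seeds_q) != 1L)
  run_id <- cumsum(new_run)
  run_start <- seeds_q[new_run]
  run_len <- tabulate(run_id)
  match_len <- run_len + k - 1L
  run_diag <- diag_id[new_run]
  qs <- run_start
  qe <- run_start + match_len - 1L
  ss <- run_start + run_diag
  se <- qe + run_diag
  ## two-way uniqueness of the matched string: candidate occurrence starts
  ## come from the k-mer index (first k-mer of the match), then the full
  ## string is compared; overlapping occurrences are counted
  qmap <- split(which(q_ok), qk[q_ok])
  count_occurrences <- function(seqstr, starts, pat) {
    if (is.null(starts)) return(0L)
    sum(substring(seqstr, starts, starts + nchar(pat) - 1L) == pat)
  }
  keep <- vapply(seq_along(qs), function(i) {
    pat <- substr(q, qs[i], qe[i])
    first_kmer <- substr(pat, 1L, k)
    count_occurrences(q, qmap[[first_kmer]], pat) == 1L &&
      count_occurrences(s, smap[[first_kmer]], pat) == 1L
  }, logical(1))
  data.frame(q_start = qs[keep], q_end = qe[keep], s_start = ss[keep],
             s_end = se[keep], length = match_len[keep])
}

#' Chain anchors into colinear runs and report inversions and indels
#'
#' Sorts anchors by query position and greedily chains consecutive anchors of
#' the same orientation that are diagonally consistent (query and subject
#' gaps between neighbours both <= `max_gap`, subject advancing in the
#' orientation's direction). Query intervals covered by reverse-orientation
#' chains are reported as inversion intervals. Between adjacent chains, the
#' unmatched span on each sequence is measured; when the net difference
#' (query span minus subject span) is at least `min_indel`, an indel carried
#' by the longer side is reported with the net difference as its length.
#' Netting the two spans discounts the junction-adjacent erosion that
#' background substitutions inflict on both sequences, and leaves
#' length-preserving divergent regions (similar spans on both sides)
#' unreported.
#'
#' @param anchors Data frame from [find_anchors()] for one query/subject pair.
#' @param min_indel Minimum net unmatched span (bp) to call an indel.
#' @param max_gap Maximum within-chain gap (bp) on either sequence.
#' @return Object of class `synteny_report`: list with `chains` (data frame:
#'   `orientation`, `n_anchors`, `q_start`, `q_end`, `s_start`, `s_end`),
#'   `inversion_intervals` (data frame `q_start`, `q_end`),
#'   `indel_intervals` (data frame `carrier`, `start`, `end`, `length`), and
#'   `n_anchors`.
#' @export
chain_anchors <- function(anchors, min_indel = 50, max_gap = 500) {
  if (nrow(anchors) == 0L) {
    warning("no anchors: empty synteny report")
    return(structure(list(chains = data.frame(), inversion_intervals =
                            data.frame(q_start = integer(0), q_end = integer(0)),
                          indel_intervals = data.frame(carrier = character(0),
                                                       start = integer(0),
                                                       end = integer(0),
                                                       length = integer(0)),
                          n_anchors = 0L),
                     class = "synteny_report"))
  }
  a <- anchors[order(anchors$q_start, anchors$s_start), , drop = FALSE]
  chain_id <- integer(nrow(a))
  chain_id[1L] <- 1L
  for (i in seq_len(nrow(a))[-1L]) {
    prev <- i - 1L
    same <- a$orientation[i] == a$orientation[prev]
    qgap <- a$q_start[i] - a$q_end[prev] - 1L
    sgap <- if (a$orientation[i] == "forward")
      a$s_start[i] - a$s_end[prev] - 1L
    else
      a$s_start[prev] - a$s_end[i] - 1L
    ok <- same && qgap <= max_gap && qgap >= -k_overlap_tol(a, i, prev) &&
      sgap <= max_gap && sgap >= -k_overlap_tol(a, i, prev)
    chain_id[i] <- if (ok) chain_id[prev] else chain_id[prev] + 1L
  }
  chains <- do.call(rbind, lapply(split(seq_len(nrow(a)), chain_id), function(ix) {
    data.frame(orientation = a$orientation[ix[1L]], n_anchors = length(ix),
               q_start = min(a$q_start[ix]), q_end = max(a$q_end[ix]),
               s_start = min(a$s_start[ix]), s_end = max(a$s_end[ix]),
               stringsAsFactors = FALSE)
  }))
  rownames(chains) <- NULL

  inv <- chains[chains$orientation == "reverse", c("q_start", "q_end"),
                drop = FALSE]
  rownames(inv) <- NULL

  ## indels: unmatched spans between adjacent chains, >= min_indel on exactly
  ## one sequence
  indels <- list()
  if (nrow(chains) >= 2L) {
    for (i in seq_len(nrow(chains) - 1L)) {
      qgap <- chains$q_start[i + 1L] - chains$q_end[i] - 1L
      ## subject gap: space between the two chains' subject intervals
      s_left <- min(max(chains$s_start[i], chains$s_end[i]),
                    max(chains$s_start[i + 1L], chains$s_end[i + 1L]))
      s_right <- max(min(chains$s_start[i], chains$s_end[i]),
                     min(chains$s_start[i + 1L], chains$s_end[i + 1L]))
      sgap <- s_right - s_left - 1L
      net <- qgap - sgap
      if (net >= min_indel) {
        indels[[length(indels) + 1L]] <-
          data.frame(carrier = "query", start = chains$q_end[i] + 1L,
                     end = chains$q_start[i + 1L] - 1L, length = net,
                     stringsAsFactors = FALSE)
      } else if (-net >= min_indel) {
        indels[[length(indels) + 1L]] <-
          data.frame(carrier = "subject", start = s_left + 1L,
                     end = s_right - 1L, length = -net,
                     stringsAsFactors = FALSE)
      }
    }
  }
  indels <- if (length(indels)) do.call(rbind, indels) else
    data.frame(carrier = character(0), start = integer(0), end = integer(0),
               length = integer(0))
  structure(list(chains = chains, inversion_intervals = inv,
                 indel_intervals = indels, n_anchors = nrow(a)),
            class = "synteny_report")
}

## chained anchors may overlap by up to their own length along one sequence
## (seed trimming is not performed in this toy chainer)
k_overlap_tol <- function(a, i, prev) {
  min(a$length[i], a$length[prev])
}

#' @export
print.synteny_report <- function(x, ...) {
  cat(sprintf("Synteny report: %d anchors in %d chains; %d inversion interval(s), %d indel interval(s)\n",
              x$n_anchors, nrow(x$chains), nrow(x$inversion_intervals),
              nrow(x$indel_intervals)))
  invisible(x)
}

#' Divergence of an aligned sequence pair
#'
#' Proportion of differing columns among the columns at which neither
#' sequence carries a gap (`-`).
#'
#' @param a,b Equal-length aligned sequences (characters, gaps as `-`).
#' @return Fraction of differing comparable columns.
#' @export
aligned_divergence <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb)) stop("sequences must have equal aligned length")
  comparable <- ca != "-" & cb != "-"
  if (!any(comparable)) stop("zero comparable columns")
  sum(ca[comparable] != cb[comparable]) / sum(comparable)
}

#' Scan protein sequences for a C-terminal CAAX prenylation motif
#'
#' Tests whether each protein ends in a CAAX box: cysteine at position -4,
#' aliphatic residues at -3 and -2, any residue at -1. The motif marks
#' substrates of protein prenylation, the canonical C-terminal signature of
#' fungal mating pheromone precursors.
#'
#' @param proteins Named character vector of amino-acid sequences, or the
#'   path to a protein FASTA file.
#' @param aliphatic Residues accepted at the two A positions.
#' @return Data frame with `sequence_id`, `terminal_residues` (last four
#'   residues), `is_caax`, `rule_version`.
#' @export
caax_scan <- function(proteins, aliphatic = c("A", "V", "I", "L", "M", "F")) {
  if (length(proteins) == 1L && is.null(names(proteins)) &&
      file.exists(proteins)) {
    ss <- Biostrings::readAAStringSet(proteins)
    proteins <- stats::setNames(as.character(ss), names(ss))
  }
  proteins <- gsub("[[:space:]]", "", toupper(proteins))
  if (any(nchar(proteins) < 4L))
    stop("too-short error: protein shorter than 4 residues")
  term <- substring(proteins, nchar(proteins) - 3L, nchar(proteins))
  c4 <- substr(term, 1L, 1L)
  a3 <- substr(term, 2L, 2L)
  a2 <- substr(term, 3L, 3L)
  data.frame(sequence_id = if (is.null(names(proteins)))
    sprintf("protein_%02d", seq_along(proteins)) else names(proteins),
    terminal_residues = unname(term),
    is_caax = unname(c4 == "C" & a3 %in% aliphatic & a2 %in% aliphatic),
    rule_version = "caax/aliphatic-AVILMF/1",
    stringsAsFactors = FALSE)
}
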