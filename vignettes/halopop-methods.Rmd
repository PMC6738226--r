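---
title: "Detecting recombination in haploid microbial populations with halopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination in haploid microbial populations with halopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halopop)
```

## The question

Many microbial eukaryotes — extremophilic fungi prominently among them — have
never been observed to mate, and are routinely assumed to be strictly clonal.
Population genomics can test that assumption without ever catching the
organism in the act: in a recombining population, linkage disequilibrium (LD)
between polymorphic loci decays with physical distance, different genes in
the same set of genomes tell different phylogenetic stories, and a
mating-type locus may segregate in two configurations. In a clonal
population, LD is flat across the genome, every gene shares the single
genome-wide genealogy, and strains fall into discrete lineages separated by
many mutations.

`halopop` implements this argument end to end for haploid strain panels: LD
statistics with a half-maximum decay estimator, SNP-distance clonal lineage
detection with a minimum spanning network, PCA ordination, gene-tree
concordance by majority-rule consensus, core-genome counting, mating-locus
synteny comparison, and a CAAX prenylation motif scan for pheromone
precursors. Because suitable public strain panels require heavyweight
upstream processing (mapping, variant calling, annotation — all out of scope
here), the package carries its own forward-time Wright–Fisher simulator so
that every stage can be exercised and validated against planted truth.

## The statistics

### Linkage disequilibrium and its decay

For two biallelic loci with allele indicators $A$ and $B$ (haploid calls, so
haplotypes are observed directly), with $p_A$, $p_B$ the allele frequencies
and $p_{AB}$ the joint frequency among strains complete at both loci:

$$D = p_{AB} - p_A p_B, \qquad
  r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad
  D' = \frac{|D|}{D_\max},$$

where $D_\max = \min\{p_A(1-p_B),\,(1-p_A)p_B\}$ for $D>0$ and
$\min\{p_A p_B,\,(1-p_A)(1-p_B)\}$ otherwise; $D'=0$ when $D=0$. `pair_ld()`
computes these for one pair; `enumerate_pairs()` computes them for every
same-contig pair within a distance window (default 10,000 bp). Strains with
a missing call at either locus are excluded pairwise; pairs monomorphic
after exclusion are skipped, not zero-filled. Only same-contig pairs are
considered, because physical distance between contigs is undefined.

Two decay summaries are reported, both anchored at half the maximum:

* **Decay interval** (`decay_interval()`): pairs are binned by distance
  (default 100 bp), and with $M$ the maximum bin mean and $H = M/2$, the left
  border is the center of the first bin whose mean falls below $H$ and the
  right border the center of the last bin above $H$. Outside this interval
  all bin means are on one side of $H$.
* **Decay distance** (`fit_decay_curve()`): a smooth curve is fitted to the
  binned means and the decay distance is the smallest distance at which the
  fitted curve crosses $H$ from above (bracketing on a dense grid, then
  bisection). If the curve never crosses within the window the estimate is
  censored — the expected outcome for a clonal population.

### Numerical choices in the decay estimator

The smoother is a weighted LOESS (local quadratic) on binned means, with the
per-bin pair count as weight; any monotone-capable smoother could be plugged
in, since the half-maximum contract only needs a fitted curve. Three
parameters deserve justification:

* **Fitting bin width, 25 bp.** $H$ is derived from the same binning as the
  fit. With coarse bins the first bin center sits far from zero, its mean
  underestimates the zero-distance LD, and $H$ — and with it the crossing —
  is biased. 25 bp keeps the first center at 12.5 bp; the display binning for
  the decay *interval* stays at the conventional 100 bp.
* **Span, 0.2.** On noise-free exponential decay $r^2(x) = e^{-x/1000}$
  (true half-life $1000\ln 2 \approx 693$ bp) a span of 0.5 inflates the
  crossing by roughly 13%: local quadratic smoothing flattens a convex
  curve. A span of 0.2 keeps the bias around 1% while still averaging ~80 of
  the ~400 bins, which is ample smoothing for the pair densities the
  simulator produces.
* **Weights.** Weighting bins by pair counts makes the estimator exactly
  invariant under duplicating every pair — the fit depends on the empirical
  distribution, not the sample size.

With fewer than eight bins LOESS is replaced by linear interpolation of the
bin means; with fewer than `min_pairs` (default 20) pairs the estimator
refuses to run.

### Clonal lineages and the minimum spanning network

`pairwise_differences()` counts, per strain pair, loci where both calls are
present and differ (missing calls excluded pairwise — the "bitwise distance"
of haploid panels). `clonal_clusters()` groups strains by single linkage at
`d < threshold`; the default threshold of 200 SNPs reflects the empirical gap
in compact fungal genomes between within-clone differences (tens of SNPs)
and between-lineage differences (thousands). The threshold is exposed
because it is an observed property of a dataset, not a constant of nature.

`minimum_spanning_network()` first collapses clones into single nodes, then
runs Kruskal's algorithm on minimum inter-lineage distances. At each
selected weight, *every* tied edge joining the same pair of components
(evaluated before any merge at that weight) is retained, so the result is a
network rather than a tree; a flag marks a spanning tree inside it.

### Ordination

`snp_pca()` mean-imputes missing calls per locus, column-centers the 0/1
matrix without scaling (allele indicators share a scale), and
eigendecomposes the $n \times n$ sample covariance — loci vastly outnumber
strains, so the small-side decomposition is exact and cheap. Axis signs are
fixed by making the largest-magnitude loading positive, and axes with
numerically zero variance are zeroed, so outputs are reproducible to the
byte. Percent variance is each eigenvalue over the total.

### Gene-tree concordance

Per-gene alignments are accepted for tree building only when strictly longer
than 200 columns *and* with mean pairwise difference strictly above 15
(`filter_alignment()`; both inequalities strict — an alignment of exactly
200 columns or exactly 15.0 mean differences is rejected). Distances are
computed per pair over unambiguous-base columns under raw, JC69 or K2P
models; trees are neighbor-joining (`ape::nj`) with negative branch lengths
clamped to zero. The tree builder is deliberately pluggable: the scientific
statistic is downstream of any builder. `majority_consensus()` tallies
nontrivial unrooted bipartitions across trees and reports the splits present
in more than half of them — the concordance count. A clonal population
shares one genealogy, so most splits recur across genes; recombination
decorrelates gene histories and drives the count toward zero. Concordance is
counted on unrooted bipartitions (not rooted clades); consensus branch
lengths are not computed.

### Mating-locus synteny

`find_anchors()` enumerates maximal exact matches of length ≥ k (default 20,
a MUMmer-like scale) that are unique in both sequences, in forward and
reverse-complement orientation; `N` never matches. Matching is seeded on
shared k-mers and merged along diagonals, which yields exactly the maximal
matches; uniqueness is verified by counting overlapping occurrences.
`chain_anchors()` chains diagonally consistent same-orientation anchors
greedily (gaps ≤ `max_gap` = 500 bp on both sequences); an optimal
longest-increasing-subsequence chainer is unnecessary at mating-locus scale
(tens of kb). Reverse chains become inversion intervals in query-forward
coordinates.

Indels between adjacent chains are called on the **net** unmatched span:
query span minus subject span, reported when the absolute difference is at
least `min_indel` (default 50 bp), carried by the longer side. Netting
matters because background substitutions erode anchors on *both* sides of an
indel junction; the raw spans overstate the indel by the erosion on each
flank, while their difference recovers the inserted length almost exactly.
It also leaves length-preserving divergent regions (large but similar spans
on both sequences) unreported, which is the intended semantics.

`aligned_divergence()` is the per-column mismatch fraction of an externally
aligned pair, with gap columns removed from the denominator.
`caax_scan()` tests the last four residues of a protein for a CAAX box:
cysteine at −4, aliphatic residues at −3 and −2 (default set
{A, V, I, L, M, F} — the motif's residue rule is conventional, and both
canonical pheromone-precursor terminals, CIIV and CIIT, pass), any residue
at −1.

### Core genome

`core_genome_counts()` summarizes a gene-cluster × genome presence table:
core clusters occur in every genome, soft-core clusters in at least
`soft_min` genomes (default: all but two, the usual near-universal
convention). The package does not produce such tables from annotation —
orthology clustering is out of scope — so the pipeline's demonstration input
comes from `simulate_presence_table()`, a randomized synthetic generator of
a realistic pangenome shape (a universal majority, a near-core minority
missing from one or two genomes, a patchy tail).

## The simulator

`simulate_population()` is a forward-time haploid Wright–Fisher model:

* Each generation, every one of $N$ individuals draws one parent, or two
  parents when at least one crossover occurs; crossovers per birth are
  Poisson($\rho L$), placed uniformly, and contigs segregate as independent
  linkage groups (each contig starts from a random parent).
* Mutations per birth are Poisson($\mu L$), placed uniformly, **finite-sites
  biallelic**: a second hit at a site toggles back, so every segregating site
  has exactly two alleles — matching the LD module's input contract. Sites
  fixed in the whole population are pruned periodically (a relabelling of
  the reference state that leaves segregating sites untouched).
* The run starts from a monomorphic founder population; the `generations`
  parameter is the burn-in. Genotypes are stored as sorted integer sets of
  derived positions, so memory scales with polymorphism, not genome length.
* After the final generation, clonal lineages are planted: each lineage
  copies a distinct individual `n_copies` times, every copy receiving
  Poisson(λ) private mutations, so two clone-mates differ by ~2λ SNPs.
  Remaining strains are sampled from distinct individuals.
* The mating-locus orientation flips whole lineages, filled greedily in
  random lineage order toward the configured fraction (achieved exactly
  whenever lineage sizes permit). Inverted strains carry the central 70% of
  the locus reverse-complemented. Gene windows are emitted as equal-length
  alignments (substitutions only, so alignment equals extraction — there is
  no indel mutation to align around).
* A single seeded RNG stream drives every draw in a documented order, so an
  identical configuration is bit-identical in output; when $\rho = 0$ the
  pedigree is recorded and the sample's true genealogy is returned for
  concordance checks.

### Default conditions

The defaults emulate a resequencing survey of a compact-genome halophilic
basidiomycete: 21 sampled strains on a 20-contig, 9.55 Mbp genome; four
planted clonal clusters of 3, 4, 6 and 2 strains (λ = 30, so clone-mates
differ by ~60 SNPs, comfortably under the 200-SNP threshold) plus six
singletons; 24 gene windows of 20 kb; a 30 kb mating locus inverted in 4 of
21 strains. No estimates of per-base mutation or recombination rates exist
for such organisms, so μ = 8.9 × 10⁻⁶ and ρ = 8 × 10⁻⁶ per base per
generation with N = 50 and 250 generations were chosen once, for
demonstration, to land the observable summaries in realistic ranges — SNP
density a few tenths of a percent, thousands of SNPs between lineages — at
desk-scale runtime (tens of seconds), and are biological claims about
nothing. Sample sizes this small and genomes this compact make the absolute
rates unidentifiable anyway; what the package demonstrates is the *contrast*
between recombining and clonal regimes under identical conditions.

### What the simulator does not emulate

No selection, no demographic change, no gene conversion, no indel mutation,
no read-level error, no missing calls (real panels have them; the analysis
functions handle missingness, the generator does not produce it), no
annotation model (hence the synthetic presence table), uniform mutation and
recombination rates along the genome, and mating-locus inversion inherited
clonally rather than through actual mating. Passing tests on simulated data
therefore validate the statistical machinery and its contracts — not the
claim that any particular real dataset would yield any particular number.

## Validation design

The test suite validates each operation against an independent oracle or
planted truth: LD against explicit haplotype tabulation (to 10⁻¹²), PCA
against dense `prcomp` (to 10⁻⁸, with per-axis score comparison guarded
against eigenvalue ties, where axes are arbitrary), clusters against a
brute-force union-find, the MSN spanning-tree weight against an independent
Prim implementation, distance models against `ape::dist.dna`, split
frequencies against a `phangorn`-based tally, anchors against a naive
all-diagonal enumerator, and inversion/indel calls against planted fixtures
(boundaries within k bp in ≥ 19/20 seeded replicates at 2% background
divergence).

The system-level claim — recombination shortens LD decay and erodes
gene-tree concordance — is tested on paired simulations: ten clonal
(ρ = 0) vs recombining (ρ = 2 × 10⁻⁵) runs at N = 100, 1 Mbp, 500
generations, 20 strains, ten 25 kb gene windows, identical otherwise. The
recombining run must show a finite, smaller decay distance and fewer
majority splits in at least 8 of 10 pairs; in practice clonal runs are
censored with ~10–12 majority splits while recombining runs decay within
~1 kb with 0–2 splits. These problem sizes keep the full suite within a
coffee break while leaving wide stochastic margins.

## Limitations

* The decay distance depends on the binning and smoother; the package fixes
  reproducible defaults rather than claiming a canonical estimator, and the
  half-maximum anchor inherits noise in the maximum bin mean.
* Greedy chaining can split a chain in anchor deserts (dense substitution
  clusters) and the indel interval then fragments; at the intended locus
  scale and ≤ 2% divergence this is rare.
* NJ on raw/JC69/K2P distances is a deliberate stand-in for likelihood-based
  tree inference; concordance counts are robust to the builder, branch
  lengths are not meaningful beyond ordering.
* Clonal-cluster detection by a hard SNP threshold assumes the within-clone
  and between-lineage difference distributions do not overlap; panels with
  intermediate relatedness need the threshold re-examined.
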