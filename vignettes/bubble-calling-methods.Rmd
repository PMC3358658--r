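---
title: "Calling transcriptome polymorphisms as bubbles in a bidirected De Bruijn graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transcriptome polymorphisms as bubbles in a bidirected De Bruijn graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kisbubble)
```

## The model

kisbubble detects polymorphisms in RNA-seq data with no reference genome and
without assembling full-length transcripts. The premise: every local
difference between two co-expressed RNA molecules — a skipped exon, an
alternative donor or acceptor site, a retained intron, a SNP, a short indel,
an inexact tandem duplication — leaves a recognisable *bubble* in the De
Bruijn graph of the reads.

The graph is bidirected, because DNA is double stranded. A node stores a
forward sequence `F(N)` and its reverse complement `R(N)`; an arc from `N1`
to `N2` labelled `XY` (X, Y ∈ {F, R}) records that the (k−1)-suffix of side
X of `N1` equals the (k−1)-prefix of side Y of `N2`. Arcs come in mirror
pairs (`XY` on one, `Y'X'` on the other, where `'` flips F and R). A path is
*valid* when at every internal node the entering arc's second letter matches
the leaving arc's first letter, and a node where this fails is *switching*.
One degenerate case is worth naming: a k-mer whose (k−1)-overlap is its own
reverse complement carries a self-arc that is its own mirror, so the "arc
count is even" invariant holds for all *paired* arcs only.

A **bubble** is a simple cycle of at least three distinct nodes with exactly
two switching nodes. The two switching nodes split the cycle into two valid
paths — the two variants of the polymorphic locus. Any pair of sequences
`a s b` / `a s' b` with `|a|, |b| ≥ k` and `s`, `s'` sharing no k-mer
creates one. The path-length signature classifies the event:

* a substitution gives two internal paths of exactly `2k − 1` nt;
* a splicing variant (with `s` empty) gives a shorter path of at most
  `2k − 2` nt — the spelled junction — against a longer path carrying the
  variable region;
* an inexact tandem duplication looks like a splicing variant, except that
  the whole shorter path re-aligns against one end of the longer path;
* genomic indels are mostly shorter than 3 nt whereas almost all splicing
  variants are longer, so length differences strictly below 3 are called
  indels.

## The pipeline

`run_pipeline()` executes six steps.

1. **Counting and graph construction.** Reads are decomposed into canonical
   k-mers (lexicographic minimum of k-mer and reverse complement; `k` is
   restricted to odd values so no k-mer equals its own reverse complement).
   k-mers whose pooled count falls below the minimum k-mer coverage `mkC`
   are discarded — the cheapest and most effective error filter. Maximal
   simple paths are compressed into single nodes of length `k + (i − 1)`,
   whose per-experiment count is the mean of the constituent k-mer counts
   (rounded to two decimals; the aggregation rule is our choice, the graph
   definition does not impose one).

2. **Biconnected components.** Bubbles are cycles, every cycle lies in
   exactly one biconnected component of the underlying undirected
   multigraph, and bridge edges form singleton components that can be
   discarded outright. Decomposition (Tarjan's lowpoint depth-first search,
   via igraph) therefore shrinks the search space dramatically without
   changing the result. Mirror arc pairs project to one undirected edge;
   parallel edges with different label classes stay distinct; self-loops
   are dropped since a bubble needs three distinct nodes.

3. **Substitution compression.** Single substitutions — SNPs and sequencing
   errors — generate four-node bubbles whose two single-node internal paths
   have equal length and Hamming distance one. Each is reported as a SNP
   candidate and merged into one consensus node with `N` at the variant
   position. We extend the same merge to *any* equal-length parallel
   configuration between the same anchors (a non-branching variant node
   absorbed into an equal-length valid backbone path, with `N` written at
   every disagreement and `N`s propagated when an already-merged node is
   absorbed again). The extension is lossless for event calling: two paths
   of equal length spell at least `2k − 1` nt each, so no reportable bubble
   — whose shorter path must stay within `2k − 2` — is ever removed. What it
   buys is robustness: reads carrying two or more nearby errors leave
   equal-length Hamming-2+ variants that the classic four-node rule cannot
   touch, and whose route combinations otherwise multiply the cycle count
   exponentially. Simple-path recompression is interleaved until fixpoint.

4. **Bubble enumeration.** The search exploits an exact reformulation: a
   bubble is precisely a pair of internally node-disjoint valid paths that
   leave one node on the same strand side and enter another node on the same
   side (the endpoints are then automatically the two switching nodes).
   All "short" paths — spelled length within the `2k − 2` bound — are
   enumerated exhaustively, which is cheap; disjoint short pairs are emitted
   directly, and longer partners are searched per oriented endpoint group by
   depth-first search. Three scheduling devices keep worst-case components
   (approximate tandem repeats, residual error webs) from starving the rest:
   neighbours are visited in decreasing coverage order, the partner length
   ceiling grows geometrically up to the component's total length (at which
   point the search is exhaustive), and every search start — and every root
   arc within a start — receives a guaranteed slice of the per-component
   step budget. A component that exhausts its budget keeps the bubbles found
   so far and is flagged *aborted*. The unoptimised baseline — plain
   backtracking over all simple cycles with post-filtering — is retained
   behind `prune = FALSE` and the two routes are property-tested for
   equality on random graphs.

5. **Classification.** The cascade is: exact substitution signature
   (`2k − 1`/`2k − 1`, Hamming distance one) → SNP; whole shorter path
   matching one end-window of the longer path at ≥ 80% identity → REPEAT;
   length difference strictly below 3 → INDEL; otherwise AS. The end-window
   comparison is ungapped positionwise identity; a position where either
   sequence carries an `N` consensus base contributes the 0.25 random
   background rather than a free match, so error-consensus paths cannot
   drift over the repeat threshold.
   A gapped comparison would be wrong here: any insertion of `m` nt can be
   aligned back with about `2m` edits, which makes *every* small splicing
   variant look like a repeat, while the ungapped window keeps a genuine
   duplication in register at one end (identity near 1) and throws a shifted
   junction out of register (identity near the 0.25 background). The 80%
   threshold and the indel bound are exposed as configuration because both
   are pragmatic defaults, not laws.

6. **Read coherence and coverage.** Each experiment's reads are mapped back
   onto each path (the spelled internal sequence flanked by up to `k − 1` nt
   of each switching node). Mapping is ungapped and exact-seed anchored:
   a read is placed wherever it shares a k-mer with the path — path k-mers
   containing up to two `N`s are expanded so consensus positions do not
   create unmappable seed deserts — and the best placement with at most
   `max_mismatches` substitutions over the overlap counts once. Reads
   overlapping a path extremity by fewer than k bases can share no k-mer and
   are discarded, which biases the `k − 1` border positions down by a factor
   `(L − i)/L` (`L` the read length, `i` the distance to the first unbiased
   position); the profile is corrected by multiplying those positions by
   `L/(L − i)`. A bubble with any position covered by no read, pooled over
   experiments, is *not read-coherent* and is discarded (and logged). Mean
   corrected coverage over the internal positions is reported per path and
   per experiment.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 25 (odd) | k-mer size; the window every variant must be anchored in |
| `min_kmer_coverage` | 1 | mkC; pooled count below which a k-mer is dropped |
| `max_shorter_path` | `2k − 2` | bound on the shorter internal path (nt) |
| `indel_max_diff` | 3 | length differences strictly below are indels |
| `repeat_identity_min` | 0.8 | end-window identity for a repeat call |
| `max_cycles_per_bcc` | 5e5 | per-component search-step budget before aborting |
| `max_mismatches` | 2 | substitutions tolerated per mapped read |

The step budget counts individual arc extensions, roughly an order of
magnitude more numerous than "paths explored"; aborting is a property of
repeat-dense or error-dense components, not an error.

## The synthetic-data generator

`sim_scenario()` / `make_transcript_pair()` plant one polymorphism between
two transcripts: random flanks of 350 nt per side by default (so transcripts
comfortably exceed the read length), a 200-nt skipped exon for the
exon-skipping scenario, single-base substitution pairs, short indels, or an
inexact tandem duplication whose inserted copy is mutated every
`(k − 1)/2` positions so the copies share no (k−1)-mer. Pairs are
rejection-sampled until no canonical (k−1)-mer repeats within either
transcript and the junction nucleotides are distinct, which pins the bubble
geometry exactly (`len_short = 2k − 2`, `len_long = 2k − 2 + |s|`).

`simulate_reads()` draws `ceiling(coverage × length / L)` single-end reads
per transcript with uniform starts, uniform strand, and independent
per-base substitution errors. Uniform starts give the Poisson-like
heterogeneous depth that limits sensitivity at low coverage. The model omits
what real sequencers add: indel errors, quality-correlated error positions
(real Illumina errors concentrate near read 3' ends, where they truncate
into harmless graph tips rather than full-length variant paths — i.i.d.
errors are therefore the *harder* case for the graph), and fragment-level
biases. Passing tests on these simulations demonstrates the machinery, not
performance on any particular instrument.

`sensitivity_sweep()` runs the full pipeline over a coverage grid with
replicates and reports, per cell, whether an AS call reproduces the planted
paths exactly (up to strand, with `N` consensus positions matching
anything) and how many other AS calls appeared. Coverage labels follow the
protocol's printed unit of 15 reads per kilobase per fold (8× = 120 RPK at
75-bp reads), which is ~12% denser than the plain `coverage × length / L`
read count; `rpk_per_fold = NULL` restores the plain unit. The sweep sizes
used in the tests (coverages 4–20×, three replicates, k = 21, 200-nt exon,
350-nt flanks) keep a full two-condition sweep within a few minutes on one
core.

With three replicates per coverage the detection *fraction* is a noisy
estimate; it is monotone in expectation, but single seeds can dip at one
coverage because a replicate happens to leave a k-mer of the variable
region uncovered. The recovery floors (lowest coverage with all replicates
recovered) are the quantities the protocol compares.

## Numerical and design choices

* Canonical node identity (lexicographic min of sequence and reverse
  complement) makes graph construction deterministic; arcs, neighbours and
  search starts are always iterated in a fixed order, so all outputs are
  reproducible bit for bit under a fixed seed.
* Bubble identity is the pair of switching nodes plus the canonicalised
  internal node paths with their spelled sequences; each bubble is reported
  once regardless of traversal direction. Ties between equal-length paths
  are broken lexicographically.
* A bubble whose shorter side has no internal node (paths joining early) has
  internal length 0 and is supported; two-node cycles through parallel arcs
  are excluded, as a bubble requires three distinct nodes.
* Four-node compression consensus counts are summed (the two alleles tile
  one locus), unlike simple-path compression where counts are averaged along
  a single haplotype.
* Read-coherence is decided on raw (uncorrected) counts pooled across
  experiments; per-experiment coherence is reported but does not discard.
* Reads shorter than k are skipped with a warning; `k` larger than every
  read yields an empty table and empty (successful) results.

## Limitations

* Components that exhaust the search budget are flagged and their remaining
  bubbles are unreported; this is by design the fate of approximate-repeat
  tangles, and at `mkC = 1` with dense substitution errors also of residual
  error webs. Raising `mkC` to 2 removes nearly all of the latter.
* The classifier does not separate genomic indels of 3 nt or more from true
  splicing variants, does not check splice-site motifs, and reports repeat
  and SNP collections without further error filtering.
* Quantification reports per-path mean coverage only; no statistical test
  of differential usage between conditions is attempted.
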