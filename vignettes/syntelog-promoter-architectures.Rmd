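---
title: "Methods: syntelog detection and promoter TFBS architecture comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: syntelog detection and promoter TFBS architecture comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntarch)
```

# Scope and model

`syntarch` implements a comparative-genomics workflow for putative
stress-responsive gene families in plants: detect homologous gene pairs
across (and within) genomes, chain them into collinear blocks, classify
each gene's duplication origin, group differentially-expressed-gene (DEG)
anchored syntelogs across species, extract 1000 bp promoters, scan them
with transcription-factor binding site (TFBS) models under a Z-score
filter, summarise the token "architecture" of every promoter, compare
architectures with an alignment-free triplet-event distance, and cluster
the resulting distance matrix with neighbor joining.

Because real multi-genome inputs are large external downloads, the package
carries a synthetic genome generator that plants every structure the
pipeline is supposed to find — collinear blocks (including inverted ones),
tandem/proximal/dispersed duplicates, whole-chromosome duplications, and
promoter motif instances at recorded offsets — and emits machine-readable
truth tables. All validation is against these planted truths, against
printed summary tables treated as inputs, and against independent
brute-force oracles.

# Homology

`align_all_vs_all()` performs Smith–Waterman local alignment (BLOSUM62,
affine gaps 11/1, via `Biostrings::pairwiseAlignment`) over every protein
pair surviving an exact 5-mer seed prefilter. The prefilter mirrors the
seeding heuristic of practical search tools: two random 150-residue
proteins share a 5-mer with probability well below 1%, so the quadratic
pair set collapses to near-linear work, and any pair with genuine local
similarity shares many seeds. Setting `seed_length = 0` disables it.

Scores are converted to approximate E-values with the Karlin–Altschul
form \(E = K m n e^{-\lambda S}\), with the standard gapped BLOSUM62
constants \(\lambda = 0.267\), \(K = 0.041\), \(m\) the shorter sequence
length and \(n\) the total residue count of the set (overridable).
Exact parity with any particular search engine is not a goal: only the
threshold decision at \(E \le 10^{-5}\) feeds downstream, and both the
internal aligner and `parse_alignment_table()` (12-column tabular input)
produce the same pair type. Pairs are stored once, lexicographically
ordered, keeping the smallest E-value of reciprocal hits.

# Collinear blocks and duplication classes

`detect_collinear_blocks()` places every homolog pair as a dot at
(rank~a~, rank~b~) for each chromosome pair — rank being the 0-based
position of the gene along its chromosome ordered by start coordinate —
and chains dots by dynamic programming into maximal-scoring runs that are
strictly monotone on both axes (descending on the second axis for
inverted blocks) with at most `max_gap` intervening ranks per step.
Chain score is `anchors − 0.1 × total intervening-rank gap`; chains are
extracted best-first with their dots removed until none reaches
`min_anchors`. Defaults `min_anchors = 5` and `max_gap = 25` follow the
conventional MCScanX-style parameterisation (`MATCH_SIZE`, `MAX_GAPS`);
the linear gap penalty is a deliberate simplification of that tool's
E-value scoring, defensible here because downstream consumers use only
block membership and orientation, both pinned by an exhaustive
chain-enumeration oracle in the tests.

`classify_duplicates()` assigns exactly one class per gene by precedence:

1. no within-species homolog → `singleton`;
2. anchor of any collinear block (with a within-species homolog) →
   `wgd_segmental`;
3. within-species homolog at the adjacent rank on the same chromosome →
   `tandem`;
4. within `proximal_window` (default 10) intervening genes → `proximal`;
5. otherwise → `dispersed`.

The precedence chain is stated explicitly (rather than inherited from any
binary tool) so it can be tested against planted truth; on generated
genomes with 5% protein divergence it recovers every planted label.
`summarize_duplications()` truncates percentages to one decimal rather
than rounding, matching the convention of published duplication tables
(64/196 prints as 32.6, where round-half-up would give 32.7).

`group_syntelogs()` forms a graph over the anchor pairs of all blocks and
keeps connected components containing at least one DEG anchor. A gene
that anchors blocks against several species links its partners into one
group transitively; components without a DEG are discarded. Group ids
are assigned in descending component size, ties broken by the smallest
member gene id, making output order reproducible.

# Promoters and TFBS scanning

Promoters are the 1000 bp (configurable) upstream of the annotated gene
start — `[start − L, start − 1]` for plus-strand genes, the reverse
complement of `[end + 1, end + L]` for minus-strand genes — truncated at
chromosome boundaries and always reading 5'→3' toward the gene. No
TSS/UTR refinement and no masking of overlapping neighbour genes is
applied; the procedure anchors on gene coordinates only, which is the
choice a coordinate-level annotation supports.

Scanning is position-weight-matrix log-odds: each window of length L
scores \(\sum_j \log(p_j(b_j)/q(b_j))\), with a 0.01 pseudocount added to
every matrix cell (renormalised) so zero cells never produce \(-\infty\)
on informative columns. Windows containing an ambiguous base are
excluded entirely. Both strands are scanned by default; strand is
recorded but ignored in token order, since printed architectures carry no
strand annotation.

The retention rule is the Z-score filter: a window is kept when its score
lies at least 1.5 standard deviations above the mean of *all* window
scores of the same model over the entire scanned promoter set. The
reference population (per model, over the scanned set) is one of several
defensible readings of a population Z-score; it is the package's choice,
recorded in output metadata, and the hit-table ingestion path accepts
externally computed (hit, Z) tables in the same TSV schema so trained
binding-site models can replace the bundle without code changes. Note
that a relative filter of this kind retains the upper tail of the
background score distribution by construction, so absolute hit counts
depend strongly on the sharpness of the matrices; planted consensus
instances always dominate that tail (they are the maximum-scoring
windows), which is what the recovery tests assert.

The bundled 19 matrices (10 TF families, the subfamily taxonomy of the
standard abiotic-stress cis-element sets: five MYB boxes, G/N-box bHLH,
DRE/CRT and GCC-box for AP2/EREBP, W-box, four bZIP ABRE/G-box variants,
AuxRE, NAC box, HSE, HBE, and the ABI3/VP1 ABRE) are consensus-derived
(0.91 on the consensus base per column). They stand in for trained
models, which are not redistributable; their role in this package is to
make the decision rule and its filtering behaviour testable, not to
reproduce any trained model's hit calls.

`build_architecture()` orders retained hits 5'→3' and resolves
overlapping windows by keeping the higher Z (ties: leftmost offset, then
subfamily name); a keep-all mode exists because it is unknown whether
reference scanners report overlaps separately. Tokens are family display
names (`AP2` for AP2/EREBP), matching printed architecture strings such
as `WRKY~MYB~MYB~MYB~MYB~AP2`, which `parse_architecture()` reads back
whitespace- and parenthesis-tolerantly.

# The triplet-event architecture distance

`make_triplets()` pads the token string with sentinels `^` and `$` and
emits all overlapping windows of three consecutive padded tokens, so an
architecture of n ≥ 1 tokens yields exactly n triplets; the sentinels
make one- and two-token architectures comparable at all. The
overlapping-window reading (rather than all unordered token triples) is
chosen because it preserves order sensitivity, which is the point of an
*architecture* comparison.

`adass_distance()` matches the two triplet multisets in three passes:
exact matches (cost 0), inversions — a residual triplet whose reversed
token order occurs in the other residual set (cost `w_inversion = 0.5`
per pair) — and duplications — a residual triplet identical to an
already-matched triplet of its own set (cost `w_duplication = 0.25` per
copy). Each side's leftover residuals cost 1 each (shuffled/unique
events). The per-side residual costs are then combined as their maximum,
and the total event cost is divided by the larger triplet count:

\[
d(A,B) = \frac{w_{inv} n_{inv} + \max(w_{dup}\,dup_A + rem_A,\;
w_{dup}\,dup_B + rem_B)}{\max(|A|, |B|)}
\]

The max-combination (rather than summing both sides' residuals) is what
makes the stated endpoints hold exactly: identical architectures score
0, equal-length architectures over disjoint token alphabets score 1, the
value never leaves [0, 1], the measure is symmetric, and at
`w_inversion = w_duplication = 1` it reduces identically to
\(1 - |A \cap B| / \max(|A|,|B|)\). A summed combination violates all of
these (two disjoint length-n architectures would score 2). The greedy
pass order is provably optimal for this cost structure — matching
exactly always saves at least as much as any alternative role for the
two copies — and the test suite pins the implementation against an
exhaustive enumeration of all pass-respecting matchings on 200 random
cases. The triangle inequality is *not* claimed. Event weights sit in
`distance_config()` so alternative calibrations are one-line changes;
the similarity threshold defaults to 0.4, the conventional cut for
calling two promoter architectures similar in this analysis.

# Neighbor joining

`neighbor_joining()` is a from-scratch classical NJ (Saitou–Nei
Q-criterion, standard branch-length formulas) rather than a wrapper, so
two behaviours can be fixed and tested: ties in the Q minimisation
resolve to the smallest (row, column) pair, and a negative branch-length
estimate is clamped to zero with the deficit transferred to its sibling,
preserving the joined pair's path length. On additive matrices the
generating topology and branch lengths are recovered exactly (verified
to machine precision); on random matrices the topology agrees with an
independent NJ implementation (`ape::nj`), which serves as the
cross-check, never the implementation.

# The synthetic generator: what it does and does not emulate

Genes sit on a regular grid (300 bp genes, 1700 bp intergenic, first
gene at 1501, a full promoter window after the last gene) so every gene
owns an unobstructed 1000 bp promoter. Proteins are i.i.d. random
150-mers; planted homologs are substituted copies at a configurable
per-residue rate (default 0.05, the regime where label recovery is
expected to be exact). Homology is planted at the protein level so the
internal aligner and external tabular input find the same pairs.
Inverted blocks reverse both rank order and strand. Whole-genome
duplication is planted as a duplicated chromosome, which the chaining
stage rediscovers as a within-species collinear block. Promoter
background is i.i.d. uniform over ACGT and planted motifs are exact
consensus strings at recorded non-overlapping offsets, written
strand-aware into the genome.

Real genomes are none of these things: gene density varies, promoters
overlap neighbours, proteins evolve with indels and domain shuffling,
motif instances are degenerate, and background composition is skewed.
Passing tests on this generator therefore demonstrates that the
*algorithms* recover what was planted under their stated assumptions —
not that any biological conclusion transfers to real data. Conversely,
every pipeline stage accepts standard external formats (FASTA, GFF3,
BLAST outfmt 6, hit TSVs), so real inputs drop in where available.

Problem sizes used by the test suite and the acceptance script — three
species × two chromosomes × 40 genes for synteny/duplication recovery,
50 promoters × 5 planted motifs for scan recovery, ≤ 12 dots for the
chain-enumeration oracle, ≤ 6 tokens for the matching oracle — are the
package's chosen validation scales: small enough for exhaustive oracles
to be exact, large enough that every planted class and both block
orientations occur.

# Numerical and degenerate-input choices

* Percentages: truncated, one decimal (see above).
* Rank ties (identical start coordinates) break by gene id, making rank
  assignment — and hence chaining — deterministic.
* A promoter shorter than a motif is skipped for that model with a
  warning; a zero-variance score population (e.g. a single homopolymer
  promoter) emits no hits for that model, with a warning, rather than
  dividing by zero.
* Empty architectures produce empty triplet sets; two empty sets are at
  distance 0 by convention, an empty vs non-empty pair at 1.
* A gene flush against its chromosome boundary has an empty promoter
  (warning, not an error).
* Pipeline stages are resumable by content hash of their inputs;
  reruns with unchanged inputs skip all stages, and outputs are
  byte-identical across runs for a fixed fixture and config.

# Known limitations

* E-values are scale approximations, not search-engine replicas; only
  the threshold decision is meaningful.
* The bundled matrices are consensus stand-ins; absolute hit counts and
  Table-style family tallies on synthetic data are not comparable to
  counts produced by trained models on real promoters.
* The block scorer's linear gap penalty can split very gappy blocks that
  an E-value-based scorer would keep whole.
* `wgd_segmental` requires block-anchor evidence; a WGD remnant whose
  block decayed below `min_anchors` is classified by the remaining rules.
* The distance is not a metric (no triangle inequality), which NJ
  tolerates but ultrametric-style interpretations should not assume.
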