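# syntarch

Comparative genomics of stress-responsive gene families in plants:
**syn**telog detection and promoter TFBS **arch**itecture comparison.

Starting from per-species genomes (FASTA + GFF3 + protein FASTA) and a
list of differentially expressed anchor genes, `syntarch`:

1. finds homologous gene pairs — either by parsing all-vs-all BLAST
   tabular output or with an internal Smith–Waterman path filtered at
   *E* ≤ 10⁻⁵ (Karlin–Altschul approximation, BLOSUM62, gaps 11/1);
2. chains pairs into **collinear blocks**: maximal runs of dots at
   (rank₁, rank₂) that are strictly monotone on both chromosomes
   (ascending, or descending for inverted blocks), ≥ 5 anchors, gaps
   ≤ 25 ranks, score = anchors − 0.1·gap;
3. classifies every gene's duplication origin by precedence —
   singleton → WGD/segmental (block anchor) → tandem (adjacent rank) →
   proximal (≤ 10 intervening genes) → dispersed — and tabulates counts
   with truncated one-decimal percentages;
4. groups DEG-anchored **syntelogs** as connected components of the
   anchor-pair graph;
5. extracts 1000 bp strand-aware promoters and scans them with 19
   cis-element weight matrices (10 TF families: MYB, bHLH, AP2/EREBP,
   WRKY, bZIP, ARF, NAC, HSF, HB, ABI3/VP1), keeping windows whose
   log-odds score satisfies *Z* = (s − μ)/σ ≥ 1.5 against the scanned
   set;
6. writes each promoter's **TFBS architecture** (ordered family tokens,
   `WRKY~MYB~MYB~AP2`), compares architectures with a triplet-event
   distance

   d(A,B) = [ w_inv·n_inv + max(w_dup·dupA + remA, w_dup·dupB + remB) ] / max(|A|,|B|)

   over sentinel-padded token triplets (exact match 0, inversion 0.5,
   duplication 0.25, shuffled/unique 1; d ∈ [0,1], 0 = identical,
   1 = completely different), reports per-species percentages of pairs
   within the 0.4 similarity threshold, and clusters the distance matrix
   with a deterministic neighbor-joining implementation (Newick output).

A synthetic-genome generator (`sim_config()` / `generate_genomes()`)
plants collinear blocks, duplication events and promoter motifs with
machine-readable truth tables, so the whole pipeline is testable without
any downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
simulated three-species genome set:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_homology.R
Rscript analysis/03_synteny_duplication.R
Rscript analysis/04_promoter_scan.R
Rscript analysis/05_architecture_distance.R
Rscript analysis/06_worked_examples.R
```

which prints, among other things:

```
Simulated 3 species; 280 genes in total.
Planted: 14 collinear anchor pairs, 89 duplicated genes, 12 motif instances.
60 homolog pairs at E <= 1e-5 from 280 proteins; 100 % of planted homolog pairs recovered.
3 collinear blocks ( 1 inverted ).
Duplication classifier agreement with planted truth: 100 %
2 DEG-anchored syntelog groups covering 4 genes.
```

The three blocks are the two planted cross-species blocks plus the
planted whole-chromosome duplication rediscovered as a within-species
block; classifier agreement of 100% means every planted
tandem/proximal/dispersed/WGD label was reproduced from sequence alone.
`06_worked_examples.R` recomputes published summary numbers from their
printed inputs:

```
            wgd_pct_of_231  27.7
       dispersed_pct_of_37  54.0
           tfbs_total_pp2c  34.0
         tfbs_total_kinase  32.0
 ap2_in_udpgt_architecture   7.0
  ap2_in_bbox_architecture   9.0
           adass_identical   0.0
            adass_disjoint   1.0
```

e.g. 64 WGD-retained genes of 231 is 27.7% (percentages are truncated,
not rounded), and the printed B-box promoter architecture contains nine
AP2 tokens.

Programmatic use mirrors the scripts:

```r
library(syntarch)
sim <- generate_genomes(sim_config(seed = 7, planted_block_specs = list(
  list(species_pair = c("sp1", "sp2"), length = 8, orientation = "same"))))
pairs  <- align_all_vs_all(do.call(c, unname(lapply(sim$genomes, `[[`, "proteins"))))
blocks <- detect_collinear_blocks(pairs, sim$genomes)
```

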