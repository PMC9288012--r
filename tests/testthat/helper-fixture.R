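# Shared synthetic fixture: built once per test run, reused across files.
# Three species, two chromosomes each, planted collinear blocks (one
# inverted), a tandem array, a proximal pair, dispersed pairs and a
# whole-chromosome duplication, plus planted DREB motif instances.

fixture_config <- function(seed = 7) {
  sim_config(
    n_species = 3, chromosomes_per_species = 2, genes_per_chromosome = 40,
    planted_block_specs = list(
      list(species_pair = c("sp1", "sp2"), length = 8, orientation = "same"),
      list(species_pair = c("sp1", "sp3"), length = 6,
           orientation = "inverted")),
    tandem_array_specs = list(list(species = "sp1", array_size = 3)),
    proximal_specs = list(list(species = "sp2", intervening = 4)),
    dispersed_specs = list(list(species = "sp3", count = 2)),
    wgd_specs = "sp2",
    motif_plant_specs = list(
      list(subfamily = "DREB", n_promoters = 4, plants_per_promoter = 3)),
    mutation_rate_homologs = 0.05,
    seed = seed)
}

shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_genomes(fixture_config())
      prot <- do.call(c, unname(lapply(sim$genomes, `[[`, "proteins")))
      pairs <- align_all_vs_all(prot)
      blocks <- detect_collinear_blocks(pairs, sim$genomes)
      species_of <- do.call(c, unname(lapply(sim$genomes, function(g) {
        stats::setNames(rep(g$species, nrow(g$genes)), g$genes$gene_id)
      })))
      cache <<- list(sim = sim, pairs = pairs, blocks = blocks,
                     species_of = species_of)
    }
    cache
  }
})

# small deterministic annotation built directly in code
toy_annotation <- function() {
  seqs <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))  # 2000 bp
  genes <- data.frame(
    gene_id = c("gB", "gA", "gC"),
    chromosome = "chr1",
    start = c(500L, 100L, 900L),
    end = c(600L, 180L, 1000L),
    strand = c("+", "+", "-"),
    stringsAsFactors = FALSE)
  genome_annotation("toy", seqs, genes,
                    proteins = c(gA = "MKL", gB = "MKI"))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
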