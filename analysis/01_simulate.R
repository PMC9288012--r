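#!/usr/bin/env Rscript
# Generate the synthetic study genomes: three species, two chromosomes
# each, with planted collinear blocks (one inverted), a tandem array, a
# proximal pair, dispersed duplicates, a whole-chromosome duplication and
# DREB motif instances planted in promoters. Writes the fixture plus
# truth tables under results/fixture/.

library(syntarch)

cfg <- sim_config(
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
  seed = 7)

sim <- generate_genomes(cfg)
write_fixture(sim, "results/fixture")

cat("Simulated", length(sim$genomes), "species;",
    sum(vapply(sim$genomes, function(g) nrow(g$genes), integer(1))),
    "genes in total.\n")
cat("Planted:", nrow(sim$truth$planted_blocks), "collinear anchor pairs,",
    sum(sim$truth$duplication_labels$class != "singleton"),
    "duplicated genes,", nrow(sim$truth$planted_motifs),
    "motif instances.\n")
cat("Fixture written to results/fixture/\n")
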