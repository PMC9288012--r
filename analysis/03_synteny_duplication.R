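#!/usr/bin/env Rscript
# Chain homolog pairs into collinear blocks, classify each gene's
# duplication origin, group DEG-anchored syntelogs, and tabulate the
# per-species duplication summary. Writes results/collinearity.txt,
# results/duplication_labels.tsv, results/duplication_summary.tsv and
# results/syntelog_groups.tsv.

library(syntarch)

fx <- "results/fixture"
sps <- sub("\\.fa$", "", basename(list.files(fx, "\\.fa$")))
genomes <- lapply(sps, function(sp) {
  read_genome(file.path(fx, paste0(sp, ".fa")),
              file.path(fx, paste0(sp, ".gff3")),
              file.path(fx, paste0(sp, ".faa")), sp)
})
names(genomes) <- sps
pairs <- read_homolog_pairs("results/homolog_pairs.tsv")
species_of <- do.call(c, unname(lapply(genomes, function(g) {
  setNames(rep(g$species, nrow(g$genes)), g$genes$gene_id)
})))

blocks <- detect_collinear_blocks(pairs, genomes, synteny_config())
write_collinearity(blocks, "results/collinearity.txt")
cat(length(blocks), "collinear blocks (",
    sum(vapply(blocks, function(b) b$orientation == "inverted", logical(1))),
    "inverted ).\n")

labs <- do.call(rbind, lapply(genomes, function(g) {
  within <- pairs[species_of[pairs$gene_a] == g$species &
                    species_of[pairs$gene_b] == g$species, , drop = FALSE]
  d <- classify_duplicates(g, within, blocks)
  d$species <- g$species
  d
}))
write.table(labs, "results/duplication_labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
summ <- do.call(rbind, lapply(split(labs, labs$species), function(d) {
  s <- summarize_duplications(d)
  cbind(species = d$species[1], s)
}))
write.table(summ, "results/duplication_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
truth <- read.delim(file.path(fx, "duplication_labels.tsv"))
m <- merge(labs, truth, by = "gene_id")
cat("Duplication classifier agreement with planted truth:",
    round(100 * mean(m$class.x == m$class.y), 1), "%\n")

deg <- readLines(file.path(fx, "deg_anchors.txt"))
groups <- group_syntelogs(deg, blocks)
df <- do.call(rbind, lapply(groups, function(g) {
  data.frame(group_id = g$group_id,
             species = rep(names(g$members), lengths(g$members)),
             gene_id = unlist(g$members, use.names = FALSE))
}))
write.table(df, "results/syntelog_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(length(groups), "DEG-anchored syntelog groups covering", nrow(df),
    "genes.\n")
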