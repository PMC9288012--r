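#' Synthetic genome simulation configuration
#'
#' Describes a multi-species genome set with planted collinear blocks,
#' duplication events and promoter motif instances. Genes are laid out on
#' a regular grid (gene length 300 bp, 1700 bp intergenic, first gene at
#' position 1501) so that every gene owns a full-length 1000 bp promoter
#' window free of neighbouring genes.
#'
#' @param n_species number of species (named sp1, sp2, ...).
#' @param chromosomes_per_species chromosomes per species (chr1, chr2, ...).
#' @param genes_per_chromosome genes per chromosome.
#' @param planted_block_specs list of specs
#'   \code{list(species_pair = c("sp1","sp2"), length = 8,
#'   orientation = "same"|"inverted")}; cross-species collinear blocks are
#'   planted on chr1 of both species.
#' @param tandem_array_specs list of \code{list(species=, array_size=)}.
#' @param proximal_specs list of \code{list(species=, intervening=)}.
#' @param dispersed_specs list of \code{list(species=, count=)}.
#' @param wgd_specs character vector of species receiving a duplicated
#'   copy of their last chromosome (planted whole-genome/segmental
#'   duplication).
#' @param motif_plant_specs list of \code{list(subfamily=, n_promoters=,
#'   plants_per_promoter=)}; consensus strings of the default bundle are
#'   written into randomly chosen promoters at recorded offsets.
#' @param mutation_rate_homologs per-residue substitution probability
#'   applied when copying a protein to its planted homolog (default 0.05).
#' @param protein_length length of simulated proteins (default 150 aa).
#' @param seed RNG seed; identical config + seed reproduces the output
#'   byte for byte.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_species = 3L, chromosomes_per_species = 2L,
                       genes_per_chromosome = 40L,
                       planted_block_specs = list(),
                       tandem_array_specs = list(),
                       proximal_specs = list(),
                       dispersed_specs = list(),
                       wgd_specs = character(),
                       motif_plant_specs = list(),
                       mutation_rate_homologs = 0.05,
                       protein_length = 150L,
                       seed = 1L) {
  stopifnot(n_species >= 1L, chromosomes_per_species >= 1L,
            genes_per_chromosome >= 1L,
            mutation_rate_homologs >= 0, mutation_rate_homologs < 1,
            protein_length >= 10L)
  structure(list(
    n_species = as.integer(n_species),
    chromosomes_per_species = as.integer(chromosomes_per_species),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    planted_block_specs = planted_block_specs,
    tandem_array_specs = tandem_array_specs,
    proximal_specs = proximal_specs,
    dispersed_specs = dispersed_specs,
    wgd_specs = wgd_specs,
    motif_plant_specs = motif_plant_specs,
    mutation_rate_homologs = mutation_rate_homologs,
    protein_length = as.integer(protein_length),
    seed = as.integer(seed)
  ), class = "sim_config")
}

.AA <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
         "T","V","W","Y")

.random_protein <- function(len) {
  paste(sample(.AA, len, replace = TRUE), collapse = "")
}

.mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(.AA, a), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

# gene layout constants: regular grid leaving every promoter unobstructed
.GENE_LEN <- 300L
.SPACING <- 2000L
.FIRST_START <- 1501L

.gene_start <- function(rank) .FIRST_START + rank * .SPACING

# pick a run of `len` consecutive free ranks on a chromosome; marks the
# run plus one flanking rank on each side as used
.take_run <- function(free, len) {
  n <- length(free)
  if (len > n) {
    stop("config error: planted features exceed genes_per_chromosome")
  }
  ok <- vapply(seq_len(n - len + 1L), function(s) all(free[s:(s + len - 1L)]),
               logical(1))
  starts <- which(ok)
  if (length(starts) == 0L) {
    stop("config error: planted features exceed genes_per_chromosome")
  }
  s <- if (length(starts) == 1L) starts else sample(starts, 1L)
  lo <- max(1L, s - 1L); hi <- min(n, s + len)
  free[lo:hi] <- FALSE
  list(free = free, ranks = (s - 1L):(s + len - 2L))  # 0-based ranks
}

#' Generate synthetic genomes with planted ground truth
#'
#' @param config a [sim_config()].
#' @return list with elements \code{genomes} (named list of
#'   \code{genome_annotation}) and \code{truth}: \code{planted_blocks}
#'   (data.frame gene_a, gene_b, block, orientation),
#'   \code{duplication_labels} (gene_id, species, class),
#'   \code{planted_motifs} (gene_id, subfamily, promoter_offset, strand),
#'   \code{deg_anchors} (character vector) and the config.
#' @export
generate_genomes <- function(config) {
  set.seed(config$seed)
  sps <- paste0("sp", seq_len(config$n_species))
  G <- config$genes_per_chromosome
  nchr <- config$chromosomes_per_species
  chrs <- paste0("chr", seq_len(nchr))
  # leave a full promoter window beyond the last gene so minus-strand
  # promoters at the chromosome end are never truncated
  chr_len <- .gene_start(G - 1L) + .GENE_LEN + 1100L

  gid <- function(sp, chr, rank) sprintf("%s_%s_g%03d", sp, chr, rank + 1L)

  genes <- list(); proteins <- list(); free <- list()
  for (sp in sps) {
    for (chr in chrs) {
      ranks <- 0:(G - 1L)
      ids <- gid(sp, chr, ranks)
      genes[[paste(sp, chr)]] <- data.frame(
        gene_id = ids, species = sp, chromosome = chr,
        start = .gene_start(ranks), end = .gene_start(ranks) + .GENE_LEN - 1L,
        strand = sample(c("+", "-"), G, replace = TRUE),
        stringsAsFactors = FALSE)
      proteins[[paste(sp, chr)]] <- stats::setNames(
        vapply(ids, function(i) .random_protein(config$protein_length),
               character(1)), ids)
      free[[paste(sp, chr)]] <- rep(TRUE, G)
    }
  }

  labels <- character(0)   # gene_id -> class (default singleton)
  blocks <- list()
  rate <- config$mutation_rate_homologs

  # cross-species collinear blocks, planted on chr1 of each species.
  # A spec may set share_a_side_of = <earlier block index> to reuse that
  # block's first-species gene run, which links the two blocks into one
  # syntelog group through the shared genes.
  block_a_ranks <- list()
  for (bi in seq_along(config$planted_block_specs)) {
    spec <- config$planted_block_specs[[bi]]
    spA <- spec$species_pair[1]; spB <- spec$species_pair[2]
    len <- spec$length
    ka <- paste(spA, "chr1"); kb <- paste(spB, "chr1")
    if (!is.null(spec$share_a_side_of)) {
      src <- config$planted_block_specs[[spec$share_a_side_of]]
      if (!identical(src$species_pair[1], spA) ||
          src$length < len) {
        stop("config error: share_a_side_of must name an earlier block ",
             "with the same first species and at least this length")
      }
      ra0 <- block_a_ranks[[spec$share_a_side_of]][seq_len(len)]
      ta <- list(free = free[[ka]], ranks = ra0)
    } else {
      ta <- .take_run(free[[ka]], len); free[[ka]] <- ta$free
    }
    tb <- .take_run(free[[kb]], len); free[[kb]] <- tb$free
    block_a_ranks[[bi]] <- ta$ranks
    ra <- ta$ranks
    rb <- if (identical(spec$orientation, "inverted")) rev(tb$ranks) else tb$ranks
    ga <- gid(spA, "chr1", ra); gb <- gid(spB, "chr1", rb)
    for (i in seq_len(len)) {
      proteins[[kb]][gb[i]] <- .mutate_protein(proteins[[ka]][[ga[i]]], rate)
      if (identical(spec$orientation, "inverted")) {
        sa <- genes[[ka]]$strand[genes[[ka]]$gene_id == ga[i]]
        genes[[kb]]$strand[genes[[kb]]$gene_id == gb[i]] <-
          if (sa == "+") "-" else "+"
      }
    }
    blocks[[bi]] <- data.frame(gene_a = ga, gene_b = gb, block = bi,
                               orientation = spec$orientation,
                               stringsAsFactors = FALSE)
  }

  # tandem arrays: adjacent ranks, copies of the first member
  for (spec in config$tandem_array_specs) {
    k <- paste(spec$species, "chr1")
    tk <- .take_run(free[[k]], spec$array_size); free[[k]] <- tk$free
    ids <- gid(spec$species, "chr1", tk$ranks)
    for (i in 2:length(ids)) {
      proteins[[k]][ids[i]] <- .mutate_protein(proteins[[k]][[ids[1]]], rate)
    }
    labels[ids] <- "tandem"
  }

  # proximal pairs: `intervening` unrelated genes in between
  for (spec in config$proximal_specs) {
    k <- paste(spec$species, "chr1")
    tk <- .take_run(free[[k]], spec$intervening + 2L); free[[k]] <- tk$free
    ids <- gid(spec$species, "chr1", range(tk$ranks))
    proteins[[k]][ids[2]] <- .mutate_protein(proteins[[k]][[ids[1]]], rate)
    labels[ids] <- "proximal"
  }

  # dispersed pairs: far apart on the same chromosome (second copy well
  # outside any plausible proximal window of the first)
  for (spec in config$dispersed_specs) {
    k <- paste(spec$species, "chr1")
    for (i in seq_len(spec$count)) {
      t1 <- .take_run(free[[k]], 1L); free[[k]] <- t1$free
      far <- which(free[[k]] & abs(seq_along(free[[k]]) - 1L - t1$ranks) > 15L)
      if (length(far) == 0L) {
        stop("config error: no room for a dispersed duplicate")
      }
      r2 <- (if (length(far) == 1L) far else sample(far, 1L)) - 1L
      free[[k]][r2 + 1L] <- FALSE
      ids <- gid(spec$species, "chr1", c(t1$ranks, r2))
      proteins[[k]][ids[2]] <- .mutate_protein(proteins[[k]][[ids[1]]], rate)
      labels[ids] <- "dispersed"
    }
  }

  # planted WGD: duplicate the last chromosome wholesale
  for (sp in config$wgd_specs) {
    src_chr <- chrs[nchr]
    ks <- paste(sp, src_chr)
    new_chr <- "chrW"
    ids_src <- genes[[ks]]$gene_id
    ranks <- 0:(G - 1L)
    ids_new <- gid(sp, new_chr, ranks)
    genes[[paste(sp, new_chr)]] <- data.frame(
      gene_id = ids_new, species = sp, chromosome = new_chr,
      start = .gene_start(ranks), end = .gene_start(ranks) + .GENE_LEN - 1L,
      strand = genes[[ks]]$strand, stringsAsFactors = FALSE)
    proteins[[paste(sp, new_chr)]] <- stats::setNames(
      vapply(ids_src, function(i) .mutate_protein(proteins[[ks]][[i]], rate),
             character(1)), ids_new)
    labels[c(ids_src, ids_new)] <- "wgd_segmental"
  }

  # assemble genomes with random chromosome sequences, then plant motifs
  planted_motifs <- data.frame(gene_id = character(), subfamily = character(),
                               promoter_offset = integer(),
                               strand = character(), stringsAsFactors = FALSE)
  all_genes <- do.call(rbind, genes)
  bundle <- default_motif_bundle()
  names(bundle) <- vapply(bundle, `[[`, character(1), "subfamily")

  seqs_by_sp <- list()
  for (sp in sps) {
    gsp <- all_genes[all_genes$species == sp, , drop = FALSE]
    sp_chrs <- unique(gsp$chromosome)
    seqs <- lapply(sp_chrs, function(chr) {
      paste(sample(c("A", "C", "G", "T"), chr_len, replace = TRUE),
            collapse = "")
    })
    names(seqs) <- sp_chrs
    seqs_by_sp[[sp]] <- seqs
  }

  if (length(config$motif_plant_specs)) {
    pool <- all_genes$gene_id
    for (spec in config$motif_plant_specs) {
      model <- bundle[[spec$subfamily]]
      if (is.null(model)) stop("config error: unknown subfamily ", spec$subfamily)
      cons <- motif_consensus(model)
      Lm <- nchar(cons)
      chosen <- sample(pool, spec$n_promoters)
      pool <- setdiff(pool, chosen)  # one spec per promoter
      for (g in chosen) {
        row <- all_genes[all_genes$gene_id == g, ]
        # non-overlapping offsets within the 1000 bp promoter
        slots <- seq(0L, 1000L - Lm, by = Lm + 4L)
        offs <- sort(sample(slots, spec$plants_per_promoter))
        for (o in offs) {
          sq <- seqs_by_sp[[row$species]][[row$chromosome]]
          if (row$strand == "+") {
            at <- row$start - 1000L + o          # genomic 1-based start
            substr(sq, at, at + Lm - 1L) <- cons
          } else {
            at <- row$end + 1000L - o - Lm + 1L
            substr(sq, at, at + Lm - 1L) <- .revcomp_chr(cons)
          }
          seqs_by_sp[[row$species]][[row$chromosome]] <- sq
          planted_motifs <- rbind(planted_motifs, data.frame(
            gene_id = g, subfamily = spec$subfamily, promoter_offset = o,
            strand = "+", stringsAsFactors = FALSE))
        }
      }
    }
  }

  genomes <- lapply(sps, function(sp) {
    gsp <- all_genes[all_genes$species == sp, , drop = FALSE]
    rownames(gsp) <- NULL
    prot <- unlist(proteins[grep(paste0("^", sp, " "), names(proteins))],
                   use.names = FALSE)
    names(prot) <- unlist(lapply(proteins[grep(paste0("^", sp, " "),
                                               names(proteins))], names),
                          use.names = FALSE)
    genome_annotation(sp, Biostrings::DNAStringSet(unlist(seqs_by_sp[[sp]])),
                      gsp, prot)
  })
  names(genomes) <- sps

  dup <- data.frame(gene_id = all_genes$gene_id,
                    species = all_genes$species,
                    class = "singleton", stringsAsFactors = FALSE)
  dup$class[match(names(labels), dup$gene_id)] <- unname(labels)

  deg <- vapply(blocks, function(b) b$gene_a[1], character(1))

  list(genomes = genomes,
       truth = list(
         planted_blocks = if (length(blocks)) do.call(rbind, blocks) else
           data.frame(gene_a = character(), gene_b = character(),
                      block = integer(), orientation = character(),
                      stringsAsFactors = FALSE),
         duplication_labels = dup,
         planted_motifs = planted_motifs,
         deg_anchors = deg,
         config = config))
}

.revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

#' Write a generated genome set as a plain-text fixture
#'
#' Emits, per species, a genome FASTA, a GFF3 annotation and a protein
#' FASTA, plus tab-separated truth tables and a JSON manifest recording
#' the seed and configuration.
#'
#' @param sim result of [generate_genomes()].
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  paths <- character(0)
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]
    fa <- file.path(out_dir, paste0(sp, ".fa"))
    Biostrings::writeXStringSet(g$sequences, fa)
    gff <- file.path(out_dir, paste0(sp, ".gff3"))
    writeLines(c("##gff-version 3", sprintf(
      "%s\tsyntarch\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$genes$chromosome, g$genes$start, g$genes$end, g$genes$strand,
      g$genes$gene_id)), gff)
    faa <- file.path(out_dir, paste0(sp, ".faa"))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(g$proteins), faa)
    paths <- c(paths, fa, gff, faa)
  }
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths,
             tsv(sim$truth$planted_blocks, "planted_blocks.tsv"),
             tsv(sim$truth$duplication_labels, "duplication_labels.tsv"),
             tsv(sim$truth$planted_motifs, "planted_motifs.tsv"))
  deg <- file.path(out_dir, "deg_anchors.txt")
  writeLines(sim$truth$deg_anchors, deg)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(seed = sim$truth$config$seed,
         config = unclass(sim$truth$config)),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, deg, manifest))
}
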