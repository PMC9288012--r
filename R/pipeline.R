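#' End-to-end pipeline configuration
#'
#' @param species_files data.frame with columns species, fasta, gff,
#'   proteins — one row per species.
#' @param deg_file text file with one DEG anchor gene id per line.
#' @param out_dir output directory.
#' @param motif_file optional motif model file ([load_motifs()] format);
#'   when NULL the default consensus bundle is used.
#' @param homology,synteny,promoter,scan,distance stage configurations.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the inputs were simulated).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(species_files, deg_file, out_dir,
                            motif_file = NULL,
                            homology = homology_config(),
                            synteny = synteny_config(),
                            promoter = promoter_config(),
                            scan = scan_config(),
                            distance = distance_config(),
                            seed = 1L) {
  stopifnot(is.data.frame(species_files),
            all(c("species", "fasta", "gff", "proteins") %in%
                  names(species_files)))
  structure(list(species_files = species_files, deg_file = deg_file,
                 out_dir = out_dir, motif_file = motif_file,
                 homology = homology, synteny = synteny,
                 promoter = promoter, scan = scan, distance = distance,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Convenience: pipeline configuration for a written fixture directory
#' @param fixture_dir directory produced by [write_fixture()].
#' @param out_dir output directory.
#' @param ... passed to [pipeline_config()].
#' @return a \code{pipeline_config}.
#' @export
pipeline_config_from_fixture <- function(fixture_dir, out_dir, ...) {
  fa <- sort(list.files(fixture_dir, "\\.fa$", full.names = TRUE))
  sps <- sub("\\.fa$", "", basename(fa))
  pipeline_config(
    species_files = data.frame(
      species = sps, fasta = fa,
      gff = file.path(fixture_dir, paste0(sps, ".gff3")),
      proteins = file.path(fixture_dir, paste0(sps, ".faa")),
      stringsAsFactors = FALSE),
    deg_file = file.path(fixture_dir, "deg_anchors.txt"),
    out_dir = out_dir, ...)
}

.read_manifest <- function(path) {
  if (file.exists(path)) jsonlite::read_json(path) else
    list(stages = list())
}

.stage_hash <- function(inputs) {
  inputs <- inputs[file.exists(inputs)]
  paste(unname(tools::md5sum(sort(inputs))), collapse = "")
}

#' Run the full pipeline
#'
#' Executes, in order: homolog detection, collinear block chaining,
#' duplication classification and summary, DEG-anchored syntelog
#' grouping, promoter extraction, motif scanning, architecture building,
#' the pairwise architecture distance matrix, per-species similarity
#' statistics, and the neighbor-joining tree. A JSON manifest in the
#' output directory records the configuration, the seed and per-stage
#' record counts; a stage is skipped on re-run when its outputs exist and
#' its inputs are unchanged (tracked by content hash).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return named list of output paths, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  cfg_json <- file.path(out, "config.json")
  jsonlite::write_json(
    list(species = config$species_files, deg_file = config$deg_file,
         motif_file = config$motif_file,
         homology = unclass(config$homology),
         synteny = unclass(config$synteny),
         promoter = unclass(config$promoter),
         scan = unclass(config$scan),
         distance = unclass(config$distance),
         seed = config$seed),
    cfg_json, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")

  manifest_path <- file.path(out, "manifest.json")
  manifest <- .read_manifest(manifest_path)
  manifest$seed <- config$seed

  paths <- list(
    pairs = file.path(out, "homolog_pairs.tsv"),
    collinearity = file.path(out, "collinearity.txt"),
    blocks_tsv = file.path(out, "collinearity.txt.tsv"),
    duplication = file.path(out, "duplication_labels.tsv"),
    dup_summary = file.path(out, "duplication_summary.tsv"),
    groups = file.path(out, "syntelog_groups.tsv"),
    promoters = file.path(out, "promoters.fa"),
    hits = file.path(out, "tfbs_hits.tsv"),
    architectures = file.path(out, "architectures.tsv"),
    dist = file.path(out, "adass_distance.phy"),
    dist_tsv = file.path(out, "adass_distance.phy.tsv"),
    simstats = file.path(out, "similarity_stats.tsv"),
    tree = file.path(out, "tree.nwk"))

  in_files <- c(config$species_files$fasta, config$species_files$gff,
                config$species_files$proteins, config$deg_file,
                config$motif_file, cfg_json)

  stage <- function(name, inputs, outputs, fun) {
    h <- .stage_hash(inputs)
    st <- manifest$stages[[name]]
    if (!is.null(st) && identical(st$hash, h) && all(file.exists(outputs))) {
      say("[", name, "] up to date, skipped")
      return(invisible(FALSE))
    }
    t0 <- Sys.time()
    n <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      hash = h, records = n,
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    say("[", name, "] ", n, " records")
    invisible(TRUE)
  }

  genomes <- lapply(seq_len(nrow(config$species_files)), function(i) {
    r <- config$species_files[i, ]
    read_genome(r$fasta, r$gff, r$proteins, r$species)
  })
  names(genomes) <- config$species_files$species
  species_of <- do.call(c, unname(lapply(genomes, function(g) {
    stats::setNames(rep(g$species, nrow(g$genes)), g$genes$gene_id)
  })))
  deg <- readLines(config$deg_file)
  deg <- deg[nzchar(deg)]

  stage("homology", in_files, paths$pairs, function() {
    prot <- do.call(c, unname(lapply(genomes, `[[`, "proteins")))
    pairs <- align_all_vs_all(prot, config$homology)
    write_homolog_pairs(pairs, paths$pairs)
    nrow(pairs)
  })
  pairs <- read_homolog_pairs(paths$pairs)

  stage("synteny", c(in_files, paths$pairs),
        c(paths$collinearity, paths$blocks_tsv), function() {
    blocks <- detect_collinear_blocks(pairs, genomes, config$synteny)
    write_collinearity(blocks, paths$collinearity)
    length(blocks)
  })
  blocks_df <- utils::read.table(paths$blocks_tsv, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  blocks <- .blocks_from_df(blocks_df)

  stage("classify", c(in_files, paths$pairs, paths$blocks_tsv),
        c(paths$duplication, paths$dup_summary), function() {
    labs <- do.call(rbind, lapply(genomes, function(g) {
      within <- pairs[species_of[pairs$gene_a] == g$species &
                        species_of[pairs$gene_b] == g$species, , drop = FALSE]
      d <- classify_duplicates(g, within, blocks, config$synteny)
      d$species <- g$species
      d
    }))
    utils::write.table(labs, paths$duplication, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    summ <- do.call(rbind, lapply(split(labs, labs$species), function(d) {
      s <- summarize_duplications(d)
      s$species <- d$species[1]
      s
    }))
    utils::write.table(summ, paths$dup_summary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nrow(labs)
  })

  stage("syntelogs", c(in_files, paths$blocks_tsv), paths$groups, function() {
    groups <- group_syntelogs(deg, blocks)
    df <- do.call(rbind, lapply(groups, function(g) {
      data.frame(group_id = g$group_id,
                 species = rep(names(g$members), lengths(g$members)),
                 gene_id = unlist(g$members, use.names = FALSE),
                 is_deg_anchor = unlist(g$members, use.names = FALSE) %in%
                   g$anchor_degs,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- data.frame(group_id = integer(),
                                      species = character(),
                                      gene_id = character(),
                                      is_deg_anchor = logical())
    utils::write.table(df, paths$groups, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nrow(df)
  })
  groups_df <- utils::read.table(paths$groups, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  target_genes <- if (nrow(groups_df)) unique(groups_df$gene_id) else
    unname(unlist(lapply(genomes, function(g) g$genes$gene_id)))

  stage("promoters", c(in_files, paths$groups), paths$promoters, function() {
    proms <- do.call(c, unname(lapply(genomes, function(g) {
      ids <- intersect(target_genes, g$genes$gene_id)
      if (length(ids) == 0L) return(NULL)
      extract_promoter_set(g, ids, config$promoter)
    })))
    write_promoters(proms, paths$promoters)
    length(proms)
  })

  stage("scan", c(in_files, paths$promoters), paths$hits, function() {
    proms <- Biostrings::readDNAStringSet(paths$promoters)
    models <- if (is.null(config$motif_file)) default_motif_bundle() else
      load_motifs(config$motif_file)
    hits <- scan_promoter_set(stats::setNames(as.character(proms),
                                              names(proms)),
                              models, config$scan)
    utils::write.table(hits, paths$hits, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nrow(hits)
  })
  hits <- utils::read.table(paths$hits, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)

  stage("architectures", c(in_files, paths$hits, paths$promoters),
        paths$architectures, function() {
    proms <- Biostrings::readDNAStringSet(paths$promoters)
    archs <- build_architecture_set(hits, gene_ids = sort(names(proms)))
    write_architectures(archs, paths$architectures)
    length(archs)
  })
  archs <- read_architectures(paths$architectures)

  stage("adass", c(in_files, paths$architectures),
        c(paths$dist, paths$dist_tsv, paths$simstats), function() {
    d <- adass_distance_matrix(archs, config$distance,
                               species_of = species_of)
    write_phylip(d, paths$dist)
    st <- similarity_stats(d, config = config$distance)
    utils::write.table(st, paths$simstats, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nrow(d)
  })

  stage("tree", c(in_files, paths$dist_tsv), paths$tree, function() {
    dtab <- utils::read.table(paths$dist_tsv, header = TRUE, sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE)
    d <- as.matrix(dtab[, -1, drop = FALSE])
    rownames(d) <- dtab$label
    tree <- neighbor_joining(d)
    write_newick(tree, paths$tree)
    length(tree$tip.label)
  })

  invisible(paths)
}

# rebuild collinear_block objects from the flat anchor table
.blocks_from_df <- function(df) {
  if (nrow(df) == 0L) return(list())
  lapply(split(df, df$block), function(b) {
    structure(list(species_a = b$species_a[1], chromosome_a = b$chromosome_a[1],
                   species_b = b$species_b[1], chromosome_b = b$chromosome_b[1],
                   orientation = b$orientation[1], score = NA_real_,
                   anchors = data.frame(gene_a = b$gene_a, gene_b = b$gene_b,
                                        stringsAsFactors = FALSE)),
              class = "collinear_block")
  })
}
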