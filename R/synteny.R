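#' Collinearity detection configuration
#'
#' Defaults follow the conventional MCScanX-style parameterisation:
#' at least 5 anchor pairs per block and at most 25 intervening gene ranks
#' between consecutive anchors.
#'
#' @param min_anchors minimum anchors per emitted block (default 5).
#' @param max_gap maximum intervening gene ranks between consecutive
#'   anchors, on either chromosome (default 25).
#' @param proximal_window maximum intervening genes for the proximal
#'   duplication class (default 10).
#' @return list of class \code{synteny_config}.
#' @export
synteny_config <- function(min_anchors = 5L, max_gap = 25L,
                           proximal_window = 10L) {
  stopifnot(min_anchors >= 2L, max_gap >= 1L, proximal_window >= 2L)
  structure(list(min_anchors = as.integer(min_anchors),
                 max_gap = as.integer(max_gap),
                 proximal_window = as.integer(proximal_window)),
            class = "synteny_config")
}

.gene_index <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    a$genes[, c("gene_id", "species", "chromosome", "rank")]
  }))
}

# Best monotone chain through dots (ra strictly increasing; rb strictly
# increasing or decreasing depending on orientation), consecutive gaps
# (intervening ranks) bounded by max_gap on both axes.
# score = n_anchors - 0.1 * total intervening-rank gap.
.best_chain <- function(ra, rb, orientation, max_gap) {
  n <- length(ra)
  if (n == 0L) return(NULL)
  sb <- if (orientation == "same") rb else -rb
  ord <- order(ra, sb)
  ra <- ra[ord]; sb <- sb[ord]
  s <- rep(1, n)      # best chain score ending at i
  pred <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- sb[i] - sb[j]
      if (da < 1L || db < 1L) next
      if (da - 1L > max_gap || db - 1L > max_gap) next
      cand <- s[j] + 1 - 0.1 * ((da - 1L) + (db - 1L))
      if (cand > s[i] + 1e-12) { s[i] <- cand; pred[i] <- j }
    }
  }
  end <- which.max(s)
  chain <- integer(0)
  i <- end
  while (i != 0L) { chain <- c(i, chain); i <- pred[i] }
  list(idx = ord[chain], score = s[end], orientation = orientation)
}

#' Detect collinear blocks from homolog pairs
#'
#' Homolog pairs are placed as dots at (rank_a, rank_b) for every
#' chromosome pair and chained by dynamic programming into
#' maximal-scoring runs that are strictly monotone on both chromosomes
#' (ascending for same-orientation blocks, descending on the second
#' chromosome for inverted blocks) with bounded rank gaps. Chains are
#' extracted iteratively (best first, dots removed) until none reaches
#' \code{min_anchors}.
#'
#' @param pairs data.frame of homolog pairs (gene_a, gene_b, ...).
#' @param annotations named list of \code{genome_annotation}s covering all
#'   genes in \code{pairs}.
#' @param config a [synteny_config()].
#' @return list of \code{collinear_block} objects; each has species_a/b,
#'   chromosome_a/b, orientation, score and an \code{anchors} data.frame
#'   (gene_a, gene_b, rank_a, rank_b) ordered along the chain.
#' @export
detect_collinear_blocks <- function(pairs, annotations,
                                    config = synteny_config()) {
  idx <- .gene_index(annotations)
  rownames(idx) <- idx$gene_id
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), idx$gene_id)
  if (length(missing)) {
    stop("gene(s) without rank in any annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (nrow(pairs) == 0L) return(list())
  # orient every pair so the lexicographically smaller species is side a;
  # the dot-plot grouping below is then independent of pair storage order
  swap <- idx[pairs$gene_a, "species"] > idx[pairs$gene_b, "species"]
  tmp <- pairs$gene_a[swap]
  pairs$gene_a[swap] <- pairs$gene_b[swap]
  pairs$gene_b[swap] <- tmp
  a <- idx[pairs$gene_a, ]
  b <- idx[pairs$gene_b, ]
  key <- paste(a$species, a$chromosome, b$species, b$chromosome, sep = "\r")
  blocks <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    ga <- pairs$gene_a[sel]; gb <- pairs$gene_b[sel]
    ra <- a$rank[sel]; rb <- b$rank[sel]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    active <- rep(TRUE, length(sel))
    repeat {
      ii <- which(active)
      if (length(ii) < config$min_anchors) break
      best <- NULL
      for (ori in c("same", "inverted")) {
        ch <- .best_chain(ra[ii], rb[ii], ori, config$max_gap)
        if (is.null(ch)) next
        if (is.null(best) || ch$score > best$score + 1e-12) {
          ch$idx <- ii[ch$idx]
          best <- ch
        }
      }
      if (is.null(best) || length(best$idx) < config$min_anchors) break
      anchors <- data.frame(gene_a = ga[best$idx], gene_b = gb[best$idx],
                            rank_a = ra[best$idx], rank_b = rb[best$idx],
                            stringsAsFactors = FALSE)
      blocks[[length(blocks) + 1L]] <- structure(
        list(species_a = parts[1], chromosome_a = parts[2],
             species_b = parts[3], chromosome_b = parts[4],
             orientation = best$orientation, score = best$score,
             anchors = anchors),
        class = "collinear_block")
      active[best$idx] <- FALSE
    }
  }
  blocks
}

#' @export
print.collinear_block <- function(x, ...) {
  cat(sprintf("collinear_block %s:%s ~ %s:%s (%s, %d anchors, score %.1f)\n",
              x$species_a, x$chromosome_a, x$species_b, x$chromosome_b,
              x$orientation, nrow(x$anchors), x$score))
  invisible(x)
}

#' Classify gene duplication origin
#'
#' Every gene of one species receives exactly one class, assigned by
#' precedence: genes with no within-species homolog are
#' \code{singleton}; genes that are anchors of any collinear block (and
#' have a within-species homolog) are \code{wgd_segmental}; genes with a
#' within-species homolog at the adjacent rank on the same chromosome are
#' \code{tandem}; within \code{proximal_window} intervening genes,
#' \code{proximal}; anything else is \code{dispersed}.
#'
#' @param annotation \code{genome_annotation} of the species.
#' @param within_species_pairs homolog pairs restricted to this species.
#' @param blocks collinear blocks from [detect_collinear_blocks()] (any
#'   species pair; only anchors belonging to this species matter).
#' @param config a [synteny_config()].
#' @return data.frame gene_id, class.
#' @export
classify_duplicates <- function(annotation, within_species_pairs, blocks,
                                config = synteny_config()) {
  genes <- annotation$genes
  known <- genes$gene_id
  ref <- unique(c(within_species_pairs$gene_a, within_species_pairs$gene_b))
  if (length(setdiff(ref, known))) {
    stop("pair references gene(s) absent from the annotation: ",
         paste(utils::head(setdiff(ref, known), 5), collapse = ", "))
  }
  partners <- split(
    c(within_species_pairs$gene_b, within_species_pairs$gene_a),
    c(within_species_pairs$gene_a, within_species_pairs$gene_b))
  anchor_genes <- unique(unlist(lapply(blocks, function(b) {
    c(b$anchors$gene_a[b$species_a == annotation$species],
      b$anchors$gene_b[b$species_b == annotation$species])
  })))
  chr <- genes$chromosome; names(chr) <- known
  rnk <- genes$rank; names(rnk) <- known
  cls <- vapply(known, function(g) {
    p <- partners[[g]]
    if (is.null(p)) return("singleton")
    if (g %in% anchor_genes) return("wgd_segmental")
    same_chr <- p[chr[p] == chr[g]]
    if (length(same_chr)) {
      gap <- abs(rnk[same_chr] - rnk[g]) - 1L
      if (any(gap == 0L)) return("tandem")
      if (any(gap <= config$proximal_window)) return("proximal")
    }
    "dispersed"
  }, character(1))
  data.frame(gene_id = known, class = unname(cls), stringsAsFactors = FALSE)
}

#' Group DEG-anchored syntelogs across species
#'
#' Builds a graph over all anchor pairs of the given blocks and keeps
#' connected components containing at least one differentially expressed
#' anchor gene. Group ids are assigned in descending component size,
#' breaking ties by the lexicographically smallest member gene id.
#'
#' @param deg_anchors character vector of DEG gene ids.
#' @param blocks collinear blocks.
#' @return list of groups; each a list with group_id, anchor_degs and
#'   members (named list species -> sorted gene ids).
#' @export
group_syntelogs <- function(deg_anchors, blocks) {
  if (length(blocks) == 0L || length(deg_anchors) == 0L) return(list())
  edges <- do.call(rbind, lapply(blocks, function(b) {
    cbind(b$anchors$gene_a, b$anchors$gene_b)
  }))
  species_of <- unlist(unname(lapply(blocks, function(b) {
    stats::setNames(c(rep(b$species_a, nrow(b$anchors)),
                      rep(b$species_b, nrow(b$anchors))),
                    c(b$anchors$gene_a, b$anchors$gene_b))
  })))
  species_of <- species_of[!duplicated(names(species_of))]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- Filter(function(m) any(m %in% deg_anchors), members)
  if (length(members) == 0L) return(list())
  ord <- order(-lengths(members),
               vapply(members, function(m) min(m), character(1)))
  members <- members[ord]
  lapply(seq_along(members), function(i) {
    m <- sort(members[[i]])
    list(group_id = i,
         anchor_degs = intersect(deg_anchors, m),
         members = lapply(split(m, unname(species_of[m])), sort))
  })
}

.dup_classes <- c("wgd_segmental", "dispersed", "proximal", "tandem",
                  "singleton")

#' Summarise duplication classes
#'
#' Counts and percentages per duplication class. Percentages are
#' truncated (not rounded) to one decimal place, matching the convention
#' of printed duplication tables (64/196 reports as 32.6).
#'
#' @param labels data.frame from [classify_duplicates()] (possibly several
#'   species row-bound together).
#' @param restrict_to optional gene ids to restrict the summary to.
#' @return data.frame class, count, percentage.
#' @export
summarize_duplications <- function(labels, restrict_to = NULL) {
  stopifnot(nrow(labels) > 0L)
  if (!is.null(restrict_to)) {
    unknown <- setdiff(restrict_to, labels$gene_id)
    if (length(unknown)) {
      stop("restrict_to contains unknown gene(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    labels <- labels[labels$gene_id %in% restrict_to, , drop = FALSE]
  }
  total <- nrow(labels)
  counts <- table(factor(labels$class, levels = .dup_classes))
  pct <- floor(1000 * as.numeric(counts) / total) / 10
  data.frame(class = .dup_classes, count = as.integer(counts),
             percentage = pct, stringsAsFactors = FALSE)
}

#' Write blocks in a collinearity text layout plus TSV
#'
#' @param blocks collinear blocks.
#' @param path output text file; a sibling \code{<path>.tsv} with one row
#'   per anchor is written as well.
#' @return the path, invisibly.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## Collinearity blocks", con)
  rows <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    ori <- if (b$orientation == "inverted") "minus" else "plus"
    writeLines(sprintf(
      "## Alignment %d: score=%.1f e_value=NA N=%d %s:%s&%s:%s %s",
      i - 1L, b$score, nrow(b$anchors), b$species_a, b$chromosome_a,
      b$species_b, b$chromosome_b, ori), con)
    writeLines(sprintf("%3d-%3d:\t%s\t%s", i - 1L,
                       seq_len(nrow(b$anchors)) - 1L,
                       b$anchors$gene_a, b$anchors$gene_b), con)
    rows[[i]] <- data.frame(block = i, species_a = b$species_a,
                            chromosome_a = b$chromosome_a,
                            species_b = b$species_b,
                            chromosome_b = b$chromosome_b,
                            orientation = b$orientation,
                            gene_a = b$anchors$gene_a,
                            gene_b = b$anchors$gene_b,
                            stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), paste0(path, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
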