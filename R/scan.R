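#' Promoter scan configuration
#'
#' @param z_threshold minimum Z-score for a hit to be retained
#'   (default 1.5). The Z-score of a window is computed against the mean
#'   and standard deviation of all window scores of the same model over
#'   the entire scanned promoter set.
#' @param pseudocount probability added to every matrix cell (then
#'   renormalised) before taking log-odds (default 0.01).
#' @param scan_both_strands scan the reverse complement as well
#'   (default TRUE).
#' @return a list of class \code{scan_config}.
#' @export
scan_config <- function(z_threshold = 1.5, pseudocount = 0.01,
                        scan_both_strands = TRUE) {
  stopifnot(is.finite(z_threshold), pseudocount > 0)
  structure(list(z_threshold = z_threshold, pseudocount = pseudocount,
                 scan_both_strands = scan_both_strands),
            class = "scan_config")
}

.encode_dna <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  x  # N and any other symbol -> NA
}

.logodds <- function(model, pseudocount) {
  m <- model$matrix + pseudocount
  m <- sweep(m, 2, colSums(m), "/")
  log(m / model$background)
}

# Window scores of one log-odds matrix along one encoded sequence.
# Windows touching an ambiguous base (NA code) score -Inf.
.window_scores <- function(x, lom) {
  L <- ncol(lom)
  W <- length(x) - L + 1L
  if (W < 1L) return(numeric(0))
  s <- numeric(W)
  for (j in seq_len(L)) {
    s <- s + lom[, j][x[j:(j + W - 1L)]]
  }
  s[is.na(s)] <- -Inf
  s
}

.revcomp_lom <- function(lom) {
  # scoring the reverse complement of each window with the original matrix
  # equals scoring the forward window with the reverse-complemented matrix
  lom[c(4, 3, 2, 1), rev(seq_len(ncol(lom))), drop = FALSE]
}

#' Scan a promoter set with motif models and a Z-score filter
#'
#' Every window of each promoter (both strands by default) is scored with
#' each model's log-odds matrix. Per model, window scores are standardised
#' against the mean and standard deviation over the whole promoter set and
#' windows with Z at or above \code{z_threshold} are reported. Windows
#' containing an ambiguous base never score.
#'
#' @param promoters named character vector of promoter sequences (names are
#'   gene ids), e.g. from [extract_promoter_set()].
#' @param models list of \code{motif_model}s, e.g. [default_motif_bundle()].
#' @param config a [scan_config()].
#' @return data.frame of hits: gene_id, subfamily, family, token, offset
#'   (0-based window start, 5'->3' toward the gene), width, strand,
#'   score, zscore.
#' @export
scan_promoter_set <- function(promoters, models, config = scan_config()) {
  stopifnot(length(promoters) > 0L)
  enc <- lapply(promoters, .encode_dna)
  out <- vector("list", length(models))
  skipped <- character()
  for (k in seq_along(models)) {
    model <- models[[k]]
    lom <- .logodds(model, config$pseudocount)
    L <- ncol(lom)
    rc <- .revcomp_lom(lom)
    short <- vapply(enc, length, integer(1)) < L
    if (any(short)) skipped <- union(skipped, names(promoters)[short])
    fw <- lapply(enc[!short], .window_scores, lom = lom)
    rv <- if (config$scan_both_strands) {
      lapply(enc[!short], .window_scores, lom = rc)
    } else NULL
    pool <- unlist(c(fw, rv), use.names = FALSE)
    pool <- pool[is.finite(pool)]
    if (length(pool) < 2L) next
    mu <- mean(pool)
    sigma <- stats::sd(pool)
    if (sigma == 0) {
      warning("degenerate score distribution for model '", model$subfamily,
              "'; no hits emitted")
      next
    }
    emit <- function(scores_by_gene, strand) {
      res <- lapply(names(scores_by_gene), function(g) {
        z <- (scores_by_gene[[g]] - mu) / sigma
        i <- which(is.finite(z) & z >= config$z_threshold)
        if (length(i) == 0L) return(NULL)
        data.frame(gene_id = g, subfamily = model$subfamily,
                   family = model$family,
                   token = family_token(model$family),
                   offset = i - 1L, width = L, strand = strand,
                   score = scores_by_gene[[g]][i], zscore = z[i],
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, res)
    }
    out[[k]] <- rbind(emit(fw, "+"),
                      if (!is.null(rv)) emit(rv, "-"))
  }
  if (length(skipped)) {
    warning("promoter(s) shorter than a motif skipped for that model: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) " ...")
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) {
    hits <- data.frame(gene_id = character(), subfamily = character(),
                       family = character(), token = character(),
                       offset = integer(), width = integer(),
                       strand = character(), score = numeric(),
                       zscore = numeric(), stringsAsFactors = FALSE)
  }
  hits[order(hits$gene_id, hits$offset, hits$subfamily), , drop = FALSE]
}

#' Build the ordered TFBS architecture of one promoter
#'
#' Hits are ordered 5'->3' by offset. Overlapping hits (windows sharing at
#' least one bp) are resolved by keeping the hit with the higher Z-score;
#' ties break by leftmost offset, then by subfamily name. Tokens are TF
#' family display names (\code{AP2} for AP2/EREBP).
#'
#' @param hits data.frame of hits for a single gene, as produced by
#'   [scan_promoter_set()].
#' @param gene_id gene id; defaults to the one in \code{hits}.
#' @param keep_overlaps if TRUE, overlap resolution is skipped and every
#'   hit contributes a token.
#' @return object of class \code{tfbs_architecture}: list with gene_id,
#'   tokens, subfamilies, offsets, strands, zscores, display.
#' @export
build_architecture <- function(hits, gene_id = NULL, keep_overlaps = FALSE) {
  if (is.null(gene_id)) {
    gene_id <- if (nrow(hits) > 0L) unique(hits$gene_id) else NA_character_
  }
  if (nrow(hits) > 0L && length(unique(hits$gene_id)) != 1L) {
    stop("hits must belong to a single gene")
  }
  if (nrow(hits) > 0L && !keep_overlaps) {
    o <- order(-hits$zscore, hits$offset, hits$subfamily)
    h <- hits[o, , drop = FALSE]
    kept <- logical(nrow(h))
    starts <- integer(0); ends <- integer(0)
    for (i in seq_len(nrow(h))) {
      s <- h$offset[i]; e <- h$offset[i] + h$width[i] - 1L
      if (!any(s <= ends & e >= starts)) {
        kept[i] <- TRUE
        starts <- c(starts, s); ends <- c(ends, e)
      }
    }
    hits <- h[kept, , drop = FALSE]
  }
  hits <- hits[order(hits$offset, hits$subfamily), , drop = FALSE]
  structure(list(
    gene_id = gene_id,
    tokens = hits$token,
    subfamilies = hits$subfamily,
    offsets = hits$offset,
    strands = hits$strand,
    zscores = hits$zscore,
    display = paste(hits$token, collapse = "~")
  ), class = "tfbs_architecture")
}

#' Build architectures for every gene in a hit table
#'
#' @param hits data.frame from [scan_promoter_set()].
#' @param gene_ids genes to build; defaults to genes present in
#'   \code{hits}. Genes with no hits yield empty architectures.
#' @param keep_overlaps see [build_architecture()].
#' @return named list of \code{tfbs_architecture} objects.
#' @export
build_architecture_set <- function(hits, gene_ids = NULL,
                                   keep_overlaps = FALSE) {
  if (is.null(gene_ids)) gene_ids <- unique(hits$gene_id)
  out <- lapply(gene_ids, function(g) {
    build_architecture(hits[hits$gene_id == g, , drop = FALSE], gene_id = g,
                       keep_overlaps = keep_overlaps)
  })
  names(out) <- gene_ids
  out
}

#' @export
print.tfbs_architecture <- function(x, ...) {
  cat("tfbs_architecture", x$gene_id, ":",
      if (length(x$tokens)) x$display else "(no TFBS)", "\n")
  invisible(x)
}

#' Parse a printed architecture string
#'
#' Accepts strings as printed in the literature, e.g.
#' \code{"(WRKY~MYB ~ MYB ~ MYB ~ MYB ~ AP2)"}: surrounding parentheses and
#' whitespace around the \code{~} separators are tolerated.
#'
#' @param string architecture string.
#' @param gene_id optional gene id to attach.
#' @return a \code{tfbs_architecture} (no offsets/subfamilies).
#' @export
parse_architecture <- function(string, gene_id = NA_character_) {
  s <- gsub("[()\\s]", "", string, perl = TRUE)
  tokens <- if (nzchar(s)) strsplit(s, "~", fixed = TRUE)[[1]] else character()
  valid <- unname(.family_token_map)
  if (!all(tokens %in% valid)) {
    stop("unknown token(s): ",
         paste(setdiff(tokens, valid), collapse = ", "))
  }
  structure(list(gene_id = gene_id, tokens = tokens,
                 subfamilies = rep(NA_character_, length(tokens)),
                 offsets = rep(NA_integer_, length(tokens)),
                 strands = rep(NA_character_, length(tokens)),
                 zscores = rep(NA_real_, length(tokens)),
                 display = paste(tokens, collapse = "~")),
            class = "tfbs_architecture")
}

#' Tabulate TFBS counts per family and subfamily
#'
#' @param architectures list of \code{tfbs_architecture} objects.
#' @param species_of optional named character vector mapping gene_id to
#'   species; when given, per-species totals are included.
#' @return list with elements \code{per_gene} (data.frame gene_id,
#'   n_tfbs plus one column per family token), \code{family_totals},
#'   \code{subfamily_totals}, \code{genes_with_tfbs},
#'   \code{genes_without_tfbs}, \code{total_hits} (and \code{per_species}
#'   when \code{species_of} is supplied).
#' @export
count_families <- function(architectures, species_of = NULL) {
  toks <- unname(.family_token_map)
  per_gene <- do.call(rbind, lapply(architectures, function(a) {
    counts <- table(factor(a$tokens, levels = toks))
    cbind(data.frame(gene_id = a$gene_id, n_tfbs = length(a$tokens),
                     stringsAsFactors = FALSE),
          as.data.frame(t(as.matrix(counts))))
  }))
  rownames(per_gene) <- NULL
  all_tokens <- unlist(lapply(architectures, `[[`, "tokens"))
  all_sub <- unlist(lapply(architectures, `[[`, "subfamilies"))
  fam_tab <- as.data.frame(table(factor(all_tokens, levels = toks)),
                           stringsAsFactors = FALSE)
  names(fam_tab) <- c("token", "count")
  sub_tab <- as.data.frame(table(factor(all_sub[!is.na(all_sub)],
                                        levels = names(.tfbs_taxonomy))),
                           stringsAsFactors = FALSE)
  names(sub_tab) <- c("subfamily", "count")
  sub_tab$family <- classify_family(sub_tab$subfamily)
  out <- list(
    per_gene = per_gene,
    family_totals = fam_tab,
    subfamily_totals = sub_tab[, c("family", "subfamily", "count")],
    genes_with_tfbs = sum(per_gene$n_tfbs > 0),
    genes_without_tfbs = sum(per_gene$n_tfbs == 0),
    total_hits = length(all_tokens)
  )
  if (!is.null(species_of)) {
    sp <- unname(species_of[per_gene$gene_id])
    out$per_species <- do.call(rbind, lapply(sort(unique(sp)), function(s) {
      d <- per_gene[sp == s, , drop = FALSE]
      data.frame(species = s,
                 genes_with_tfbs = sum(d$n_tfbs > 0),
                 genes_without_tfbs = sum(d$n_tfbs == 0),
                 total_hits = sum(d$n_tfbs), stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Write architectures as a tab-separated file
#' @param architectures list of \code{tfbs_architecture}s.
#' @param path output file; one line per gene: gene_id TAB tok1~tok2~...
#' @return the path, invisibly.
#' @export
write_architectures <- function(architectures, path) {
  lines <- vapply(architectures, function(a) {
    paste0(a$gene_id, "\t", a$display)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an architecture file written by [write_architectures()]
#' @param path input file.
#' @return named list of \code{tfbs_architecture}s.
#' @export
read_architectures <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parse_architecture(if (length(parts) > 1L) parts[2] else "", parts[1])
  })
  names(out) <- vapply(out, `[[`, character(1), "gene_id")
  out
}
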