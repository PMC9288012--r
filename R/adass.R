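#' Architecture distance configuration
#'
#' @param w_inversion cost of an inversion event (a triplet matched in
#'   reversed token order), default 0.5.
#' @param w_duplication cost of a duplication event (a residual triplet
#'   identical to an already-matched triplet of its own architecture),
#'   default 0.25.
#' @param similarity_threshold distance at or below which two
#'   architectures count as similar (default 0.4).
#' @return list of class \code{distance_config}.
#' @export
distance_config <- function(w_inversion = 0.5, w_duplication = 0.25,
                            similarity_threshold = 0.4) {
  stopifnot(w_inversion >= 0, w_inversion <= 1,
            w_duplication >= 0, w_duplication <= 1,
            similarity_threshold > 0, similarity_threshold < 1)
  structure(list(w_inversion = w_inversion, w_duplication = w_duplication,
                 similarity_threshold = similarity_threshold),
            class = "distance_config")
}

#' Decompose an architecture into overlapping token triplets
#'
#' The token string is padded with a start sentinel \code{^} and an end
#' sentinel \code{$}; all overlapping windows of three consecutive padded
#' tokens are emitted left to right, so an architecture of n >= 1 tokens
#' yields exactly n triplets and an empty architecture yields none.
#'
#' @param arch a \code{tfbs_architecture} (or plain character vector of
#'   tokens).
#' @return list of class \code{triplet_set} with gene_id and triplets
#'   (character vector, tokens joined by \code{"|"}).
#' @export
make_triplets <- function(arch) {
  tokens <- if (inherits(arch, "tfbs_architecture")) arch$tokens else arch
  gene_id <- if (inherits(arch, "tfbs_architecture")) arch$gene_id else NA_character_
  n <- length(tokens)
  trip <- if (n == 0L) character(0) else {
    padded <- c("^", tokens, "$")
    vapply(seq_len(n), function(i) {
      paste(padded[i:(i + 2L)], collapse = "|")
    }, character(1))
  }
  structure(list(gene_id = gene_id, triplets = trip), class = "triplet_set")
}

.rev_triplet <- function(t) {
  vapply(strsplit(t, "|", fixed = TRUE), function(p) {
    paste(rev(p), collapse = "|")
  }, character(1))
}

#' Triplet-event distance between two architectures
#'
#' Both architectures are decomposed into token triplets and matched as
#' multisets in three passes: exact matches (cost 0), inversions (a
#' residual triplet whose reversed token order occurs in the other
#' residual set, cost \code{w_inversion} per matched pair), and
#' duplications (a residual triplet identical to an already-matched
#' triplet of its own set, cost \code{w_duplication} per copy). Residuals
#' left on each side after these passes are shuffled/unique events at cost
#' 1 each; the two sides' residual costs are aligned against each other,
#' so the larger side's residual cost is what remains unexplained. The
#' total event cost is normalised by the larger triplet count:
#' identical architectures score 0, architectures over disjoint token
#' alphabets score 1.
#'
#' @param a,b \code{triplet_set}s (see [make_triplets()]).
#' @param config a [distance_config()].
#' @return a distance in [0, 1]; two empty architectures score 0.
#' @export
adass_distance <- function(a, b, config = distance_config()) {
  ta <- a$triplets; tb <- b$triplets
  na <- length(ta); nb <- length(tb)
  if (na == 0L && nb == 0L) return(0)
  cA <- table(ta); cB <- table(tb)
  cA <- stats::setNames(as.integer(cA), names(cA))
  cB <- stats::setNames(as.integer(cB), names(cB))
  matchedA <- character(0); matchedB <- character(0)

  # pass 1: exact matches
  common <- intersect(names(cA), names(cB))
  if (length(common)) {
    m <- pmin(cA[common], cB[common])
    cA[common] <- cA[common] - m
    cB[common] <- cB[common] - m
    matchedA <- c(matchedA, common[m > 0])
    matchedB <- c(matchedB, common[m > 0])
  }

  # pass 2: inversions among residuals
  n_inv <- 0L
  for (t in sort(names(cA)[cA > 0])) {
    r <- .rev_triplet(t)
    if (!is.na(match(r, names(cB))) && cB[r] > 0L && cA[t] > 0L) {
      k <- min(cA[t], cB[r])
      cA[t] <- cA[t] - k
      cB[r] <- cB[r] - k
      n_inv <- n_inv + k
      matchedA <- c(matchedA, t)
      matchedB <- c(matchedB, r)
    }
  }

  # pass 3: duplications of already-matched triplets, per side
  dupA <- sum(cA[names(cA) %in% matchedA])
  dupB <- sum(cB[names(cB) %in% matchedB])
  remA <- sum(cA) - dupA
  remB <- sum(cB) - dupB

  cost <- config$w_inversion * n_inv +
    max(config$w_duplication * dupA + remA,
        config$w_duplication * dupB + remB)
  cost / max(na, nb)
}

#' Pairwise architecture distance matrix
#'
#' @param architectures list of \code{tfbs_architecture}s with unique gene
#'   ids.
#' @param config a [distance_config()].
#' @param species_of optional named character vector gene_id -> species;
#'   when given, matrix labels are \code{species_gene} and the species map
#'   is carried as an attribute.
#' @return symmetric numeric matrix with zero diagonal, entries in [0,1];
#'   attribute \code{species_of} maps labels to species when supplied.
#' @export
adass_distance_matrix <- function(architectures, config = distance_config(),
                                  species_of = NULL) {
  stopifnot(length(architectures) >= 2L)
  ids <- vapply(architectures, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  labels <- if (is.null(species_of)) ids else {
    paste(unname(species_of[ids]), ids, sep = "_")
  }
  trips <- lapply(architectures, make_triplets)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- adass_distance(trips[[i]], trips[[j]], config)
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  if (!is.null(species_of)) {
    attr(d, "species_of") <- stats::setNames(unname(species_of[ids]), labels)
  }
  d
}

#' Per-species-pair architecture similarity percentages
#'
#' For each ordered (query, target) species pair, the percentage of
#' cross-species gene pairs whose architecture distance is at or below the
#' similarity threshold.
#'
#' @param d distance matrix from [adass_distance_matrix()].
#' @param species_of named character vector label -> species; defaults to
#'   the matrix's \code{species_of} attribute.
#' @param config a [distance_config()].
#' @return data.frame query_species, target_species, n_pairs,
#'   pct_within_threshold.
#' @export
similarity_stats <- function(d, species_of = NULL,
                             config = distance_config()) {
  if (is.null(species_of)) species_of <- attr(d, "species_of")
  if (is.null(species_of)) stop("species_of is required")
  labs <- rownames(d)
  sp <- species_of[labs]
  if (anyNA(sp)) {
    stop("label(s) without species: ",
         paste(utils::head(labs[is.na(sp)], 5), collapse = ", "))
  }
  species <- sort(unique(sp))
  if (length(species) < 2L) stop("at least two species required")
  grid <- expand.grid(query_species = species, target_species = species,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$query_species != grid$target_species, , drop = FALSE]
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    qi <- which(sp == grid$query_species[r])
    ti <- which(sp == grid$target_species[r])
    vals <- as.vector(d[qi, ti, drop = FALSE])
    data.frame(query_species = grid$query_species[r],
               target_species = grid$target_species[r],
               n_pairs = length(vals),
               pct_within_threshold =
                 100 * mean(vals <= config$similarity_threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res[order(res$query_species, res$target_species), , drop = FALSE]
}

#' Write a distance matrix in PHYLIP square format (and TSV)
#'
#' @param d distance matrix.
#' @param path output file (PHYLIP layout, label width 10); a sibling
#'   \code{<path>.tsv} carries full labels.
#' @return the path, invisibly.
#' @export
write_phylip <- function(d, path) {
  labs <- rownames(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    lab <- substr(labs[i], 1, 10)
    writeLines(paste0(sprintf("%-10s", lab),
                      paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  utils::write.table(
    data.frame(label = labs, d, check.names = FALSE),
    paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
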