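#' Homology search configuration
#'
#' @param evalue_threshold maximum E-value for a pair to be kept
#'   (default 1e-5).
#' @param substitution_matrix scoring matrix name (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties (defaults 11, 1).
#' @param effective_db_size search-space size n for the Karlin-Altschul
#'   E-value approximation E = K*m*n*exp(-lambda*S); defaults to the total
#'   residue count of the sequence set at alignment time.
#' @param lambda,K Karlin-Altschul parameters; defaults are the standard
#'   gapped BLOSUM62/(11,1) values (0.267, 0.041).
#' @param seed_length k-mer length of the exact-seed prefilter used by
#'   [align_all_vs_all()]; pairs sharing no k-mer are skipped. Set to 0 to
#'   align every pair.
#' @return list of class \code{homology_config}.
#' @export
homology_config <- function(evalue_threshold = 1e-5,
                            substitution_matrix = "BLOSUM62",
                            gap_open = 11, gap_extend = 1,
                            effective_db_size = NULL,
                            lambda = 0.267, K = 0.041,
                            seed_length = 5L) {
  stopifnot(evalue_threshold > 0, gap_open >= 0, gap_extend >= 0,
            lambda > 0, K > 0)
  structure(list(evalue_threshold = evalue_threshold,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 effective_db_size = effective_db_size,
                 lambda = lambda, K = K,
                 seed_length = as.integer(seed_length)),
            class = "homology_config")
}

.canonical_pairs <- function(df) {
  # order each pair lexicographically, drop self-hits, keep best E-value
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]
  df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$gene_a, df$gene_b, df$evalue, -df$bitscore), , drop = FALSE]
  df <- df[!duplicated(df[, c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Parse BLAST tabular (outfmt 6) output into homolog pairs
#'
#' Expects the standard 12 columns (query, subject, identity, length,
#' mismatches, gapopens, qstart, qend, sstart, send, evalue, bitscore).
#' Self-hits are removed, reciprocal hits are collapsed onto a
#' lexicographically ordered pair keeping the lowest E-value, and only
#' pairs with E-value at or below the configured threshold are returned.
#'
#' @param path tabular alignment file; an empty file yields an empty table.
#' @param config a [homology_config()].
#' @return data.frame with columns gene_a, gene_b, evalue, bitscore.
#' @export
parse_alignment_table <- function(path, config = homology_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("malformed alignment row at line ", which(nf != 12L)[1],
         ": expected 12 tab-separated columns, got ", nf[nf != 12L][1])
  }
  m <- do.call(rbind, fields)
  ev <- suppressWarnings(as.numeric(m[, 11]))
  bs <- suppressWarnings(as.numeric(m[, 12]))
  if (anyNA(ev) || anyNA(bs)) {
    stop("malformed alignment row at line ",
         which(is.na(ev) | is.na(bs))[1], ": non-numeric evalue/bitscore")
  }
  df <- data.frame(gene_a = m[, 1], gene_b = m[, 2], evalue = ev,
                   bitscore = bs, stringsAsFactors = FALSE)
  df <- .canonical_pairs(df)
  df[df$evalue <= config$evalue_threshold, , drop = FALSE]
}

.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' All-vs-all protein homology with local alignment
#'
#' Smith-Waterman local alignment (affine gaps, BLOSUM62 by default) over
#' every sequence pair, with an exact k-mer seed prefilter. Alignment
#' scores are converted to approximate E-values with the Karlin-Altschul
#' formula E = K*m*n*exp(-lambda*S), where m is the shorter sequence
#' length and n the effective database size; pairs at or below the E-value
#' threshold are returned.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param config a [homology_config()].
#' @param within_species_only optional: if given a named species vector
#'   (gene_id -> species), restricts output to within-species (TRUE) or
#'   cross-species (FALSE) pairs; NULL keeps all pairs.
#' @param species_of named character vector mapping gene_id to species,
#'   required when \code{within_species_only} is not NULL.
#' @return data.frame gene_a, gene_b, evalue, bitscore (bitscore column
#'   holds the raw Smith-Waterman score).
#' @export
align_all_vs_all <- function(proteins, config = homology_config(),
                             within_species_only = NULL, species_of = NULL) {
  stopifnot(length(proteins) > 0L, !is.null(names(proteins)))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", proteins)
  if (any(bad)) {
    stop("non-amino-acid characters in sequence(s): ",
         paste(utils::head(names(proteins)[bad], 5), collapse = ", "))
  }
  ids <- sort(names(proteins))
  proteins <- proteins[ids]
  dbsize <- if (is.null(config$effective_db_size)) {
    sum(nchar(proteins))
  } else config$effective_db_size

  cand <- .candidate_pairs(proteins, config$seed_length)
  if (!is.null(within_species_only)) {
    stopifnot(!is.null(species_of))
    same <- species_of[cand$a] == species_of[cand$b]
    cand <- cand[if (within_species_only) same else !same, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  utils::data(list = config$substitution_matrix, package = "Biostrings",
              envir = environment())
  submat <- get(config$substitution_matrix, envir = environment())
  scores <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(proteins[cand$a]),
    subject = Biostrings::AAStringSet(proteins[cand$b]),
    type = "local", substitutionMatrix = submat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend,
    scoreOnly = TRUE)
  m <- pmin(nchar(proteins[cand$a]), nchar(proteins[cand$b]))
  evalue <- config$K * m * dbsize * exp(-config$lambda * scores)
  df <- data.frame(gene_a = cand$a, gene_b = cand$b, evalue = evalue,
                   bitscore = scores, stringsAsFactors = FALSE)
  df <- .canonical_pairs(df)
  df[df$evalue <= config$evalue_threshold, , drop = FALSE]
}

# Candidate pairs sharing at least one exact k-mer (k = 0 -> all pairs).
.candidate_pairs <- function(proteins, k) {
  ids <- names(proteins)
  n <- length(ids)
  if (k <= 0L) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
                      stringsAsFactors = FALSE))
  }
  kmers <- lapply(proteins, .kmer_set, k = k)
  bucket <- split(rep(seq_len(n), lengths(kmers)),
                  unlist(kmers, use.names = FALSE))
  pairs <- unlist(lapply(bucket, function(ix) {
    if (length(ix) < 2L) return(NULL)
    cmb <- utils::combn(sort(ix), 2L)
    (cmb[1, ] - 1L) * n + cmb[2, ]  # encode pair as single integer
  }), use.names = FALSE)
  pairs <- unique(pairs)
  if (length(pairs) == 0L) {
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  }
  i <- (pairs - 1L) %/% n + 1L
  j <- (pairs - 1L) %% n + 1L
  j[j == 0L] <- n
  data.frame(a = ids[i], b = ids[j], stringsAsFactors = FALSE)
}

#' Write homolog pairs as TSV
#' @param pairs data.frame from [align_all_vs_all()] or
#'   [parse_alignment_table()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_homolog_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read homolog pairs written by [write_homolog_pairs()]
#' @param path input TSV.
#' @return data.frame gene_a, gene_b, evalue, bitscore.
#' @export
read_homolog_pairs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
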