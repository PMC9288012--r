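#' Read a genome: sequence, gene models and proteins
#'
#' Loads a nucleotide FASTA, a GFF3-style annotation and a protein FASTA
#' into a single annotation object. Gene models are assigned a 0-based
#' \code{rank} along each chromosome ordered by ascending start coordinate
#' (ties broken by gene id), which downstream collinearity chaining relies
#' on. Coordinates are 1-based inclusive throughout, following GFF3.
#'
#' @param fasta_path path to the genome FASTA (chromosome sequences).
#' @param gff_path path to the annotation; only records of type
#'   \code{feature_type} are used and the gene identifier is taken from the
#'   \code{id_attribute} key of the attributes column.
#' @param protein_fasta_path path to the protein FASTA; sequence names must
#'   match gene ids. Genes without a protein are retained and flagged.
#' @param species species label stored on the annotation and its genes.
#' @param feature_type GFF3 feature type to keep (default \code{"gene"}).
#' @param id_attribute attribute key holding the gene id (default \code{"ID"}).
#' @return an object of class \code{genome_annotation}: a list with elements
#'   \code{species}, \code{sequences} (a \code{DNAStringSet}), \code{genes}
#'   (a data.frame with columns gene_id, species, chromosome, start, end,
#'   strand, rank, has_protein) and \code{proteins} (named character vector).
#' @export
read_genome <- function(fasta_path, gff_path, protein_fasta_path, species,
                        feature_type = "gene", id_attribute = "ID") {
  for (p in c(fasta_path, gff_path, protein_fasta_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- as.character(S4Vectors::mcols(gr)[[id_attribute]])
  if (anyNA(ids) || any(ids == "")) {
    stop("annotation record without a '", id_attribute, "' attribute")
  }
  genes <- data.frame(
    gene_id    = ids,
    species    = species,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start      = GenomicRanges::start(gr),
    end        = GenomicRanges::end(gr),
    strand     = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  prot <- Biostrings::readAAStringSet(protein_fasta_path)
  proteins <- as.character(prot)
  names(proteins) <- sub("\\s.*$", "", names(prot))
  genome_annotation(species, seqs, genes, proteins)
}

#' Construct and validate a genome annotation object
#'
#' @param species species label.
#' @param sequences \code{DNAStringSet} (or named character vector) of
#'   chromosome sequences.
#' @param genes data.frame with columns gene_id, chromosome, start, end,
#'   strand; \code{rank} is (re)computed here.
#' @param proteins named character vector of protein sequences.
#' @return a \code{genome_annotation} object.
#' @export
genome_annotation <- function(species, sequences, genes, proteins = character()) {
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  stopifnot(is.data.frame(genes))
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  bad <- !(genes$chromosome %in% names(sequences))
  if (any(bad)) {
    stop("gene(s) reference unknown chromosome: ",
         paste(genes$gene_id[bad], collapse = ", "))
  }
  if (any(genes$start > genes$end)) {
    stop("malformed coordinates (start > end) for gene(s): ",
         paste(genes$gene_id[genes$start > genes$end], collapse = ", "))
  }
  lens <- Biostrings::width(sequences)[match(genes$chromosome, names(sequences))]
  if (any(genes$end > lens)) {
    stop("gene(s) extend past chromosome end: ",
         paste(genes$gene_id[genes$end > lens], collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  genes$species <- species
  genes$rank <- NA_integer_
  for (chr in unique(genes$chromosome)) {
    i <- which(genes$chromosome == chr)
    ord <- order(genes$start[i], genes$gene_id[i])
    genes$rank[i[ord]] <- seq_along(i) - 1L
  }
  genes$has_protein <- genes$gene_id %in% names(proteins)
  structure(
    list(species = species, sequences = sequences, genes = genes,
         proteins = proteins),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", x$species, "-",
      length(x$sequences), "chromosome(s),",
      nrow(x$genes), "gene(s),",
      length(x$proteins), "protein(s)\n")
  invisible(x)
}

#' Promoter extraction configuration
#'
#' @param upstream_length promoter window size in bp upstream of the
#'   annotated gene start (default 1000).
#' @return a list of class \code{promoter_config}.
#' @export
promoter_config <- function(upstream_length = 1000L) {
  upstream_length <- as.integer(upstream_length)
  stopifnot(length(upstream_length) == 1L, upstream_length >= 1L)
  structure(list(upstream_length = upstream_length), class = "promoter_config")
}

#' Extract the upstream promoter of one gene
#'
#' For a plus-strand gene the window is \code{[start - L, start - 1]}
#' (1-based inclusive), truncated at position 1; for a minus-strand gene it
#' is the reverse complement of \code{[end + 1, end + L]}, truncated at the
#' chromosome end. The returned string therefore always reads 5'->3' toward
#' the gene. A gene flush against the chromosome boundary yields an empty
#' string with a warning, not an error.
#'
#' @param annotation a \code{genome_annotation}.
#' @param gene_id gene to extract.
#' @param config a \code{promoter_config}.
#' @return a single nucleotide string (possibly empty).
#' @export
extract_promoter <- function(annotation, gene_id, config = promoter_config()) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown gene_id: ", gene_id)
  L <- config$upstream_length
  chr <- annotation$sequences[[g$chromosome]]
  if (g$strand == "+") {
    from <- max(1L, g$start - L)
    to <- g$start - 1L
    if (to < from) {
      warning("empty promoter for gene at chromosome start: ", gene_id)
      return("")
    }
    as.character(Biostrings::subseq(chr, from, to))
  } else {
    from <- g$end + 1L
    to <- min(length(chr), g$end + L)
    if (to < from) {
      warning("empty promoter for gene at chromosome end: ", gene_id)
      return("")
    }
    as.character(Biostrings::reverseComplement(Biostrings::subseq(chr, from, to)))
  }
}

#' Extract promoters for a set of genes
#'
#' @param annotation a \code{genome_annotation}.
#' @param gene_ids genes to extract; defaults to all genes.
#' @param config a \code{promoter_config}.
#' @return named character vector of promoter sequences.
#' @export
extract_promoter_set <- function(annotation, gene_ids = NULL,
                                 config = promoter_config()) {
  if (is.null(gene_ids)) gene_ids <- annotation$genes$gene_id
  out <- vapply(gene_ids, extract_promoter, character(1),
                annotation = annotation, config = config)
  names(out) <- gene_ids
  out
}

#' Write promoters as FASTA
#' @param promoters named character vector from [extract_promoter_set()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  promoters <- promoters[nchar(promoters) > 0L]
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(promoters), path)
  invisible(path)
}
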