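
# TF subfamily -> family taxonomy. 19 cis-element subfamilies across 10
# transcription factor families commonly implicated in abiotic stress
# response in plants. Note the bHLH G-box and the bZIP G-box variants are
# distinct subfamilies (G_box vs G_box1/G_box2).
.tfbs_taxonomy <- c(
  Myb_box1 = "MYB", Myb_box2 = "MYB", Myb_box3 = "MYB",
  Myb_box4 = "MYB", Myb_box5 = "MYB",
  G_box = "bHLH", N_box = "bHLH",
  DREB = "AP2/EREBP", GCC_box = "AP2/EREBP",
  W_box = "WRKY",
  G_box1 = "bZIP", G_box2 = "bZIP", C_ABRE = "bZIP", G_ABRE = "bZIP",
  AuxRE = "ARF",
  Nac_box = "NAC",
  HSE = "HSF",
  HBE = "HB",
  ABRE = "ABI3/VP1"
)

# Display tokens used in architecture strings. AP2/EREBP is conventionally
# printed as "AP2"; all other families print under their own name.
.family_token_map <- c(
  MYB = "MYB", bHLH = "bHLH", "AP2/EREBP" = "AP2", WRKY = "WRKY",
  bZIP = "bZIP", ARF = "ARF", NAC = "NAC", HSF = "HSF", HB = "HB",
  "ABI3/VP1" = "ABI3/VP1"
)

# Consensus sequences the default matrix bundle is derived from. These are
# plausible plant cis-element cores (DRE/CRT, GCC-box, W-box, G-box, ABRE,
# AuxRE, HSE, ...); they stand in for trained binding-site models, which
# are not redistributable.
.default_consensus <- c(
  Myb_box1 = "AAACCA",
  Myb_box2 = "TAACTG",
  Myb_box3 = "CAGTTA",
  Myb_box4 = "AACTAAC",
  Myb_box5 = "CCAACC",
  G_box    = "CACGTG",
  N_box    = "CACGAG",
  DREB     = "ACCGACAT",
  GCC_box  = "AGCCGCC",
  W_box    = "TTGACC",
  G_box1   = "ACACGTGG",
  G_box2   = "TGACGTCA",
  C_ABRE   = "CGCGTGTC",
  G_ABRE   = "CACGTGTC",
  AuxRE    = "TGTCTC",
  Nac_box  = "ACACGCAA",
  HSE      = "TTCTAGAA",
  HBE      = "CAATTATTG",
  ABRE     = "TACGTGTC"
)

#' Map a TF subfamily to its family
#'
#' @param subfamily a subfamily name (e.g. \code{"W_box"}, \code{"DREB"}).
#' @return the family name (e.g. \code{"WRKY"}, \code{"AP2/EREBP"}).
#' @export
classify_family <- function(subfamily) {
  fam <- .tfbs_taxonomy[subfamily]
  if (anyNA(fam)) {
    stop("unknown subfamily: ",
         paste(subfamily[is.na(fam)], collapse = ", "),
         "; valid subfamilies: ", paste(names(.tfbs_taxonomy), collapse = ", "))
  }
  unname(fam)
}

#' Architecture display token for a TF family
#' @param family family name as returned by [classify_family()].
#' @return the token used in architecture strings (\code{"AP2"} for
#'   AP2/EREBP, otherwise the family name).
#' @export
family_token <- function(family) {
  tok <- .family_token_map[family]
  if (anyNA(tok)) stop("unknown family: ", paste(family[is.na(tok)], collapse = ", "))
  unname(tok)
}

#' TF family / subfamily taxonomy table
#' @return data.frame with columns subfamily, family, token.
#' @export
tfbs_taxonomy <- function() {
  data.frame(
    subfamily = names(.tfbs_taxonomy),
    family = unname(.tfbs_taxonomy),
    token = unname(.family_token_map[.tfbs_taxonomy]),
    stringsAsFactors = FALSE
  )
}

.motif_model <- function(subfamily, family, matrix, background = rep(0.25, 4)) {
  rownames(matrix) <- c("A", "C", "G", "T")
  if (ncol(matrix) < 4L) stop("motif '", subfamily, "' shorter than 4 columns")
  csum <- colSums(matrix)
  if (any(abs(csum - 1) > 1e-9)) {
    stop("motif '", subfamily, "': column(s) ",
         paste(which(abs(csum - 1) > 1e-9), collapse = ","),
         " do not sum to 1")
  }
  if (!family %in% names(.family_token_map)) {
    stop("unknown family name: ", family)
  }
  if (subfamily %in% names(.tfbs_taxonomy) &&
      .tfbs_taxonomy[[subfamily]] != family) {
    stop("subfamily '", subfamily, "' belongs to family '",
         .tfbs_taxonomy[[subfamily]], "', not '", family, "'")
  }
  names(background) <- c("A", "C", "G", "T")
  structure(list(subfamily = subfamily, family = family, matrix = matrix,
                 background = background),
            class = "motif_model")
}

.consensus_matrix <- function(consensus, major = 0.91) {
  bases <- strsplit(consensus, "")[[1]]
  minor <- (1 - major) / 3
  m <- matrix(minor, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- major
  m
}

#' The default motif model bundle
#'
#' Consensus-derived position weight matrices for all 19 subfamilies of the
#' taxonomy (10 TF families). Each column places probability 0.91 on the
#' consensus base and 0.03 on each alternative.
#'
#' @return list of \code{motif_model} objects.
#' @export
default_motif_bundle <- function() {
  lapply(names(.default_consensus), function(sf) {
    .motif_model(sf, .tfbs_taxonomy[[sf]], .consensus_matrix(.default_consensus[[sf]]))
  })
}

#' Consensus string of a motif model
#' @param model a \code{motif_model}.
#' @return the per-column argmax base string.
#' @export
motif_consensus <- function(model) {
  paste(rownames(model$matrix)[apply(model$matrix, 2, which.max)], collapse = "")
}

#' Read motif models from a text file
#'
#' The format is plain text: for each model a header line
#' \code{subfamily family length} followed by \code{length} rows of four
#' whitespace-separated probabilities (A C G T order). Blank lines and lines
#' starting with \code{#} are ignored.
#'
#' @param path motif file.
#' @return list of \code{motif_model} objects.
#' @export
load_motifs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  models <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(hdr) != 3L) {
      stop("line ", lineno[i], ": expected header 'subfamily family length'")
    }
    L <- suppressWarnings(as.integer(hdr[3]))
    if (is.na(L) || L < 1L) stop("line ", lineno[i], ": bad motif length")
    if (i + L > length(lines)) stop("line ", lineno[i], ": truncated matrix")
    m <- matrix(NA_real_, nrow = 4, ncol = L)
    for (j in seq_len(L)) {
      row <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + j]), "\\s+")[[1]]))
      if (length(row) != 4L || anyNA(row)) {
        stop("line ", lineno[i + j], ": expected 4 probabilities")
      }
      m[, j] <- row
    }
    models[[length(models) + 1L]] <- tryCatch(
      .motif_model(hdr[1], hdr[2], m),
      error = function(e) stop("line ", lineno[i], ": ", conditionMessage(e))
    )
    i <- i + L + 1L
  }
  models
}

#' Write motif models to the text format read by [load_motifs()]
#' @param models list of \code{motif_model} objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_motifs <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    writeLines(paste(m$subfamily, m$family, ncol(m$matrix)), con)
    writeLines(apply(m$matrix, 2, function(col) {
      paste(sprintf("%.17g", col), collapse = " ")
    }), con)
  }
  invisible(path)
}
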