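#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining (Saitou-Nei Q-criterion with the standard
#' branch-length formulas), re-implemented so that tie-breaking and
#' negative-branch handling are deterministic and documented: ties in the
#' Q minimisation resolve to the smallest (row, column) index pair, and a
#' negative branch length is clamped to zero with the deficit transferred
#' to its sibling so the pair's path length is preserved. For additive
#' input matrices the generating topology and branch lengths are
#' recovered exactly.
#'
#' @param d symmetric distance matrix with labelled rows/columns, at
#'   least 3 taxa.
#' @return an object of class \code{phylo} (unrooted, with branch
#'   lengths).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  fmt <- function(x) sprintf("%.15g", x)
  repr <- rownames(d)
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    mn <- min(Q)
    cand <- which(Q == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_repr <- paste0("(", repr[i], ":", fmt(li), ",",
                       repr[j], ":", fmt(lj), ")")
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    repr <- c(repr[keep], new_repr)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  x1 <- max(x1, 0); x2 <- max(x2, 0); x3 <- max(x3, 0)
  newick <- paste0("(", repr[1], ":", fmt(x1), ",",
                   repr[2], ":", fmt(x2), ",",
                   repr[3], ":", fmt(x3), ");")
  ape::read.tree(text = newick)
}

#' Write a tree as Newick
#' @param tree a \code{phylo} object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
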