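# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# reverse complement by table lookup, character by character
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# quadratic-time Gotoh local alignment (affine gaps, same convention as
# the package: a gap of length k costs open + k * extend)
oracle_sw_score <- function(a, b, submat, open = 11, extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)   # best ending in a match
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (vertical)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i - 1, j - 1] + s,
                     Y[i - 1, j - 1] + s)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# exhaustive enumeration of all monotone gap-bounded chains through dots;
# returns the maximum score (anchors - 0.1 * total intervening-rank gap)
oracle_best_chain_score <- function(ra, rb, orientation, max_gap) {
  sb <- if (orientation == "same") rb else -rb
  n <- length(ra)
  best <- -Inf
  extend <- function(last, score, gaps) {
    best <<- max(best, score - 0.1 * gaps)
    for (k in seq_len(n)) {
      da <- ra[k] - ra[last]; db <- sb[k] - sb[last]
      if (da >= 1 && db >= 1 && da - 1 <= max_gap && db - 1 <= max_gap) {
        extend(k, score + 1, gaps + (da - 1) + (db - 1))
      }
    }
  }
  for (s in seq_len(n)) extend(s, 1, 0)
  best
}

# exhaustive minimum-cost triplet matching: enumerates every choice of
# exact-match counts and inversion-match counts, assigns duplications
# greedily (always cheaper than a shuffle when w_dup <= 1), and applies
# the same cost combination as the package definition
oracle_adass <- function(ta, tb, w_inv = 0.5, w_dup = 0.25) {
  na <- length(ta); nb <- length(tb)
  if (na == 0 && nb == 0) return(0)
  revt <- function(t) vapply(strsplit(t, "|", fixed = TRUE),
                             function(p) paste(rev(p), collapse = "|"),
                             character(1))
  cA0 <- table(ta); cB0 <- table(tb)
  types_ex <- intersect(names(cA0), names(cB0))
  # inversion-capable ordered type pairs (A type -> B type = its reverse)
  inv_pairs <- list()
  for (t in names(cA0)) {
    r <- revt(t)
    if (r %in% names(cB0)) inv_pairs[[length(inv_pairs) + 1]] <- c(t, r)
  }
  best <- Inf
  eval_choice <- function(ex_counts, inv_counts) {
    cA <- as.vector(cA0); names(cA) <- names(cA0)
    cB <- as.vector(cB0); names(cB) <- names(cB0)
    mA <- character(0); mB <- character(0)
    for (k in seq_along(types_ex)) {
      t <- types_ex[k]; m <- ex_counts[k]
      if (m > min(cA[t], cB[t])) return(invisible())
      cA[t] <- cA[t] - m; cB[t] <- cB[t] - m
      if (m > 0) { mA <- c(mA, t); mB <- c(mB, t) }
    }
    n_inv <- 0
    for (k in seq_along(inv_pairs)) {
      p <- inv_pairs[[k]]; m <- inv_counts[k]
      if (m == 0) next
      if (m > cA[p[1]] || m > cB[p[2]]) return(invisible())
      cA[p[1]] <- cA[p[1]] - m; cB[p[2]] <- cB[p[2]] - m
      n_inv <- n_inv + m
      mA <- c(mA, p[1]); mB <- c(mB, p[2])
    }
    dupA <- sum(cA[names(cA) %in% mA]); dupB <- sum(cB[names(cB) %in% mB])
    remA <- sum(cA) - dupA; remB <- sum(cB) - dupB
    cost <- w_inv * n_inv + max(w_dup * dupA + remA, w_dup * dupB + remB)
    best <<- min(best, cost / max(na, nb))
  }
  ex_grid <- lapply(types_ex, function(t) 0:min(cA0[t], cB0[t]))
  inv_grid <- lapply(inv_pairs, function(p) 0:min(cA0[p[1]], cB0[p[2]]))
  ex_combos <- if (length(ex_grid)) do.call(expand.grid, ex_grid) else
    data.frame(row.names = 1)
  inv_combos <- if (length(inv_grid)) do.call(expand.grid, inv_grid) else
    data.frame(row.names = 1)
  for (i in seq_len(nrow(ex_combos))) {
    for (j in seq_len(nrow(inv_combos))) {
      eval_choice(as.integer(ex_combos[i, ]), as.integer(inv_combos[j, ]))
    }
  }
  best
}

# direct per-window PWM log-odds scorer over a character promoter
oracle_window_scores <- function(promoter, matrix, pseudocount = 0.01,
                                 background = rep(0.25, 4)) {
  m <- sweep(matrix + pseudocount, 2, colSums(matrix + pseudocount), "/")
  lom <- log(m / background)
  rownames(lom) <- c("A", "C", "G", "T")
  L <- ncol(lom)
  chars <- strsplit(promoter, "")[[1]]
  n <- length(chars)
  vapply(seq_len(n - L + 1), function(s) {
    w <- chars[s:(s + L - 1)]
    if (any(!w %in% rownames(lom))) return(-Inf)
    sum(vapply(seq_len(L), function(j) lom[w[j], j], numeric(1)))
  }, numeric(1))
}
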