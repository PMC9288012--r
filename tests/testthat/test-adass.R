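arch <- function(tokens, id = "g") {
  parse_architecture(paste(tokens, collapse = "~"), id)
}

test_that("triplet decomposition pads with sentinels", {
  t1 <- make_triplets(arch("MYB"))
  expect_equal(t1$triplets, "^|MYB|$")
  t3 <- make_triplets(arch(c("WRKY", "MYB", "AP2")))
  expect_equal(t3$triplets,
               c("^|WRKY|MYB", "WRKY|MYB|AP2", "MYB|AP2|$"))
  expect_length(make_triplets(arch(character()))$triplets, 0L)
  # n tokens -> n triplets
  for (n in 1:6) {
    expect_length(make_triplets(arch(rep("MYB", n)))$triplets, n)
  }
})

test_that("distance endpoints: identical 0, token-disjoint 1", {
  a <- make_triplets(arch(c("WRKY", "MYB", "MYB", "MYB", "MYB", "AP2")))
  expect_equal(adass_distance(a, a), 0)
  b1 <- make_triplets(arch(c("MYB", "WRKY", "MYB", "WRKY")))
  b2 <- make_triplets(arch(c("NAC", "HSF", "NAC", "HSF")))
  expect_equal(adass_distance(b1, b2), 1)
  # both empty -> 0 by convention; empty vs non-empty -> 1
  e <- make_triplets(arch(character()))
  expect_equal(adass_distance(e, e), 0)
  expect_equal(adass_distance(e, b1), 1)
})

test_that("greedy multiset matching equals the exhaustive oracle", {
  set.seed(77)
  alphabet <- c("MYB", "AP2", "WRKY")
  for (i in 1:200) {
    na <- sample(0:6, 1); nb <- sample(1:6, 1)
    a <- make_triplets(arch(sample(alphabet, na, replace = TRUE), "a"))
    b <- make_triplets(arch(sample(alphabet, nb, replace = TRUE), "b"))
    expect_equal(adass_distance(a, b),
                 oracle_adass(a$triplets, b$triplets),
                 tolerance = 1e-12)
  }
})

test_that("distance is symmetric, bounded, and zero on the diagonal", {
  set.seed(31)
  alphabet <- c("MYB", "AP2", "WRKY", "NAC", "bHLH")
  for (i in 1:50) {
    a <- make_triplets(arch(sample(alphabet, sample(1:8, 1), TRUE), "a"))
    b <- make_triplets(arch(sample(alphabet, sample(1:8, 1), TRUE), "b"))
    d1 <- adass_distance(a, b); d2 <- adass_distance(b, a)
    expect_equal(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
    expect_equal(adass_distance(a, a), 0)
  }
})

test_that("unit weights reduce the distance to a pure triplet overlap form", {
  set.seed(13)
  cfg1 <- distance_config(w_inversion = 1, w_duplication = 1)
  alphabet <- c("MYB", "AP2", "WRKY", "NAC")
  for (i in 1:50) {
    ta <- make_triplets(arch(sample(alphabet, sample(1:7, 1), TRUE), "a"))
    tb <- make_triplets(arch(sample(alphabet, sample(1:7, 1), TRUE), "b"))
    cA <- table(ta$triplets); cB <- table(tb$triplets)
    common <- intersect(names(cA), names(cB))
    inter <- sum(pmin(cA[common], cB[common]))
    want <- 1 - inter / max(length(ta$triplets), length(tb$triplets))
    expect_equal(adass_distance(ta, tb, cfg1), want, tolerance = 1e-12)
  }
})

test_that("inversions and duplications cost less than full mismatches", {
  # reversed token order is matched as an inversion at half cost
  a <- make_triplets(arch(c("MYB", "AP2", "WRKY")))
  b <- make_triplets(arch(c("WRKY", "AP2", "MYB")))
  full <- adass_distance(a, make_triplets(arch(c("NAC", "HSF", "NAC"))))
  expect_lt(adass_distance(a, b), full)
  # extra repeats of a matched triplet cost the duplication weight:
  # the tandem expansion leaves two residual triplets identical to
  # already-matched ones -> cost 2 * 0.25 over 6 triplets
  x <- make_triplets(arch(rep(c("MYB", "AP2"), 2)))
  y <- make_triplets(arch(rep(c("MYB", "AP2"), 3)))
  expect_equal(adass_distance(x, y), 0.5 / 6)
})

test_that("distance matrices are symmetric, zero-diagonal and order-invariant", {
  archs <- list(arch(c("MYB", "AP2"), "g1"), arch(c("MYB", "AP2"), "g2"),
                arch(c("MYB", "AP2"), "g3"), arch(c("WRKY", "NAC"), "g4"))
  d <- adass_distance_matrix(archs)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(unname(d["g1", c("g2", "g3")]), c(0, 0))
  expect_true(all(d >= 0 & d <= 1))
  # permuting input order permutes labels but not values
  d2 <- adass_distance_matrix(archs[c(3, 1, 4, 2)])
  expect_equal(d2[rownames(d), colnames(d)], d)
  expect_error(adass_distance_matrix(list(arch("MYB", "g1"),
                                          arch("AP2", "g1"))),
               "duplicate gene ids")
})

test_that("similarity percentages behave at the extremes and are monotone", {
  archs <- list(arch(c("MYB", "AP2"), "a1"), arch(c("MYB", "AP2"), "a2"),
                arch(c("MYB", "AP2"), "b1"), arch(c("MYB", "AP2"), "b2"))
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  d0 <- adass_distance_matrix(archs, species_of = sp)
  st <- similarity_stats(d0)
  expect_equal(st$pct_within_threshold, rep(100, 2))
  expect_equal(st$n_pairs, rep(4, 2))
  # all-different architectures: 0%
  archs1 <- list(arch(c("MYB", "MYB"), "a1"), arch(c("MYB", "MYB"), "a2"),
                 arch(c("WRKY", "NAC"), "b1"), arch(c("NAC", "WRKY"), "b2"))
  d1 <- adass_distance_matrix(archs1, species_of = sp)
  expect_equal(similarity_stats(d1)$pct_within_threshold, rep(0, 2))
  # threshold sweep on the fixture-free random case: never decreasing
  set.seed(55)
  alphabet <- c("MYB", "AP2", "WRKY", "NAC")
  archs2 <- lapply(1:12, function(i) {
    arch(sample(alphabet, sample(2:8, 1), TRUE), sprintf("g%02d", i))
  })
  sp2 <- stats::setNames(rep(c("A", "B", "C"), each = 4),
                         sprintf("g%02d", 1:12))
  dm <- adass_distance_matrix(archs2, species_of = sp2)
  prev <- NULL
  for (thr in seq(0.1, 0.9, by = 0.1)) {
    cur <- similarity_stats(dm, config = distance_config(
      similarity_threshold = thr))$pct_within_threshold
    if (!is.null(prev)) expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})
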