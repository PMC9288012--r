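blast_row <- function(q, s, ev, bits = 100) {
  paste(q, s, 98.0, 100, 2, 0, 1, 100, 1, 100,
        format(ev, scientific = TRUE), bits, sep = "\t")
}

test_that("alignment table parsing filters, dedups and validates", {
  f <- withr::local_tempfile(lines = c(
    blast_row("g1", "g2", 1e-6),
    blast_row("g3", "g4", 1e-4),
    blast_row("g1", "g1", 1e-30),
    blast_row("g5", "g6", 1e-8, bits = 50),
    blast_row("g6", "g5", 1e-9, bits = 60)))
  pairs <- parse_alignment_table(f)
  expect_equal(nrow(pairs), 2L)
  expect_true(all(pairs$gene_a < pairs$gene_b))
  expect_false("g3" %in% pairs$gene_a)          # above threshold dropped
  expect_equal(pairs$evalue[pairs$gene_a == "g5"], 1e-9)  # best kept
  # exact threshold boundary is retained
  f2 <- withr::local_tempfile(lines = blast_row("a", "b", 1e-5))
  expect_equal(nrow(parse_alignment_table(f2)), 1L)
  # malformed row reports its line number
  f3 <- withr::local_tempfile(lines = c(blast_row("a", "b", 1e-8),
                                        "not\ta\tvalid\trow"))
  expect_error(parse_alignment_table(f3), "line 2")
  # empty file is an empty result, not an error
  f4 <- withr::local_tempfile(lines = character())
  expect_equal(nrow(parse_alignment_table(f4)), 0L)
})

test_that("identical proteins pass, unrelated random proteins never do", {
  set.seed(42)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  rnd <- function(n) paste(sample(aa, n, replace = TRUE), collapse = "")
  twin <- rnd(100)
  pairs <- align_all_vs_all(c(p1 = twin, p2 = twin))
  expect_equal(nrow(pairs), 1L)
  # empirical null: 1000 random pairs, none below the threshold
  cfg <- homology_config(seed_length = 0)  # force alignment of every pair
  n_hits <- 0L
  for (i in 1:10) {
    prot <- vapply(1:20, function(j) rnd(50), character(1))
    names(prot) <- sprintf("r%02d_%02d", i, 1:20)
    hits <- align_all_vs_all(prot, cfg)   # 190 pairs per batch
    n_hits <- n_hits + nrow(hits)
  }
  expect_equal(n_hits, 0L)
})

test_that("planted homologs are recovered and scores match a brute-force DP", {
  set.seed(9)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  src <- paste(sample(aa, 200, replace = TRUE), collapse = "")
  mut <- strsplit(src, "")[[1]]
  idx <- sample(200, 10)  # 5% substitutions
  mut[idx] <- vapply(mut[idx], function(x) sample(setdiff(aa, x), 1),
                     character(1))
  pairs <- align_all_vs_all(c(orig = src, homolog = paste(mut, collapse = "")))
  expect_equal(nrow(pairs), 1L)
  expect_lt(pairs$evalue, 1e-5)

  data(BLOSUM62, package = "Biostrings", envir = environment())
  cfg <- homology_config(seed_length = 0)
  for (k in 1:10) {
    la <- sample(25:40, 1); lb <- sample(25:40, 1)
    a <- paste(sample(aa, la, replace = TRUE), collapse = "")
    b <- paste(sample(aa, lb, replace = TRUE), collapse = "")
    got <- align_all_vs_all(c(x = a, y = b),
                            homology_config(evalue_threshold = Inf,
                                            seed_length = 0))
    expect_equal(got$bitscore,
                 oracle_sw_score(a, b, BLOSUM62, open = 11, extend = 1))
  }
})

test_that("pair output is invariant to input ordering", {
  fx <- shared_fixture()
  prot <- do.call(c, unname(lapply(fx$sim$genomes, `[[`, "proteins")))
  set.seed(5)
  shuffled <- prot[sample(length(prot))]
  p2 <- align_all_vs_all(shuffled)
  expect_equal(fx$pairs[order(fx$pairs$gene_a, fx$pairs$gene_b), ],
               p2[order(p2$gene_a, p2$gene_b), ], ignore_attr = TRUE)
})

test_that("every planted homolog pair is found on the fixture", {
  fx <- shared_fixture()
  tb <- fx$sim$truth$planted_blocks
  expect_true(all(pair_key(tb$gene_a, tb$gene_b) %in%
                    pair_key(fx$pairs$gene_a, fx$pairs$gene_b)))
  expect_error(align_all_vs_all(c(bad = "MKX1")), "non-amino-acid")
})
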