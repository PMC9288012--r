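# two-species annotation scaffold where gene g<i> sits at rank i on one
# chromosome per species; proteins are irrelevant for chaining
grid_annotations <- function(n = 20) {
  mk <- function(sp) {
    starts <- seq(1000L, by = 2000L, length.out = n)
    genome_annotation(sp, stats::setNames(
      paste(rep("A", max(starts) + 3000L), collapse = ""), "c1"),
      data.frame(gene_id = sprintf("%s_g%02d", sp, seq_len(n) - 1L),
                 chromosome = "c1", start = starts, end = starts + 100L,
                 strand = "+", stringsAsFactors = FALSE))
  }
  list(A = mk("A"), B = mk("B"))
}

dot_pairs <- function(ra, rb) {
  data.frame(gene_a = sprintf("A_g%02d", ra), gene_b = sprintf("B_g%02d", rb),
             evalue = 1e-10, bitscore = 100, stringsAsFactors = FALSE)
}

test_that("diagonal runs become blocks only at min_anchors", {
  ann <- grid_annotations()
  b5 <- detect_collinear_blocks(dot_pairs(0:4, 0:4), ann)
  expect_length(b5, 1L)
  expect_equal(nrow(b5[[1]]$anchors), 5L)
  expect_equal(b5[[1]]$orientation, "same")
  expect_length(detect_collinear_blocks(dot_pairs(0:3, 0:3), ann), 0L)
  # anti-diagonal: inverted block with descending rank_b
  inv <- detect_collinear_blocks(dot_pairs(0:7, 7:0), ann)
  expect_length(inv, 1L)
  expect_equal(inv[[1]]$orientation, "inverted")
  expect_equal(inv[[1]]$anchors$rank_b, 7:0)
  expect_error(
    detect_collinear_blocks(dot_pairs(0, 99), ann), "without rank")
})

test_that("emitted blocks satisfy monotonicity and gap invariants", {
  fx <- shared_fixture()
  cfg <- synteny_config()
  expect_gt(length(fx$blocks), 0L)
  for (b in fx$blocks) {
    expect_gte(nrow(b$anchors), cfg$min_anchors)
    expect_true(all(diff(b$anchors$rank_a) >= 1))
    expect_true(all(diff(b$anchors$rank_a) - 1 <= cfg$max_gap))
    db <- diff(b$anchors$rank_b)
    if (b$orientation == "same") expect_true(all(db >= 1)) else
      expect_true(all(db <= -1))
    expect_true(all(abs(db) - 1 <= cfg$max_gap))
  }
})

test_that("chaining matches exhaustive enumeration on random dot sets", {
  set.seed(101)
  for (rep in 1:100) {
    nd <- sample(4:12, 1)
    cells <- sample(100, nd)  # distinct dots on a 10x10 rank grid
    ra <- (cells - 1) %/% 10
    rb <- (cells - 1) %% 10
    gap <- sample(c(3, 25), 1)
    for (ori in c("same", "inverted")) {
      got <- syntarch:::.best_chain(ra, rb, ori, gap)
      expect_equal(got$score, oracle_best_chain_score(ra, rb, ori, gap),
                   tolerance = 1e-9)
    }
  }
})

test_that("duplicate classification follows the precedence rules", {
  n <- 20L
  starts <- seq(1000L, by = 2000L, length.out = n)
  ann <- genome_annotation("S", stats::setNames(
    paste(rep("A", max(starts) + 3000L), collapse = ""), "c1"),
    data.frame(gene_id = sprintf("g%02d", seq_len(n) - 1L),
               chromosome = "c1", start = starts, end = starts + 100L,
               strand = "+", stringsAsFactors = FALSE))
  within <- data.frame(
    gene_a = c("g07", "g02", "g05"),
    gene_b = c("g08", "g06", "g19"),
    evalue = 1e-10, bitscore = 99, stringsAsFactors = FALSE)
  labs <- classify_duplicates(ann, within, blocks = list())
  cls <- stats::setNames(labs$class, labs$gene_id)
  expect_equal(unname(cls[c("g07", "g08")]), c("tandem", "tandem"))
  expect_equal(unname(cls[c("g02", "g06")]), c("proximal", "proximal"))
  expect_equal(unname(cls[c("g05", "g19")]), c("dispersed", "dispersed"))
  expect_equal(unname(cls["g00"]), "singleton")
  expect_error(
    classify_duplicates(ann, data.frame(gene_a = "gXX", gene_b = "g01",
                                        evalue = 1e-9, bitscore = 1),
                        list()),
    "absent from the annotation")
})

test_that("classifier recovers all planted duplication labels", {
  fx <- shared_fixture()
  labs <- do.call(rbind, lapply(fx$sim$genomes, function(g) {
    within <- fx$pairs[fx$species_of[fx$pairs$gene_a] == g$species &
                         fx$species_of[fx$pairs$gene_b] == g$species, ]
    classify_duplicates(g, within, fx$blocks)
  }))
  truth <- fx$sim$truth$duplication_labels
  m <- merge(labs, truth, by = "gene_id")
  expect_equal(m$class.x, m$class.y)
  # duplication classes partition the gene set
  s <- summarize_duplications(labs)
  expect_equal(sum(s$count), nrow(labs))
})

test_that("syntelog grouping merges blocks transitively and orders groups", {
  mkblock <- function(ga, gb, spa = "A", spb = "B") {
    structure(list(species_a = spa, chromosome_a = "c1",
                   species_b = spb, chromosome_b = "c1",
                   orientation = "same", score = length(ga),
                   anchors = data.frame(gene_a = ga, gene_b = gb,
                                        stringsAsFactors = FALSE)),
              class = "collinear_block")
  }
  b1 <- mkblock(c("a1", "a2"), c("b1", "b2"))
  b2 <- mkblock(c("b1"), c("c5"), "B", "C")  # shares b1 -> merges with a1-b1
  b3 <- mkblock(c("a8"), c("b9"))            # no DEG anchor
  g <- group_syntelogs(c("a1"), list(b1, b2, b3))
  expect_length(g, 1L)
  expect_setequal(unlist(g[[1]]$members, use.names = FALSE),
                  c("a1", "b1", "c5"))
  expect_equal(names(g[[1]]$members), c("A", "B", "C"))
  # invariant to block input order
  g2 <- group_syntelogs(c("a1"), list(b3, b2, b1))
  expect_equal(g, g2)
  # two anchored components and one unanchored -> two groups
  g3 <- group_syntelogs(c("a1", "a2"), list(b1, b2, b3))
  expect_length(g3, 2L)
  # fixture: one group per DEG anchor, holding the anchor and its partners
  fx <- shared_fixture()
  groups <- group_syntelogs(fx$sim$truth$deg_anchors, fx$blocks)
  expect_length(groups, 2L)
  tb <- fx$sim$truth$planted_blocks
  got <- lapply(groups, function(gr) sort(unlist(gr$members, use.names = FALSE)))
  want <- unname(lapply(split(tb, tb$block), function(b) {
    sort(c(b$gene_a[1], b$gene_b[b$gene_a == b$gene_a[1]]))
  }))
  key <- function(l) vapply(l, `[`, character(1), 1)
  expect_equal(got[order(key(got))], want[order(key(want))])
})

test_that("duplication percentages are truncated to one decimal", {
  labs <- data.frame(
    gene_id = sprintf("g%03d", 1:231),
    class = c(rep("wgd_segmental", 64), rep("dispersed", 43),
              rep("proximal", 80), rep("tandem", 43), "singleton"),
    stringsAsFactors = FALSE)
  s <- summarize_duplications(labs)
  expect_equal(s$percentage[s$class == "wgd_segmental"], 27.7)
  # 64/196 truncates to 32.6 (rounding would give 32.7)
  labs2 <- data.frame(gene_id = sprintf("h%03d", 1:196),
                      class = c(rep("wgd_segmental", 64),
                                rep("dispersed", 132)))
  expect_equal(
    summarize_duplications(labs2)$percentage[1], 32.6)
  expect_equal(summarize_duplications(labs2)$percentage[4], 0.0)
  expect_error(summarize_duplications(labs, restrict_to = "nope"),
               "unknown gene")
})
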