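random_promoters <- function(n, len = 1000, seed = 1) {
  set.seed(seed)
  p <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  names(p) <- sprintf("gene%03d", seq_len(n))
  p
}

model_by_name <- function(sf) {
  bundle <- default_motif_bundle()
  bundle[[which(vapply(bundle, `[[`, character(1), "subfamily") == sf)]]
}

test_that("the default bundle covers the full taxonomy", {
  bundle <- default_motif_bundle()
  expect_length(bundle, 19L)
  fams <- unique(vapply(bundle, `[[`, character(1), "family"))
  expect_length(fams, 10L)
  tax <- tfbs_taxonomy()
  expect_setequal(vapply(bundle, `[[`, character(1), "subfamily"),
                  tax$subfamily)
  expect_true(all(vapply(bundle, function(m) {
    all(abs(colSums(m$matrix) - 1) < 1e-9) && ncol(m$matrix) >= 4
  }, logical(1))))
})

test_that("subfamilies map to their families; unknown names error", {
  expect_equal(classify_family("W_box"), "WRKY")
  expect_equal(classify_family("DREB"), "AP2/EREBP")
  expect_equal(classify_family("GCC_box"), "AP2/EREBP")
  expect_equal(classify_family(c("Myb_box3", "HSE")), c("MYB", "HSF"))
  expect_error(classify_family("Xyz_box"), "valid subfamilies")
  expect_equal(family_token("AP2/EREBP"), "AP2")
  expect_equal(family_token("WRKY"), "WRKY")
})

test_that("motif files round-trip and malformed matrices are rejected", {
  bundle <- default_motif_bundle()
  f <- withr::local_tempfile()
  write_motifs(bundle, f)
  back <- load_motifs(f)
  expect_equal(back, bundle)
  bad <- withr::local_tempfile(lines = c(
    "DREB AP2/EREBP 4",
    "0.5 0.5 0.1 0.1", "0.25 0.25 0.25 0.25",
    "0.25 0.25 0.25 0.25", "0.25 0.25 0.25 0.25"))
  expect_error(load_motifs(bad), "line 1.*sum to 1")
  badfam <- withr::local_tempfile(lines = c(
    "New_box NOFAM 4", rep("0.25 0.25 0.25 0.25", 4)))
  expect_error(load_motifs(badfam), "unknown family")
})

test_that("planted consensus is the top-scoring window and is recovered", {
  proms <- random_promoters(20, seed = 2)
  model <- model_by_name("W_box")
  cons <- motif_consensus(model)
  substr(proms[["gene005"]], 301, 300 + nchar(cons)) <- cons
  hits <- scan_promoter_set(proms, list(model))
  g5 <- hits[hits$gene_id == "gene005" & hits$strand == "+", ]
  expect_true(300 %in% g5$offset)
  # the planted window has the maximum Z of the whole scan
  expect_equal(g5$offset[which.max(g5$zscore)], 300)
  # window scores agree with a direct per-window oracle
  sc <- oracle_window_scores(proms[["gene005"]], model$matrix)
  expect_equal(max(sc), g5$score[g5$offset == 300], tolerance = 1e-9)
  expect_true(all(hits$zscore >= 1.5))
})

test_that("ambiguous bases never score and degenerate sets warn", {
  proms <- random_promoters(10, seed = 3)
  substr(proms[["gene001"]], 100, 120) <- paste(rep("N", 21), collapse = "")
  model <- model_by_name("G_box")
  hits <- scan_promoter_set(proms, list(model))
  w <- ncol(model$matrix)
  in_n <- hits$gene_id == "gene001" &
    hits$offset + w - 1 >= 99 & hits$offset <= 119
  expect_equal(sum(in_n), 0L)
  # a single promoter of one repeated base has zero score variance
  expect_warning(
    h0 <- scan_promoter_set(c(gx = strrep("A", 100)), list(model)),
    "degenerate")
  expect_equal(nrow(h0), 0L)
})

test_that("raising the Z threshold never adds hits (monotone filter)", {
  proms <- random_promoters(15, seed = 4)
  models <- default_motif_bundle()[c(1, 8, 10)]
  h15 <- scan_promoter_set(proms, models, scan_config(z_threshold = 1.5))
  h20 <- scan_promoter_set(proms, models, scan_config(z_threshold = 2.0))
  expect_lte(nrow(h20), nrow(h15))
  key <- function(h) paste(h$gene_id, h$subfamily, h$offset, h$strand)
  expect_true(all(key(h20) %in% key(h15)))
})

test_that("reverse-complementing promoters mirrors offsets with identical Z", {
  proms <- random_promoters(8, seed = 6, len = 400)
  model <- model_by_name("DREB")
  h <- scan_promoter_set(proms, list(model))
  rc <- vapply(proms, oracle_revcomp, character(1))
  h_rc <- scan_promoter_set(rc, list(model))
  L <- ncol(model$matrix)
  flip <- function(hh, plen) {
    data.frame(gene_id = hh$gene_id,
               offset = plen - L - hh$offset,
               strand = ifelse(hh$strand == "+", "-", "+"),
               z = round(hh$zscore, 9), stringsAsFactors = FALSE)
  }
  a <- flip(h, 400)
  b <- data.frame(gene_id = h_rc$gene_id, offset = h_rc$offset,
                  strand = h_rc$strand, z = round(h_rc$zscore, 9),
                  stringsAsFactors = FALSE)
  ord <- function(d) d[order(d$gene_id, d$offset, d$strand), ]
  expect_equal(ord(a), ord(b), ignore_attr = TRUE)
})

test_that("short promoters are skipped for a model with a warning", {
  proms <- c(random_promoters(3, seed = 8), tiny = "ACGT")
  expect_warning(h <- scan_promoter_set(proms, list(model_by_name("DREB"))),
                 "shorter than a motif")
  expect_false("tiny" %in% h$gene_id)
})
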