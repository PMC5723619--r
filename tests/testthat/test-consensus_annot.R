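# build a scan-like data frame for consensus input
fake_scan <- function(loci, sig, method, broodline, tested = NULL) {
  df <- data.frame(locus = loci, outlier = loci %in% sig,
                   stringsAsFactors = FALSE)
  if (!is.null(tested)) {
    df$scannable <- loci %in% tested
    df$outlier[!df$scannable] <- NA
  }
  attr(df, "method") <- method
  attr(df, "broodline") <- broodline
  df
}

ten_loci <- paste0("m", 1:10)

hand_built <- function() {
  list(
    fake_scan(ten_loci, c("m1", "m2", "m3"), "temporal", "A"),
    fake_scan(ten_loci, c("m2", "m9"), "temporal", "B"),
    fake_scan(ten_loci, character(), "temporal", "C"),
    fake_scan(ten_loci, c("m1", "m4"), "fst", "A"),
    fake_scan(ten_loci, c("m9",  "m5"), "fst", "B"),
    fake_scan(ten_loci, c("m5"), "fst", "C"),
    fake_scan(ten_loci, c("m4"), "bayes", "A",
              tested = setdiff(ten_loci, "m7")))
}

test_that("consensus tiers match the hand-computed table", {
  ct <- build_consensus(hand_built())
  t <- ct$tiers
  rownames(t) <- t$locus
  # per-locus significant-test counts computed by hand:
  # m1: tempA + fstA = 2; m2: tempA + tempB = 2; m3: 1; m4: fstA + bayesA = 2
  # m5: fstB + fstC = 2; m9: tempB + fstB = 2; m6,m7,m8,m10: 0
  expect_equal(t[ten_loci, "n_significant"],
               c(2, 2, 1, 2, 2, 0, 0, 0, 2, 0))
  expect_setequal(t$locus[t$candidate],
                  c("m1", "m2", "m3", "m4", "m5", "m9"))
  expect_setequal(t$locus[t$highly_significant],
                  c("m1", "m2", "m4", "m5", "m9"))
  # within-broodline 2-of-3-methods consensus
  expect_setequal(t$locus[t$consensus_A], c("m1", "m4"))
  expect_setequal(t$locus[t$consensus_B], c("m9"))
  expect_false(any(t$consensus_C))
  # locus untested by a method is NA, not FALSE
  expect_true(is.na(ct$matrix["m7", "bayes:A"]))
  expect_false(is.na(ct$matrix["m7", "temporal:A"]))
  # cross-broodline sharing per method
  expect_equal(ct$shared_by_broodlines$temporal[["two_broodlines"]], 1) # m2
  expect_equal(ct$shared_by_broodlines$fst[["two_broodlines"]], 1)     # m5
  expect_equal(ct$shared_by_broodlines$temporal[["all_broodlines"]], 0)
})

test_that("tier sets nest and flagged loci appear in some test", {
  set.seed(111)
  for (rep in 1:30) {
    loci <- paste0("x", 1:40)
    scans <- list()
    for (m in c("temporal", "fst")) for (b in c("A", "B", "C")) {
      scans[[paste(m, b)]] <-
        fake_scan(loci, sample(loci, rpois(1, 4)), m, b)
    }
    ct <- build_consensus(scans)
    t <- ct$tiers
    expect_true(all(t$locus[t$highly_significant] %in% t$locus[t$candidate]))
    expect_true(all(rowSums(ct$matrix[t$candidate, , drop = FALSE],
                            na.rm = TRUE) >= 1))
  }
})

test_that("venn region counts partition the flagged set", {
  set.seed(112)
  for (rep in 1:30) {
    loci <- paste0("x", 1:30)
    scans <- list()
    for (m in c("temporal", "fst", "bayes")) for (b in c("A", "B", "C")) {
      scans[[paste(m, b)]] <-
        fake_scan(loci, sample(loci, rpois(1, 3)), m, b)
    }
    ct <- build_consensus(scans)
    for (axis in c("method", "broodline")) {
      v <- venn_counts(ct, axis)
      expect_equal(sum(v), sum(ct$tiers$candidate))
    }
  }
})

test_that("venn edge patterns: disjoint sets and a triple hit", {
  loci <- paste0("x", 1:6)
  ct <- build_consensus(list(
    fake_scan(loci, "x1", "temporal", "A"),
    fake_scan(loci, "x2", "fst", "A"),
    fake_scan(loci, "x3", "bayes", "A")))
  v <- venn_counts(ct, "method")
  expect_equal(unname(v[c("temporal", "fst", "bayes")]), c(1, 1, 1))
  expect_true(all(v[grepl("&", names(v))] == 0))
  ct2 <- build_consensus(list(
    fake_scan(loci, "x4", "temporal", "A"),
    fake_scan(loci, "x4", "fst", "A"),
    fake_scan(loci, "x4", "bayes", "A")))
  v2 <- venn_counts(ct2, "method")
  expect_equal(unname(v2["temporal&fst&bayes"]), 1)
  expect_equal(sum(v2), 1)
})

genes_fixture <- data.frame(
  gene_id = c("g1", "g2", "g3", "g4"),
  name = c("scn1", "g2", "g3", "g4"),
  chrom = c("chr1", "chr1", "chr1", "chr2"),
  start = c(1000L, 250000L, 400000L, 500L),
  end = c(2000L, 260000L, 410000L, 900L),
  strand = "+", stringsAsFactors = FALSE)

test_that("a position inside a gene span is rank 1 at distance 0", {
  aln <- data.frame(locus_id = "Coho_1-10", chrom = "chr1", pos = 1500L,
                    mapq = 42L, strand = "+", stringsAsFactors = FALSE)
  res <- nearest_genes(aln, genes_fixture)
  expect_equal(res$gene_id[res$rank == 1], "g1")
  expect_equal(res$distance[res$rank == 1], 0L)
  expect_equal(res$name[1], "scn1")
})

test_that("the 100,000-base window boundary is inclusive", {
  # g2 starts at 250,000: a position at 150,000 is exactly 100,000 away
  aln <- data.frame(locus_id = c("at", "beyond"), chrom = "chr1",
                    pos = c(150000L, 149999L), mapq = 42L, strand = "+",
                    stringsAsFactors = FALSE)
  res <- nearest_genes(aln, genes_fixture, window = 100000)
  expect_true("g2" %in% res$gene_id[res$locus_id == "at"])
  expect_false("g2" %in% res$gene_id[res$locus_id == "beyond"])
})

test_that("multi-mapped loci are annotated at every retained position", {
  aln <- data.frame(locus_id = "Coho_9-9", chrom = c("chr1", "chr2"),
                    pos = c(1500L, 600L), mapq = c(30L, 20L), strand = "+",
                    stringsAsFactors = FALSE)
  res <- nearest_genes(aln, genes_fixture)
  expect_setequal(res$gene_id, c("g1", "g4"))
  expect_equal(nrow(res), 2)
})

test_that("positions on unannotated chromosomes warn and return nothing", {
  aln <- data.frame(locus_id = "q", chrom = "chrZ", pos = 5L, mapq = 11L,
                    strand = "+", stringsAsFactors = FALSE)
  expect_warning(res <- nearest_genes(aln, genes_fixture), "absent")
  expect_equal(nrow(res), 0)
})

test_that("nearest-gene search matches the brute-force oracle", {
  set.seed(115)
  for (rep in 1:40) {
    genes <- random_genes(n = 50)
    pos <- sample.int(1e6, 8)
    chrom <- sample(c("chr1", "chr2"), 8, TRUE)
    aln <- data.frame(locus_id = paste0("t", 1:8), chrom = chrom, pos = pos,
                      mapq = 30L, strand = "+", stringsAsFactors = FALSE)
    res <- suppressWarnings(nearest_genes(aln, genes, window = 120000, k = 3))
    for (i in 1:8) {
      want <- oracle_nearest(chrom[i], pos[i], genes, window = 120000, k = 3)
      got <- res[res$locus_id == paste0("t", i), ]
      expect_equal(got$gene_id, want$gene_id,
                   label = sprintf("rep %d pos %d", rep, i))
      expect_equal(got$distance, as.integer(want$distance))
    }
  }
})

test_that("deliberate distance ties break by start then gene id", {
  genes <- data.frame(
    gene_id = c("gB", "gA"), name = c("gB", "gA"), chrom = "chr1",
    start = c(2000L, 2000L), end = c(2500L, 2500L), strand = "+",
    stringsAsFactors = FALSE)
  aln <- data.frame(locus_id = "t", chrom = "chr1", pos = 1000L, mapq = 30L,
                    strand = "+", stringsAsFactors = FALSE)
  res <- nearest_genes(aln, genes, window = 10000, k = 2)
  expect_equal(res$gene_id, c("gA", "gB"))
})
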