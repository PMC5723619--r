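test_that("group frequencies count tracked alleles per year class", {
  a1 <- matrix(c(1L, 1L), 2, 1); a2 <- matrix(c(1L, 2L), 2, 1)
  meta <- data.frame(sample_id = c("s1", "s2"), brood_year = 2000,
                     broodline = "A", generation = 0L)
  ds <- genotype_dataset(a1, a2, c("s1", "s2"), "L1", sample_meta = meta)
  ft <- group_allele_frequencies(ds)
  expect_equal(unname(ft$freq[1, 1]), 0.75)   # 3 of 4 alleles tracked
  expect_equal(unname(ft$size[1, 1]), 2)
})

test_that("all-missing groups are flagged undefined", {
  a1 <- matrix(c(1L, NA), 2, 1); a2 <- matrix(c(2L, NA), 2, 1)
  meta <- data.frame(sample_id = c("s1", "s2"), brood_year = c(2000, 2003),
                     broodline = "A", generation = c(0L, 1L))
  ds <- genotype_dataset(a1, a2, c("s1", "s2"), "L1", sample_meta = meta)
  ft <- group_allele_frequencies(ds)
  expect_true(is.na(ft$freq["A:1", 1]))
  expect_equal(unname(ft$size["A:1", 1]), 0)
})

test_that("group frequencies match a direct counting oracle", {
  set.seed(202)
  for (rep in 1:5) {
    ds <- random_dataset(n = 50, L = 200, miss = 0.15, meta = TRUE)
    ft <- group_allele_frequencies(ds)
    gens <- ds$sample_meta$generation
    for (g in sort(unique(gens))) for (j in sample(200, 10)) {
      rows <- which(gens == g)
      al <- c(ds$a1[rows, j], ds$a2[rows, j])
      al <- al[!is.na(al)]
      expected <- if (length(al)) mean(al == ds$tracked_allele[j]) else NA_real_
      expect_equal(unname(ft$freq[paste0("A:", g), j]), expected,
                   tolerance = 1e-15)
    }
  }
})

# small dataset from explicit genotype pairs at one locus
pair_ds <- function(...) {
  pairs <- list(...)
  a1 <- matrix(vapply(pairs, `[`, 0L, 1), ncol = 1)
  a2 <- matrix(vapply(pairs, `[`, 0L, 2), ncol = 1)
  genotype_dataset(a1, a2, paste0("s", seq_along(pairs)), "L1")
}

test_that("genotypic distances reproduce the codominant table", {
  # AA vs BB = 4, AA vs AB = 1, AB vs CD = 2, AA vs BC = 3, AB vs AB = 0
  d <- genotypic_distance_matrix(pair_ds(c(1L, 1L), c(2L, 2L)))
  expect_equal(d["s1", "s2"], 4)
  d <- genotypic_distance_matrix(pair_ds(c(1L, 1L), c(1L, 2L)))
  expect_equal(d["s1", "s2"], 1)
  d <- genotypic_distance_matrix(pair_ds(c(1L, 2L), c(3L, 4L)))
  expect_equal(d["s1", "s2"], 2)
  d <- genotypic_distance_matrix(pair_ds(c(1L, 1L), c(2L, 3L)))
  expect_equal(d["s1", "s2"], 3)
  d <- genotypic_distance_matrix(pair_ds(c(1L, 2L), c(1L, 2L), c(1L, 1L)))
  expect_equal(d["s1", "s2"], 0)
  expect_true(all(diag(d) == 0))
  expect_true(isSymmetric(unname(d)))
})

test_that("distance matrix matches the brute-force oracle with missingness", {
  set.seed(404)
  for (rep in 1:20) {
    ds <- random_dataset(n = 8, L = 15, miss = 0.2,
                         n_alleles = sample(2:3, 1))
    D <- genotypic_distance_matrix(ds)
    for (i in 1:7) for (j in (i + 1):8) {
      expect_equal(D[i, j], oracle_distance(ds, i, j), tolerance = 1e-9,
                   label = sprintf("rep %d pair (%d,%d)", rep, i, j))
    }
  }
})

test_that("pairs sharing no called loci raise an error naming the pair", {
  a1 <- matrix(c(1L, NA, NA, 1L), 2, 2); a2 <- a1
  ds <- genotype_dataset(a1, a2, c("s1", "s2"), c("L1", "L2"))
  expect_error(genotypic_distance_matrix(ds), "s1/s2")
})

test_that("principal coordinates recover a Euclidean configuration", {
  # four points at unit-square corners; squared distances known exactly
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  D2 <- as.matrix(dist(pts))^2
  ord <- principal_coordinates(D2, n_axes = 2)
  rec <- as.matrix(dist(ord$coords))^2
  expect_equal(unname(rec), unname(D2), tolerance = 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))  # sorted decreasing
})

test_that("identical samples get identical coordinates", {
  ds <- pair_ds(c(1L, 2L), c(1L, 2L), c(2L, 2L), c(1L, 1L))
  ord <- principal_coordinates(genotypic_distance_matrix(ds), n_axes = 1)
  expect_equal(ord$coords["s1", ], ord$coords["s2", ], tolerance = 1e-9)
})

test_that("ordination is invariant (up to nothing) to sample permutation", {
  set.seed(11)
  ds <- random_dataset(n = 12, L = 60, miss = 0.05)
  D <- genotypic_distance_matrix(ds)
  perm <- sample(12)
  o1 <- principal_coordinates(D, 2)
  o2 <- principal_coordinates(D[perm, perm], 2)
  # sign convention pins each axis, so coordinates must agree exactly
  expect_equal(o2$coords[ds$sample_ids, ], o1$coords[ds$sample_ids, ],
               tolerance = 1e-8)
})

test_that("simulated broodline structure is recovered by the ordination", {
  cfg <- sim_config(n_loci = 800, n_selected = 0, founder_divergence = 3,
                    seed = 71,
                    sample_sizes = list(A = c(15, 0, 15, 15),
                                        B = c(15, 15, 15, 15),
                                        C = c(15, 15, 15, 15)))
  st <- simulate_study(cfg)
  D2 <- genotypic_distance_matrix(st$dataset)
  ord <- principal_coordinates(D2, n_axes = 2)
  bl <- factor(st$dataset$sample_meta$broodline)
  km <- kmeans(ord$coords, centers = 3, nstart = 25)
  agree <- max_label_agreement(km$cluster, bl)
  expect_gte(agree, 0.95)
})

test_that("no clusters emerge without founder divergence (negative control)", {
  cfg <- sim_config(n_loci = 800, n_selected = 0, founder_divergence = 0,
                    seed = 72,
                    sample_sizes = list(A = c(15, 0, 15, 15),
                                        B = c(15, 15, 15, 15),
                                        C = c(15, 15, 15, 15)))
  st <- simulate_study(cfg)
  # founders only: later generations re-acquire structure from their own
  # within-line drift even with a common founder pool
  ds0 <- subset_dataset(st$dataset, st$dataset$sample_meta$generation == 0)
  D2 <- genotypic_distance_matrix(ds0)
  ord <- principal_coordinates(D2, n_axes = 2)
  bl <- factor(ds0$sample_meta$broodline)
  sil <- cluster::silhouette(as.integer(bl), dist(ord$coords))
  expect_lt(mean(sil[, "sil_width"]), 0.1)
})
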