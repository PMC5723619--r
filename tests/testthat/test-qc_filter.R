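# build a dataset from explicit per-locus genotype call lists;
# calls: list of loci, each a list of c(a1, a2) pairs (NA = missing)
dataset_from_calls <- function(calls, meta = NULL) {
  n <- length(calls[[1]])
  a1 <- sapply(calls, function(l) vapply(l, `[`, 0L, 1))
  a2 <- sapply(calls, function(l) vapply(l, `[`, 0L, 2))
  ids <- names(calls)
  if (is.null(ids)) ids <- paste0("L", seq_along(calls))
  genotype_dataset(a1, a2, paste0("s", seq_len(n)), ids, sample_meta = meta)
}

test_that("minor allele frequency counts pooled alleles", {
  # 9 x (1,1) + 1 x (1,2): one copy of allele 2 in 20 -> 0.05
  calls <- list(c(rep(list(c(1L, 1L)), 9), list(c(1L, 2L))))
  ds <- dataset_from_calls(calls)
  expect_equal(unname(minor_allele_frequency(ds)), 0.05)
  # monomorphic -> 0
  ds2 <- dataset_from_calls(list(rep(list(c(1L, 1L)), 5)))
  expect_equal(unname(minor_allele_frequency(ds2)), 0)
  # all-missing locus errors
  ds3 <- dataset_from_calls(list(rep(list(c(NA_integer_, NA_integer_)), 3)))
  expect_error(minor_allele_frequency(ds3), "all-missing")
})

test_that("minor allele frequency matches the counting oracle", {
  set.seed(101)
  for (rep in 1:50) {
    ds <- random_dataset(n = 100, L = 4, miss = 0.2)
    for (j in 1:4) {
      expect_equal(unname(minor_allele_frequency(ds, j)),
                   oracle_maf(ds$a1[, j], ds$a2[, j]), tolerance = 1e-15)
    }
  }
})

test_that("HWE exact test reproduces hand-enumerated cases", {
  # n=2, one het configuration each with prob 1/3 and 2/3
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # all-heterozygote extreme tail
  expect_lt(hwe_exact_test(0, 100, 0), 1e-10)
  # modal configuration has p = 1
  expect_equal(hwe_exact_test(25, 50, 25), 1.0, tolerance = 1e-9)
  # monomorphic: no test possible
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)
})

test_that("HWE exact test matches full enumeration for all n <= 10", {
  for (n in 1:10) {
    for (n1 in 0:n) for (nh in 0:(n - n1)) {
      n2 <- n - n1 - nh
      expect_equal(hwe_exact_test(n1, nh, n2), oracle_hwe(n1, nh, n2),
                   tolerance = 1e-9,
                   label = sprintf("triple (%d,%d,%d)", n1, nh, n2))
    }
  }
})

test_that("BY filter handles the single-test and all-null edges", {
  r <- by_fdr_filter(0.005, alpha = 0.01)
  expect_true(r$reject)          # c(1) = 1, threshold alpha itself
  expect_equal(r$threshold, 0.005)
  r2 <- by_fdr_filter(rep(1, 50), alpha = 0.01)
  expect_false(any(r2$reject))
  expect_true(is.na(r2$threshold))
  r3 <- by_fdr_filter(numeric(0))
  expect_length(r3$keep, 0)
})

test_that("BY filter equals the naive sort-and-scan step-up", {
  set.seed(55)
  for (rep in 1:250) {
    m <- sample(c(1:20, 500), 1)
    p <- runif(m)^sample(1:3, 1)   # occasionally enriched near zero
    got <- by_fdr_filter(p, alpha = 0.05)$reject
    expect_identical(got, oracle_by_reject(p, 0.05))
  }
})

# fixture with one known violation per stage:
#  L1 monomorphic-ish low MAF, L2 triallelic, L3 low call rate, L4 extreme
#  HWE deviation, L5-L10 clean; s10 loses calls at clean loci -> low call rate
qc_fixture <- function() {
  n <- 40
  ok <- function() list(sample(list(c(1L, 1L), c(1L, 2L), c(2L, 2L)),
                               1, prob = c(.49, .42, .09))[[1]])
  clean <- function() unlist(lapply(seq_len(n), function(i) ok()),
                             recursive = FALSE)
  calls <- list(
    L1 = c(rep(list(c(1L, 1L)), n - 1), list(c(1L, 2L))),  # MAF 1/80
    L2 = c(rep(list(c(1L, 2L)), n - 2), list(c(1L, 3L)), list(c(2L, 2L))),
    L3 = c(rep(list(c(NA_integer_, NA_integer_)), 12),
           rep(list(c(1L, 2L)), 10), rep(list(c(1L, 1L)), 10),
           rep(list(c(2L, 2L)), 8)),                        # call rate 0.7
    L4 = rep(list(c(1L, 2L)), n))                           # all-het HWE
  for (k in 5:10) calls[[paste0("L", k)]] <- clean()
  # sample 40: missing at all clean loci -> call rate 4/9 < 0.75 after stage 1
  for (k in 5:10) calls[[paste0("L", k)]][[40]] <- c(NA_integer_, NA_integer_)
  dataset_from_calls(calls)
}

test_that("QC cascade removes the intended entities in printed stage order", {
  set.seed(77)
  ds <- qc_fixture()
  res <- run_qc(ds, qc_config())
  rem <- res$report$removed
  expect_equal(rem$stage[rem$id == "L1"], "maf")
  expect_equal(rem$reason[rem$id == "L2"], "not biallelic")
  expect_equal(rem$stage[rem$id == "s40"], "sample_call_rate")
  expect_equal(rem$stage[rem$id == "L3"], "locus_call_rate")
  expect_equal(rem$stage[rem$id == "L4"], "hwe")
  expect_setequal(res$dataset$locus_ids, paste0("L", 5:10))
  expect_equal(n_samples(res$dataset), 39)
  # report telescopes at every stage
  st <- res$report$stages
  expect_equal(st$n_input - st$n_removed, st$n_surviving)
  expect_equal(st$n_surviving[st$entity == "locus"][1] -
                 sum(st$n_removed[-(1:2)]),
               n_loci(res$dataset))
})

test_that("boundary values survive: removal is strictly 'less than'", {
  # MAF exactly 0.05: 1 het in 10 samples = 1/20 alleles
  calls <- list(
    Lb = c(rep(list(c(1L, 1L)), 9), list(c(1L, 2L))),
    Lc = c(rep(list(c(1L, 2L)), 5), rep(list(c(1L, 1L)), 3),
           rep(list(c(2L, 2L)), 2)))
  ds <- dataset_from_calls(calls)
  res <- run_qc(ds, qc_config())
  expect_true("Lb" %in% res$dataset$locus_ids)
  # locus call rate exactly 0.80 survives stage 3
  calls2 <- list(
    L1 = c(rep(list(c(NA_integer_, NA_integer_)), 2),
           rep(list(c(1L, 2L)), 4), rep(list(c(1L, 1L)), 2),
           rep(list(c(2L, 2L)), 2)),
    L2 = c(rep(list(c(1L, 2L)), 5), rep(list(c(1L, 1L)), 3),
           rep(list(c(2L, 2L)), 2)))
  res2 <- run_qc(dataset_from_calls(calls2), qc_config())
  expect_true("L1" %in% res2$dataset$locus_ids)
})

test_that("cascade order matters: a locus can pass only because a bad sample left first", {
  # locus Lx is in HWE among samples 1-30; samples 31-40 carry extreme excess
  # heterozygosity at Lx but are themselves removed at the sample-call-rate
  # stage, so Lx survives the pooled HWE stage
  set.seed(13)
  n <- 50
  hw <- function() {
    g <- sample(0:2, n, TRUE, prob = c(0.25, 0.5, 0.25))
    lapply(g, function(d) if (d == 2) c(1L, 1L) else if (d == 1) c(1L, 2L)
           else c(2L, 2L))
  }
  calls <- lapply(1:12, function(i) hw())
  names(calls) <- paste0("L", 1:12)
  # samples 1-20: exact HW counts at Lx; samples 21-50: all heterozygous
  calls$Lx <- c(rep(list(c(1L, 1L)), 5), rep(list(c(1L, 2L)), 10),
                rep(list(c(2L, 2L)), 5), rep(list(c(1L, 2L)), 30))
  # make samples 21-50 fail the 75% call rate once loci are intact
  for (k in paste0("L", 1:12))
    for (i in 21:50) calls[[k]][[i]] <- c(NA_integer_, NA_integer_)
  ds <- dataset_from_calls(calls)
  res <- run_qc(ds, qc_config())
  expect_true("Lx" %in% res$dataset$locus_ids)
  # whereas pooling everyone (HWE first) would have rejected Lx
  dos <- tracked_dosage(ds)[, "Lx"]
  p_all <- hwe_exact_test(sum(dos == 2, na.rm = TRUE),
                          sum(dos == 1, na.rm = TRUE),
                          sum(dos == 0, na.rm = TRUE))
  p_kept <- res$report$hwe_p["Lx"]
  expect_lt(p_all, 0.01 / 13)   # below even a Bonferroni-sharpened level
  expect_gt(p_kept, 0.05)
})

test_that("HWE-conforming simulated data loses at most 0.5% of loci to stage 4", {
  set.seed(303)
  n <- 600; L <- 5000
  p <- runif(L, 0.1, 0.9)
  dos <- matrix(rbinom(n * L, 2L, rep(p, each = n)), n, L)
  a1 <- ifelse(dos >= 1L, 1L, 2L); a2 <- ifelse(dos == 2L, 1L, 2L)
  ds <- genotype_dataset(a1, a2, paste0("s", 1:n), paste0("L", 1:L))
  res <- run_qc(ds, qc_config())
  st <- res$report$stages
  expect_lte(st$n_removed[st$stage == "hwe"], 0.005 * L)
})

test_that("emptying a stage raises an error naming the stage", {
  calls <- list(L1 = rep(list(c(1L, 1L)), 10))   # monomorphic only locus
  expect_error(run_qc(dataset_from_calls(calls)), "maf")
})
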