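# Independent brute-force oracles used to cross-check the package's
# estimators. Deliberately written in the most literal way possible (scalar
# loops, textbook formulas), sharing no code with the implementation.

# random small genotype dataset; codes 1/2 (optionally more alleles)
random_dataset <- function(n = 10, L = 20, miss = 0.1, n_alleles = 2,
                           meta = FALSE) {
  a1 <- matrix(sample.int(n_alleles, n * L, TRUE), n, L)
  a2 <- matrix(sample.int(n_alleles, n * L, TRUE), n, L)
  gone <- matrix(runif(n * L) < miss, n, L)
  a1[gone] <- NA_integer_; a2[gone] <- NA_integer_
  sm <- NULL
  if (meta) {
    sm <- data.frame(sample_id = paste0("s", seq_len(n)),
                     brood_year = 2000 + 3 * ((seq_len(n) - 1) %% 4),
                     broodline = "A",
                     generation = (seq_len(n) - 1) %% 4)
  }
  genotype_dataset(a1, a2, paste0("s", seq_len(n)), paste0("L", seq_len(L)),
                   sample_meta = sm)
}

# allele-counting minor allele frequency
oracle_maf <- function(a1_col, a2_col) {
  al <- c(a1_col, a2_col)
  al <- al[!is.na(al)]
  tab <- table(al)
  1 - max(tab) / sum(tab)
}

# full-enumeration exact HWE test via choose(); probability-ordering tail
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na <- 2 * n_hom1 + n_het
  nm <- min(na, 2 * n - na)
  if (nm == 0) return(1)
  hs <- seq(nm %% 2, nm, by = 2)
  pr <- sapply(hs, function(h) {
    hm <- (nm - h) / 2
    choose(n, hm) * choose(n - hm, h) * 2^h / choose(2 * n, nm)
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hs == n_het] * (1 + 1e-9)])
}

# naive sort-and-scan Benjamini-Yekutieli step-up
oracle_by_reject <- function(p, alpha) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  thr <- seq_len(m) * alpha / (m * cm)
  k <- suppressWarnings(max(which(ps <= thr)))
  rej <- rep(FALSE, m)
  if (is.finite(k)) rej[o[seq_len(k)]] <- TRUE
  rej
}

# naive BH step-up
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * alpha / m)))
  rej <- rep(FALSE, m)
  if (is.finite(k)) rej[o[seq_len(k)]] <- TRUE
  rej
}

# longhand Weir-Cockerham (1984) variance components for one biallelic locus;
# groups: list of dosage vectors (0/1/2, NA allowed)
oracle_wc_fst <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, 0L) >= 2]
  r <- length(groups)
  n_i <- vapply(groups, length, 0L)
  p_i <- vapply(groups, function(g) sum(g) / (2 * length(g)), 0)
  h_i <- vapply(groups, function(g) mean(g == 1), 0)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(fst = a / (a + b + cc), he = 2 * pbar * (1 - pbar))
}

# brute-force squared Smouse-Peakall distance between two samples of one
# dataset, with pairwise deletion + rescaling
oracle_distance <- function(ds, i, j) {
  L <- n_loci(ds)
  tot <- 0; shared <- 0
  for (l in seq_len(L)) {
    ci <- c(ds$a1[i, l], ds$a2[i, l])
    cj <- c(ds$a1[j, l], ds$a2[j, l])
    if (anyNA(ci) || anyNA(cj)) next
    shared <- shared + 1
    alleles <- unique(c(ds$a1[, l], ds$a2[, l]))
    alleles <- alleles[!is.na(alleles)]
    di <- sapply(alleles, function(a) sum(ci == a))
    dj <- sapply(alleles, function(a) sum(cj == a))
    tot <- tot + 0.5 * sum((di - dj)^2)
  }
  if (shared == 0) stop("no shared loci")
  tot * L / shared
}

# brute-force k nearest genes within a window of a single position
oracle_nearest <- function(chrom, pos, genes, window = 100000, k = 3) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(g[0, ])
  d <- ifelse(pos < g$start, g$start - pos,
              ifelse(pos > g$end, pos - g$end, 0L))
  g$distance <- d
  g <- g[d <= window, , drop = FALSE]
  g <- g[order(g$distance, g$start, g$gene_id), , drop = FALSE]
  head(g, k)
}

# random gene table on a couple of chromosomes
random_genes <- function(n = 50, chroms = c("chr1", "chr2"), span = 1e6) {
  start <- sample.int(span, n, TRUE)
  width <- sample.int(20000, n, TRUE)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             name = sprintf("name%03d", seq_len(n)),
             chrom = sample(chroms, n, TRUE),
             start = start, end = start + width,
             strand = sample(c("+", "-"), n, TRUE),
             stringsAsFactors = FALSE)
}

# best agreement between a clustering and reference labels over label
# permutations (3 clusters at most here)
max_label_agreement <- function(cluster, truth) {
  truth <- as.integer(factor(truth))
  k <- max(max(cluster), max(truth))
  perms <- combinat_perms(seq_len(k))
  best <- 0
  for (p in perms) best <- max(best, mean(p[cluster] == truth))
  best
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
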