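#' QC configuration
#'
#' Thresholds of the four-stage SNP filter cascade applied by [run_qc()].
#' Removal is by strict inequality at every stage ("less than" the
#' threshold), so entities sitting exactly on a boundary are kept.
#'
#' @param maf_min minimum pooled minor allele frequency (stage 1).
#' @param sample_call_rate_min minimum fraction of called genotypes per
#'   sample, over loci surviving stage 1 (stage 2).
#' @param locus_call_rate_min minimum fraction of called genotypes per locus,
#'   over samples surviving stage 2 (stage 3).
#' @param hwe_alpha Benjamini-Yekutieli FDR level for Hardy-Weinberg removal
#'   (stage 4), all surviving samples pooled as a single population.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.05, sample_call_rate_min = 0.75,
                      locus_call_rate_min = 0.80, hwe_alpha = 0.01) {
  stopifnot(maf_min > 0, maf_min < 0.5,
            sample_call_rate_min > 0, sample_call_rate_min <= 1,
            locus_call_rate_min > 0, locus_call_rate_min <= 1,
            hwe_alpha > 0, hwe_alpha <= 1)
  structure(list(maf_min = maf_min,
                 sample_call_rate_min = sample_call_rate_min,
                 locus_call_rate_min = locus_call_rate_min,
                 hwe_alpha = hwe_alpha), class = "qc_config")
}

#' Minor allele frequency of each locus
#'
#' Computed over all non-missing calls pooled across every sample. For a
#' biallelic locus this is `min(p, 1-p)`; monomorphic loci return 0; for a
#' locus with more than two observed alleles the frequency of all but the
#' most common allele is returned (such loci are removed by [run_qc()]
#' as "not biallelic" regardless).
#'
#' @param dataset a [genotype_dataset()].
#' @param loci optional subset of loci (indices or ids).
#' @return named numeric vector of minor allele frequencies in `[0, 0.5]`
#'   (values above 0.5 are impossible for biallelic loci). All-missing loci
#'   raise an error.
#' @export
minor_allele_frequency <- function(dataset, loci = NULL) {
  li <- if (is.null(loci)) seq_len(n_loci(dataset)) else loci
  if (is.character(li)) li <- match(li, dataset$locus_ids)
  out <- vapply(li, function(j) {
    al <- c(dataset$a1[, j], dataset$a2[, j])
    al <- al[!is.na(al)]
    if (!length(al))
      stop("minor allele frequency undefined for all-missing locus ",
           dataset$locus_ids[j])
    tab <- sort(table(al), decreasing = TRUE)
    1 - tab[1] / sum(tab)
  }, 0)
  names(out) <- dataset$locus_ids[li]
  out
}

#' Exact test for Hardy-Weinberg equilibrium at a biallelic locus
#'
#' Two-sided exact conditional test: given the total genotype count `n` and
#' the minor-allele count, every heterozygote count `h` of the right parity
#' has conditional probability proportional to
#' `n! / (n_hom1! h! n_hom2!) * 2^h`; the p-value is the summed probability
#' of all configurations no more probable than the observed one
#' (probability-ordering tail). Exact behaviour at the small minor-allele
#' counts RAD panels produce is the point; a chi-square approximation is not
#' used anywhere.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (homozygote, heterozygote,
#'   other homozygote).
#' @return p-value; a monomorphic locus returns 1 (no test possible).
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop("no genotypes")
  n_a <- 2 * n_hom1 + n_het
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1.0)
  h_obs <- n_het
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  # log conditional probability of each heterozygote configuration
  logp <- vapply(hs, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lfactorial(n) - lfactorial(hom_min) - lfactorial(h) -
      lfactorial(hom_maj) + h * log(2) - lchoose(2 * n, n_minor)
  }, 0)
  p <- exp(logp)
  p <- p / sum(p)  # guard against rounding; exact weights sum to 1
  min(1, sum(p[p <= p[hs == h_obs] * (1 + 1e-7)]))
}

#' Benjamini-Yekutieli FDR filter
#'
#' Step-up procedure at level `alpha` with the harmonic correction
#' `c(m) = sum(1/i)`, valid under arbitrary dependence. Returns which tests
#' are rejected (flagged for removal) and the effective per-test threshold,
#' i.e. the largest raw p-value that was rejected.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `keep` (logical, `TRUE` = not rejected), `reject`
#'   (logical), and `threshold` (largest rejected raw p, `NA` if none).
#' @export
by_fdr_filter <- function(p_values, alpha = 0.01) {
  if (!length(p_values))
    return(list(keep = logical(), reject = logical(), threshold = NA_real_))
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  adj <- p.adjust(p_values, method = "BY")
  reject <- !is.na(adj) & adj <= alpha
  list(keep = !reject, reject = reject,
       threshold = if (any(reject)) max(p_values[reject]) else NA_real_)
}

#' Run the four-stage QC cascade
#'
#' Stage order is fixed and order-sensitive: (1) drop non-biallelic loci and
#' loci with pooled minor allele frequency below `maf_min`; (2) drop samples
#' with a call rate below `sample_call_rate_min` over the remaining loci;
#' (3) drop loci with a call rate below `locus_call_rate_min` over the
#' remaining samples; (4) test every remaining locus for Hardy-Weinberg
#' equilibrium pooling all remaining samples as one population and remove
#' loci rejected by the Benjamini-Yekutieli step-up at `hwe_alpha` (guards
#' against null alleles and paralogous sequence variants).
#'
#' @param dataset a [genotype_dataset()].
#' @param config a [qc_config()].
#' @return list of class `qc_result`: `dataset` (filtered), `report` (a
#'   `qc_report`: per-stage telescoping counts, removal table, per-locus HWE
#'   p-values and the effective BY threshold).
#' @export
run_qc <- function(dataset, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  removed <- data.frame(id = character(), entity = character(),
                        stage = character(), reason = character(),
                        value = numeric(), stringsAsFactors = FALSE)
  stages <- data.frame(stage = character(), entity = character(),
                       n_input = integer(), n_removed = integer(),
                       n_surviving = integer(), stringsAsFactors = FALSE)
  note_stage <- function(stage, entity, n_in, n_rm) {
    stages <<- rbind(stages, data.frame(
      stage = stage, entity = entity, n_input = n_in, n_removed = n_rm,
      n_surviving = n_in - n_rm, stringsAsFactors = FALSE))
  }
  die_if_empty <- function(x, stage) {
    if (n_loci(x) == 0 || n_samples(x) == 0)
      stop("QC stage '", stage, "' removed every remaining ",
           if (n_loci(x) == 0) "locus" else "sample")
    x
  }

  # stage 1: biallelic + MAF
  n_al <- locus_n_alleles(dataset)
  all_missing <- n_al == 0L
  non_bi <- n_al > 2L
  maf <- rep(NA_real_, n_loci(dataset))
  scan_ok <- !all_missing
  maf[scan_ok] <- minor_allele_frequency(dataset, which(scan_ok))
  low_maf <- scan_ok & !non_bi & maf < config$maf_min
  drop1 <- all_missing | non_bi | low_maf
  if (any(drop1)) {
    reason <- ifelse(all_missing, "all missing",
                     ifelse(non_bi, "not biallelic", "MAF below cutoff"))
    removed <- rbind(removed, data.frame(
      id = dataset$locus_ids[drop1], entity = "locus", stage = "maf",
      reason = reason[drop1], value = maf[drop1], stringsAsFactors = FALSE))
  }
  note_stage("maf", "locus", n_loci(dataset), sum(drop1))
  ds <- die_if_empty(subset_dataset(dataset, loci = !drop1), "maf")

  # stage 2: sample call rate over remaining loci
  cr_s <- rowMeans(!is.na(ds$a1))
  drop2 <- cr_s < config$sample_call_rate_min
  if (any(drop2)) removed <- rbind(removed, data.frame(
    id = ds$sample_ids[drop2], entity = "sample", stage = "sample_call_rate",
    reason = "call rate below cutoff", value = cr_s[drop2],
    stringsAsFactors = FALSE))
  note_stage("sample_call_rate", "sample", n_samples(ds), sum(drop2))
  ds <- die_if_empty(subset_dataset(ds, samples = !drop2), "sample_call_rate")

  # stage 3: locus call rate over remaining samples
  cr_l <- colMeans(!is.na(ds$a1))
  drop3 <- cr_l < config$locus_call_rate_min
  if (any(drop3)) removed <- rbind(removed, data.frame(
    id = ds$locus_ids[drop3], entity = "locus", stage = "locus_call_rate",
    reason = "call rate below cutoff", value = cr_l[drop3],
    stringsAsFactors = FALSE))
  note_stage("locus_call_rate", "locus", n_loci(ds), sum(drop3))
  ds <- die_if_empty(subset_dataset(ds, loci = !drop3), "locus_call_rate")

  # stage 4: HWE over all remaining samples pooled, BY removal
  dos <- tracked_dosage(ds)
  n2 <- colSums(dos == 2L, na.rm = TRUE)
  n1 <- colSums(dos == 1L, na.rm = TRUE)
  n0 <- colSums(dos == 0L, na.rm = TRUE)
  hwe_p <- vapply(seq_len(n_loci(ds)),
                  function(j) hwe_exact_test(n2[j], n1[j], n0[j]), 0)
  names(hwe_p) <- ds$locus_ids
  by <- by_fdr_filter(hwe_p, config$hwe_alpha)
  if (any(by$reject)) removed <- rbind(removed, data.frame(
    id = ds$locus_ids[by$reject], entity = "locus", stage = "hwe",
    reason = "Hardy-Weinberg deviation (BY)", value = hwe_p[by$reject],
    stringsAsFactors = FALSE))
  note_stage("hwe", "locus", n_loci(ds), sum(by$reject))
  ds <- die_if_empty(subset_dataset(ds, loci = by$keep), "hwe")

  report <- structure(list(stages = stages, removed = removed,
                           hwe_p = hwe_p, hwe_threshold = by$threshold,
                           config = config), class = "qc_report")
  structure(list(dataset = ds, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC cascade report\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("effective BY threshold (largest removed raw p): %s\n",
              format(x$hwe_threshold)))
  invisible(x)
}

#' Write the QC removal report as TSV
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  write.table(report$removed, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
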