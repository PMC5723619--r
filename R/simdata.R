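#' Configuration for the broodline simulator
#'
#' Builds the parameter set for [simulate_study()]. The defaults emulate the
#' design of a three-broodline salmonid reintroduction program: three
#' reproductively isolated lines ("A", "B", "C") founded in consecutive years
#' on a 3-year generation interval, four generations each, one missing
#' generation in line A, per-year sample sizes between 7 and ~100 totalling
#' 664 fish, ~5,392 pre-ascertained biallelic SNPs with founder minor allele
#' frequency at least 0.05, drift at small effective broodstock size, and a
#' small fraction of loci under shared directional selection.
#'
#' @param n_loci number of biallelic SNP loci.
#' @param n_selected number of loci under directional selection (shared across
#'   broodlines, same sign of `s`).
#' @param s additive selection coefficient favouring the tracked allele at
#'   selected loci.
#' @param Ne effective broodstock size per generation (binomial drift of
#'   `2*Ne` gametes).
#' @param founder_divergence number of pure-drift generations separating each
#'   broodline founder pool from a common source pool; 0 makes founder pools
#'   identical.
#' @param sample_sizes named list (one element per broodline) of per-generation
#'   sample sizes; 0 marks a generation with no samples (the missing-generation
#'   mask). All broodlines must have the same number of generations.
#' @param founding_years named integer vector of founding brood years.
#' @param generation_interval years between generations (3 for Coho).
#' @param maf_min lower bound of the uniform founder-frequency distribution
#'   (`Uniform(maf_min, 1 - maf_min)`).
#' @param missing_rate_sample,missing_rate_locus `c(shape1, shape2)` of the
#'   beta distributions from which per-sample / per-locus missing-call rates
#'   are drawn (defaults have mean 0.05), a single constant rate, or a
#'   per-entity rate vector.
#' @param infusion fraction of each post-founder generation's gene pool drawn
#'   from the source pool (supplementation from the source stock); default 0.
#' @param seed integer seed making the whole study reproducible.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 5392, n_selected = 50, s = 0.5, Ne = 100,
                       founder_divergence = 3,
                       sample_sizes = list(A = c(24, 0, 63, 80),
                                           B = c(50, 65, 7, 90),
                                           C = c(55, 70, 85, 75)),
                       founding_years = c(A = 2000, B = 2001, C = 2002),
                       generation_interval = 3,
                       maf_min = 0.05,
                       missing_rate_sample = c(2, 38),
                       missing_rate_locus = c(2, 38),
                       infusion = 0,
                       seed = NULL) {
  stopifnot(s >= 0, maf_min > 0, maf_min < 0.5, Ne >= 2,
            n_selected >= 0, n_selected <= n_loci,
            infusion >= 0, infusion <= 1, founder_divergence >= 0)
  gens <- unique(lengths(sample_sizes))
  if (length(gens) != 1)
    stop("sample_sizes: all broodlines must list the same number of generations")
  if (any(unlist(sample_sizes) < 0))
    stop("sample_sizes must be >= 0 (0 marks a missing generation)")
  if (!all(names(sample_sizes) %in% names(founding_years)))
    stop("every broodline in sample_sizes needs a founding year")
  structure(list(
    n_loci = n_loci, n_selected = n_selected, s = s, Ne = Ne,
    founder_divergence = founder_divergence, sample_sizes = sample_sizes,
    founding_years = founding_years,
    generation_interval = generation_interval, maf_min = maf_min,
    missing_rate_sample = missing_rate_sample,
    missing_rate_locus = missing_rate_locus,
    infusion = infusion, seed = seed), class = "sim_config")
}

# one Wright-Fisher generation, vectorised over loci
wf_step <- function(p, Ne, s = 0) {
  pp <- p * (1 + s) / (1 + p * s)
  m <- max(2L, as.integer(round(2 * Ne)))   # gamete count; Ne may be fractional
  rbinom(length(p), m, pp) / m
}

#' Wright-Fisher allele-frequency trajectory
#'
#' Propagates an allele frequency through `n_generations` discrete
#' Wright-Fisher generations at effective size `Ne` with additive selection
#' `s` on the tracked allele: the deterministic update
#' `p' = p(1+s) / (1+ps)` is followed by a binomial draw of `2*Ne` gametes.
#' Frequencies 0 and 1 are absorbing; `s = 0` gives pure drift, under which
#' the trajectory is a martingale (the expected final frequency equals the
#' starting frequency) with final-frequency variance
#' `p0*(1-p0)*(1 - (1 - 1/(2*Ne))^t)`.
#'
#' @param p0 starting frequency in `[0, 1]` (vector allowed; loci evolve
#'   independently).
#' @param Ne effective population size.
#' @param s additive selection coefficient (scalar or per-locus).
#' @param n_generations number of Wright-Fisher transitions.
#' @return a numeric matrix with `n_generations + 1` rows (row 1 is `p0`) and
#'   one column per locus; a plain vector if `p0` is scalar.
#' @export
wright_fisher_trajectory <- function(p0, Ne, s = 0, n_generations = 3) {
  stopifnot(all(p0 >= 0 & p0 <= 1))
  L <- length(p0)
  out <- matrix(NA_real_, n_generations + 1L, L)
  out[1, ] <- p0
  p <- p0
  if (n_generations > 0) for (t in seq_len(n_generations)) {
    p <- wf_step(p, Ne, s)
    out[t + 1L, ] <- p
  }
  if (L == 1L) drop(out) else out
}

#' Simulate a multi-generation broodline study with known truth
#'
#' Draws a common source pool of founder frequencies
#' `Uniform(maf_min, 1 - maf_min)`, derives each broodline's founder pool by
#' `founder_divergence` pure-drift generations from it (this creates the
#' between-broodline cluster structure), propagates each broodline through
#' its generations by [wright_fisher_trajectory()] (selected loci share the
#' same positive `s` in every broodline), draws Hardy-Weinberg genotypes
#' binomially from each generation's frequency at the configured sample
#' sizes, and finally applies per-sample/per-locus missingness via
#' [apply_missingness()].
#'
#' @param config a [sim_config()].
#' @return a list of class `simulated_study`: `dataset` (a
#'   [genotype_dataset()]), and `truth` with `labels` (per-locus
#'   `"neutral"`/`"selected"`), `s`, and `trajectories` (per broodline, a
#'   generations x loci matrix of true frequencies, masked generations
#'   included).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$n_loci
  n_gens <- length(config$sample_sizes[[1]])
  locus_ids <- sprintf("Coho_%05d-%02d", seq_len(L), sample(20:79, L, TRUE))
  source_p <- runif(L, config$maf_min, 1 - config$maf_min)
  sel <- rep(FALSE, L)
  if (config$n_selected > 0) sel[sample.int(L, config$n_selected)] <- TRUE
  svec <- ifelse(sel, config$s, 0)

  blines <- names(config$sample_sizes)
  traj <- list()
  a1_all <- NULL; a2_all <- NULL
  ids <- character(); meta <- NULL
  for (bl in blines) {
    sizes <- config$sample_sizes[[bl]]
    pf <- source_p
    if (config$founder_divergence > 0)
      for (g in seq_len(config$founder_divergence)) pf <- wf_step(pf, config$Ne)
    tr <- matrix(NA_real_, n_gens, L,
                 dimnames = list(NULL, locus_ids))
    p <- pf
    for (g in seq_len(n_gens)) {
      tr[g, ] <- p
      n <- sizes[g]
      if (n > 0) {
        dos <- matrix(rbinom(n * L, 2L, rep(p, each = n)), nrow = n)
        a1 <- ifelse(dos >= 1L, 1L, 2L)
        a2 <- ifelse(dos == 2L, 1L, 2L)
        year <- config$founding_years[[bl]] +
          (g - 1L) * config$generation_interval
        sid <- sprintf("%s%d_%03d", bl, year, seq_len(n))
        ids <- c(ids, sid)
        meta <- rbind(meta, data.frame(
          sample_id = sid, brood_year = year, broodline = bl,
          generation = g - 1L, stringsAsFactors = FALSE))
        a1_all <- rbind(a1_all, a1)
        a2_all <- rbind(a2_all, a2)
      }
      if (g < n_gens) {
        p <- wf_step(p, config$Ne, svec)
        if (config$infusion > 0)
          p <- (1 - config$infusion) * p + config$infusion * source_p
      }
    }
    traj[[bl]] <- tr
  }
  ds <- genotype_dataset(a1_all, a2_all, sample_ids = ids,
                         locus_ids = locus_ids, sample_meta = meta)
  ds <- apply_missingness(ds, config$missing_rate_sample,
                          config$missing_rate_locus)
  structure(list(
    dataset = ds,
    truth = list(
      labels = data.frame(locus_id = locus_ids,
                          label = ifelse(sel, "selected", "neutral"),
                          s = svec, stringsAsFactors = FALSE),
      trajectories = traj),
    config = config), class = "simulated_study")
}

#' Overlay missing genotype calls on a dataset
#'
#' Each sample gets a missing rate `r_s` and each locus a rate `r_l` (drawn
#' from beta distributions when shape pairs are given); a call is set missing
#' independently with probability `1 - (1 - r_s) * (1 - r_l)`, emulating the
#' joint effect of poorly sequenced samples and poorly captured loci.
#'
#' @param dataset a [genotype_dataset()].
#' @param sample_rates,locus_rates either `c(shape1, shape2)` for a beta draw
#'   per entity, a single constant rate, or a vector of per-entity rates.
#' @return the dataset with additional missing calls.
#' @export
apply_missingness <- function(dataset, sample_rates = c(2, 38),
                              locus_rates = c(2, 38)) {
  n <- n_samples(dataset); L <- n_loci(dataset)
  expand <- function(r, k) {
    if (length(r) == 2 && !all(r == 0)) rbeta(k, r[1], r[2])
    else if (length(r) == 1) rep(r, k)
    else if (length(r) == k) r
    else if (all(r == 0)) rep(0, k)
    else stop("rates must be a beta shape pair, a scalar, or per-entity")
  }
  rs <- expand(sample_rates, n)
  rl <- expand(locus_rates, L)
  stopifnot(all(rs >= 0 & rs <= 1), all(rl >= 0 & rl <= 1))
  pmiss <- 1 - outer(1 - rs, 1 - rl)
  drop_it <- matrix(runif(n * L) < pmiss, n, L)
  dataset$a1[drop_it] <- NA_integer_
  dataset$a2[drop_it] <- NA_integer_
  dataset
}

#' Two-point temporal FST (Nei-Tajima)
#'
#' Standardised variance of allele-frequency change between two time points,
#' `sum((p0 - pt)^2) / sum(pbar * (1 - pbar))` with `pbar = (p0 + pt)/2`,
#' pooled over loci. Under pure drift at effective size `Ne` for `t`
#' generations its expectation is approximately `1 - (1 - 1/(2*Ne))^t`,
#' which makes it the calibration diagnostic for the simulator.
#'
#' @param p0,pt allele-frequency vectors at the two time points.
#' @return a single FST value.
#' @export
temporal_fst <- function(p0, pt) {
  stopifnot(length(p0) == length(pt))
  pbar <- (p0 + pt) / 2
  denom <- pbar * (1 - pbar)
  keep <- denom > 0
  if (!any(keep)) stop("all loci fixed at both time points")
  sum((p0[keep] - pt[keep])^2) / sum(denom[keep])
}

#' Write a simulated study to disk
#'
#' Emits the four external files of a study: GenePop, VCF, the metadata
#' sidecar TSV and the truth table TSV (`locus_id`, `label`, `s`).
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if absent).
#' @return named character vector of the four paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genepop = file.path(dir, "study.gen"),
    vcf = file.path(dir, "study.vcf"),
    meta = file.path(dir, "meta.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_genepop(study$dataset, paths["genepop"])
  write_vcf_genotypes(study$dataset, paths["vcf"])
  write_sample_metadata(study$dataset, paths["meta"])
  write.table(study$truth$labels, paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
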