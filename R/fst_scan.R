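# FST-heterozygosity outlier scan with a temporal-drift neutral envelope.
#
# The neutral null is multi-generation drift of one line sampled at each
# generation (year classes of a single population), not an island model:
# the "populations" being compared are temporal samples, so drift at the
# calibrated effective size is the honest neutral model for them.

# Weir & Cockerham (1984) theta and expected heterozygosity, vectorised.
# dos: samples x loci tracked-allele dosage; group: factor per sample.
# Groups with fewer than min_group_size samples are excluded from the scan;
# per locus, groups with < 2 called diploids are ignored; loci with < 2
# usable groups (or no variation) come back NA.
wc_fst_matrix <- function(dos, group, min_group_size = 2) {
  group <- factor(group)
  keep_g <- table(group) >= min_group_size
  use <- group %in% names(keep_g)[keep_g]
  dos <- dos[use, , drop = FALSE]
  group <- droplevels(group[use])
  if (nlevels(group) < 2)
    stop("fewer than two groups of at least ", min_group_size, " samples")
  called <- !is.na(dos)
  dos0 <- ifelse(called, dos, 0L)
  het <- !is.na(dos) & dos == 1L
  n_g <- rowsum(called + 0L, group)            # groups x loci called counts
  cnt <- rowsum(dos0, group)
  het_g <- rowsum(het + 0L, group)
  elig <- n_g >= 2L
  n_g[!elig] <- 0L; cnt[!elig] <- 0L; het_g[!elig] <- 0L
  r <- colSums(elig)
  N <- colSums(n_g)                            # total diploids per locus
  p_g <- ifelse(n_g > 0, cnt / (2 * n_g), 0)
  nbar <- N / r
  nc <- (N - colSums(n_g^2) / N) / (r - 1)
  pbar <- colSums(n_g * p_g) / N
  s2 <- colSums(n_g * (p_g - rep(pbar, each = nrow(n_g)))^2) /
    ((r - 1) * nbar)
  hbar <- colSums(het_g) / N
  pq <- pbar * (1 - pbar)
  a <- nbar / nc *
    (s2 - (pq - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pq - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- a / denom
  bad <- r < 2 | !is.finite(fst) | denom == 0
  fst[bad] <- NA_real_
  he <- 2 * pq
  he[r < 2] <- NA_real_
  data.frame(fst = fst, he = he, n_groups = r,
             row.names = colnames(dos) %||% NULL)
}

#' Weir-Cockerham FST and expected heterozygosity at one locus
#'
#' The 1984 variance-components estimator theta across two or more sample
#' groups, with expected heterozygosity `He = 2 * pbar * (1 - pbar)` at the
#' sample-size-weighted mean frequency. Slightly negative estimates at
#' undifferentiated loci are normal for this estimator and are returned
#' as-is.
#'
#' @param groups list of tracked-allele dosage vectors (values 0, 1, 2 or
#'   `NA`), one per group; every group needs at least two called diploids.
#' @return list with `fst`, `he`, `n_groups`.
#' @export
wc_fst_he <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  dos <- matrix(unlist(groups), ncol = 1)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- wc_fst_matrix(dos, g, min_group_size = 2)
  list(fst = res$fst[1], he = res$he[1], n_groups = res$n_groups[1])
}

# simulate n_sim neutral temporal loci: founder freq uniform, drift at Ne
# over the generation times, genotype sampling at the given group sizes;
# returns fst/he of each simulated locus
simulate_neutral_loci <- function(n_sim, Ne, gen_times, group_sizes,
                                  founder_range = c(0.02, 0.98)) {
  p0 <- runif(n_sim, founder_range[1], founder_range[2])
  tmax <- max(gen_times)
  traj <- matrix(NA_real_, length(gen_times), n_sim)
  p <- p0
  t_now <- 0
  for (k in seq_along(gen_times)) {
    while (t_now < gen_times[k]) {
      p <- wf_step(p, Ne)
      t_now <- t_now + 1
    }
    traj[k, ] <- p
  }
  # genotype counts per group via sequential binomials (multinomial HWE draw)
  dos <- NULL; grp <- NULL
  for (k in seq_along(group_sizes)) {
    n <- group_sizes[k]
    pk <- traj[k, ]
    nAA <- rbinom(n_sim, n, pk^2)
    prem <- ifelse(pk < 1, 2 * pk * (1 - pk) / (1 - pk^2), 0)
    nAB <- rbinom(n_sim, n - nAA, pmin(prem, 1))
    # expand to per-sample dosages for the estimator
    d <- matrix(0L, n, n_sim)
    d[] <- rep(0L, n * n_sim)
    # fill columns: first nAA twos, then nAB ones
    idx2 <- sequence(nAA)
    if (length(idx2))
      d[cbind(idx2, rep(seq_len(n_sim), nAA))] <- 2L
    idx1 <- sequence(nAB)
    if (length(idx1))
      d[cbind(idx1 + rep(nAA, nAB), rep(seq_len(n_sim), nAB))] <- 1L
    dos <- rbind(dos, d)
    grp <- c(grp, rep(k, n))
  }
  wc_fst_matrix(dos, factor(grp), min_group_size = 2)
}

# mean simulated theta for a candidate Ne (calibration helper)
mean_sim_fst <- function(Ne, gen_times, group_sizes, n_sim) {
  s <- simulate_neutral_loci(n_sim, Ne, gen_times, group_sizes)
  mean(s$fst, na.rm = TRUE)
}

#' Build the He-conditioned neutral FST envelope
#'
#' Three steps. (1) The neutral mean FST is estimated iteratively: starting
#' from the mean of all observed per-locus estimates, loci outside a
#' provisional envelope are dropped and the mean recomputed, until stable
#' (at most `max_iter` rounds) — so strongly selected loci do not inflate
#' the null. (2) An effective size is calibrated by bisection so that the
#' mean FST of simulated neutral temporal loci (drift over the observed
#' generation times, genotypes drawn at the observed group sizes) matches
#' the neutral mean. (3) `n_sims` neutral loci are simulated at that
#' calibration, binned by He into `n_bins` equal-count bins, and per-bin FST
#' quantiles at `(1 - ci)/2` and `1 - (1 - ci)/2` are interpolated between
#' bin centres to give the envelope.
#'
#' @param fst,he observed per-locus values (from the scan; `NA`s allowed).
#' @param gen_times generation indices of the groups in the scan.
#' @param group_sizes diploid sample count of each group.
#' @param n_sims number of simulated neutral loci for the final envelope.
#' @param ci envelope confidence level.
#' @param n_bins number of equal-count He bins (at least 20).
#' @param max_iter maximum neutral-mean iterations.
#' @param calib_sims simulated loci per calibration/provisional round.
#' @return object of class `fst_envelope`: simulated `sims` (fst, he), `bins`
#'   (centre, lo, hi, n), He bin `breaks`, `neutral_mean`, calibrated `Ne`,
#'   `ci`, `n_sims`.
#' @export
neutral_envelope <- function(fst, he, gen_times, group_sizes,
                             n_sims = 50000, ci = 0.95, n_bins = 20,
                             max_iter = 10, calib_sims = 5000) {
  ok <- is.finite(fst) & is.finite(he)
  if (sum(ok) < 100)
    stop("too few scannable loci (", sum(ok), ") to calibrate an envelope")
  stopifnot(n_bins >= 20, n_sims >= 1000)
  fst_o <- fst[ok]; he_o <- he[ok]
  target <- mean(fst_o)
  calibrate <- function(target) {
    lo <- 5; hi <- 2e5
    for (i in 1:18) {
      mid <- sqrt(lo * hi)
      m <- mean_sim_fst(mid, gen_times, group_sizes, calib_sims)
      if (m > target) lo <- mid else hi <- mid
      if (abs(m - target) < 0.02 * abs(target) + 1e-5) break
    }
    mid
  }
  keep <- rep(TRUE, length(fst_o))
  Ne <- NA_real_
  for (it in seq_len(max_iter)) {
    target <- mean(fst_o[keep])
    if (target <= 0) { target <- max(mean(fst_o), 1e-4); }
    Ne <- calibrate(target)
    sims <- simulate_neutral_loci(calib_sims, Ne, gen_times, group_sizes)
    env <- bin_envelope(sims, ci, n_bins)
    inside <- fst_o <= env_interp(env, he_o, "hi") &
      fst_o >= env_interp(env, he_o, "lo")
    if (mean(abs(mean(fst_o[inside]) - target)) < 1e-3 ||
        identical(inside, keep)) { keep <- inside; break }
    keep <- inside
  }
  target <- mean(fst_o[keep])
  if (target > 0) Ne <- calibrate(target)
  sims <- simulate_neutral_loci(n_sims, Ne, gen_times, group_sizes)
  env <- bin_envelope(sims, ci, n_bins)
  structure(list(sims = sims, bins = env$bins, breaks = env$breaks,
                 neutral_mean = target, Ne = Ne, ci = ci, n_sims = n_sims,
                 gen_times = gen_times, group_sizes = group_sizes),
            class = "fst_envelope")
}

# equal-count He binning of simulated loci + per-bin quantiles
bin_envelope <- function(sims, ci, n_bins) {
  ok <- is.finite(sims$fst) & is.finite(sims$he)
  he <- sims$he[ok]; fst <- sims$fst[ok]
  breaks <- unique(quantile(he, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(he, breaks, include.lowest = TRUE, labels = FALSE)
  qlo <- (1 - ci) / 2; qhi <- 1 - qlo
  agg <- function(f) vapply(split(fst, bin), f, 0)
  bins <- data.frame(
    centre = vapply(split(he, bin), median, 0),
    lo = agg(function(v) quantile(v, qlo, names = FALSE)),
    hi = agg(function(v) quantile(v, qhi, names = FALSE)),
    n = as.integer(table(bin)))
  list(bins = bins, breaks = breaks)
}

env_interp <- function(env, he, which = c("hi", "lo")) {
  which <- match.arg(which)
  b <- if (inherits(env, "fst_envelope")) env$bins else env$bins
  approx(b$centre, b[[which]], xout = he, rule = 2)$y
}

#' Designate FST outliers against a neutral envelope
#'
#' Per locus the empirical p-value for directional selection is the
#' (add-one smoothed) fraction of He-bin-matched simulated neutral loci with
#' FST at least as large as observed; Benjamini-Hochberg at level `fdr`
#' designates outliers. Loci above the upper envelope are additionally
#' flagged (`above_envelope`) for plotting, and loci below the lower
#' envelope are reported separately as balancing-selection candidates
#' (`below_envelope`) — they never feed the directional consensus.
#'
#' @param fst,he observed per-locus values.
#' @param envelope an `fst_envelope` from [neutral_envelope()].
#' @param fdr false-discovery-rate level for outlier designation.
#' @param locus_ids optional locus names for the result.
#' @return data frame of class `fst_scan` (`locus`, `fst`, `he`, `env_lo`,
#'   `env_hi`, `p`, `q`, `outlier`, `above_envelope`, `below_envelope`,
#'   `scannable`) with attributes `neutral_mean`, `ci`, `fdr`, `n_sims`,
#'   `method`.
#' @export
fst_outliers <- function(fst, he, envelope, fdr = 0.1, locus_ids = NULL) {
  stopifnot(inherits(envelope, "fst_envelope"))
  sims <- envelope$sims
  ok_s <- is.finite(sims$fst) & is.finite(sims$he)
  she <- sims$he[ok_s]; sfst <- sims$fst[ok_s]
  breaks <- envelope$breaks
  sbin <- cut(she, breaks, include.lowest = TRUE, labels = FALSE)
  L <- length(fst)
  p <- rep(NA_real_, L)
  scannable <- is.finite(fst) & is.finite(he)
  if (any(scannable)) {
    obin <- cut(he[scannable], breaks, include.lowest = TRUE, labels = FALSE)
    out_of_range <- is.na(obin)
    if (any(out_of_range)) {
      warning(sum(out_of_range),
              " loci have He outside the simulated range; nearest bin used")
      lo_side <- he[scannable][out_of_range] < breaks[1]
      obin[out_of_range] <- ifelse(lo_side, 1L, length(breaks) - 1L)
    }
    by_bin <- split(sfst, sbin)
    p[scannable] <- mapply(function(b, f) {
      v <- by_bin[[as.character(b)]]
      (1 + sum(v >= f)) / (1 + length(v))
    }, obin, fst[scannable])
  }
  q <- rep(NA_real_, L)
  q[scannable] <- p.adjust(p[scannable], method = "BH")
  env_lo <- env_interp(envelope, he, "lo")
  env_hi <- env_interp(envelope, he, "hi")
  env_lo[!scannable] <- NA_real_; env_hi[!scannable] <- NA_real_
  res <- data.frame(
    locus = locus_ids %||% paste0("L", seq_len(L)),
    fst = fst, he = he, env_lo = env_lo, env_hi = env_hi, p = p, q = q,
    outlier = ifelse(scannable, q <= fdr & fst > envelope$neutral_mean, NA),
    above_envelope = ifelse(scannable, fst > env_hi, NA),
    below_envelope = ifelse(scannable, fst < env_lo, NA),
    scannable = scannable, stringsAsFactors = FALSE)
  attr(res, "neutral_mean") <- envelope$neutral_mean
  attr(res, "ci") <- envelope$ci
  attr(res, "fdr") <- fdr
  attr(res, "n_sims") <- envelope$n_sims
  attr(res, "Ne") <- envelope$Ne
  attr(res, "method") <- "fst"
  class(res) <- c("fst_scan", "data.frame")
  res
}

#' FST-heterozygosity outlier scan of one broodline
#'
#' Runs [wc_fst_matrix] across the broodline's generations (each year class
#' a population; groups below `min_group_size` samples are excluded, the
#' default 8 dropping N = 7 year classes), builds the temporal-drift neutral
#' envelope with [neutral_envelope()] and designates directional outliers
#' with [fst_outliers()].
#'
#' @param dataset a QC-filtered [genotype_dataset()] with metadata.
#' @param broodline broodline label.
#' @param n_sims,ci,fdr envelope and outlier parameters.
#' @param min_group_size minimum samples for a generation to enter the scan.
#' @param seed optional seed for the envelope simulations.
#' @return an `fst_scan` data frame (see [fst_outliers()]) with an
#'   additional `broodline` attribute and the envelope in attribute
#'   `envelope`.
#' @export
run_fst_scan <- function(dataset, broodline, n_sims = 50000, ci = 0.95,
                         fdr = 0.1, min_group_size = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dataset$sample_meta))
    stop("dataset has no sample metadata")
  if (!broodline %in% dataset$sample_meta$broodline)
    stop("broodline '", broodline, "' absent from metadata")
  ds <- subset_dataset(dataset,
                       samples = dataset$sample_meta$broodline == broodline)
  gen <- ds$sample_meta$generation
  sizes <- table(gen)
  use_gens <- as.integer(names(sizes)[sizes >= min_group_size])
  if (length(use_gens) < 2)
    stop("broodline ", broodline, ": fewer than two generations with >= ",
         min_group_size, " samples")
  ds <- subset_dataset(ds, samples = gen %in% use_gens)
  grp <- factor(ds$sample_meta$generation, levels = sort(use_gens))
  wc <- wc_fst_matrix(tracked_dosage(ds), grp, min_group_size = min_group_size)
  env <- neutral_envelope(wc$fst, wc$he,
                          gen_times = sort(use_gens),
                          group_sizes = as.integer(table(grp)),
                          n_sims = n_sims, ci = ci)
  res <- fst_outliers(wc$fst, wc$he, env, fdr = fdr,
                      locus_ids = ds$locus_ids)
  attr(res, "broodline") <- broodline
  attr(res, "envelope") <- env
  res
}

#' @export
print.fst_scan <- function(x, ...) {
  cat(sprintf(
    "FST-He outlier scan%s: %d loci scanned, %d directional outliers (ci = %g, fdr = %g)\n",
    if (!is.null(attr(x, "broodline")))
      paste0(", broodline ", attr(x, "broodline")) else "",
    sum(x$scannable), sum(x$outlier, na.rm = TRUE),
    attr(x, "ci"), attr(x, "fdr")))
  cat(sprintf("  neutral mean FST = %.4g (calibrated Ne = %.0f, %d sims)\n",
              attr(x, "neutral_mean"), attr(x, "Ne"), attr(x, "n_sims")))
  invisible(x)
}

#' FST-He scan plot with the neutral envelope
#'
#' @param scan an `fst_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_fst_scan <- function(scan, ...) {
  ok <- scan$scannable
  graphics::plot(scan$he[ok], scan$fst[ok], pch = 20,
                 col = ifelse(scan$outlier[ok], "red", "grey40"),
                 xlab = "He", ylab = "FST", ...)
  env <- attr(scan, "envelope")
  if (!is.null(env)) {
    o <- order(env$bins$centre)
    graphics::lines(env$bins$centre[o], env$bins$hi[o], col = "grey60")
    graphics::lines(env$bins$centre[o], env$bins$lo[o], col = "grey60")
  }
  invisible(scan)
}
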