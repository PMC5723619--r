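# Per-locus regression / Q-Q linearity outlier scan.
#
# Slopes are computed on the percentage-frequency scale (frequency x 100).
# The chi-square statistic d^2 / mean(d) is not scale-invariant, and the
# percent scale is the one on which its alpha = 0.01 cutoff corresponds to a
# realized low-single-digit multiple of the average deviation; on the raw
# proportion scale the cutoff is unreachable and the scan could never flag
# anything. See the methods vignette for the full argument.

# vectorised OLS slopes of freq (gens x loci, percent) on generation index
ols_slopes <- function(freq, gen_index) {
  W <- !is.na(freq)
  F0 <- ifelse(W, freq, 0)
  x <- gen_index
  n <- colSums(W)
  Sx <- colSums(W * x)
  Sy <- colSums(F0)
  Sxx <- colSums(W * x^2)
  Sxy <- colSums(F0 * x)
  denom <- n * Sxx - Sx^2
  slope <- (n * Sxy - Sx * Sy) / denom
  slope[n < 2 | denom <= 0] <- NA_real_
  slope
}

#' OLS slope of allele frequency on generation index for one locus
#'
#' Ordinary least-squares slope of (percent) frequency on the generation
#' index. Missing generations keep their true spacing: a broodline observed
#' at generations 0, 2, 3 is regressed on x = (0, 2, 3), because the slope is
#' a per-generation rate.
#'
#' @param freqs allele frequencies (proportions in `[0,1]`), one per
#'   generation; `NA` for generations without data.
#' @param generations generation indices (abscissa).
#' @return slope in percentage points per generation; `NA` if fewer than two
#'   defined generations remain.
#' @export
slope_per_locus <- function(freqs, generations = seq_along(freqs) - 1) {
  stopifnot(length(freqs) == length(generations))
  ols_slopes(cbind(100 * freqs), generations)
}

#' Expected slopes under Q-Q linearity
#'
#' Orders the observed slopes, pairs them with standard normal quantiles at
#' Blom plotting positions `(i - 3/8) / (m + 1/4)`, and fits the reference
#' line through the first/third-quartile points of the (theoretical,
#' observed) pairs — the robust convention, so that the suspect tails get no
#' leverage on the fit. The expected slope of each locus is the line
#' evaluated at its own rank's quantile.
#'
#' @param slopes numeric vector of observed slopes (no `NA`s; at least 20).
#' @return numeric vector of expected slopes aligned with the input, with
#'   attributes `z` (theoretical quantile per locus), `intercept` and
#'   `slope` of the reference line.
#' @export
qq_expected_slopes <- function(slopes) {
  m <- length(slopes)
  if (m < 20) stop("need at least 20 slopes for a Q-Q reference line")
  if (anyNA(slopes)) stop("slopes must not contain NA")
  qy <- quantile(slopes, c(0.25, 0.75), names = FALSE)
  if (diff(qy) <= 0)
    stop("degenerate scan: zero interquartile spread of slopes")
  qz <- qnorm(c(0.25, 0.75))
  line_b <- diff(qy) / diff(qz)
  line_a <- qy[1] - line_b * qz[1]
  o <- order(slopes)
  z <- numeric(m)
  z[o] <- qnorm((seq_len(m) - 3 / 8) / (m + 1 / 4))
  expected <- line_a + line_b * z
  attr(expected, "z") <- z
  attr(expected, "intercept") <- line_a
  attr(expected, "slope") <- line_b
  expected
}

#' Chi-square significance of Q-Q deviations
#'
#' Per locus, the absolute deviation `d` between observed and expected slope
#' is referred to a chi-square with 1 df through the statistic
#' `X = d^2 / mean(d)`. A locus is an outlier when `p < alpha`, equivalently
#' when `d >= sqrt(q * mean(d))` with `q` the chi-square `1 - alpha`
#' quantile; that realized cutoff, expressed as a multiple of the average
#' deviation, is recorded so scans can be compared across datasets.
#'
#' @param slopes,expected observed and Q-Q-expected slopes, aligned.
#' @param alpha significance level (default 0.01).
#' @return data frame (`slope`, `expected`, `deviation`, `statistic`, `p`,
#'   `outlier`) with attributes `mean_deviation`, `cutoff_deviation`,
#'   `cutoff_multiple` and `alpha`.
#' @export
deviation_chi_square <- function(slopes, expected, alpha = 0.01) {
  stopifnot(length(slopes) == length(expected))
  expected <- as.numeric(expected)
  d <- abs(slopes - expected)
  dbar <- mean(d)
  if (!is.finite(dbar) || dbar <= 0)
    stop("degenerate scan: zero mean deviation")
  X <- d^2 / dbar
  p <- pchisq(X, df = 1, lower.tail = FALSE)
  q <- qchisq(1 - alpha, df = 1)
  out <- data.frame(slope = slopes, expected = as.numeric(expected),
                    deviation = d, statistic = X, p = p,
                    outlier = p < alpha)
  attr(out, "mean_deviation") <- dbar
  attr(out, "cutoff_deviation") <- sqrt(q * dbar)
  attr(out, "cutoff_multiple") <- sqrt(q / dbar)
  attr(out, "alpha") <- alpha
  out
}

#' Temporal allele-frequency outlier scan of one broodline
#'
#' The per-broodline selection scan: per-locus OLS slope of (percent) allele
#' frequency on generation index, Q-Q comparison of the slope distribution
#' against normality ([qq_expected_slopes()]), and chi-square significance of
#' the per-locus deviation from the Q-Q line ([deviation_chi_square()]).
#' Each broodline is scanned separately (the broodlines are biological
#' replicates of the same reintroduction). Loci with fewer than two
#' generations of defined frequency are reported as unscannable (`NA` rows)
#' and excluded from the Q-Q fit.
#'
#' @param dataset a QC-filtered [genotype_dataset()] with metadata.
#' @param broodline broodline label to scan.
#' @param alpha outlier significance level.
#' @return a data frame of class `slope_scan` with one row per locus
#'   (`locus`, `slope`, `expected`, `deviation`, `statistic`, `p`,
#'   `outlier`, `scannable`) and scan-level attributes `mean_deviation`,
#'   `cutoff_deviation`, `cutoff_multiple`, `alpha`, `broodline`, `method`.
#' @export
run_temporal_scan <- function(dataset, broodline, alpha = 0.01) {
  if (is.null(dataset$sample_meta))
    stop("dataset has no sample metadata")
  if (!broodline %in% dataset$sample_meta$broodline)
    stop("broodline '", broodline, "' absent from metadata")
  keep <- dataset$sample_meta$broodline == broodline
  ds <- subset_dataset(dataset, samples = keep)
  gens <- sort(unique(ds$sample_meta$generation))
  ft <- group_allele_frequencies(
    ds, group = factor(ds$sample_meta$generation, levels = gens))
  slopes <- ols_slopes(100 * ft$freq, gens)
  scannable <- !is.na(slopes)
  L <- n_loci(ds)
  res <- data.frame(locus = ds$locus_ids,
                    slope = slopes, expected = NA_real_,
                    deviation = NA_real_, statistic = NA_real_,
                    p = NA_real_, outlier = NA, scannable = scannable,
                    stringsAsFactors = FALSE)
  if (length(gens) < 2 || !any(scannable)) {
    res$outlier <- ifelse(scannable, FALSE, NA)
    attr(res, "mean_deviation") <- NA_real_
    attr(res, "cutoff_multiple") <- NA_real_
    attr(res, "alpha") <- alpha
    attr(res, "broodline") <- broodline
    attr(res, "method") <- "temporal"
    class(res) <- c("slope_scan", "data.frame")
    return(res)
  }
  exp_s <- qq_expected_slopes(slopes[scannable])
  chi <- deviation_chi_square(slopes[scannable], exp_s, alpha = alpha)
  res$expected[scannable] <- chi$expected
  res$deviation[scannable] <- chi$deviation
  res$statistic[scannable] <- chi$statistic
  res$p[scannable] <- chi$p
  res$outlier[scannable] <- chi$outlier
  for (a in c("mean_deviation", "cutoff_deviation", "cutoff_multiple"))
    attr(res, a) <- attr(chi, a)
  attr(res, "alpha") <- alpha
  attr(res, "broodline") <- broodline
  attr(res, "method") <- "temporal"
  class(res) <- c("slope_scan", "data.frame")
  res
}

#' @export
print.slope_scan <- function(x, ...) {
  cat(sprintf(
    "temporal slope scan, broodline %s: %d loci scanned, %d outliers (alpha = %g)\n",
    attr(x, "broodline"), sum(x$scannable), sum(x$outlier, na.rm = TRUE),
    attr(x, "alpha")))
  if (is.finite(attr(x, "mean_deviation") %||% NA))
    cat(sprintf("  mean |deviation| = %.4g; cutoff = %.3g x mean deviation\n",
                attr(x, "mean_deviation"), attr(x, "cutoff_multiple")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
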