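#' Per-group allele frequency table
#'
#' Frequency of the tracked allele in each group of samples, where a group is
#' by default a broodline x generation cell (each year class treated as an
#' independent population). Frequency is tracked-allele count over twice the
#' number of non-missing diploid calls; empty cells are flagged undefined
#' (`NA` frequency, size 0).
#'
#' @param dataset a [genotype_dataset()] with sample metadata.
#' @param group optional factor-like vector (one entry per sample) overriding
#'   the default broodline x generation grouping.
#' @return a list of class `frequency_table`: `freq` (groups x loci), `size`
#'   (groups x loci matrix of non-missing diploid counts) and `groups` (data
#'   frame with `group`, `broodline`, `generation` when derivable).
#' @export
group_allele_frequencies <- function(dataset, group = NULL) {
  if (is.null(group)) {
    if (is.null(dataset$sample_meta))
      stop("dataset has no sample metadata to group by")
    group <- paste(dataset$sample_meta$broodline,
                   dataset$sample_meta$generation, sep = ":")
  }
  group <- factor(group, levels = unique(group))
  dos <- tracked_dosage(dataset)
  called <- !is.na(dos)
  dos0 <- ifelse(called, dos, 0L)
  count <- rowsum(dos0, group)               # tracked-allele copies per group
  size <- rowsum(called + 0L, group)         # called diploids per group
  freq <- count / (2 * size)
  freq[size == 0] <- NA_real_
  ginfo <- data.frame(group = levels(group), stringsAsFactors = FALSE)
  if (!is.null(dataset$sample_meta)) {
    m <- dataset$sample_meta[match(levels(group), paste(
      dataset$sample_meta$broodline, dataset$sample_meta$generation,
      sep = ":")), ]
    if (!anyNA(m$sample_id)) {
      ginfo$broodline <- m$broodline
      ginfo$generation <- m$generation
    }
  }
  structure(list(freq = freq, size = size, groups = ginfo),
            class = "frequency_table")
}

#' Smouse-Peakall squared genotypic distance matrix
#'
#' Codominant-genotypic squared distance between individuals: per locus, half
#' the squared Euclidean distance between allele-count vectors, summed over
#' loci called in both individuals. This reproduces the classic genotype
#' table (AA-AA 0, AA-AB 1, AB-AB 0, AB-AC 1, AB-CD 2, AA-BC 3, AA-BB 4).
#' Missing data use pairwise deletion with rescaling: each pair's sum is
#' multiplied by `total loci / shared called loci`, keeping distances
#' comparable across missingness patterns without imputing frequencies.
#'
#' @param dataset a [genotype_dataset()] (at least two samples).
#' @return symmetric matrix of squared distances with zero diagonal and a
#'   `shared` attribute (matrix of shared-called locus counts).
#' @export
genotypic_distance_matrix <- function(dataset) {
  n <- n_samples(dataset); L <- n_loci(dataset)
  if (n < 2) stop("need at least two samples")
  # allele-count columns: one per (locus, observed allele), weighted so that
  # squared Euclidean distance over columns equals 1/2 sum (count diff)^2
  cols <- list(); col_locus <- integer()
  for (j in seq_len(L)) {
    for (al in locus_alleles(dataset, j)) {
      cnt <- (dataset$a1[, j] == al) + (dataset$a2[, j] == al)
      cols[[length(cols) + 1L]] <- cnt
      col_locus <- c(col_locus, j)
    }
  }
  Y <- do.call(cbind, cols) / sqrt(2)
  called <- !is.na(dataset$a1)               # samples x loci
  Ym <- ifelse(is.na(Y), 0, Y)
  M <- (called + 0)[, col_locus, drop = FALSE]
  # squared distance over shared columns
  S <- tcrossprod(Ym^2, M) + tcrossprod(M, Ym^2) - 2 * tcrossprod(Ym)
  shared <- tcrossprod(called + 0)           # shared called loci per pair
  off_empty <- shared == 0 & !diag(TRUE, n)
  if (any(off_empty)) {
    idx <- which(off_empty, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    stop("sample pairs share no called loci: ",
         paste(dataset$sample_ids[idx[, 1]], dataset$sample_ids[idx[, 2]],
               sep = "/", collapse = ", "))
  }
  D <- S * L / pmax(shared, 1)
  D[abs(D) < 1e-12] <- 0
  diag(D) <- 0
  dimnames(D) <- list(dataset$sample_ids, dataset$sample_ids)
  attr(D, "shared") <- shared
  D
}

#' Principal coordinates of a squared-distance matrix
#'
#' Classical metric multidimensional scaling: Gower double-centering of
#' `-D2/2` followed by eigendecomposition; coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues. Negative
#' eigenvalues are reported but contribute no coordinates. Axis signs are
#' fixed by forcing the largest-magnitude loading of each axis positive, so
#' ordinations are reproducible across sample orderings.
#'
#' @param D2 symmetric matrix of squared distances, zero diagonal (e.g. from
#'   [genotypic_distance_matrix()]).
#' @param n_axes number of leading axes to return.
#' @return a list of class `ordination`: `coords` (samples x axes),
#'   `eigenvalues` (all), `explained` (fraction of positive-eigenvalue
#'   variance per returned axis).
#' @export
principal_coordinates <- function(D2, n_axes = 2) {
  stopifnot(isSymmetric(unname(D2)), all(diag(D2) == 0))
  n <- nrow(D2)
  fit <- suppressWarnings(cmdscale(sqrt(D2), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > 1e-9)
  if (n_axes > pos) {
    warning("n_axes exceeds the number of positive eigenvalues (", pos,
            "); truncating")
    n_axes <- pos
  }
  n_axes <- min(n_axes, ncol(fit$points))
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  rownames(coords) <- rownames(D2)
  structure(list(
    coords = coords,
    eigenvalues = eig,
    explained = pmax(eig[seq_len(n_axes)], 0) / sum(pmax(eig, 0))),
    class = "ordination")
}

#' Scatter plot of the leading ordination axes
#'
#' @param ord an `ordination` from [principal_coordinates()].
#' @param group optional vector colouring the samples (e.g. broodline).
#' @param axes which two axes to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot_ordination <- function(ord, group = NULL, axes = c(1, 2), ...) {
  xy <- ord$coords[, axes, drop = FALSE]
  col <- if (is.null(group)) 1 else as.integer(factor(group))
  graphics::plot(xy, col = col, pch = 19,
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1],
                                100 * ord$explained[axes[1]]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2],
                                100 * ord$explained[axes[2]]), ...)
  if (!is.null(group))
    graphics::legend("topright", legend = levels(factor(group)),
                     col = seq_along(levels(factor(group))), pch = 19)
  invisible(ord)
}
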