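#' Diploid SNP genotype dataset
#'
#' The central container of the package: a samples-by-loci matrix of unordered
#' diploid allele calls plus per-sample brood metadata. Allele calls are stored
#' as two integer matrices `a1`, `a2` with `a1 <= a2` (the pair is unordered;
#' `NA` in both marks a missing genotype). Allele codes are 1-based: code 1 is
#' the tracked allele by default (the VCF REF allele or, for GenePop input, the
#' lowest allele code present at the locus). All frequencies reported by the
#' package are frequencies of the tracked allele.
#'
#' @param a1,a2 integer matrices (samples x loci) of allele codes, `NA` where
#'   the genotype is missing. They need not be ordered on input; they are
#'   normalised so that `a1 <= a2` elementwise.
#' @param sample_ids character vector of unique sample identifiers.
#' @param locus_ids character vector of unique locus identifiers
#'   (tag-id + offset convention, e.g. `"Coho_64855-71"`).
#' @param sample_meta data frame with columns `sample_id`, `brood_year`,
#'   `broodline`, `generation` (one row per sample), or `NULL`.
#' @param tracked_allele integer vector, one allele code per locus, whose
#'   frequency the analyses follow. Defaults to 1 for every locus.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(a1, a2, sample_ids, locus_ids,
                             sample_meta = NULL, tracked_allele = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2)))
    stop("a1 and a2 must have identical dimensions")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids")
  if (nrow(a1) != length(sample_ids) || ncol(a1) != length(locus_ids))
    stop("call matrices must be samples x loci")
  if (xor(is.na(a1), is.na(a2)) |> any())
    stop("half-missing genotypes are not allowed")
  # unordered pair: normalise
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(sample_ids, locus_ids)
  if (is.null(tracked_allele)) tracked_allele <- rep(1L, length(locus_ids))
  tracked_allele <- as.integer(tracked_allele)
  if (length(tracked_allele) != length(locus_ids))
    stop("tracked_allele must have one entry per locus")
  if (!is.null(sample_meta)) {
    req <- c("sample_id", "brood_year", "broodline", "generation")
    miss <- setdiff(req, names(sample_meta))
    if (length(miss))
      stop("sample_meta lacks columns: ", paste(miss, collapse = ", "))
    sample_meta <- sample_meta[match(sample_ids, sample_meta$sample_id), req]
    if (anyNA(sample_meta$sample_id))
      stop("sample_meta does not cover all samples")
    rownames(sample_meta) <- NULL
  }
  structure(
    list(a1 = a1, a2 = a2,
         sample_ids = as.character(sample_ids),
         locus_ids = as.character(locus_ids),
         sample_meta = sample_meta,
         tracked_allele = tracked_allele),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", n_samples(x), "samples x", n_loci(x), "loci\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  if (!is.null(x$sample_meta)) {
    tab <- table(x$sample_meta$broodline)
    cat("  broodlines:",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname genotype_dataset
#' @param x a `genotype_dataset`.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname genotype_dataset
#' @export
n_loci <- function(x) length(x$locus_ids)

#' Dosage matrix of the tracked allele
#'
#' @param x a `genotype_dataset`.
#' @return integer matrix (samples x loci) with entries 0, 1, 2 or `NA`:
#'   the number of copies of the tracked allele in each call.
#' @export
tracked_dosage <- function(x) {
  tr <- rep(x$tracked_allele, each = nrow(x$a1))
  d <- (x$a1 == tr) + (x$a2 == tr)
  storage.mode(d) <- "integer"
  dimnames(d) <- dimnames(x$a1)
  d
}

#' Subset a genotype dataset
#'
#' @param x a `genotype_dataset`.
#' @param samples,loci index vectors (logical, integer or character) selecting
#'   samples / loci to keep; `NULL` keeps all.
#' @return a `genotype_dataset`.
#' @export
subset_dataset <- function(x, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  li <- if (is.null(loci)) seq_along(x$locus_ids) else loci
  if (is.character(si)) si <- match(si, x$sample_ids)
  if (is.character(li)) li <- match(li, x$locus_ids)
  meta <- x$sample_meta
  a1 <- x$a1[si, li, drop = FALSE]
  genotype_dataset(
    a1, x$a2[si, li, drop = FALSE],
    sample_ids = x$sample_ids[si][seq_len(nrow(a1))],
    locus_ids = colnames(a1),
    sample_meta = if (!is.null(meta)) meta[match(rownames(a1), meta$sample_id), ],
    tracked_allele = x$tracked_allele[if (is.logical(li)) which(li) else li])
}

# observed allele codes at locus j, sorted
locus_alleles <- function(x, j) {
  sort(unique(c(x$a1[, j], x$a2[, j])), na.last = NA)
}

# per-locus count of distinct observed alleles (0 for all-missing loci)
locus_n_alleles <- function(x) {
  vapply(seq_len(n_loci(x)), function(j) length(locus_alleles(x, j)), 0L)
}

#' Read the sample metadata sidecar table
#'
#' Neither GenePop nor VCF carries brood metadata, so it travels in a
#' tab-delimited sidecar keyed by `sample_id` with columns `brood_year`,
#' `broodline`, `generation`. `broodline` and `generation` may be omitted, in
#' which case they are derived from `brood_year`: broodlines follow the 3-year
#' generation interval, so `brood_year mod 3` identifies the line
#' (2000-founded = "A", 2001 = "B", 2002 = "C") and the generation index is
#' `(brood_year - founding_year) / 3`.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param founding_years named integer vector mapping broodline label to
#'   founding brood year.
#' @return data frame with columns `sample_id`, `brood_year`, `broodline`,
#'   `generation`.
#' @export
read_sample_metadata <- function(path,
                                 founding_years = c(A = 2000, B = 2001, C = 2002)) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(m)) stop("metadata lacks a sample_id column")
  if (!"brood_year" %in% names(m)) stop("metadata lacks a brood_year column")
  rem <- founding_years %% 3
  if (!"broodline" %in% names(m)) {
    idx <- match(m$brood_year %% 3, rem)
    if (anyNA(idx)) stop("cannot derive broodline for some brood years")
    m$broodline <- names(founding_years)[idx]
  }
  if (!"generation" %in% names(m)) {
    m$generation <- (m$brood_year - founding_years[m$broodline]) %/% 3L
  }
  m$generation <- as.integer(m$generation)
  m[, c("sample_id", "brood_year", "broodline", "generation")]
}

#' @rdname read_sample_metadata
#' @param dataset a `genotype_dataset` whose `sample_meta` is written.
#' @param meta_path output path.
#' @export
write_sample_metadata <- function(dataset, meta_path) {
  if (is.null(dataset$sample_meta)) stop("dataset has no sample metadata")
  write.table(dataset$sample_meta, meta_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(meta_path)
}
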