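#' Build the cross-method, cross-broodline consensus table
#'
#' Assembles per-locus significance across every (method, broodline) test
#' into one matrix and derives the candidate tiers: *candidate* (significant
#' in at least one test), *highly significant* (at least two tests overall),
#' and per-broodline *consensus* (at least two of the three methods within
#' one broodline). Loci a method never scanned are recorded as not-tested
#' (`NA`), distinct from tested-but-not-significant (`FALSE`), so a missing
#' generation cannot silently deflate consensus.
#'
#' @param scans list of scan results. Each element is either a `slope_scan` /
#'   `fst_scan` (method and broodline read from attributes) or any data
#'   frame with columns `locus`, `outlier` and optionally `scannable`, plus
#'   `method`/`broodline` columns or attributes — externally computed
#'   Bayesian outlier tables are supplied this way.
#' @return list of class `consensus_table`: `matrix` (loci x tests, entries
#'   `TRUE`/`FALSE`/`NA`), `tests` (data frame: test, method, broodline),
#'   `tiers` (per-locus data frame with `n_significant`, `n_tested`,
#'   `candidate`, `highly_significant` and one consensus column per
#'   broodline), `shared_by_broodlines` (per method, count of loci
#'   significant in >= 2 broodlines and in all).
#' @export
build_consensus <- function(scans) {
  stopifnot(is.list(scans), length(scans) >= 2)
  norm <- lapply(scans, function(s) {
    method <- attr(s, "method") %||% unique(s$method)
    broodline <- attr(s, "broodline") %||% unique(s$broodline)
    if (is.null(method) || length(method) != 1)
      stop("scan without a single method label")
    if (is.null(broodline) || length(broodline) != 1)
      stop("scan without a single broodline label")
    sig <- s$outlier
    if (!is.null(s$scannable)) sig[!s$scannable] <- NA
    data.frame(locus = s$locus, sig = sig,
               method = method, broodline = broodline,
               stringsAsFactors = FALSE)
  })
  flat <- do.call(rbind, norm)
  loci <- sort(unique(flat$locus))
  tests <- unique(flat[, c("method", "broodline")])
  tests$test <- paste(tests$method, tests$broodline, sep = ":")
  mat <- matrix(NA, length(loci), nrow(tests),
                dimnames = list(loci, tests$test))
  for (i in seq_len(nrow(tests))) {
    sub <- flat[flat$method == tests$method[i] &
                  flat$broodline == tests$broodline[i], ]
    if (anyDuplicated(sub$locus))
      stop("duplicate loci in test ", tests$test[i])
    idx <- match(sub$locus, loci)
    mat[idx, i] <- sub$sig
  }
  n_sig <- rowSums(mat, na.rm = TRUE)
  n_tested <- rowSums(!is.na(mat))
  tiers <- data.frame(locus = loci, n_significant = n_sig,
                      n_tested = n_tested,
                      candidate = n_sig >= 1,
                      highly_significant = n_sig >= 2,
                      stringsAsFactors = FALSE)
  for (bl in unique(tests$broodline)) {
    cols <- tests$test[tests$broodline == bl]
    tiers[[paste0("consensus_", bl)]] <-
      rowSums(mat[, cols, drop = FALSE], na.rm = TRUE) >= 2
  }
  shared <- lapply(split(tests$test, tests$method), function(cols) {
    per_bl <- mat[, cols, drop = FALSE]
    nb <- rowSums(per_bl, na.rm = TRUE)
    c(two_broodlines = sum(nb >= 2), all_broodlines = sum(nb == ncol(per_bl)))
  })
  structure(list(matrix = mat, tests = tests[, c("test", "method", "broodline")],
                 tiers = tiers, shared_by_broodlines = shared),
            class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat("consensus table:", nrow(x$matrix), "loci x", ncol(x$matrix), "tests\n")
  cat("  candidates (>=1 test):", sum(x$tiers$candidate), "\n")
  cat("  highly significant (>=2 tests):", sum(x$tiers$highly_significant),
      "\n")
  invisible(x)
}

#' Three-set Venn region counts of flagged loci
#'
#' Counts the loci in each of the seven regions of the three-set Venn diagram
#' along the chosen axis: by `method`, a locus belongs to a method's set if
#' significant in at least one broodline with that method; by `broodline`,
#' if significant by at least one method in that broodline. Only flagged
#' loci (candidates) are counted, so the region counts partition the
#' candidate set exactly.
#'
#' @param ct a `consensus_table`.
#' @param axis `"method"` or `"broodline"`.
#' @return named integer vector of region counts; names like `"A"`, `"A&B"`,
#'   `"A&B&C"` built from the axis labels.
#' @export
venn_counts <- function(ct, axis = c("method", "broodline")) {
  axis <- match.arg(axis)
  labels <- unique(ct$tests[[axis]])
  member <- vapply(labels, function(lab) {
    cols <- ct$tests$test[ct$tests[[axis]] == lab]
    rowSums(ct$matrix[, cols, drop = FALSE], na.rm = TRUE) >= 1
  }, logical(nrow(ct$matrix)))
  flagged <- rowSums(member) >= 1
  member <- member[flagged, , drop = FALSE]
  key <- apply(member, 1, function(m) paste(labels[m], collapse = "&"))
  regions <- unlist(lapply(seq_along(labels), function(k)
    combn(labels, k, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  counts <- table(factor(key, levels = regions))
  setNames(as.integer(counts), regions)
}

#' Nearest genes around mapped outlier positions
#'
#' For every retained alignment position of every query locus, finds the
#' genes on the same chromosome whose span lies within `window` bases of the
#' position (distance 0 if the position falls inside the span; the window
#' boundary is inclusive) and reports the `k` nearest, ranked by distance.
#' Multi-mapped loci are annotated at every retained position. Candidate
#' genes are collected with [IRanges::findOverlaps()] on the padded windows;
#' ties in distance are broken by smaller gene start, then lexicographic
#' gene id, so output is deterministic.
#'
#' @param alignments data frame from [read_alignments()], typically
#'   restricted to candidate loci.
#' @param genes data frame from [read_gene_annotation()].
#' @param window maximum distance in bases (inclusive).
#' @param k number of genes to report per mapped position.
#' @return data frame with columns `locus_id`, `chrom`, `pos`, `gene_id`,
#'   `name`, `distance`, `rank`. Positions on chromosomes absent from the
#'   annotation yield no rows (with a warning).
#' @export
nearest_genes <- function(alignments, genes, window = 100000, k = 3) {
  if (!nrow(alignments))
    return(data.frame(locus_id = character(), chrom = character(),
                      pos = integer(), gene_id = character(),
                      name = character(), distance = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  missing_chrom <- !alignments$chrom %in% genes$chrom
  if (any(missing_chrom))
    warning(sum(missing_chrom),
            " mapped positions lie on chromosomes absent from the annotation")
  all_chroms <- union(alignments$chrom, genes$chrom)
  qry <- GenomicRanges::GRanges(
    factor(alignments$chrom, all_chroms),
    IRanges::IRanges(alignments$pos, width = 1))
  sbj <- GenomicRanges::GRanges(
    factor(genes$chrom, all_chroms),
    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(qry, sbj, maxgap = window)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  pos <- alignments$pos[qh]
  d <- pmax(genes$start[sh] - pos, pos - genes$end[sh], 0L)
  keep <- d <= window   # findOverlaps maxgap admits distance window + 1
  qh <- qh[keep]; sh <- sh[keep]; d <- d[keep]
  if (!length(qh))
    return(nearest_genes(alignments[0, ], genes, window, k))
  ord <- order(qh, d, genes$start[sh], genes$gene_id[sh])
  qh <- qh[ord]; sh <- sh[ord]; d <- d[ord]
  rank <- stats::ave(d, qh, FUN = seq_along)
  take <- rank <= k
  data.frame(
    locus_id = alignments$locus_id[qh[take]],
    chrom = alignments$chrom[qh[take]],
    pos = alignments$pos[qh[take]],
    gene_id = genes$gene_id[sh[take]],
    name = genes$name[sh[take]],
    distance = as.integer(d[take]),
    rank = as.integer(rank[take]),
    stringsAsFactors = FALSE)
}
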