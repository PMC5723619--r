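#' Read a GenePop genotype file
#'
#' Parses the classic GenePop dialect: a title line, locus names (one per line
#' or comma-separated on one line), then population blocks introduced by a
#' line equal to `POP` / `Pop` / `pop`, each row `sample_id ,  0101 0202 ...`
#' with 4- or 6-digit diploid codes and `0000` / `000000` for missing. The
#' allele-code width is auto-detected from the first genotype row.
#'
#' @param path path to a GenePop file.
#' @param meta optional metadata data frame (see [read_sample_metadata()])
#'   attached as `sample_meta`.
#' @return a [genotype_dataset()]. The per-locus tracked allele is the lowest
#'   allele code observed. Population block membership is returned in the
#'   `pop` attribute (integer block index per sample).
#' @export
read_genepop <- function(path, meta = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a GenePop file: too few lines")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a GenePop file: no POP separator")
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  body <- lines[first_pop:length(lines)]
  pop_idx <- cumsum(grepl("^\\s*pop\\s*$", body, ignore.case = TRUE))
  rows <- body[!grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)]
  pop_of_row <- pop_idx[!grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)]
  if (!length(rows)) stop("GenePop file has no genotype rows")

  parts <- regmatches(rows, regexpr(",", rows), invert = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad))
    stop("GenePop parse error at line without sample/genotype comma: ",
         rows[which(bad)[1]])
  ids <- trimws(vapply(parts, `[[`, "", 1))
  gstr <- vapply(parts, `[[`, "", 2)
  gtok <- strsplit(trimws(gstr), "\\s+")
  ragged <- lengths(gtok) != length(loci)
  if (any(ragged)) {
    i <- which(ragged)[1]
    stop(sprintf(
      "ragged genotype row for sample '%s': %d codes, %d loci declared",
      ids[i], lengths(gtok)[i], length(loci)))
  }
  gmat <- matrix(unlist(gtok), nrow = length(rows), byrow = TRUE)
  width <- unique(as.vector(nchar(gmat)))
  if (length(width) != 1 || !width %in% c(4L, 6L))
    stop("unknown GenePop allele-code width (expected uniform 4 or 6 digits)")
  half <- width / 2
  a1 <- matrix(as.integer(substr(gmat, 1, half)), nrow = nrow(gmat))
  a2 <- matrix(as.integer(substr(gmat, half + 1, width)), nrow = nrow(gmat))
  if (anyNA(a1) || anyNA(a2))
    stop("non-numeric allele codes in GenePop body")
  # code 0 on either side = missing genotype
  missing <- a1 == 0L | a2 == 0L
  a1[missing] <- NA_integer_; a2[missing] <- NA_integer_

  ds <- genotype_dataset(a1, a2, sample_ids = ids, locus_ids = loci,
                         sample_meta = meta)
  tr <- vapply(seq_along(loci), function(j) {
    al <- locus_alleles(ds, j)
    if (length(al)) al[1] else 1L
  }, 0L)
  ds$tracked_allele <- tr
  attr(ds, "pop") <- pop_of_row
  ds
}

#' Write a GenePop genotype file
#'
#' Emits 4-digit allele codes verbatim (allele codes must be in 1..99) with
#' `0000` for missing. One population block is written per group given by
#' `pop`; by default samples are grouped by `broodline:brood_year` when
#' metadata is present, else emitted as a single block.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @param pop optional factor-like vector (one per sample) defining the
#'   population blocks.
#' @param title title line; defaults to a note naming the tracked-allele
#'   convention.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(dataset, path, pop = NULL,
                          title = "broodscan export; allele code 1 = tracked allele") {
  a1 <- dataset$a1; a2 <- dataset$a2
  if (any(a1 > 99L | a2 > 99L, na.rm = TRUE))
    stop("GenePop 4-digit codes require allele codes <= 99")
  if (is.null(pop)) {
    pop <- if (!is.null(dataset$sample_meta))
      paste(dataset$sample_meta$broodline, dataset$sample_meta$brood_year)
    else rep("all", n_samples(dataset))
  }
  pop <- factor(pop, levels = unique(pop))
  code <- matrix(sprintf("%02d%02d",
                         ifelse(is.na(a1), 0L, a1),
                         ifelse(is.na(a2), 0L, a2)),
                 nrow = nrow(a1))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(dataset$locus_ids, con)
  for (lev in levels(pop)) {
    writeLines("POP", con)
    idx <- which(pop == lev)
    writeLines(paste0(dataset$sample_ids[idx], " ,  ",
                      apply(code[idx, , drop = FALSE], 1, paste,
                            collapse = " ")),
               con)
  }
  invisible(path)
}
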