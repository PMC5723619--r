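#' Read genotypes from a VCF file
#'
#' Thin wrapper over [vcfR::read.vcfR()] that extracts the GT field into the
#' package's internal representation. VCF allele indices are shifted up by one
#' (REF becomes allele code 1, the tracked allele); the phase separator is
#' discarded, so `0|1` and `1/0` yield the same unordered call, and `./.`
#' becomes missing. Multiallelic records are retained with all allele codes;
#' the QC stage removes non-biallelic loci later.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param meta optional metadata data frame (see [read_sample_metadata()]).
#' @return a [genotype_dataset()].
#' @export
read_vcf_genotypes <- function(path, meta = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2) stop("VCF has no sample columns")
  fmt <- strsplit(vcf@gt[, "FORMAT"], ":")
  if (!all(vapply(fmt, function(f) "GT" %in% f, TRUE)))
    stop("VCF records lack the GT format key")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  if (is.null(ids) || anyNA(ids) || any(ids == "."))
    ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  samples <- colnames(gt)
  parse_side <- function(k) {
    side <- sub("^([^/|]*)[/|]([^/|]*)$", sprintf("\\%d", k), gt)
    side[which(side == "." | side == gt)] <- NA  # unmatched or half calls
    matrix(as.integer(side) + 1L, nrow = nrow(gt))
  }
  a1 <- suppressWarnings(parse_side(1))
  a2 <- suppressWarnings(parse_side(2))
  both_na <- is.na(a1) | is.na(a2)
  a1[both_na] <- NA_integer_; a2[both_na] <- NA_integer_
  genotype_dataset(t(a1), t(a2), sample_ids = samples, locus_ids = ids,
                   sample_meta = meta)
}

#' Write a genotype dataset as a minimal VCF
#'
#' Emits a VCF v4.2 with GT-only genotype columns. Allele codes are rendered
#' as nucleotides (code 1 = REF = `A`, codes 2..k = ALT `C`,`G`,`T`); positions
#' default to the locus index on a synthetic contig unless `chrom`/`pos` are
#' given.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @param chrom,pos optional per-locus coordinates.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(dataset, path, chrom = NULL, pos = NULL) {
  L <- n_loci(dataset)
  if (is.null(chrom)) chrom <- rep("sim_contig", L)
  if (is.null(pos)) pos <- seq_len(L)
  nt <- c("A", "C", "G", "T")
  max_code <- vapply(seq_len(L), function(j) {
    al <- locus_alleles(dataset, j)
    if (length(al)) max(al) else 2L
  }, 0L)
  if (any(max_code > 4L)) stop("VCF writer supports allele codes up to 4")
  alt <- vapply(max_code, function(m)
    if (m >= 2) paste(nt[2:m], collapse = ",") else nt[2], "")
  gt_codes <- matrix(
    ifelse(is.na(dataset$a1), "./.",
           paste0(dataset$a1 - 1L, "/", dataset$a2 - 1L)),
    nrow = n_samples(dataset))
  body <- cbind(chrom, pos, dataset$locus_ids, nt[1], alt, ".", "PASS", ".",
                "GT", t(gt_codes))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=broodscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$sample_ids), collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
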