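#' Read locus tag alignments from a SAM file
#'
#' Reads the alignment records of RAD locus tag sequences against a reference
#' assembly. The locus id is taken from the read name. Unmapped records are
#' dropped; records below the mapping-quality cutoff are dropped; secondary
#' and supplementary alignments that pass the cutoff are kept, so one locus
#' may contribute several genome positions (multi-mapping is retained on
#' purpose — every candidate location is annotated downstream).
#'
#' @param path path to a SAM file.
#' @param min_mapq minimum mapping quality to keep a record (default 10;
#'   positions with mapQ below this are discarded).
#' @return data frame with columns `locus_id`, `chrom`, `pos` (1-based
#'   leftmost aligned base), `mapq`, `strand`.
#' @export
read_alignments <- function(path, min_mapq = 10) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(trimws(body))]
  out <- data.frame(locus_id = character(), chrom = character(),
                    pos = integer(), mapq = integer(), strand = character(),
                    stringsAsFactors = FALSE)
  if (!length(body)) return(out)
  f <- strsplit(body, "\t")
  short <- lengths(f) < 11
  if (any(short))
    stop("unparseable SAM line (fewer than 11 fields) at body line ",
         which(short)[1])
  flag <- as.integer(vapply(f, `[[`, "", 2))
  pos <- as.integer(vapply(f, `[[`, "", 4))
  mapq <- as.integer(vapply(f, `[[`, "", 5))
  if (anyNA(flag) || anyNA(pos) || anyNA(mapq))
    stop("unparseable SAM line (non-numeric FLAG/POS/MAPQ) at body line ",
         which(is.na(flag) | is.na(pos) | is.na(mapq))[1])
  unmapped <- bitwAnd(flag, 4L) != 0L
  keep <- !unmapped & mapq >= min_mapq
  data.frame(
    locus_id = vapply(f, `[[`, "", 1)[keep],
    chrom = vapply(f, `[[`, "", 3)[keep],
    pos = pos[keep],
    mapq = mapq[keep],
    strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+"),
    stringsAsFactors = FALSE)
}

#' Read gene records from a GFF3 annotation
#'
#' Extracts features of type `gene` via [ape::read.gff()]. The gene name is
#' taken from the `Name=` attribute, falling back to `ID=`.
#'
#' @param path path to a GFF3 file.
#' @return data frame with columns `gene_id`, `name`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @export
read_gene_annotation <- function(path) {
  g <- ape::read.gff(path, GFF3 = TRUE)
  g <- g[g$type == "gene", , drop = FALSE]
  attr_field <- function(attrs, key) {
    hit <- regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs)
    val <- rep(NA_character_, length(attrs))
    val[hit > 0] <- sub(paste0("^;?\\s*", key, "="), "",
                        regmatches(attrs, hit))
    val
  }
  ids <- attr_field(as.character(g$attributes), "ID")
  nms <- attr_field(as.character(g$attributes), "Name")
  if (any(is.na(g$start) | is.na(g$end)))
    stop("GFF gene rows with missing coordinates")
  if (any(g$start > g$end)) stop("GFF gene rows with start > end")
  data.frame(
    gene_id = ifelse(is.na(ids), paste0("gene", seq_len(nrow(g))), ids),
    name = ifelse(is.na(nms), ids, nms),
    chrom = as.character(g$seqid),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = as.character(g$strand),
    stringsAsFactors = FALSE,
    row.names = NULL)
}
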