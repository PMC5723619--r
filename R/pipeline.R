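#' Pipeline run configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. Stage configs keep
#' their own defaults; the global `seed` drives simulation and every
#' stochastic scan deterministically.
#'
#' @param out_dir output directory for all stage outputs and the manifest.
#' @param sim a [sim_config()].
#' @param qc a [qc_config()].
#' @param alpha temporal-scan significance level.
#' @param fst_sims,ci,fdr,min_group_size FST-scan parameters.
#' @param sam,gff optional paths to a SAM file of locus tag alignments and a
#'   GFF3 annotation; when both are given candidates are gene-annotated.
#' @param bayes optional external Bayesian outlier table (data frame or TSV
#'   path with columns `locus`, `broodline`, `outlier`) merged into the
#'   consensus as a third method.
#' @param seed global integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, sim = sim_config(), qc = qc_config(),
                       alpha = 0.01, fst_sims = 50000, ci = 0.95, fdr = 0.1,
                       min_group_size = 8, sam = NULL, gff = NULL,
                       bayes = NULL, seed = 1L) {
  structure(list(out_dir = out_dir, sim = sim, qc = qc, alpha = alpha,
                 fst_sims = fst_sims, ci = ci, fdr = fdr,
                 min_group_size = min_group_size, sam = sam, gff = gff,
                 bayes = bayes, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [run_config()] (`sim` and `qc` as nested maps of their constructors'
#' arguments); keys not present keep their defaults, and arguments passed in
#' `...` override the file.
#'
#' @param path YAML file path.
#' @param ... overrides forwarded to [run_config()].
#' @return a `run_config`.
#' @export
load_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  args <- list(...)
  take <- function(key) if (!is.null(args[[key]])) args[[key]] else y[[key]]
  sim <- do.call(sim_config, as.list(y$sim))
  qc <- do.call(qc_config, as.list(y$qc))
  extra <- setdiff(names(y), c("sim", "qc"))
  base <- y[extra]
  base[names(args)] <- args
  base$sim <- if (is.null(args$sim)) sim else args$sim
  base$qc <- if (is.null(args$qc)) qc else args$qc
  do.call(run_config, base)
}

#' Run the full simulate-to-consensus pipeline
#'
#' Executes the stages in order — simulate, write/re-read the external
#' formats, QC cascade, principal coordinates, temporal scan and FST scan
#' per broodline, consensus, optional gene annotation, truth-vs-called
#' evaluation — writing each stage's output under `config$out_dir` and a
#' JSON manifest (`manifest.json`) recording package version, seed, input
#' hashes, stage outputs and timings. On simulated input the evaluation
#' stage writes a per-method confusion matrix against the simulated truth.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_run`: `manifest`, `dataset` (filtered),
#'   `ordination`, `scans`, `consensus`, `evaluation`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages <- list()
  tick <- function(name, paths) {
    stages[[name]] <<- list(
      outputs = as.character(paths),
      md5 = unname(tools::md5sum(as.character(paths))),
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    t0 <<- Sys.time()
  }
  set.seed(config$seed)
  config$sim$seed <- config$seed

  # 1. simulate
  study <- simulate_study(config$sim)
  sim_paths <- write_study(study, file.path(config$out_dir, "sim"))
  tick("simulate", sim_paths)

  # 2. ingest through the external formats
  meta <- read_sample_metadata(sim_paths["meta"])
  ds_raw <- read_vcf_genotypes(sim_paths["vcf"], meta = meta)
  tick("ingest", sim_paths["vcf"])

  # 3. QC cascade
  qc <- run_qc(ds_raw, config$qc)
  p_qc <- file.path(config$out_dir, "qc_report.tsv")
  write_qc_report(qc$report, p_qc)
  p_filtered <- file.path(config$out_dir, "filtered.vcf")
  write_vcf_genotypes(qc$dataset, p_filtered)
  tick("qc", c(p_qc, p_filtered))

  # 4. ordination
  D2 <- genotypic_distance_matrix(qc$dataset)
  ord <- principal_coordinates(D2, n_axes = 2)
  coords <- data.frame(sample = rownames(ord$coords), ord$coords,
                       qc$dataset$sample_meta[
                         match(rownames(ord$coords),
                               qc$dataset$sample_meta$sample_id),
                         c("broodline", "brood_year")])
  p_pca <- file.path(config$out_dir, "pcoa.tsv")
  write.table(coords, p_pca, sep = "\t", quote = FALSE, row.names = FALSE)
  tick("pcoa", p_pca)

  # 5-6. scans per broodline
  blines <- sort(unique(qc$dataset$sample_meta$broodline))
  scans <- list()
  p_scan <- character()
  for (i in seq_along(blines)) {
    bl <- blines[i]
    ts <- run_temporal_scan(qc$dataset, bl, alpha = config$alpha)
    pth <- file.path(config$out_dir, paste0("temporal_", bl, ".tsv"))
    write.table(as.data.frame(ts), pth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    scans[[paste0("temporal_", bl)]] <- ts
    p_scan <- c(p_scan, pth)
  }
  tick("temporal_scan", p_scan)
  p_scan <- character()
  for (i in seq_along(blines)) {
    bl <- blines[i]
    fs <- run_fst_scan(qc$dataset, bl, n_sims = config$fst_sims,
                       ci = config$ci, fdr = config$fdr,
                       min_group_size = config$min_group_size,
                       seed = config$seed + 7919L * i)
    pth <- file.path(config$out_dir, paste0("fst_", bl, ".tsv"))
    write.table(as.data.frame(fs), pth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    scans[[paste0("fst_", bl)]] <- fs
    p_scan <- c(p_scan, pth)
  }
  tick("fst_scan", p_scan)

  # 7. consensus
  inputs <- scans
  if (!is.null(config$bayes)) {
    bay <- if (is.character(config$bayes))
      read.delim(config$bayes, stringsAsFactors = FALSE) else config$bayes
    for (bl in unique(bay$broodline)) {
      sub <- bay[bay$broodline == bl, ]
      sub$method <- "bayes"
      inputs[[paste0("bayes_", bl)]] <- sub
    }
  }
  ct <- build_consensus(inputs)
  p_cons <- file.path(config$out_dir, "consensus.tsv")
  write.table(cbind(ct$tiers,
                    as.data.frame(ifelse(is.na(ct$matrix), "not_tested",
                                         ifelse(ct$matrix, "significant",
                                                "not_significant")))),
              p_cons, sep = "\t", quote = FALSE, row.names = FALSE)
  p_venn <- file.path(config$out_dir, "venn.json")
  jsonlite::write_json(list(method = as.list(venn_counts(ct, "method")),
                            broodline = as.list(venn_counts(ct, "broodline"))),
                       p_venn, auto_unbox = TRUE)
  tick("consensus", c(p_cons, p_venn))

  # 8. optional gene annotation of candidates
  annot <- NULL
  p_annot <- character()
  if (!is.null(config$sam) && !is.null(config$gff)) {
    aln <- read_alignments(config$sam)
    cand <- ct$tiers$locus[ct$tiers$candidate]
    aln <- aln[aln$locus_id %in% cand, , drop = FALSE]
    annot <- nearest_genes(aln, read_gene_annotation(config$gff))
    p_annot <- file.path(config$out_dir, "nearest_genes.tsv")
    write.table(annot, p_annot, sep = "\t", quote = FALSE, row.names = FALSE)
    tick("annotate", p_annot)
  }

  # 9. evaluation against simulated truth
  evaluation <- evaluate_calls(study, scans, ct)
  p_eval <- file.path(config$out_dir, "evaluation.tsv")
  write.table(evaluation, p_eval, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tick("evaluate", p_eval)

  manifest <- list(
    package = "broodscan",
    version = as.character(utils::packageVersion("broodscan")),
    seed = config$seed,
    n_loci = config$sim$n_loci,
    n_selected = config$sim$n_selected,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages)
  p_manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, digits = NA)
  structure(list(manifest = manifest, dataset = qc$dataset,
                 ordination = ord, scans = scans, consensus = ct,
                 evaluation = evaluation, annotation = annot,
                 paths = c(manifest = p_manifest)),
            class = "pipeline_run")
}

# confusion matrices of each method's union-over-broodline calls, plus the
# highly-significant consensus tier, against simulated truth
evaluate_calls <- function(study, scans, ct) {
  truth <- study$truth$labels
  sel <- truth$locus_id[truth$label == "selected"]
  methods <- unique(vapply(scans, function(s) attr(s, "method"), ""))
  rows <- lapply(methods, function(m) {
    called <- unique(unlist(lapply(scans[vapply(scans, function(s)
      identical(attr(s, "method"), m), TRUE)], function(s)
        s$locus[which(s$outlier)])))
    conf(m, called, sel, truth$locus_id)
  })
  tier <- ct$tiers$locus[ct$tiers$highly_significant]
  rows <- c(rows, list(conf("consensus_2plus", tier, sel, truth$locus_id)))
  do.call(rbind, rows)
}

conf <- function(label, called, sel, universe) {
  called <- intersect(called, universe)
  tp <- length(intersect(called, sel))
  fp <- length(setdiff(called, sel))
  fn <- length(setdiff(sel, called))
  tn <- length(universe) - tp - fp - fn
  data.frame(method = label, tp = tp, fp = fp, fn = fn, tn = tn,
             sensitivity = if (length(sel)) tp / length(sel) else NA_real_,
             stringsAsFactors = FALSE)
}
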