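# Orchestration: classify -> features -> coverage -> divergence ->
# contrasts -> report, with provenance (input checksums + config hash) so
# a report is reproducible from its config alone.

#' Build and validate a pipeline run configuration
#'
#' All referenced paths must exist; the focal term must be present in the
#' OBO file (checked at run time). CDS FASTA pairs plus an ortholog table
#' enable Ka/Ks estimation; alternatively a precomputed `kaks_table` TSV
#' (columns `gene_id`, `ka`, `ks`) bypasses estimation. Settings mirror
#' the analysis switches: coverage mode, TFBS flank, miRNA scope,
#' representative-transcript rule, whether unannotated genes fall in the
#' complement, and optional ortholog-based annotation transfer.
#'
#' @param gff,obo,gaf Paths to the gene models, ontology and annotations.
#' @param focal_term Focal ontology term id (e.g. the nervous system
#'   development term).
#' @param mirna_bed,tfbs_bed Optional BED site tracks.
#' @param cds_fasta_a,cds_fasta_b,orthologs Optional CDS FASTA pair and
#'   one-to-one ortholog TSV for Ka/Ks estimation.
#' @param kaks_table Optional precomputed per-gene Ka/Ks TSV.
#' @param ontology_level Optional level used to list comparison terms
#'   (`terms_at_level`) in the report; classification itself uses
#'   `focal_term`.
#' @param depth_mode `"min"` (default) or `"max"` level convention.
#' @param coverage_mode `"span"` or `"exonic"`.
#' @param tfbs_flank_bp,mirna_scope,representative See [gene_features()].
#' @param complement_includes_unannotated Keep unannotated genes in the
#'   universe (default TRUE).
#' @param transfer Transfer annotations through `orthologs` before
#'   classifying (for a non-model target species).
#' @param adjust Multiple-testing adjustment for the contrast table
#'   (`"none"` or `"holm"`).
#' @param out_dir Report directory (`NULL` = no files written).
#' @param seed Seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(gff, obo, gaf, focal_term,
                       mirna_bed = NULL, tfbs_bed = NULL,
                       cds_fasta_a = NULL, cds_fasta_b = NULL,
                       orthologs = NULL, kaks_table = NULL,
                       ontology_level = NULL, depth_mode = "min",
                       coverage_mode = c("span", "exonic"),
                       tfbs_flank_bp = 2000,
                       mirna_scope = c("utr3", "exonic"),
                       representative = c("longest_cds", "union"),
                       complement_includes_unannotated = TRUE,
                       transfer = FALSE,
                       adjust = c("none", "holm"),
                       out_dir = NULL, seed = 1) {
  coverage_mode <- match.arg(coverage_mode)
  mirna_scope <- match.arg(mirna_scope)
  representative <- match.arg(representative)
  adjust <- match.arg(adjust)
  cfg <- as.list(environment())
  paths <- c(gff = gff, obo = obo, gaf = gaf, mirna_bed = mirna_bed,
             tfbs_bed = tfbs_bed, cds_fasta_a = cds_fasta_a,
             cds_fasta_b = cds_fasta_b, orthologs = orthologs,
             kaks_table = kaks_table)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) {
    stopf("run_config: input file(s) not found: %s",
          paste(sprintf("%s (%s)", names(missing), missing), collapse = ", "))
  }
  if (isTRUE(transfer) && is.null(orthologs)) {
    stopf("run_config: transfer = TRUE requires an ortholog table")
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  # out_dir is where the report lands, not part of the analysis identity
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  flat <- cfg[order(names(cfg))]
  flat <- lapply(flat, function(v) if (is.null(v)) NA else v)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(flat, tmp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  unname(md5sum(tmp))
}

#' Run the full target-size analysis
#'
#' Executes: read inputs, (optionally) transfer annotations through
#' orthologs, partition genes by the focal term (true-path rule), compute
#' per-gene features, class-wise coverage, (optionally) per-pair Ka/Ks,
#' contrast every feature between the classes, and write the report.
#' Per-stage gene counts and exclusions are logged via `message()`.
#'
#' @param config A [run_config()].
#' @return A `run_report` (invisibly if `out_dir` is set): list with
#'   `partition`, `features`, `coverage`, `divergence` (or NULL),
#'   `contrasts`, `comparison_terms`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config

  nt_log("stage read: parsing inputs")
  genes <- read_gff3(cfg$gff)
  dag <- read_obo(cfg$obo)
  ann <- read_gaf(cfg$gaf)
  ann <- annotation_set(ann$map, ann$provenance, dag = dag)
  universe <- names(genes)
  nt_log("stage read: %d genes, %d ontology terms, %d annotated products",
         length(universe), nrow(dag$terms), length(ann$map))
  if (!cfg$focal_term %in% dag$terms$id) {
    stopf("run_pipeline: focal term '%s' absent from the ontology",
          cfg$focal_term)
  }

  orth <- if (!is.null(cfg$orthologs)) read_orthologs(cfg$orthologs) else NULL
  if (isTRUE(cfg$transfer)) {
    ann <- transfer_annotations(ann, orth, targets = universe)
    nt_log("stage transfer: annotations transferred to %d target genes",
           length(ann$map))
  }

  if (!cfg$complement_includes_unannotated) {
    annotated <- names(ann$map)[lengths(ann$map) > 0]
    universe <- intersect(universe, annotated)
    nt_log("stage classify: universe restricted to %d annotated genes",
           length(universe))
  }
  focal_label <- dag$terms$name[match(cfg$focal_term, dag$terms$id)]
  focal <- genes_for_term(dag, ann, cfg$focal_term, universe)
  partition <- make_partition(focal, universe, label = focal_label)
  nt_log("stage classify: %d focal / %d complement",
         length(partition$focal), length(partition$complement))

  mirna <- if (!is.null(cfg$mirna_bed)) read_bed(cfg$mirna_bed, "mirna_target")
  tfbs <- if (!is.null(cfg$tfbs_bed)) read_bed(cfg$tfbs_bed, "tfbs")
  feats <- feature_table(genes[universe], mirna_track = mirna,
                         tfbs_track = tfbs, flank_bp = cfg$tfbs_flank_bp,
                         mirna_scope = cfg$mirna_scope,
                         representative = cfg$representative)
  nt_log("stage features: %d rows", nrow(feats))

  coverage <- class_coverage(genes, partition, mode = cfg$coverage_mode,
                             features = feats)

  divergence <- NULL
  if (!is.null(cfg$kaks_table)) {
    kaks <- read_kaks_table(cfg$kaks_table)
    nt_log("stage divergence: %d precomputed estimates loaded", nrow(kaks))
  } else if (!is.null(cfg$cds_fasta_a) && !is.null(cfg$cds_fasta_b) &&
             !is.null(orth)) {
    fa <- read_fasta(cfg$cds_fasta_a)
    fb <- read_fasta(cfg$cds_fasta_b)
    rows <- list()
    for (i in seq_len(nrow(orth))) {
      a <- orth$gene_id_a[i]; b <- orth$gene_id_b[i]
      if (!a %in% names(fa) || !b %in% names(fb)) next
      est <- kaks_pair(fa[[a]], fb[[b]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = a, ka = est$ka, ks = est$ks,
        omega = if (est$saturated) NA_real_ else est$omega,
        stringsAsFactors = FALSE)
    }
    kaks <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(kaks)) {
      nt_log("stage divergence: %d pairs estimated", nrow(kaks))
    }
  } else {
    kaks <- NULL
  }
  if (!is.null(kaks) && nrow(kaks) > 0) {
    divergence <- class_divergence(kaks, partition)
    feats <- merge(feats, kaks[, c("gene_id", "omega")], by = "gene_id",
                   all.x = TRUE, sort = FALSE)
  }

  contrast_cols <- intersect(
    c("transcript_length", "cds_length", "utr_length", "n_exons",
      "n_mirna_sites", "n_tfbs", "omega"), names(feats))
  contrasts <- compare_all_features(feats, partition,
                                    columns = contrast_cols,
                                    adjust = cfg$adjust)

  comparison_terms <- NULL
  if (!is.null(cfg$ontology_level)) {
    ns <- term_namespace(dag, cfg$focal_term)
    comparison_terms <- terms_at_level(dag, ns, cfg$ontology_level,
                                       mode = cfg$depth_mode)
  }

  inputs <- Filter(Negate(is.null),
                   cfg[c("gff", "obo", "gaf", "mirna_bed", "tfbs_bed",
                         "cds_fasta_a", "cds_fasta_b", "orthologs",
                         "kaks_table")])
  provenance <- list(
    package_version = as.character(utils::packageVersion("neurotarget")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    input_md5 = setNames(as.list(unname(md5sum(unlist(inputs)))),
                         names(inputs)))

  report <- structure(list(partition = partition, features = feats,
                           coverage = coverage, divergence = divergence,
                           contrasts = contrasts,
                           comparison_terms = comparison_terms,
                           provenance = provenance,
                           config = cfg),
                      class = "run_report")

  if (!is.null(cfg$out_dir)) {
    write_report(report_tables(report), cfg$out_dir)
    nt_log("stage report: written to %s", cfg$out_dir)
    return(invisible(report))
  }
  report
}

# flatten a run_report into the named tables the report writer expects
report_tables <- function(report) {
  cov <- report$coverage
  summarize <- function(cl) {
    s <- cov[[cl]]
    data.frame(class = cl, n_genes = s$n_genes,
               gene_fraction = s$gene_fraction,
               total_span_bp = s$total_span_bp,
               total_exonic_bp = s$total_exonic_bp,
               bp_fraction = s$bp_fraction, stringsAsFactors = FALSE)
  }
  tabs <- list(
    features = report$features,
    contrasts = report$contrasts,
    class_summary = rbind(summarize("focal"), summarize("complement")),
    provenance = report$provenance)
  if (!is.null(report$divergence)) {
    d <- report$divergence
    tabs$divergence_summary <- data.frame(
      class = c("focal", "complement"),
      n = c(length(d$focal_omega), length(d$complement_omega)),
      n_excluded = c(d$n_excluded_focal, d$n_excluded_complement),
      median_omega = c(d$median_focal, d$median_complement),
      p_two_sided = d$test$p_two_sided, stringsAsFactors = FALSE)
  }
  if (!is.null(report$comparison_terms)) {
    tabs$comparison_terms <- data.frame(term_id = report$comparison_terms,
                                        stringsAsFactors = FALSE)
  }
  tabs
}

#' @export
print.run_report <- function(x, ...) {
  cat("Functional-class genomic target-size analysis\n")
  print(x$partition)
  print(x$coverage)
  cat("\nFeature contrasts (Wilcoxon rank-sum):\n")
  ct <- x$contrasts
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  %-18s p = %-10.3g r = %6.3f %s\n", ct$feature[i],
                ct$p[i], ct$rank_biserial[i], ct$stars[i]))
  }
  if (!is.null(x$divergence)) {
    cat("\n")
    print(x$divergence)
  }
  invisible(x)
}
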