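# Per-gene architecture metrics and class-wise genomic coverage — the
# "mutational target size" accounting.

#' Representative transcript of a gene
#'
#' Per-gene length metrics need one value per gene; the
#' representative is the transcript with the longest CDS, ties broken by
#' longest spliced length, then lexicographically smallest transcript id.
#'
#' @param gene A `gene_model`.
#' @return A `transcript_model`.
#' @export
representative_transcript <- function(gene) {
  txs <- gene$transcripts
  if (length(txs) == 1) return(txs[[1]])
  cdsl <- vapply(txs, cds_length, numeric(1))
  spll <- vapply(txs, spliced_length, numeric(1))
  ids <- vapply(txs, `[[`, character(1), "transcript_id")
  ord <- order(-cdsl, -spll, ids)
  txs[[ord[1]]]
}

#' Architecture and regulatory-repertoire features for one gene
#'
#' Length metrics come from the representative transcript (or, with
#' `representative = "union"`, from the union of exons/CDS across all
#' transcripts). Regulatory sites are attributed to the gene by explicit
#' target-gene label when the track carries labels, otherwise by >= 1 bp
#' coordinate overlap: TFBS against the gene span extended upstream
#' (strand-aware) by `flank_bp`; miRNA target sites against the
#' representative transcript's 3' UTR (`mirna_scope = "utr3"`) or all
#' exonic intervals (`"exonic"`).
#'
#' @param gene A `gene_model`.
#' @param mirna_track,tfbs_track Optional `regulatory_track`s; when a track
#'   is `NULL` the corresponding count is `NA`.
#' @param flank_bp Upstream flank width for TFBS attribution (default 2000).
#' @param mirna_scope `"utr3"` or `"exonic"`.
#' @param representative `"longest_cds"` or `"union"`.
#' @param use_labels Use the track's target labels when present (default);
#'   set `FALSE` to force coordinate overlap.
#' @return One-row `data.frame` with columns `gene_id`, `transcript_length`,
#'   `cds_length`, `utr_length`, `n_exons`, `span_length`, `n_mirna_sites`,
#'   `n_tfbs`, `representative_transcript_id`.
#' @export
gene_features <- function(gene, mirna_track = NULL, tfbs_track = NULL,
                          flank_bp = 2000, mirna_scope = c("utr3", "exonic"),
                          representative = c("longest_cds", "union"),
                          use_labels = TRUE) {
  mirna_scope <- match.arg(mirna_scope)
  representative <- match.arg(representative)
  rep_tx <- representative_transcript(gene)
  if (representative == "longest_cds") {
    tl <- spliced_length(rep_tx)
    cl <- cds_length(rep_tx)
    ne <- nrow(rep_tx$exons)
  } else {
    ex <- merge_intervals(do.call(rbind, lapply(gene$transcripts, `[[`, "exons")))
    cd_all <- do.call(rbind, lapply(gene$transcripts, `[[`, "cds"))
    tl <- interval_length(ex)
    cl <- if (NROW(cd_all)) as.integer(covered_bp(cd_all)) else 0L
    ne <- nrow(ex)
  }
  ul <- tl - cl
  span <- gene$span
  span_len <- interval_length(span)

  count_track <- function(track, regions) {
    if (is.null(track)) return(NA_integer_)
    if (use_labels && any(!is.na(track$target))) {
      labels <- c(gene$gene_id, if (!is.na(gene$symbol)) gene$symbol)
      return(sum(track$target %in% labels, na.rm = TRUE))
    }
    if (nrow(regions) == 0) return(0L)
    if (!gene$chrom %in% track$chrom) return(0L)
    as.integer(count_overlapping_sites(track, regions))
  }

  # TFBS: span plus an upstream flank on the transcribed strand
  flank_region <- span
  if (flank_bp > 0) {
    if (identical(gene$strand, "-")) {
      flank_region$end <- flank_region$end + as.integer(flank_bp)
    } else {
      flank_region$start <- max(0L, flank_region$start - as.integer(flank_bp))
    }
  }
  mirna_regions <- if (mirna_scope == "utr3") rep_tx$utr3 else rep_tx$exons

  data.frame(gene_id = gene$gene_id,
             transcript_length = as.integer(tl),
             cds_length = as.integer(cl),
             utr_length = as.integer(ul),
             n_exons = as.integer(ne),
             span_length = as.integer(span_len),
             n_mirna_sites = count_track(mirna_track, mirna_regions),
             n_tfbs = count_track(tfbs_track, flank_region),
             representative_transcript_id = rep_tx$transcript_id,
             stringsAsFactors = FALSE)
}

#' Feature table for a list of genes
#'
#' Applies [gene_features()] to every gene and binds the rows.
#'
#' @param genes Named list of `gene_model`s (as from [read_gff3()]).
#' @param ... Passed on to [gene_features()].
#' @return `data.frame`, one row per gene, in input order.
#' @export
feature_table <- function(genes, ...) {
  out <- do.call(rbind, lapply(genes, gene_features, ...))
  rownames(out) <- NULL
  out
}

#' Class-wise genomic coverage and feature summaries
#'
#' Computes, for the focal class and its complement, the number of genes,
#' the fraction of the universe, and the union-merged base-pair footprint
#' of the class: gene spans in `mode = "span"` ("total genomic coverage"),
#' or all exons of all transcripts in `mode = "exonic"`. Bases shared by
#' two genes of the same class count once; bases shared across classes
#' count in both classes, and `bp_fraction` renormalizes by the two-class
#' total so the fractions sum to 1.
#'
#' @param genes Named list of `gene_model`s covering every partition member.
#' @param partition A `class_partition`.
#' @param mode `"span"` or `"exonic"` — which footprint drives
#'   `bp_fraction`.
#' @param features Optional feature table from [feature_table()]; when
#'   given, per-class means and medians of each metric are included.
#' @return A `target_summary_pair`: list with elements `focal` and
#'   `complement` (each a `target_summary`), plus `mode` and `label`.
#' @export
class_coverage <- function(genes, partition, mode = c("span", "exonic"),
                           features = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(partition, "class_partition"))
  unknown <- setdiff(c(partition$focal, partition$complement), names(genes))
  if (length(unknown)) {
    stopf("class_coverage: partition references unknown gene(s): %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  }
  one_class <- function(ids) {
    gs <- genes[ids]
    spans <- do.call(rbind, lapply(gs, `[[`, "span"))
    exons <- do.call(rbind, lapply(gs, function(g) {
      do.call(rbind, lapply(g$transcripts, `[[`, "exons"))
    }))
    span_bp <- if (length(ids)) covered_bp(spans) else 0
    exonic_bp <- if (length(ids)) covered_bp(exons) else 0
    s <- list(n_genes = length(ids), total_span_bp = span_bp,
              total_exonic_bp = exonic_bp)
    if (!is.null(features)) {
      ft <- features[features$gene_id %in% ids, , drop = FALSE]
      num <- vapply(ft, is.numeric, logical(1))
      s$mean <- vapply(ft[num], function(v) mean(v, na.rm = TRUE), numeric(1))
      s$median <- vapply(ft[num], function(v) median(v, na.rm = TRUE), numeric(1))
    }
    s
  }
  foc <- one_class(partition$focal)
  com <- one_class(partition$complement)
  n_tot <- foc$n_genes + com$n_genes
  key <- if (mode == "span") "total_span_bp" else "total_exonic_bp"
  bp_tot <- foc[[key]] + com[[key]]
  finish <- function(s) {
    s$gene_fraction <- if (n_tot) s$n_genes / n_tot else NA_real_
    s$bp_fraction <- if (bp_tot) s[[key]] / bp_tot else NA_real_
    structure(s, class = "target_summary")
  }
  structure(list(focal = finish(foc), complement = finish(com),
                 mode = mode, label = partition$label),
            class = "target_summary_pair")
}

#' @export
print.target_summary_pair <- function(x, ...) {
  cat(sprintf("Genomic target size by class ('%s', %s mode)\n", x$label, x$mode))
  for (cl in c("focal", "complement")) {
    s <- x[[cl]]
    cat(sprintf("  %-10s %6d genes (%5.1f%%)  span %12.0f bp  exonic %12.0f bp  bp share %5.1f%%\n",
                cl, s$n_genes, 100 * s$gene_fraction, s$total_span_bp,
                s$total_exonic_bp, 100 * s$bp_fraction))
  }
  invisible(x)
}
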