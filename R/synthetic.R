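# Self-contained synthetic annotation bundles (GFF3 + OBO + GAF + BED +
# FASTA + ortholog TSV) with ground truth, emulating the statistical
# structure the analysis assumes: two gene classes, a class-specific
# length multiplier on CDS/UTR draws, per-class exon-count means,
# length-proportional regulatory-site densities, and ortholog CDS pairs
# diverged under a specified dN/dS.

#' Configuration for the synthetic genome generator
#'
#' Lengths are lognormal (gene-length distributions are heavy-tailed and
#' non-Gaussian); the focal class multiplies its CDS and total-UTR draws by
#' `focal_length_multiplier`. Exon counts are `1 + Poisson(exon_mean)` per
#' class. Regulatory sites are Poisson with density per kb of eligible
#' region (3' UTR for miRNA target sites, the upstream flank for TFBS), so
#' longer genes mechanically harbor more sites; `site_mode = "fixed"`
#' instead draws per-gene Poisson counts independent of length, letting
#' tests separate length from repertoire effects. All randomness flows
#' from `seed`.
#'
#' @param seed Integer seed driving every draw.
#' @param n_genes,n_chromosomes Genome size.
#' @param focal_fraction Fraction of genes annotated to the focal term
#'   (assigned exactly: `round(f * n)` genes).
#' @param cds_meanlog,cds_sdlog Lognormal parameters of CDS length in
#'   codons.
#' @param utr_meanlog,utr_sdlog Lognormal parameters of total UTR length in
#'   bp (split 1/3 five-prime, 2/3 three-prime).
#' @param focal_length_multiplier Multiplier applied to focal-class CDS and
#'   UTR draws.
#' @param exon_mean Named vector `c(focal = , complement = )`; exon count
#'   is `1 + Poisson(exon_mean)`.
#' @param intron_meanlog,intron_sdlog Lognormal parameters of individual
#'   intron lengths in bp (class-independent).
#' @param intergenic_gap_bp Gap between consecutive genes on a chromosome.
#' @param mirna_density,tfbs_density Named per-class site densities
#'   (sites per kb of eligible region).
#' @param tfbs_flank_bp Width of the upstream flank holding TFBS.
#' @param site_mode `"length_proportional"` (default) or `"fixed"`.
#' @param dnds Named per-class omega for simulated ortholog pairs.
#' @param divergence_ts Expected synonymous substitutions per synonymous
#'   site between the two species.
#' @param pairs_per_class Named vector: how many ortholog CDS pairs to
#'   simulate per class.
#' @param chrom_length_bp Optional hard chromosome capacity; exceeding it
#'   is an error suggesting more chromosomes.
#' @return A `genome_config` list.
#' @export
genome_config <- function(seed = 1,
                          n_genes = 2000,
                          n_chromosomes = 5,
                          focal_fraction = 0.05,
                          cds_meanlog = log(450), cds_sdlog = 0.4,
                          utr_meanlog = log(900), utr_sdlog = 0.6,
                          focal_length_multiplier = 2,
                          exon_mean = c(focal = 7, complement = 7),
                          intron_meanlog = log(1200), intron_sdlog = 0.7,
                          intergenic_gap_bp = 5000,
                          mirna_density = c(focal = 2, complement = 2),
                          tfbs_density = c(focal = 3, complement = 3),
                          tfbs_flank_bp = 2000,
                          site_mode = c("length_proportional", "fixed"),
                          dnds = c(focal = 0.1, complement = 0.3),
                          divergence_ts = 0.2,
                          pairs_per_class = c(focal = 30, complement = 30),
                          chrom_length_bp = NULL) {
  site_mode <- match.arg(site_mode)
  stopifnot(is_count(seed) || (is.numeric(seed) && seed == round(seed)),
            is_count(n_genes), n_genes >= 2,
            is_count(n_chromosomes), n_chromosomes >= 1,
            focal_fraction > 0, focal_fraction < 1,
            focal_length_multiplier > 0,
            all(c("focal", "complement") %in% names(exon_mean)),
            all(mirna_density >= 0), all(tfbs_density >= 0),
            divergence_ts >= 0, all(dnds >= 0))
  structure(as.list(environment()), class = "genome_config")
}

#' @export
print.genome_config <- function(x, ...) {
  cat(sprintf("<genome config: %d genes on %d chromosome(s), focal fraction %.3f, length multiplier %.3g, seed %s>\n",
              x$n_genes, x$n_chromosomes, x$focal_fraction,
              x$focal_length_multiplier, format(x$seed)))
  invisible(x)
}

class_value <- function(param, cls) {
  unname(param[ifelse(cls == "focal", "focal", "complement")])
}

# all per-gene scalar draws, in a fixed order so that the file emitter and
# the in-memory route consume the identical random stream
draw_genes <- function(cfg) {
  n <- cfg$n_genes
  n_focal <- max(1L, round(cfg$focal_fraction * n))
  cls <- rep("complement", n)
  cls[sample.int(n, n_focal)] <- "focal"
  lam <- ifelse(cls == "focal", cfg$focal_length_multiplier, 1)

  cds_codons <- pmax(35L, as.integer(round(rlnorm(n, cfg$cds_meanlog, cfg$cds_sdlog) * lam)))
  cds_bp <- 3L * cds_codons
  utr_bp <- pmax(30L, as.integer(round(rlnorm(n, cfg$utr_meanlog, cfg$utr_sdlog) * lam)))
  utr5_bp <- pmax(10L, as.integer(round(utr_bp / 3)))
  utr3_bp <- utr_bp - utr5_bp

  n_exons <- 1L + rpois(n, class_value(cfg$exon_mean, cls))
  n_introns <- n_exons - 1L
  intron_draws <- pmax(30L, as.integer(round(rlnorm(sum(n_introns),
                                                    cfg$intron_meanlog,
                                                    cfg$intron_sdlog))))
  gene_of_intron <- rep(seq_len(n), n_introns)
  introns <- split(intron_draws, factor(gene_of_intron, levels = seq_len(n)))
  intron_bp <- vapply(introns, function(v) sum(as.numeric(v)), numeric(1))

  strand <- sample(c("+", "-"), n, replace = TRUE)

  mir_d <- class_value(cfg$mirna_density, cls)
  tf_d <- class_value(cfg$tfbs_density, cls)
  if (cfg$site_mode == "length_proportional") {
    n_mirna <- rpois(n, mir_d * utr3_bp / 1000)
    n_tfbs <- rpois(n, tf_d * cfg$tfbs_flank_bp / 1000)
  } else {
    n_mirna <- rpois(n, mir_d)
    n_tfbs <- rpois(n, tf_d)
  }

  width <- max(4L, nchar(as.character(n)))
  out <- data.frame(
    gene_id = sprintf("G%0*d", width, seq_len(n)),
    class = cls, strand = strand,
    cds_length = cds_bp, utr5_length = utr5_bp, utr3_length = utr3_bp,
    utr_length = utr_bp,
    transcript_length = cds_bp + utr_bp,
    n_exons = n_exons, intron_bp = as.integer(intron_bp),
    span_length = as.integer(cds_bp + utr_bp + intron_bp),
    n_mirna_sites = n_mirna, n_tfbs = n_tfbs,
    stringsAsFactors = FALSE)
  out$introns <- introns
  out
}

#' Per-gene ground-truth feature draws without file emission
#'
#' Draws the same gene table [generate_genome()] materializes to files —
#' identical values for identical configs — but stops before coordinate
#' layout, which makes large simulation studies (type-I error, power)
#' cheap.
#'
#' @param config A [genome_config()].
#' @return `data.frame` with one row per gene: class, lengths, exon count,
#'   intron total, span length and regulatory-site counts.
#' @export
simulate_gene_features <- function(config) {
  stopifnot(inherits(config, "genome_config"))
  withr::with_seed(config$seed, draw_genes(config))
}

# map a spliced interval [a, b) (transcription order) onto genomic exon
# coordinates
map_spliced_to_genomic <- function(chrom, exons, strand, a, b) {
  ord <- seq_len(nrow(exons))
  if (strand == "-") ord <- rev(ord)
  off <- 0L
  out <- list()
  for (k in ord) {
    w <- exons$end[k] - exons$start[k]
    lo <- max(a, off); hi <- min(b, off + w)
    if (lo < hi) {
      if (strand == "-") {
        gs <- exons$end[k] - (hi - off); ge <- exons$end[k] - (lo - off)
      } else {
        gs <- exons$start[k] + (lo - off); ge <- exons$start[k] + (hi - off)
      }
      out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = gs,
                                            end = ge, strand = strand,
                                            stringsAsFactors = FALSE)
    }
    off <- off + w
  }
  out <- do.call(rbind, out)
  out[order(out$start), , drop = FALSE]
}

synthetic_ontology <- function() {
  list(
    list(id = "SGO:0000001", name = "biological_process",
         parents = character()),
    list(id = "SGO:0000010", name = "nervous system development",
         parents = "SGO:0000001"),
    list(id = "SGO:0000020", name = "metabolic process",
         parents = "SGO:0000001"),
    list(id = "SGO:0000030", name = "immune system process",
         parents = "SGO:0000001"),
    list(id = "SGO:0000011", name = "neurogenesis",
         parents = "SGO:0000010"),
    list(id = "SGO:0000012", name = "synapse assembly",
         parents = "SGO:0000010"),
    list(id = "SGO:0000021", name = "lipid metabolic process",
         parents = "SGO:0000020"),
    list(id = "SGO:0000031", name = "innate immune response",
         parents = "SGO:0000030"))
}

#' Focal term id used by synthetic bundles
#'
#' @return The term id all synthetic GAF focal annotations hang under.
#' @export
synthetic_focal_term <- function() "SGO:0000010"

#' Generate a complete synthetic annotation bundle
#'
#' Places genes left-to-right per chromosome with intergenic gaps (never
#' overlapping), gives each gene one transcript whose exon count, CDS and
#' UTR lengths follow the class-specific distributions, and emits GFF3,
#' a small ontology (3 levels, focal term `"nervous system development"`),
#' GAF annotations (focal genes to a leaf under the focal term, half the
#' complement to non-focal leaves), BED site tracks (TFBS in the upstream
#' flank, miRNA target sites in the 3' UTR), ortholog CDS FASTA pairs
#' diverged under the per-class dN/dS, an ortholog table, and ground-truth
#' TSVs. Re-parsing the bundle reproduces the ground truth exactly.
#'
#' @param config A [genome_config()].
#' @param dir Output directory (created if needed).
#' @return List with `dir`, `paths` (named file paths), `truth` (gene and
#'   pair tables, realized `gene_fraction` and span-mode `bp_fraction`,
#'   `focal_term`) and `config`.
#' @export
generate_genome <- function(config, dir = tempfile("synthgenome")) {
  stopifnot(inherits(config, "genome_config"))
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(cfg$seed, {
    genes <- draw_genes(cfg)
    n <- nrow(genes)

    chrom <- paste0("chr", ((seq_len(n) - 1L) %% cfg$n_chromosomes) + 1L)
    cursor <- setNames(rep(max(cfg$intergenic_gap_bp, cfg$tfbs_flank_bp + 100L),
                           cfg$n_chromosomes),
                       paste0("chr", seq_len(cfg$n_chromosomes)))
    gstart <- integer(n)
    for (i in seq_len(n)) {
      gstart[i] <- cursor[chrom[i]]
      cursor[chrom[i]] <- cursor[chrom[i]] + genes$span_length[i] +
        cfg$intergenic_gap_bp
    }
    if (!is.null(cfg$chrom_length_bp) && any(cursor > cfg$chrom_length_bp)) {
      stopf("generate_genome: chromosome capacity exceeded (%d bp needed, %d available); increase n_chromosomes or chrom_length_bp",
            max(cursor), cfg$chrom_length_bp)
    }

    gff <- vector("list", n)
    gaf <- vector("list", n)
    bed_mir <- vector("list", n)
    bed_tf <- vector("list", n)
    leaf_focal <- c("SGO:0000011", "SGO:0000012")
    leaf_other <- c("SGO:0000021", "SGO:0000031")

    for (i in seq_len(n)) {
      gid <- genes$gene_id[i]
      tid <- paste0(gid, ".t1")
      st <- genes$strand[i]
      S <- genes$transcript_length[i]
      e <- genes$n_exons[i]
      widths <- if (e == 1) S else
        diff(c(0L, sort(sample.int(S - 1L, e - 1L)), S))
      intr <- genes$introns[[i]]
      ex_start <- integer(e)
      ex_start[1] <- gstart[i]
      if (e > 1) {
        for (k in 2:e) ex_start[k] <- ex_start[k - 1] + widths[k - 1] + intr[k - 1]
      }
      exons <- data.frame(chrom = chrom[i], start = ex_start,
                          end = ex_start + widths, strand = st,
                          stringsAsFactors = FALSE)
      gend <- exons$end[e]
      u5 <- genes$utr5_length[i]; cdsl <- genes$cds_length[i]
      cds_iv <- map_spliced_to_genomic(chrom[i], exons, st, u5, u5 + cdsl)
      utr3_iv <- map_spliced_to_genomic(chrom[i], exons, st, u5 + cdsl, S)

      gff[[i]] <- c(
               sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       chrom[i], gstart[i] + 1L, gend, st, gid, gid),
               sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       chrom[i], gstart[i] + 1L, gend, st, tid, gid),
               sprintf("%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       chrom[i], exons$start + 1L, exons$end, st, tid),
               sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t.\tParent=%s",
                       chrom[i], cds_iv$start + 1L, cds_iv$end, st, tid))

      if (genes$class[i] == "focal") {
        term <- sample(leaf_focal, 1)
      } else if (runif(1) < 0.5) {
        term <- sample(leaf_other, 1)
      } else {
        term <- NA_character_
      }
      if (!is.na(term)) {
        gaf[[i]] <- c(sprintf("SYNTH\t%s\t%s\t\t%s\tSYNTH:0001\tIEA\t\tP\t%s\t\tgene\ttaxon:0\t20160101\tSYNTH\t\t",
                              gid, gid, term, gid))
      }

      if (genes$n_tfbs[i] > 0) {
        flank_len <- cfg$tfbs_flank_bp
        site_len <- min(12L, flank_len)
        fs <- if (st == "-") gend else gstart[i] - flank_len
        pos <- fs + sample.int(flank_len - site_len + 1L,
                               genes$n_tfbs[i], replace = TRUE) - 1L
        pos <- sort(pos)
        bed_tf[[i]] <- sprintf("%s\t%d\t%d\t%s\t0\t.",
                               chrom[i], pos, pos + site_len, gid)
      }
      if (genes$n_mirna_sites[i] > 0 && nrow(utr3_iv) > 0) {
        w <- utr3_iv$end - utr3_iv$start
        pick <- sample.int(nrow(utr3_iv), genes$n_mirna_sites[i],
                           replace = TRUE, prob = w)
        site_len <- pmin(8L, w[pick])
        pos <- utr3_iv$start[pick] +
          floor(runif(length(pick)) * (w[pick] - site_len + 1L))
        ord <- order(pos)
        bed_mir[[i]] <- sprintf("%s\t%d\t%d\t%s\t0\t.",
                                chrom[i], pos[ord],
                                (pos + site_len)[ord], gid)
      }
    }

    # ortholog CDS pairs diverged under the per-class omega
    pairs <- list()
    fa_a <- character(0); fa_b <- character(0); orth <- character(0)
    for (cl in c("focal", "complement")) {
      ids <- genes$gene_id[genes$class == cl]
      k <- min(unname(cfg$pairs_per_class[cl]), length(ids))
      if (k < 1) next
      sel <- sort(sample(ids, k))
      for (gid in sel) {
        nc <- genes$cds_length[match(gid, genes$gene_id)] / 3L
        pair <- evolve_cds_pair(nc, unname(cfg$dnds[cl]), cfg$divergence_ts)
        bid <- paste0(gid, "_sp2")
        fa_a <- c(fa_a, paste0(">", gid), pair$cds_a)
        fa_b <- c(fa_b, paste0(">", bid), pair$cds_b)
        orth <- c(orth, sprintf("%s\t%s\tortholog_one2one", gid, bid))
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene_id = gid, gene_id_b = bid, class = cl,
          omega = unname(cfg$dnds[cl]), t_s = cfg$divergence_ts,
          n_codons = nc, stringsAsFactors = FALSE)
      }
    }
    pairs <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(gene_id = character(), gene_id_b = character(),
                 class = character(), omega = numeric(), t_s = numeric(),
                 n_codons = integer())

    paths <- c(gff = file.path(dir, "genome.gff3"),
               obo = file.path(dir, "ontology.obo"),
               gaf = file.path(dir, "annotations.gaf"),
               mirna_bed = file.path(dir, "mirna_targets.bed"),
               tfbs_bed = file.path(dir, "tfbs.bed"),
               cds_a = file.path(dir, "cds_species_a.fa"),
               cds_b = file.path(dir, "cds_species_b.fa"),
               orthologs = file.path(dir, "orthologs.tsv"),
               truth_genes = file.path(dir, "ground_truth_genes.tsv"),
               truth_pairs = file.path(dir, "ground_truth_pairs.tsv"))

    gff <- unlist(gff, use.names = FALSE)
    gaf <- unlist(gaf, use.names = FALSE)
    bed_mir <- unlist(bed_mir, use.names = FALSE) %||% character(0)
    bed_tf <- unlist(bed_tf, use.names = FALSE) %||% character(0)
    writeLines(c("##gff-version 3", gff), paths["gff"])
    writeLines(obo_text(), paths["obo"])
    writeLines(c("!gaf-version: 2.2", gaf), paths["gaf"])
    writeLines(bed_mir, paths["mirna_bed"])
    writeLines(bed_tf, paths["tfbs_bed"])
    writeLines(fa_a, paths["cds_a"])
    writeLines(fa_b, paths["cds_b"])
    writeLines(c("gene_id_a\tgene_id_b\thomology_type", orth),
               paths["orthologs"])

    truth_genes <- genes[, setdiff(names(genes), "introns")]
    write.table(truth_genes, paths["truth_genes"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pairs, paths["truth_pairs"], sep = "\t", quote = FALSE,
                row.names = FALSE)

    span_f <- sum(as.numeric(genes$span_length[genes$class == "focal"]))
    span_all <- sum(as.numeric(genes$span_length))
    list(dir = dir, paths = paths,
         truth = list(genes = truth_genes, pairs = pairs,
                      gene_fraction = mean(genes$class == "focal"),
                      bp_fraction = span_f / span_all,
                      focal_term = synthetic_focal_term()),
         config = cfg)
  })
}

obo_text <- function() {
  terms <- synthetic_ontology()
  out <- c("format-version: 1.2", "ontology: sgo")
  for (t in terms) {
    out <- c(out, "", "[Term]",
             paste0("id: ", t$id),
             paste0("name: ", t$name),
             "namespace: biological_process",
             if (length(t$parents)) paste0("is_a: ", t$parents))
  }
  out
}

#' Calibrated length multiplier for a target coverage share
#'
#' Closed-form calibration from the generator's expected lengths: with
#' focal fraction `f` and target span-mode coverage share `q`, the
#' required ratio of class mean spans is
#' `r = (q / (1 - q)) * ((1 - f) / f)`; since the multiplier scales only
#' the spliced part (CDS + UTR) while introns are class-independent,
#' `lambda = (r * (S + I) - I) / S` with `S`, `I` the expected spliced and
#' intron totals.
#'
#' @param config A [genome_config()].
#' @param target_bp_fraction Desired span-mode coverage share of the focal
#'   class.
#' @return The multiplier `lambda`.
#' @export
calibrate_length_multiplier <- function(config, target_bp_fraction = 0.10) {
  f <- config$focal_fraction
  q <- target_bp_fraction
  r <- (q / (1 - q)) * ((1 - f) / f)
  S <- 3 * exp(config$cds_meanlog + config$cds_sdlog^2 / 2) +
    exp(config$utr_meanlog + config$utr_sdlog^2 / 2)
  I <- unname(config$exon_mean["complement"]) *
    exp(config$intron_meanlog + config$intron_sdlog^2 / 2)
  lam <- (r * (S + I) - I) / S
  if (lam <= 0) stopf("calibrate_length_multiplier: target %.3f unattainable", q)
  lam
}

#' The flagship five-percent fixture
#'
#' A deterministic bundle with 5% focal genes and the length multiplier
#' calibrated (see [calibrate_length_multiplier()]) so that the focal
#' class covers about a tenth of the summed genic space in span mode —
#' the constructed analogue of a small gene class with a
#' disproportionately large mutational target. Compact introns
#' (`intron_meanlog = log(200)`) keep the required multiplier in a
#' realistic range.
#'
#' @param seed Seed (default 1).
#' @param dir Output directory.
#' @return As [generate_genome()].
#' @export
make_five_percent_fixture <- function(seed = 1, dir = tempfile("fivepct")) {
  base <- genome_config(seed = seed, n_genes = 2000, focal_fraction = 0.05,
                        intron_meanlog = log(200), intron_sdlog = 0.5,
                        focal_length_multiplier = 1)
  lam <- calibrate_length_multiplier(base, target_bp_fraction = 0.10)
  cfg <- base
  cfg$focal_length_multiplier <- lam
  generate_genome(cfg, dir)
}

#' Simulate an ortholog CDS pair under a specified dN/dS
#'
#' Draws an ancestral sequence uniformly over sense codons and evolves two
#' independent lineages. Candidate events propose a random
#' single-nucleotide change; changes creating stop codons are rejected,
#' synonymous changes are accepted with relative rate 1 and nonsynonymous
#' changes with relative rate `omega`. Each lineage runs until its number
#' of accepted synonymous substitutions reaches a Poisson draw with mean
#' `t_s / 2` times the ancestral synonymous site count, so the expected
#' synonymous divergence between the pair is about `t_s` (the calibration
#' is event-based and approximate; accuracy is asserted statistically).
#'
#' @param n_codons Number of codons (>= 1).
#' @param omega Relative nonsynonymous acceptance rate (>= 0).
#' @param t_s Expected synonymous substitutions per synonymous site
#'   between the pair.
#' @param seed Optional seed; `NULL` (default) uses the current RNG
#'   stream.
#' @return List with nucleotide strings `cds_a`, `cds_b`.
#' @export
evolve_cds_pair <- function(n_codons, omega, t_s, seed = NULL) {
  stopifnot(is_count(n_codons), n_codons >= 1, omega >= 0, t_s >= 0)
  run <- function() {
    tab <- codon_tables()
    sense_idx <- which(tab$sense)
    anc <- sample(sense_idx, n_codons, replace = TRUE)
    S0 <- sum(tab$site_s[anc])
    lineage <- function(idx) {
      target <- rpois(1, t_s / 2 * S0)
      k <- 0L
      while (k < target) {
        ci <- sample.int(length(idx), 1L)
        slot <- sample.int(9L, 1L)
        from <- idx[ci]
        ty <- tab$mut_type[from, slot]
        if (ty == 0L) next
        if (ty == 1L) {
          idx[ci] <- tab$mut_idx[from, slot]
          k <- k + 1L
        } else if (omega > 0 && runif(1) < omega) {
          idx[ci] <- tab$mut_idx[from, slot]
        }
      }
      idx
    }
    a <- lineage(anc)
    b <- lineage(anc)
    list(cds_a = paste(tab$codons[a], collapse = ""),
         cds_b = paste(tab$codons[b], collapse = ""))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
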