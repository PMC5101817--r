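test_that("the same seed reproduces a byte-identical bundle", {
  d1 <- tempfile("det1"); d2 <- tempfile("det2")
  cfg <- genome_config(seed = 33, n_genes = 60, n_chromosomes = 2,
                       pairs_per_class = c(focal = 2, complement = 2))
  generate_genome(cfg, d1)
  generate_genome(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("a null construction (multiplier 1) gives matched class means", {
  cfg <- genome_config(seed = 101, n_genes = 500, focal_fraction = 0.5,
                       focal_length_multiplier = 1)
  g <- simulate_gene_features(cfg)
  ratio <- mean(g$cds_length[g$class == "focal"]) /
    mean(g$cds_length[g$class == "complement"])
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("the length multiplier is recovered from a large draw", {
  cfg <- genome_config(seed = 202, n_genes = 2000, focal_fraction = 0.05,
                       focal_length_multiplier = 2)
  g <- simulate_gene_features(cfg)
  expect_equal(sum(g$class == "focal"), 100)
  ratio <- mean(g$cds_length[g$class == "focal"]) /
    mean(g$cds_length[g$class == "complement"])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("the in-memory draw equals the emitted bundle's ground truth", {
  cfg <- genome_config(seed = 77, n_genes = 40, n_chromosomes = 2,
                       pairs_per_class = c(focal = 2, complement = 2))
  mem <- simulate_gene_features(cfg)
  fx <- generate_genome(cfg, tempfile("gt"))
  expect_equal(mem[, setdiff(names(mem), "introns")], fx$truth$genes)
})

test_that("the emitted bundle re-parses into exactly the ground truth", {
  fx <- small_genome(seed = 55, n = 40)
  truth <- fx$truth$genes
  # GAF: focal genes are annotated under the focal term
  dag <- read_obo(fx$paths[["obo"]])
  ann <- read_gaf(fx$paths[["gaf"]])
  genes <- read_gff3(fx$paths[["gff"]])
  focal <- genes_for_term(dag, ann, fx$truth$focal_term, names(genes))
  expect_setequal(focal, truth$gene_id[truth$class == "focal"])
  # BED tracks carry exactly the drawn site counts, labelled by gene
  mir <- read_bed(fx$paths[["mirna_bed"]], "mirna_target")
  tf <- read_bed(fx$paths[["tfbs_bed"]], "tfbs")
  feats <- feature_table(genes, mirna_track = mir, tfbs_track = tf)
  m <- merge(feats, truth, by = "gene_id", suffixes = c("", ".truth"))
  expect_equal(m$n_mirna_sites, m$n_mirna_sites.truth)
  expect_equal(m$n_tfbs, m$n_tfbs.truth)
  # miRNA sites really sit inside 3' UTR exonic intervals
  for (i in seq_len(nrow(mir))) {
    g <- genes[[mir$target[i]]]
    utr3 <- g$transcripts[[1]]$utr3
    expect_true(any(utr3$start <= mir$start[i] & utr3$end >= mir$end[i]),
                info = sprintf("site %d", i))
  }
  # ortholog pairs parse and estimate
  fa <- read_fasta(fx$paths[["cds_a"]])
  fb <- read_fasta(fx$paths[["cds_b"]])
  orth <- read_orthologs(fx$paths[["orthologs"]])
  expect_equal(nrow(orth), nrow(fx$truth$pairs))
  e <- kaks_pair(fa[[orth$gene_id_a[1]]], fb[[orth$gene_id_b[1]]])
  expect_true(e$s_sites + e$n_sites == 3 * e$n_codons)
})

test_that("genes never overlap and respect the intergenic gap", {
  fx <- small_genome(seed = 91, n = 50)
  genes <- read_gff3(fx$paths[["gff"]])
  spans <- do.call(rbind, lapply(genes, `[[`, "span"))
  for (p in split(spans, spans$chrom)) {
    p <- p[order(p$start), ]
    if (nrow(p) > 1) {
      expect_true(all(p$start[-1] - p$end[-nrow(p)] >=
                        fx$config$intergenic_gap_bp))
    }
  }
})

test_that("chromosome capacity overflow is a clear error", {
  cfg <- genome_config(seed = 1, n_genes = 50, n_chromosomes = 1,
                       chrom_length_bp = 10000,
                       pairs_per_class = c(focal = 0, complement = 0))
  expect_error(generate_genome(cfg, tempfile()), "more chromosomes|capacity")
})

test_that("zero divergence and zero omega constructions behave as built", {
  p0 <- evolve_cds_pair(40, 1, 0, seed = 4)
  expect_identical(p0$cds_a, p0$cds_b)
  # omega = 0: only synonymous changes fix, so the translations agree
  # (pathway averaging may still count fractional nonsynonymous steps
  # when two synonymous hits land in one codon)
  p <- evolve_cds_pair(150, 0, 0.25, seed = 6)
  aa <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s)))
  expect_identical(aa(p$cds_a), aa(p$cds_b))
  e <- kaks_pair(p$cds_a, p$cds_b)
  expect_lt(e$ka, e$ks)
})

test_that("the calibrated multiplier targets the requested coverage share", {
  base <- genome_config(seed = 1, focal_fraction = 0.05,
                        intron_meanlog = log(200), intron_sdlog = 0.5,
                        focal_length_multiplier = 1)
  lam <- calibrate_length_multiplier(base, 0.10)
  # expected span ratio under the calibration equals the required ratio
  S <- 3 * exp(base$cds_meanlog + base$cds_sdlog^2 / 2) +
    exp(base$utr_meanlog + base$utr_sdlog^2 / 2)
  I <- unname(base$exon_mean["complement"]) *
    exp(base$intron_meanlog + base$intron_sdlog^2 / 2)
  r_needed <- (0.10 / 0.90) * (0.95 / 0.05)
  expect_equal((lam * S + I) / (S + I), r_needed, tolerance = 1e-9)
})
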