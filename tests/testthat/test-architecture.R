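test_that("merge_intervals unions, sorts and joins adjacent intervals", {
  empty <- genomic_intervals(character(), integer(), integer())
  expect_equal(nrow(merge_intervals(empty)), 0)
  expect_equal(covered_bp(empty), 0)
  m <- merge_intervals(genomic_intervals("chr1", c(0, 5), c(10, 15)))
  expect_equal(m$start, 0)
  expect_equal(m$end, 15)
  # book-ended intervals join; disjoint stay apart; chromosomes separate
  m2 <- merge_intervals(genomic_intervals(c("c1", "c1", "c1", "c2"),
                                          c(0, 10, 25, 0),
                                          c(10, 20, 30, 5)))
  expect_equal(m2$start, c(0, 25, 0))
  expect_equal(m2$end, c(20, 30, 5))
  expect_error(merge_intervals(genomic_intervals("c1", 5, 5)), "invalid")
})

test_that("covered bases equal brute-force per-base counts on random fixtures", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(1:200, 1)
    s <- sample(0:990, n, replace = TRUE)
    e <- s + sample(1:100, n, replace = TRUE)
    df <- genomic_intervals(sample(c("c1", "c2"), n, TRUE), s, e)
    expect_equal(covered_bp(df), oracle_covered_bp(df), info = paste("rep", rep))
    m <- merge_intervals(df)
    # output is sorted, disjoint, maximal per chromosome
    for (p in split(m, m$chrom)) {
      if (nrow(p) > 1) expect_true(all(p$start[-1] > p$end[-nrow(p)]))
    }
  }
})

make_test_gene <- function(id, exon_sets, cds_sets = NULL, strand = "+",
                           chrom = "chr1") {
  txs <- lapply(seq_along(exon_sets), function(i) {
    transcript_model(sprintf("%s.t%d", id, i), id, chrom, strand,
                     exon_sets[[i]],
                     if (!is.null(cds_sets)) cds_sets[[i]] else NULL)
  })
  names(txs) <- vapply(txs, `[[`, character(1), "transcript_id")
  gene_model(id, NA_character_, txs)
}

test_that("representative transcript selection follows longest-CDS with documented tie-breaks", {
  ex <- function(s, e) genomic_intervals("chr1", s, e)
  g1 <- make_test_gene("g1", list(ex(0, 300)), list(ex(0, 300)))
  expect_equal(representative_transcript(g1)$transcript_id, "g1.t1")
  # CDS 300 vs 450 -> longer CDS wins
  g2 <- make_test_gene("g2", list(ex(0, 900), ex(0, 500)),
                       list(ex(0, 300), ex(0, 450)))
  expect_equal(representative_transcript(g2)$transcript_id, "g2.t2")
  # CDS tie -> longer spliced length wins
  g3 <- make_test_gene("g3", list(ex(0, 900), ex(0, 800)),
                       list(ex(0, 300), ex(0, 300)))
  expect_equal(representative_transcript(g3)$transcript_id, "g3.t1")
  # full tie -> lexicographically smallest id
  g4 <- make_test_gene("g4", list(ex(0, 800), ex(0, 800)),
                       list(ex(0, 300), ex(0, 300)))
  expect_equal(representative_transcript(g4)$transcript_id, "g4.t1")
})

test_that("regulatory site counts match containment expectations", {
  ex <- function(s, e) genomic_intervals("chr1", s, e)
  gene <- make_test_gene("g1", list(ex(5000, 6000)), list(ex(5200, 5800)))
  no_sites <- regulatory_track(
    data.frame(chrom = "chr9", start = 1, end = 9), "tfbs")
  f0 <- gene_features(gene, mirna_track = regulatory_track(
    data.frame(chrom = "chr9", start = 1, end = 9), "mirna_target"),
    tfbs_track = no_sites)
  expect_equal(f0$n_mirna_sites, 0L)
  expect_equal(f0$n_tfbs, 0L)
  # 3 TFBS fully inside the 2 kb upstream flank [3000, 5000)
  tf <- regulatory_track(data.frame(chrom = "chr1",
                                    start = c(3100, 4000, 4900),
                                    end = c(3112, 4012, 4912)), "tfbs")
  expect_equal(gene_features(gene, tfbs_track = tf, flank_bp = 2000)$n_tfbs, 3L)
  expect_equal(gene_features(gene, tfbs_track = tf, flank_bp = 0)$n_tfbs, 0L)
  # miRNA sites counted in the 3' UTR [5800, 6000) by default
  mir <- regulatory_track(data.frame(chrom = "chr1",
                                     start = c(5810, 5300, 5990),
                                     end = c(5818, 5308, 5998)),
                          "mirna_target")
  ft <- gene_features(gene, mirna_track = mir)
  expect_equal(ft$n_mirna_sites, 2L)
  expect_equal(gene_features(gene, mirna_track = mir,
                             mirna_scope = "exonic")$n_mirna_sites, 3L)
  # absent track -> NA, absent chromosome -> 0
  expect_true(is.na(gene_features(gene)$n_tfbs))
})

test_that("overlap-mode counts equal a quadratic all-pairs scan on a random fixture", {
  set.seed(99)
  genes <- lapply(1:50, function(i) {
    s <- sample(0:50000, 1)
    make_test_gene(sprintf("g%02d", i),
                   list(genomic_intervals("chr1", s, s + sample(200:2000, 1))))
  })
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  ss <- sample(0:52000, 300, replace = TRUE)
  sites <- regulatory_track(data.frame(chrom = "chr1", start = ss, end = ss + 10),
                            "tfbs")
  for (g in genes[sample(50, 10)]) {
    region <- g$span
    region$start <- max(0, region$start - 2000)
    expect_equal(gene_features(g, tfbs_track = sites, flank_bp = 2000,
                               use_labels = FALSE)$n_tfbs,
                 oracle_overlap_count(sites, region),
                 info = g$gene_id)
  }
})

test_that("class coverage fractions behave arithmetically and symmetrically", {
  ex <- function(s, e) genomic_intervals("chr1", s, e)
  g1 <- make_test_gene("g1", list(ex(0, 100)), list(ex(0, 60)))
  g2 <- make_test_gene("g2", list(ex(1000, 1300)), list(ex(1000, 1200)))
  genes <- list(g1 = g1, g2 = g2)
  universe <- c("g1", "g2")

  all_focal <- class_coverage(genes, make_partition(universe, universe))
  expect_equal(all_focal$focal$bp_fraction, 1.0)

  p <- make_partition("g1", universe)
  cov <- class_coverage(genes, p, mode = "span")
  expect_equal(cov$focal$bp_fraction, 0.25)  # 100 bp of 400 bp
  expect_equal(cov$focal$gene_fraction + cov$complement$gene_fraction, 1)
  expect_equal(cov$focal$bp_fraction + cov$complement$bp_fraction, 1)
  expect_true(cov$focal$total_exonic_bp <= cov$focal$total_span_bp)

  # swapping classes swaps the two summaries exactly
  q <- make_partition("g2", universe)
  cov2 <- class_coverage(genes, q, mode = "span")
  expect_equal(unclass(cov$focal), unclass(cov2$complement))
  expect_equal(unclass(cov$complement), unclass(cov2$focal))

  expect_error(class_coverage(genes, make_partition("g3", c(universe, "g3"))),
               "unknown gene")
})

test_that("per-gene length additivity and exonic <= span hold on a synthetic genome", {
  fx <- small_genome(seed = 21, n = 40)
  genes <- read_gff3(fx$paths[["gff"]])
  feats <- feature_table(genes)
  expect_true(all(feats$cds_length + feats$utr_length == feats$transcript_length))
  expect_true(all(feats$transcript_length <= feats$span_length))
  p <- make_partition(fx$truth$genes$gene_id[fx$truth$genes$class == "focal"],
                      names(genes))
  cov_span <- class_coverage(genes, p, mode = "span")
  cov_ex <- class_coverage(genes, p, mode = "exonic")
  expect_true(cov_ex$focal$total_exonic_bp <= cov_span$focal$total_span_bp)
  expect_equal(cov_span$focal$bp_fraction, fx$truth$bp_fraction)
})
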