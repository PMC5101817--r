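test_that("GFF3 coordinates convert to 0-based half-open and UTRs derive from exon minus CDS", {
  genes <- read_gff3(write_lines_tmp(toy_gff_lines(), ".gff3"))
  expect_length(genes, 1)
  tx <- genes[["g1"]]$transcripts[["t1"]]
  expect_equal(tx$exons$start, c(10L, 30L))
  expect_equal(tx$exons$end, c(20L, 40L))
  expect_equal(spliced_length(tx), 20L)
  expect_equal(cds_length(tx), 12L)
  # additivity: utr5 + utr3 + cds = spliced
  expect_equal(utr_length(tx), 8L)
  expect_equal(interval_length(tx$utr5), 4L)  # [10,14) upstream of CDS on +
  expect_equal(interval_length(tx$utr3), 4L)  # [36,40)
  expect_equal(interval_length(genes[["g1"]]$span), 30L)
})

test_that("UTR sides swap on the minus strand", {
  lines <- sub("\\t\\+\\t", "\t-\t", toy_gff_lines())
  genes <- read_gff3(write_lines_tmp(lines, ".gff3"))
  tx <- genes[["g1"]]$transcripts[["t1"]]
  expect_equal(interval_length(tx$utr5), 4L)
  expect_equal(tx$utr5$start, 36L)  # genomic right end is 5' on -
  expect_equal(tx$utr3$end, 14L)
})

test_that("a malformed-coordinate record is skipped with a warning naming the line", {
  lines <- c(toy_gff_lines()[1:5],
             "chr1\ttest\tCDS\t25\t15\t.\t+\t.\tParent=t1")
  expect_warning(genes <- read_gff3(write_lines_tmp(lines, ".gff3")),
                 "line 6")
  expect_length(genes, 1)
  expect_equal(cds_length(genes[["g1"]]$transcripts[["t1"]]), 0L)
})

test_that("duplicated transcript IDs abort the GFF3 read", {
  lines <- c(toy_gff_lines(),
             "chr1\ttest\tmRNA\t11\t40\t.\t+\t.\tID=t1;Parent=g1")
  expect_error(suppressWarnings(read_gff3(write_lines_tmp(lines, ".gff3"))),
               "duplicated transcript ID")
})

test_that("GAF parsing applies NOT exclusion and set semantics", {
  gaf <- c("!gaf-version: 2.2",
           "DB\tgeneA\tA\t\tGO:1\tREF\tIEA\t\tP\t",
           "DB\tgeneA\tA\t\tGO:2\tREF\tIEA\t\tP\t",
           "DB\tgeneB\tB\t\tGO:1\tREF\tIEA\t\tP\t",
           "DB\tgeneB\tB\tNOT\tGO:2\tREF\tIEA\t\tP\t",
           "DB\tgeneB\tB\t\tGO:1\tREF\tIEA\t\tP\t")
  ann <- read_gaf(write_lines_tmp(gaf, ".gaf"))
  expect_length(ann$map, 2)
  expect_equal(ann$map$geneA, c("GO:1", "GO:2"))
  expect_equal(ann$map$geneB, "GO:1")  # NOT row excluded, duplicate collapsed
  expect_identical(ann$provenance, "direct")
})

test_that("GAF rows without a GO id column are fatal with the line number", {
  gaf <- c("DB\tgeneA\tA\t\tGO:1\tREF\tIEA\t\tP\t", "DB\tgeneB")
  expect_error(read_gaf(write_lines_tmp(gaf, ".gaf")), "line 2")
})

test_that("OBO parsing keeps is_a structure, drops obsolete terms", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: T1", "name: root", "namespace: bp", "",
           "[Term]", "id: T2", "name: mid", "namespace: bp", "is_a: T1 ! root", "",
           "[Term]", "id: T3", "name: leaf", "namespace: bp", "is_a: T2", "",
           "[Term]", "id: T9", "name: gone", "namespace: bp", "is_a: T1",
           "is_obsolete: true")
  dag <- read_obo(write_lines_tmp(obo, ".obo"))
  expect_equal(sort(dag$terms$id), c("T1", "T2", "T3"))
  expect_equal(igraph::ecount(dag$graph), 2)
  expect_equal(dag$roots$bp, "T1")
  expect_equal(dag$parents$T2, "T1")  # inline comment after '!' stripped
})

test_that("a diamond retains both parent sets and an is_a cycle is fatal", {
  dag <- ontology_dag(diamond_terms())
  expect_setequal(dag$parents$X, c("A", "B"))
  cyc <- diamond_terms()
  cyc$A$parents <- c("R", "X")  # A -> X -> A
  expect_error(ontology_dag(cyc), "cycle")
})

test_that("BED is read in its native 0-based convention with record-level errors", {
  bed <- c("chr1 5 15 site1", "chr1\t100\t90\tbad", "chr2\t0\t8\t.\t0\t+")
  expect_warning(track <- read_bed(write_lines_tmp(bed, ".bed"), "tfbs"),
                 "line 2")
  expect_equal(nrow(track), 2)
  expect_equal(track$end[1] - track$start[1], 10)
  expect_identical(track$target, c("site1", NA_character_))
  expect_identical(attr(track, "kind"), "tfbs")
})

test_that("FASTA with CRLF endings yields the same sequences as LF", {
  fa <- c(">s1 some description", "ACGTAC", "GT", ">s2", "TTTT")
  p_lf <- write_lines_tmp(fa, ".fa")
  p_crlf <- tempfile(fileext = ".fa")
  writeLines(fa, p_crlf, sep = "\r\n")
  lf <- read_fasta(p_lf)
  expect_identical(lf, read_fasta(p_crlf))
  expect_identical(lf[["s1"]], "ACGTACGT")
  expect_identical(names(lf), c("s1", "s2"))
})

test_that("ortholog reader keeps only one-to-one rows", {
  tsv <- c("gene_id_a\tgene_id_b\thomology_type",
           "a1\tb1\tortholog_one2one",
           "a2\tb2\tortholog_one2many",
           "a3\tb3\tortholog_one2one",
           "a3\tb4\tortholog_one2one")  # duplicate a-id: dropped as one2many
  orth <- suppressMessages(read_orthologs(write_lines_tmp(tsv, ".tsv")))
  expect_equal(orth$gene_id_a, "a1")
})

test_that("report write/re-read/write round trip is byte-identical", {
  tab <- data.frame(feature = c("x", "y"),
                    p = c(0.123456789, 3.00000041e-7),
                    n = c(10L, 20L), stringsAsFactors = FALSE)
  d1 <- tempfile("rep1")
  write_report(list(contrasts = tab), d1)
  reread <- read.delim(file.path(d1, "contrasts.tsv"),
                       stringsAsFactors = FALSE)
  d2 <- tempfile("rep2")
  write_report(list(contrasts = reread), d2)
  expect_identical(readLines(file.path(d1, "contrasts.tsv")),
                   readLines(file.path(d2, "contrasts.tsv")))
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
})

test_that("the GFF3 reader recovers the generator's counts and lengths exactly", {
  fx <- small_genome(seed = 11, n = 50)
  genes <- read_gff3(fx$paths[["gff"]])
  truth <- fx$truth$genes
  expect_length(genes, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    g <- genes[[truth$gene_id[i]]]
    tx <- g$transcripts[[1]]
    expect_equal(length(g$transcripts), 1)
    expect_equal(nrow(tx$exons), truth$n_exons[i])
    expect_equal(spliced_length(tx), truth$transcript_length[i])
    expect_equal(cds_length(tx), truth$cds_length[i])
    expect_equal(utr_length(tx), truth$utr_length[i])
    expect_equal(interval_length(g$span), truth$span_length[i])
  }
})
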