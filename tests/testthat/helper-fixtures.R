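# Small in-code text fixtures (written to tempfiles at test time).

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# one + strand gene: exons [10,20) + [30,40), CDS [14,20) + [30,36)
toy_gff_lines <- function() {
  c("##gff-version 3",
    "chr1\ttest\tgene\t11\t40\t.\t+\t.\tID=g1;Name=G1",
    "chr1\ttest\tmRNA\t11\t40\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t11\t20\t.\t+\t.\tParent=t1",
    "chr1\ttest\texon\t31\t40\t.\t+\t.\tParent=t1",
    "chr1\ttest\tCDS\t15\t20\t.\t+\t.\tParent=t1",
    "chr1\ttest\tCDS\t31\t36\t.\t+\t.\tParent=t1")
}

# diamond: X reaches root R via A (2 steps) and via B -> A (3 steps)
diamond_terms <- function() {
  list(R = list(id = "R", name = "root", namespace = "bp",
                parents = character()),
       A = list(id = "A", name = "a", namespace = "bp", parents = "R"),
       B = list(id = "B", name = "b", namespace = "bp", parents = "A"),
       X = list(id = "X", name = "x", namespace = "bp",
                parents = c("A", "B")))
}

# 7-term DAG: level 0 = R, level 1 = A, B; level 2 = C, D, E; level 3 = F
seven_term_dag <- function() {
  ontology_dag(list(
    R = list(id = "R", name = "root", namespace = "bp", parents = character()),
    A = list(id = "A", name = "a", namespace = "bp", parents = "R"),
    B = list(id = "B", name = "b", namespace = "bp", parents = "R"),
    C = list(id = "C", name = "c", namespace = "bp", parents = "A"),
    D = list(id = "D", name = "d", namespace = "bp", parents = "A"),
    E = list(id = "E", name = "e", namespace = "bp", parents = "B"),
    F = list(id = "F", name = "f", namespace = "bp", parents = "C")))
}

# two-namespace DAG for true-path-rule classification tests:
# bp: R -> N (focal) -> n1 -> n2, R -> M;  cc: R2 -> Q
classification_dag <- function() {
  ontology_dag(list(
    R = list(id = "R", name = "bp root", namespace = "bp", parents = character()),
    N = list(id = "N", name = "neural", namespace = "bp", parents = "R"),
    n1 = list(id = "n1", name = "child", namespace = "bp", parents = "N"),
    n2 = list(id = "n2", name = "grandchild", namespace = "bp", parents = "n1"),
    M = list(id = "M", name = "metabolic", namespace = "bp", parents = "R"),
    R2 = list(id = "R2", name = "cc root", namespace = "cc", parents = character()),
    Q = list(id = "Q", name = "compartment", namespace = "cc", parents = "R2")))
}

classification_annotations <- function() {
  annotation_set(list(
    g1 = "N", g2 = "n1", g3 = "n2", g4 = c("n1", "M"),
    g5 = "M", g6 = "Q", g8 = "R", g9 = "Q", g10 = "M"))
}

# small synthetic genome for round-trip and pipeline tests
small_genome <- function(seed = 5, n = 60, dir = tempfile("smallg")) {
  cfg <- genome_config(seed = seed, n_genes = n, n_chromosomes = 2,
                       focal_fraction = 0.2,
                       pairs_per_class = c(focal = 5, complement = 5))
  generate_genome(cfg, dir)
}

# frozen 30-codon toy ortholog pair; the expected numbers below were
# computed for exactly this pair with the independent step-by-step
# enumeration oracles above (site counts, pathway-averaged differences,
# and the distance correction applied by hand) and frozen here
toy_pair <- function() {
  list(
    a = "TTAGACTGGCGAATTTACGCGTTGTCTAGTCCCCCCCTCGGGCTCCCAGCGCTAGGGGCGGGAGACTACCTTGCTGTGGTGGCACTCAAG",
    b = "TTAGATTGGCGAATTTACGCATTGTCAAGCCCACCCCTCGCTCTCCCAGAGCTAGGGGCGATAGACTACCCGGCTGTGGCGACCGTCAAG",
    S = 25.6666667, N = 64.3333333, Sd = 8, Nd = 8,
    Ka = 0.1359644, Ks = 0.4028572, omega = 0.3375002)
}
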