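test_that("term levels are shortest is_a paths to the namespace root", {
  dag <- ontology_dag(diamond_terms())
  expect_equal(term_level(dag, "R"), 0)
  expect_equal(term_level(dag, "A"), 1)
  # X has paths of length 2 (via A) and 3 (via B -> A): min-depth wins
  expect_equal(term_level(dag, "X"), 2)
  expect_equal(term_level(dag, "X", mode = "max"), 3)
  expect_error(term_level(dag, "nope"), "unknown ontology term")
})

test_that("term_level agrees with a brute-force path search on random DAGs", {
  for (seed in 1:10) {
    terms <- random_dag_terms(n = 8 + (seed %% 4) * 14, seed = 1000 + seed)
    dag <- ontology_dag(terms)
    parents <- lapply(terms, `[[`, "parents")
    for (id in names(terms)) {
      expect_equal(term_level(dag, id), oracle_depth(parents, id, min),
                   info = sprintf("seed %d, term %s (min)", seed, id))
      expect_equal(term_level(dag, id, mode = "max"),
                   oracle_depth(parents, id, max),
                   info = sprintf("seed %d, term %s (max)", seed, id))
    }
  }
})

test_that("terms_at_level slices the DAG as expected", {
  dag <- seven_term_dag()
  expect_equal(terms_at_level(dag, "bp", 0), "R")
  expect_equal(terms_at_level(dag, "bp", 2), c("C", "D", "E"))
  expect_equal(terms_at_level(dag, "bp", 3), "F")
  expect_equal(terms_at_level(dag, "bp", 9), character(0))
  chain <- ontology_dag(list(
    a = list(id = "a", namespace = "bp", parents = character()),
    b = list(id = "b", namespace = "bp", parents = "a"),
    c = list(id = "c", namespace = "bp", parents = "b")))
  expect_equal(terms_at_level(chain, "bp", 2), "c")
})

test_that("genes_for_term applies the true-path rule within the universe", {
  dag <- classification_dag()
  ann <- classification_annotations()
  universe <- paste0("g", 1:10)
  focal <- genes_for_term(dag, ann, "N", universe)
  # g3 is annotated only to the grandchild of N; g6/g9 sit in another
  # namespace; g7 is unannotated
  expect_equal(focal, c("g1", "g2", "g3", "g4"))
  expect_equal(focal,
               sort(intersect(universe, names(ann$map)[vapply(
                 ann$map, function(ts)
                   any(ts %in% oracle_descendants(lapply(
                     list(R = character(), N = "R", n1 = "N", n2 = "n1",
                          M = "R", R2 = character(), Q = "R2"),
                     identity), "N")), logical(1))])))
  expect_error(genes_for_term(dag, ann, "ZZ", universe), "unknown")
})

test_that("root gene sets contain every descendant term's gene set", {
  dag <- classification_dag()
  ann <- classification_annotations()
  universe <- paste0("g", 1:10)
  root_set <- genes_for_term(dag, ann, "R", universe)
  for (t in c("N", "n1", "n2", "M")) {
    expect_true(all(genes_for_term(dag, ann, t, universe) %in% root_set))
  }
})

test_that("partitions are exact complements within the universe", {
  universe <- sprintf("g%03d", 1:100)
  p <- make_partition(universe[1:5], universe, "focal5")
  expect_length(p$complement, 95)
  expect_length(intersect(p$focal, p$complement), 0)
  expect_setequal(c(p$focal, p$complement), universe)
  expect_length(make_partition(universe, universe)$complement, 0)
  expect_length(make_partition(character(0), universe)$complement, 100)
  expect_error(make_partition("zz", universe), "outside the universe")
})

test_that("annotation transfer inherits full term sets through one-to-one orthologs", {
  src <- annotation_set(list(a1 = c("T1", "T2"), a2 = "T3"))
  orth <- data.frame(gene_id_a = c("a1", "a2"), gene_id_b = c("b1", "b2"),
                     homology_type = "ortholog_one2one",
                     stringsAsFactors = FALSE)
  tr <- transfer_annotations(src, orth, targets = c("b1", "b2", "b3"))
  expect_identical(tr$provenance, "transferred")
  expect_equal(tr$map$b1, c("T1", "T2"))
  expect_equal(tr$map$b3, character(0))  # no ortholog row -> empty set

  dup <- rbind(orth, data.frame(gene_id_a = "a9", gene_id_b = "b1",
                                homology_type = "ortholog_one2one"))
  expect_error(transfer_annotations(src, dup), "duplicated target")
})

test_that("one-to-many rows are filtered before transfer (12-gene fixture)", {
  rows <- c(sprintf("a%02d\tb%02d\tortholog_one2one", 1:10, 1:10),
            "a11\tb11\tortholog_one2many",
            "a12\tb12\tortholog_one2many")
  tsv <- write_lines_tmp(c("gene_id_a\tgene_id_b\thomology_type", rows), ".tsv")
  orth <- suppressMessages(read_orthologs(tsv))
  expect_equal(nrow(orth), 10)
  src <- annotation_set(setNames(as.list(rep("T1", 12)), sprintf("a%02d", 1:12)))
  tr <- transfer_annotations(src, orth, targets = sprintf("b%02d", 1:12))
  expect_equal(sum(lengths(tr$map) > 0), 10)
})

test_that("annotation_set drops term ids missing from the DAG with a warning", {
  dag <- seven_term_dag()
  expect_warning(ann <- annotation_set(list(g1 = c("C", "NOPE")), dag = dag),
                 "absent from the DAG")
  expect_equal(ann$map$g1, "C")
})
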