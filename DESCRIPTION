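Package: neurotarget
Title: Genomic Target Size and Molecular Divergence of Functional Gene
    Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies the mutational target size of a functional gene
    class (for example genes annotated to nervous system development)
    relative to the rest of the genome.  Reads standard annotation
    formats (GFF3, OBO, GAF 2.x, BED, FASTA, ortholog tables), slices the
    Gene Ontology at a hierarchical level, partitions genes into a focal
    class and its complement, computes per-gene architecture metrics
    (transcript/CDS/UTR length, exon counts, miRNA-target and TFBS
    repertoires), accounts class-wise genomic base-pair coverage,
    estimates pairwise Ka/Ks for ortholog coding sequences by the
    counting method with a Jukes-Cantor correction, and contrasts the two
    classes with Wilcoxon rank-sum tests.  A self-contained synthetic
    annotation generator with ground truth supports calibration and
    power studies.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
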