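# neurotarget

Comparative-genomic accounting of the **mutational target size** of a
functional gene class. Neural genes — genes annotated to the Gene Ontology
term *nervous system development* — are a small fraction of a genome's
genes, yet they tend to be long, exon-rich and regulation-heavy, so they
present a disproportionately large base-pair footprint to mutation.
`neurotarget` quantifies that footprint and contrasts it, and the
architecture and molecular divergence behind it, between the focal class
and everything else.

The package is aimed at comparative genomicists and molecular
evolutionists who want the whole chain — class definition, architecture
metrics, coverage accounting, Ka/Ks, nonparametric contrasts — as one
reproducible, offline pipeline over standard local files, with a synthetic
annotation generator for calibration and power studies in place of
versioned database downloads.

## What it computes

Given gene models (GFF3), an ontology (OBO), annotations (GAF 2.x),
optional regulatory site tracks (BED) and optional ortholog CDS pairs
(FASTA + one-to-one ortholog TSV):

* **Class partition.** The focal class is every gene annotated, directly
  or through any `is_a` descendant (the true-path rule), to a chosen focal
  term; unannotated genes fall in the complement. Comparison terms can be
  sliced from the same hierarchical level, defined as the shortest `is_a`
  path to the namespace root.
* **Per-gene architecture.** From a representative transcript (longest
  CDS): transcript, CDS and UTR length, exon count, plus miRNA-target and
  TFBS repertoires assigned by provider gene label or by coordinate
  overlap (TFBS in the gene span + upstream flank, miRNA sites in the
  3' UTR).
* **Target size.** Per class, the union-merged base-pair coverage of gene
  spans (or exons), and the class's share `bp_fraction` of the summed
  genic space.
* **Divergence.** For each ortholog CDS pair, Ka and Ks by the counting
  method: expected synonymous sites S per codon (nonsense changes excluded
  from the mutational opportunity; S + N = 3L), pathway-averaged
  synonymous/nonsynonymous differences, and the one-parameter multiple-hit
  correction d = -(3/4) ln(1 - 4p/3). omega = Ka/Ks indexes constraint.
* **Contrasts.** Every feature is compared between the classes with a
  Wilcoxon rank-sum test (exact enumeration for small tie-free samples,
  tie-corrected normal approximation otherwise), reported with raw
  p-values, star codes (`*` p < 0.05, `**` p < 0.01) and rank-biserial
  effect sizes r = 2U/(n1 n2) - 1.

## Worked example

Everything below is computed from a self-contained synthetic bundle, so it
runs offline in seconds:

```r
library(neurotarget)

cfg <- genome_config(seed = 42, n_genes = 400, focal_fraction = 0.1,
                     focal_length_multiplier = 2,
                     pairs_per_class = c(focal = 20, complement = 20))
fx <- generate_genome(cfg, tempfile("demo"))

rcfg <- run_config(gff = fx$paths[["gff"]], obo = fx$paths[["obo"]],
                   gaf = fx$paths[["gaf"]], focal_term = synthetic_focal_term(),
                   mirna_bed = fx$paths[["mirna_bed"]], tfbs_bed = fx$paths[["tfbs_bed"]],
                   cds_fasta_a = fx$paths[["cds_a"]], cds_fasta_b = fx$paths[["cds_b"]],
                   orthologs = fx$paths[["orthologs"]])
print(run_pipeline(rcfg))
```

```
Functional-class genomic target-size analysis
<partition 'nervous system development': 40 focal / 360 complement (10.0% focal of 400 genes)>
Genomic target size by class ('nervous system development', span mode)
  focal          40 genes ( 10.0%)  span       697148 bp  exonic       214107 bp  bp share  12.6%
  complement    360 genes ( 90.0%)  span      4833131 bp  exonic       896146 bp  bp share  87.4%

Feature contrasts (Wilcoxon rank-sum):
  transcript_length  p = 1.59e-15   r =  0.768 **
  cds_length         p = 3.25e-13   r =  0.702 **
  utr_length         p = 2.24e-11   r =  0.645 **
  n_exons            p = 0.161      r =  0.134
  n_mirna_sites      p = 0.000209   r =  0.345 **
  n_tfbs             p = 0.215      r =  0.118
  omega              p = 6.8e-08    r = -1.000 **

Ka/Ks contrast ('nervous system development' vs complement)
  focal:      n =  20, median omega = 0.1015 (0 excluded)
  complement: n =  20, median omega = 0.3223 (0 excluded)
Wilcoxon rank-sum (normal_approx): U = 0.0 (n1 = 20, n2 = 20), two-sided p = 6.796e-08, rank-biserial r = -1.000
```

Reading it: the 10% focal class was built with doubled CDS/UTR draws, so
it covers 12.6% of the genic space; transcript, CDS and UTR lengths and
the length-coupled miRNA repertoire separate strongly; exon counts and the
fixed-width-flank TFBS counts do not (both were drawn identically here);
and the focal class's lower Ka/Ks (0.10 vs 0.32 medians) marks it as the
more constrained class.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/neurotarget.R simulate --seed 3 --n-genes 400 --out bundle/
Rscript inst/scripts/neurotarget.R run --gff bundle/genome.gff3 --obo bundle/ontology.obo \
    --gaf bundle/annotations.gaf --focal-term SGO:0000010 --out report/
```

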