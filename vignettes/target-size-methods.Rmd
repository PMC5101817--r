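---
title: "Methods: functional-class target size, divergence and the synthetic genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional-class target size, divergence and the synthetic genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the quantities

A functional gene class presents a *mutational target* proportional to the
genomic base pairs it occupies: its gene bodies, exons, untranslated
regions and regulatory sites. A class that holds a few percent of genes
can still absorb a disproportionate share of new mutations if its genes
are long and regulation-rich — the pattern repeatedly reported for genes
of nervous system development. `neurotarget` makes that accounting
explicit and testable. For a gene universe split into a focal class and
its complement it computes:

* `gene_fraction` — class share of genes;
* `bp_fraction` — class share of the union-merged genic space, from gene
  spans (`mode = "span"`) or from exons (`mode = "exonic"`);
* per-gene architecture metrics and regulatory repertoires;
* per-ortholog-pair Ka/Ks and the class contrast of omega;
* a Wilcoxon rank-sum contrast per feature.

# Conventions

**Coordinates.** Everything internal is 0-based, half-open. GFF3 (1-based
inclusive) is converted on read; BED passes through unchanged; lengths are
always `end - start`. A single convention removes the usual off-by-one
failure class. Strand is carried for flank placement and UTR sidedness but
never enters length or coverage arithmetic.

**Gene class.** The focal set is every universe gene annotated to the
focal term or to any `is_a` descendant (true-path rule: an annotation to
*neurogenesis* implies *nervous system development*). Without propagation
the focal class of a high-level term would be nearly empty, since curators
annotate to specific terms. Unannotated genes stay in the universe and
fall in the complement — the contrast is "focal versus everything else",
not "focal versus other-annotated"; `complement_includes_unannotated =
FALSE` switches to the annotated-only universe.

**Hierarchical level.** The level of a term is the length of the shortest
`is_a` path to its namespace root (`mode = "min"`). Shortest-path depth is
deterministic and the common convention for slicing comparable terms; the
longest-path alternative (`mode = "max"`) is available for sensitivity
checks. Only `is_a` edges build the DAG; `part_of` and other
relationships are ignored as they mix hierarchy semantics. The level at
which comparison classes are drawn is a required choice of the analyst,
not a package default.

**Representative transcript.** "Per gene" length metrics need one
transcript per gene. The package picks the transcript with the longest
CDS, breaking ties by spliced length and then by identifier — a
deterministic stand-in for database canonical flags. A union-of-exons
alternative (`representative = "union"`) measures the gene's whole exonic
footprint instead.

**Regulatory assignment.** Providers distribute site tracks either with a
target-gene label or as bare coordinates, and the package supports both:
when the BED name column carries labels they win (provider assignment);
otherwise TFBS are counted by >= 1 bp overlap with the gene span extended
upstream by `tfbs_flank_bp` (default 2,000 bp, where promoter-proximal
ChIP signal concentrates) and miRNA target sites by overlap with the
representative transcript's 3' UTR (`mirna_scope = "utr3"`; `"exonic"`
widens to all exons). Neither assignment is asserted as "the" method;
both are exposed.

**Coverage across classes.** Bases shared by two genes of the same class
count once (union). Bases shared across classes count in each class, and
the two-class fractions are renormalized to sum to 1 — a symmetric rule
that keeps `bp_fraction` well defined when genes overlap.

# The rank-sum contrast

Gene length distributions are heavy-tailed, so all contrasts are Wilcoxon
rank-sum tests on midranks. With `min(n1, n2) <= 8` and a tie-free pooled
sample the two-sided p-value is exact (`2 * min(tail probabilities)`,
capped at 1, from the full null enumeration); otherwise the normal
approximation with tie-corrected variance and a continuity correction is
used. The threshold makes toy fixtures enumeration-exact while
genome-scale runs stay fast, and the continuity correction keeps results
bit-reproducible and slightly conservative. Raw p-values are reported with
`*`/`**` stars at 0.05/0.01 and no multiple-testing adjustment by default
(per-panel reporting convention); Holm adjustment sits behind
`adjust = "holm"`. Every test carries the rank-biserial effect size
`r = 2U/(n1 n2) - 1`. If every pooled value is identical the test
degenerates and p = 1 is returned directly.

# Ka/Ks by counting

For an aligned, gap-column-free ortholog CDS pair the estimator is the
classic counting method with a one-parameter correction:

* **Sites.** Each codon position contributes one site, split between
  synonymous and nonsynonymous by the fraction of its *viable* (non-stop)
  single-nucleotide changes that preserve the amino acid. Nonsense
  changes are excluded from the mutational opportunity and the position
  renormalized over viable changes — the convention of the standard
  counting-method tools. It keeps `S + N = 3 x codons` exactly while
  describing a substitution process that never fixes internal stops;
  counting nonsense changes as nonsynonymous opportunity instead would
  make Ka/Ks converge to ~0.94 rather than 1 under neutral simulation,
  since ~5% of that opportunity is unfixable. `S` is averaged between the
  two sequences.
* **Differences.** Per codon pair with k differing positions, the k!
  single-step pathway orderings are enumerated; pathways through a stop
  codon are skipped and the synonymous/nonsynonymous step counts averaged
  over the rest (if every pathway is blocked, all are used with
  stop-passing steps counted as nonsynonymous). `sd + nd = k`.
* **Correction.** `p_s = Sd/S` and `p_n = Nd/N` are corrected with
  `d = -(3/4) ln(1 - 4p/3)`. A proportion >= 3/4 leaves the correction
  undefined and flags the pair as saturated; saturated and `Ks = 0` pairs
  are excluded from class contrasts with exclusion counts reported.
  `omega = Ka/Ks` when `Ks > 0`.

No transition/transversion weighting and no likelihood codon model are
attempted; the point is a dependency-free, reproducible contrast from CDS
FASTA alone. A loader for precomputed per-gene Ka/Ks tables
(`read_kaks_table`) bypasses estimation when curated values exist.

Note one counting subtlety: pathway averaging can attribute fractional
nonsynonymous steps to codon pairs whose actual history was purely
synonymous (two synonymous hits in one codon can leave endpoints whose
alternative pathway passes through another amino acid), so under a
synonymous-only process the *translations* agree even though `Nd` need
not be exactly zero.

# The synthetic genome generator

The generator emits a complete, self-contained input bundle — GFF3, a
three-level ontology with a "nervous system development" focal term, GAF,
two BED site tracks, ortholog CDS FASTA pairs, an ortholog table and
ground-truth TSVs — whose statistical structure matches what the analysis
assumes: two gene classes, a class-specific length multiplier, optional
exon-count differences, length-proportional site densities, and
class-specific dN/dS. All randomness flows from one seed; the same config
reproduces a byte-identical bundle, and re-parsing the bundle reproduces
the ground truth exactly.

**Length distributions.** CDS (in codons), total UTR and individual
intron lengths are lognormal — gene lengths are strongly right-skewed and
non-Gaussian, which is also why the contrasts are nonparametric. Defaults:
CDS `meanlog = log(450)`, `sdlog = 0.4` codons (mean ~1.5 kb of coding
sequence); UTR `meanlog = log(900)`, `sdlog = 0.6` (mean ~1.1 kb, split
1/3 5' / 2/3 3'); introns `meanlog = log(1200)`, `sdlog = 0.7`; exon count
`1 + Poisson(7)` per class. The `sdlog` values are set so that the
generator meets its own large-sample contract — with 100 focal genes a
class mean-length ratio should sit within about +/-10% of the configured
multiplier, which requires a coefficient of variation below ~0.4-0.5 —
while staying in the realistic heavy-tail range.

**Regulatory sites.** Site counts are Poisson with density per kb of
eligible region (3' UTR for miRNA target sites at 2/kb, the fixed 2 kb
upstream flank for TFBS at 3/kb). Longer genes therefore mechanically
harbor more miRNA sites, reproducing the length/repertoire confound of
real annotations, while TFBS counts — tied to a fixed-width flank — do
not scale with gene length. `site_mode = "fixed"` draws per-gene counts
independent of length so tests can separate the two effects.

**Ortholog pairs.** `evolve_cds_pair` draws an ancestral sequence
uniformly over sense codons and evolves two lineages by repeated
single-nucleotide proposals: stop-creating changes are rejected,
synonymous changes accepted with relative rate 1, nonsynonymous with rate
omega. Each lineage stops when its accepted synonymous substitutions
reach a Poisson draw with mean `t_s/2 x S0` (ancestral synonymous sites),
so the pair's expected synonymous divergence is about `t_s`. The
calibration is event-based and approximate — multiple hits are left to
the estimator's distance correction — so its accuracy is asserted
statistically (mean recovered omega within 3 standard errors at omega 0.2
and 1.0), not exactly. Default class omegas are 0.1 (focal) versus 0.3
(complement) with `t_s = 0.2`, mirroring a strongly constrained neural
class against a typically constrained background.

**The five-percent fixture.** `make_five_percent_fixture` builds the
flagship construction: exactly 5% focal genes whose class covers about a
tenth of the span-mode genic space. The required length multiplier is
calibrated in closed form from the generator's expected values: a target
coverage share q at focal fraction f needs a class mean-span ratio
`r = (q/(1-q)) ((1-f)/f)` (~2.11 for q = 0.10, f = 0.05), and since the
multiplier scales only the spliced part, `lambda = (r (S + I) - I)/S`
with S, I the expected spliced and intron totals. The fixture uses
compact introns (`meanlog = log(200)`, `sdlog = 0.5`) so the calibrated
multiplier lands near 2.8 — in the range of reported neural/non-neural
length ratios — rather than the ~7 that intron-dominated spans would
demand.

**What the generator does not emulate.** One transcript per gene (no
isoform diversity), a toy eight-term ontology rather than real GO
topology, uniform codon usage, no transition/transversion bias, no
overlapping genes, no chromosome-scale heterogeneity, and no
annotation-error process. Passing tests therefore demonstrate that the
*machinery* is correct and calibrated under the assumed structure; they
do not validate conclusions about any real genome, where annotation
quality, isoform choice and provider-specific site calling dominate.

# Numerical and degenerate-input choices

* Interval tables are validated on construction (`0 <= start < end`);
  merging is delegated to interval-tree reduction and tested against
  per-base counting.
* Malformed GFF3/BED records are skipped with a warning naming the line;
  duplicate transcript IDs, GAF rows without a GO column and `is_a`
  cycles (reported with the terms involved) are fatal.
* Alignments shorter than `min_codons = 30` gap-free codons are refused
  rather than estimated noisily.
* Report writers emit sorted keys and a fixed 6-significant-digit float
  format, so write -> re-read -> write is byte-identical; run provenance
  records input checksums and a config hash (output directory excluded)
  so reports are reproducible from their configuration alone.

# Problem sizes used by the test and acceptance studies

The simulation studies run at sizes chosen to give tight Monte-Carlo
error while remaining quick on one core: type-I calibration at 500 genes
x 1,000 seeds (suite) or 500 seeds (acceptance script); multiplier
recovery at 2,000 genes x 100 seeds; omega recovery at 500 codons x 100
replicates per omega; the conservation-direction study at 30 + 30 pairs
of 200 codons per replicate. The flagship fixture is 2,000 genes. At
these sizes the binomial/standard errors are a few percent of the checked
quantities, so the acceptance bands reflect method behavior rather than
simulation noise.

# Known limitations

* The counting estimator ignores transition/transversion and codon-usage
  bias; against data generated under richer models omega will be biased
  in the usual NG86 directions.
* GO levels are a coarse comparability device; terms at one level differ
  widely in specificity in real ontologies.
* Annotation transfer through one-to-one orthologs drops many-to-many
  families entirely, which is conservative for the focal class size in
  the target species.
* GFF3 is the only gene-model dialect read; GTF attribute syntax is not
  parsed.
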