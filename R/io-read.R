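# Readers for the external annotation formats. Each reader is line-based so
# that a single malformed record can be skipped with a warning naming the
# offending line, while structural problems (duplicate transcript IDs,
# missing columns) abort the read.

read_text_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # normalize CRLF transparently
  sub("\r$", "", lines)
}

gff_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;) ?", key, "=([^;]+)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(z) if (length(z) >= 2) z[2] else NA_character_,
         character(1))
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA`/`transcript`, `exon` and `CDS` features linked by
#' `ID`/`Parent` attributes. Coordinates are converted from GFF3's 1-based
#' inclusive convention to the package's 0-based half-open convention.
#' Untranslated regions are always derived as exonic bases minus CDS bases
#' and assigned 5'/3' by strand; UTR features present in the file are
#' ignored.
#'
#' Records with malformed coordinates (`start > end`, non-numeric) and
#' features whose `Parent` cannot be resolved are skipped with a warning
#' that names the line. A duplicated transcript (or gene) ID is fatal.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of `gene_model` objects (names are gene IDs), each
#'   with fields `gene_id`, `symbol`, `chrom`, `strand`, `transcripts`
#'   (named list of `transcript_model`) and `span` (one-row interval table).
#' @export
read_gff3 <- function(path) {
  lines <- read_text_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) == 0) return(structure(list(), names = character()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  short <- nf < 9
  if (any(short)) {
    warnf("read_gff3: skipping %d record(s) with fewer than 9 fields (first at line %d)",
          sum(short), lineno[short][1])
    fields <- fields[!short]
    lineno <- lineno[!short]
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9, byrow = TRUE)
  chrom <- m[, 1]
  type <- m[, 3]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  strand <- ifelse(m[, 7] %in% c("+", "-"), m[, 7], ".")
  attrs <- m[, 9]

  bad <- is.na(start1) | is.na(end1) | start1 < 1 | start1 > end1
  for (i in which(bad)) {
    warnf("read_gff3: malformed coordinates at line %d (start=%s end=%s); record skipped",
          lineno[i], m[i, 4], m[i, 5])
  }
  ok <- !bad

  id <- gff_attr(attrs, "ID")
  parent <- gff_attr(attrs, "Parent")
  name <- gff_attr(attrs, "Name")

  gsel <- ok & type == "gene"
  if (anyDuplicated(id[gsel])) {
    stopf("read_gff3: duplicated gene ID: %s",
          id[gsel][duplicated(id[gsel])][1])
  }
  genes <- data.frame(id = id[gsel], symbol = name[gsel],
                      chrom = chrom[gsel], start = start1[gsel] - 1L,
                      end = end1[gsel], strand = strand[gsel],
                      stringsAsFactors = FALSE)
  no_id <- is.na(genes$id)
  if (any(no_id)) {
    warnf("read_gff3: %d gene record(s) without ID skipped", sum(no_id))
    genes <- genes[!no_id, , drop = FALSE]
  }

  tsel <- ok & type %in% c("mRNA", "transcript")
  txdup <- id[tsel][duplicated(id[tsel])]
  if (length(txdup)) {
    stopf("read_gff3: duplicated transcript ID: %s", txdup[1])
  }
  tx <- data.frame(id = id[tsel], parent = parent[tsel],
                   chrom = chrom[tsel], strand = strand[tsel],
                   line = lineno[tsel], stringsAsFactors = FALSE)
  orphan_tx <- !(tx$parent %in% genes$id)
  for (i in which(orphan_tx)) {
    warnf("read_gff3: transcript '%s' (line %d) has unresolvable Parent '%s'; skipped",
          tx$id[i], tx$line[i], tx$parent[i])
  }
  tx <- tx[!orphan_tx, , drop = FALSE]

  # exon / CDS children; Parent may be a comma-separated list
  csel <- which(ok & type %in% c("exon", "CDS"))
  cpar <- parent[csel]
  multi <- !is.na(cpar) & grepl(",", cpar, fixed = TRUE)
  reps <- ifelse(multi, vapply(strsplit(cpar, ",", fixed = TRUE), length,
                               integer(1)), 1L)
  idx <- rep(csel, reps)
  child <- data.frame(
    parent = unlist(strsplit(cpar, ",", fixed = TRUE), use.names = FALSE),
    type = type[idx], chrom = chrom[idx],
    start = start1[idx] - 1L, end = end1[idx], strand = strand[idx],
    line = lineno[idx], stringsAsFactors = FALSE)
  unresolved <- is.na(child$parent) | !(child$parent %in% tx$id)
  if (any(unresolved)) {
    warnf("read_gff3: %d %s record(s) with unresolvable Parent skipped (first at line %d)",
          sum(unresolved),
          paste(unique(child$type[unresolved]), collapse = "/"),
          child$line[unresolved][1])
    child <- child[!unresolved, , drop = FALSE]
  }
  child_rows <- split(seq_len(nrow(child)), child$parent)
  tx_by_gene <- split(tx$id, factor(tx$parent, levels = genes$id))

  out <- vector("list", nrow(genes))
  names(out) <- genes$id
  for (g in seq_len(nrow(genes))) {
    gid <- genes$id[g]
    tids <- tx_by_gene[[gid]]
    models <- list()
    for (tid in tids) {
      rows <- child[child_rows[[tid]], , drop = FALSE]
      ex <- rows[rows$type == "exon", c("chrom", "start", "end", "strand")]
      cd <- rows[rows$type == "CDS", c("chrom", "start", "end", "strand")]
      if (nrow(ex) == 0) {
        warnf("read_gff3: transcript '%s' has no exons; skipped", tid)
        next
      }
      ti <- match(tid, tx$id)
      models[[tid]] <- transcript_model(tid, gid, tx$chrom[ti],
                                        tx$strand[ti], ex, cd)
    }
    if (length(models) == 0) {
      warnf("read_gff3: gene '%s' has no usable transcripts; skipped", gid)
      next
    }
    out[[gid]] <- gene_model(gid, genes$symbol[g], models,
                             span_hint = genes[g, c("chrom", "start", "end", "strand")])
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Build a transcript model from exon and CDS intervals
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom,strand Location of the transcript.
#' @param exons,cds Interval tables (0-based half-open); `cds` may be empty
#'   for non-coding transcripts. Exons must be non-overlapping and every CDS
#'   segment must lie inside an exon.
#' @return A `transcript_model` with derived `utr5`/`utr3` interval tables.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exons, cds = NULL) {
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  validate_intervals(exons, paste0("transcript '", transcript_id, "' exons"))
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stopf("transcript '%s': overlapping exons", transcript_id)
  }
  if (is.null(cds)) {
    cds <- exons[0, , drop = FALSE]
  }
  cds <- cds[order(cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  if (nrow(cds) > 0) {
    validate_intervals(cds, paste0("transcript '", transcript_id, "' CDS"))
    contained <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons$start <= cds$start[i] & exons$end >= cds$end[i])
    }, logical(1))
    if (!all(contained)) {
      stopf("transcript '%s': CDS interval not contained in any exon",
            transcript_id)
    }
  }
  utr5 <- utr3 <- exons[0, , drop = FALSE]
  if (nrow(cds) > 0) {
    non_cds <- subtract_sorted_intervals(exons, cds)
    if (nrow(non_cds) > 0) {
      left <- non_cds[non_cds$end <= min(cds$start), , drop = FALSE]
      right <- non_cds[non_cds$start >= max(cds$end), , drop = FALSE]
      if (identical(strand, "-")) {
        utr5 <- right; utr3 <- left
      } else {
        utr5 <- left; utr3 <- right
      }
    }
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 utr5 = utr5, utr3 = utr3),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (gene %s, %s%s): %d exon(s), spliced %d bp, CDS %d bp, UTR %d+%d bp>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), spliced_length(x), cds_length(x),
              interval_length(x$utr5), interval_length(x$utr3)))
  invisible(x)
}

#' Spliced, CDS and UTR lengths of a transcript
#'
#' `spliced_length()` is the sum of exon lengths, `cds_length()` the sum of
#' CDS segment lengths and `utr_length()` their difference (5' + 3'). For a
#' coding transcript `cds_length + utr_length == spliced_length`.
#'
#' @param tx A `transcript_model`.
#' @return Integer base-pair count.
#' @export
spliced_length <- function(tx) interval_length(tx$exons)

#' @rdname spliced_length
#' @export
cds_length <- function(tx) interval_length(tx$cds)

#' @rdname spliced_length
#' @export
utr_length <- function(tx) interval_length(tx$utr5) + interval_length(tx$utr3)

#' Assemble a gene model from transcript models
#'
#' @param gene_id Gene identifier.
#' @param symbol Optional gene symbol (NA if unknown).
#' @param transcripts Named list of `transcript_model` objects (>= 1).
#' @param span_hint Optional one-row interval table from the gene record;
#'   the stored span is widened to contain every exon.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, symbol = NA_character_, transcripts,
                       span_hint = NULL) {
  if (length(transcripts) < 1) stopf("gene '%s': needs >= 1 transcript", gene_id)
  ex <- do.call(rbind, lapply(transcripts, `[[`, "exons"))
  lo <- min(ex$start); hi <- max(ex$end)
  chrom <- transcripts[[1]]$chrom
  strand <- transcripts[[1]]$strand
  if (!is.null(span_hint) && nrow(span_hint) == 1 &&
      identical(as.character(span_hint$chrom), chrom)) {
    lo <- min(lo, span_hint$start)
    hi <- max(hi, span_hint$end)
  }
  structure(list(gene_id = gene_id, symbol = symbol, chrom = chrom,
                 strand = strand,
                 transcripts = transcripts,
                 span = genomic_intervals(chrom, lo, hi, strand)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene %s (%s): %d transcript(s), span %d bp on %s%s>\n",
              x$gene_id,
              ifelse(is.na(x$symbol), "-", x$symbol),
              length(x$transcripts),
              interval_length(x$span), x$chrom, x$strand))
  invisible(x)
}

#' Read gene-to-GO annotations from a GAF 2.x file
#'
#' Column 2 is taken as the gene/product identifier, column 4 as the
#' qualifier and column 5 as the GO term id. Rows whose qualifier contains
#' `NOT` are excluded; duplicate (gene, term) rows collapse to one (set
#' semantics).
#'
#' @param path Path to a GAF file (`!`-prefixed comment lines ignored).
#' @return An [annotation_set()] with provenance `"direct"`.
#' @export
read_gaf <- function(path) {
  lines <- read_text_lines(path)
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) == 0) return(annotation_set(list()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5)) {
    stopf("read_gaf: missing GO id column at line %d (%d field(s))",
          lineno[nf < 5][1], min(nf))
  }
  gene <- vapply(fields, `[`, character(1), 2)
  qualifier <- vapply(fields, `[`, character(1), 4)
  term <- vapply(fields, `[`, character(1), 5)
  not <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                function(q) "NOT" %in% q, logical(1))
  gene <- gene[!not]; term <- term[!not]
  map <- lapply(split(term, gene), function(ts) sort(unique(ts)))
  annotation_set(map, provenance = "direct")
}

#' Read a regulatory site track from a BED file
#'
#' BED coordinates are already 0-based half-open and are used unchanged.
#' Column 4, when present, is kept as a target-gene label (used by
#' [gene_features()] for label-based site assignment).
#'
#' @param path Path to a BED4+ file (whitespace-delimited).
#' @param kind Track kind: `"mirna_target"` or `"tfbs"`.
#' @return A `regulatory_track`: an interval `data.frame` with an extra
#'   `target` column and a `kind` attribute.
#' @export
read_bed <- function(path, kind = c("mirna_target", "tfbs")) {
  kind <- match.arg(kind)
  lines <- read_text_lines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track|browser)", lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "[ \t]+")
  nf <- lengths(fields)
  short <- nf < 3
  for (i in which(short)) {
    warnf("read_bed: line %d has < 3 fields; skipped", lineno[i])
  }
  fields <- fields[!short]
  lineno <- lineno[!short]
  get_col <- function(k) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_,
           character(1))
  }
  chrom <- get_col(1)
  s <- suppressWarnings(as.integer(get_col(2)))
  e <- suppressWarnings(as.integer(get_col(3)))
  name <- get_col(4)
  strand <- get_col(6)
  bad <- is.na(s) | is.na(e) | s < 0 | s >= e
  for (i in which(bad)) {
    warnf("read_bed: invalid interval at line %d (start=%s end=%s); skipped",
          lineno[i], fields[[i]][2], fields[[i]][3])
  }
  x <- data.frame(
    chrom = chrom[!bad], start = s[!bad], end = e[!bad],
    strand = ifelse(strand[!bad] %in% c("+", "-"), strand[!bad], "."),
    target = ifelse(!is.na(name[!bad]) & nzchar(name[!bad]) &
                      name[!bad] != ".", name[!bad], NA_character_),
    stringsAsFactors = FALSE)
  regulatory_track(x, kind)
}

#' Construct a regulatory track
#'
#' @param sites Interval `data.frame`, optionally with a `target` column of
#'   gene labels.
#' @param kind `"mirna_target"` or `"tfbs"`; fixed per track.
#' @return The validated `regulatory_track`.
#' @export
regulatory_track <- function(sites, kind = c("mirna_target", "tfbs")) {
  kind <- match.arg(kind)
  if (!"target" %in% names(sites)) sites$target <- NA_character_
  if (!"strand" %in% names(sites)) sites$strand <- "."
  validate_intervals(sites, paste0(kind, " track"))
  structure(sites, kind = kind, class = c("regulatory_track", "data.frame"))
}

track_kind <- function(track) attr(track, "kind")

#' Read sequences from a FASTA file
#'
#' @param path Path to a (possibly CRLF-terminated) FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   header up to the first whitespace.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(gsub("\\s", "", as.character(seqs)))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read a one-to-one ortholog table
#'
#' Expects a tab-separated file with header columns `gene_id_a`,
#' `gene_id_b`, `homology_type`. Only one-to-one rows (homology type
#' matching `one2one`/`one-to-one`) are retained; other rows are dropped
#' with a log message, as are any retained rows sharing a `gene_id_a`
#' (those are de facto one-to-many).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `gene_id_a`, `gene_id_b`,
#'   `homology_type`.
#' @export
read_orthologs <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t",
                  colClasses = "character", stringsAsFactors = FALSE)
  need <- c("gene_id_a", "gene_id_b", "homology_type")
  if (!all(need %in% names(x))) {
    stopf("read_orthologs: header must contain %s", paste(need, collapse = ", "))
  }
  x <- x[, need]
  one2one <- grepl("one[-_ ]?2[-_ ]?one|one[-_ ]to[-_ ]one", x$homology_type,
                   ignore.case = TRUE)
  if (any(!one2one)) {
    nt_log("read_orthologs: excluded %d non one-to-one row(s)", sum(!one2one))
  }
  x <- x[one2one, , drop = FALSE]
  dup <- x$gene_id_a %in% x$gene_id_a[duplicated(x$gene_id_a)]
  if (any(dup)) {
    nt_log("read_orthologs: excluded %d row(s) with duplicated gene_id_a",
           sum(dup))
    x <- x[!dup, , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}
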