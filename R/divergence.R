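# Pairwise Ka/Ks for ortholog CDS pairs by the classic counting method:
# expected synonymous/nonsynonymous site counts per codon, pathway-averaged
# difference counts per codon pair, and a one-parameter (Jukes-Cantor-type)
# multiple-hit correction d = -(3/4) log(1 - 4p/3).

.codon_cache <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(p3 = bases, p2 = bases, p1 = bases,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$p1, grid$p2, grid$p3)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  sense <- aa != "*"

  mutants_of <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    out <- character(0)
    for (pos in 1:3) {
      for (b in setdiff(bases, ch[pos])) {
        mut <- ch; mut[pos] <- b
        out <- c(out, paste(mut, collapse = ""))
      }
    }
    out
  }

  # expected synonymous site count per codon: per position, the fraction
  # of viable (non-stop) single-nucleotide changes that preserve the
  # amino acid; nonsense changes are excluded from the opportunity and
  # the position renormalized over viable changes, so s + n = 3 per codon
  # and the counts describe the same process a stop-rejecting
  # substitution model generates
  site_s <- rep(NA_real_, 64)
  names(site_s) <- codons
  for (i in which(sense)) {
    ch <- strsplit(codons[i], "")[[1]]
    s <- 0
    for (pos in 1:3) {
      syn <- 0L; viable <- 0L
      for (b in setdiff(bases, ch[pos])) {
        mut <- ch; mut[pos] <- b
        maa <- gc[paste(mut, collapse = "")]
        if (maa != "*") {
          viable <- viable + 1L
          if (maa == aa[i]) syn <- syn + 1L
        }
      }
      if (viable > 0) s <- s + syn / viable
    }
    site_s[i] <- s
  }

  orderings <- list(`1` = list(1L),
                    `2` = list(c(1L, 2L), c(2L, 1L)),
                    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

  pair_counts <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    diffpos <- which(ca != cb)
    k <- length(diffpos)
    if (k == 0) return(c(0, 0))
    paths <- orderings[[as.character(k)]]
    res <- lapply(paths, function(ord) {
      cur <- ca
      sd <- nd <- 0
      blocked <- FALSE
      for (j in ord) {
        pos <- diffpos[j]
        nxt <- cur; nxt[pos] <- cb[pos]
        aa_cur <- gc[paste(cur, collapse = "")]
        aa_nxt <- gc[paste(nxt, collapse = "")]
        if (aa_cur == "*" || aa_nxt == "*") {
          blocked <- TRUE
          nd <- nd + 1  # stop-passing step counted nonsynonymous (fallback)
        } else if (aa_cur == aa_nxt) {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
        cur <- nxt
      }
      c(sd, nd, blocked)
    })
    res <- do.call(rbind, res)
    open <- res[, 3] == 0
    use <- if (any(open)) res[open, , drop = FALSE] else res
    c(mean(use[, 1]), mean(use[, 2]))
  }

  sd_tab <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd_tab <- sd_tab
  for (i in which(sense)) {
    for (j in which(sense)) {
      cnt <- pair_counts(codons[i], codons[j])
      sd_tab[i, j] <- cnt[1]
      nd_tab[i, j] <- cnt[2]
    }
  }

  # single-nucleotide mutation lookup: for codon i and slot (pos, alt) in
  # 1..9, the mutant codon index and its type (0 stop, 1 synonymous,
  # 2 nonsynonymous) — used by the codon-pair simulator
  mut_idx <- matrix(NA_integer_, 64, 9)
  mut_type <- matrix(NA_integer_, 64, 9)
  for (i in seq_along(codons)) {
    muts <- mutants_of(codons[i])
    mut_idx[i, ] <- match(muts, codons)
    maa <- gc[muts]
    mut_type[i, ] <- ifelse(maa == "*", 0L,
                            ifelse(maa == aa[i], 1L, 2L))
  }

  .codon_cache$tab <- list(codons = codons, aa = aa, sense = sense,
                           site_s = site_s, sd = sd_tab, nd = nd_tab,
                           mut_idx = mut_idx, mut_type = mut_type,
                           bases = bases)
  .codon_cache$tab
}

check_sense_codon <- function(codon, arg = "codon") {
  tab <- codon_tables()
  i <- match(codon, tab$codons)
  if (is.na(i)) stopf("%s '%s' is not an unambiguous DNA codon", arg, codon)
  if (!tab$sense[i]) stopf("%s '%s' is a stop codon", arg, codon)
  i
}

#' Synonymous/nonsynonymous site counts of a codon
#'
#' For each of the three positions, the synonymous site fraction is the
#' proportion of viable single-nucleotide changes that preserve the
#' encoded amino acid; changes creating stop codons are excluded from the
#' mutational opportunity (the position is renormalized over its viable
#' changes, the convention of the standard counting-method tools, which
#' keeps the site counts consistent with a substitution process that
#' never fixes nonsense changes). `s + n == 3` for every sense codon.
#'
#' @param codon A sense codon (3-letter DNA string, standard code).
#' @return Named numeric vector `c(s = , n = )`.
#' @examples
#' codon_site_counts("TTT")
#' @export
codon_site_counts <- function(codon) {
  i <- check_sense_codon(toupper(codon))
  s <- unname(codon_tables()$site_s[i])
  c(s = s, n = 3 - s)
}

#' Pathway-averaged substitution counts between two codons
#'
#' For `k` differing positions the `k!` orderings of single-step mutational
#' pathways are enumerated; pathways passing through a stop codon are
#' skipped and the synonymous/nonsynonymous step counts are averaged over
#' the remaining pathways (if every pathway is blocked, all are used with
#' stop-passing steps counted as nonsynonymous). `sd + nd == k`.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(sd = , nd = )`.
#' @export
codon_diff_counts <- function(codon_a, codon_b) {
  i <- check_sense_codon(toupper(codon_a), "codon_a")
  j <- check_sense_codon(toupper(codon_b), "codon_b")
  tab <- codon_tables()
  c(sd = tab$sd[i, j], nd = tab$nd[i, j])
}

split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  n <- nchar(seq)
  if (n == 0 || n %% 3 != 0) {
    stopf("CDS length %d is not a positive multiple of 3", n)
  }
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Codon alignment of two CDS sequences
#'
#' Validates an aligned pair: equal lengths, length divisible by 3. Codon
#' columns containing a gap (`-`) in either sequence are removed; the
#' remaining codons must be unambiguous sense codons (an internal stop is
#' an error).
#'
#' @param cds_a,cds_b Nucleotide strings of equal length.
#' @param ids Optional character vector of length 2 with sequence ids.
#' @return A `codon_alignment`: list with codon vectors `a`, `b`,
#'   `n_codons`, `ids`.
#' @export
codon_alignment <- function(cds_a, cds_b, ids = c("a", "b")) {
  a <- split_codons(cds_a)
  b <- split_codons(cds_b)
  if (length(a) != length(b)) {
    stopf("codon_alignment: sequences differ in length (%d vs %d codons)",
          length(a), length(b))
  }
  gap <- grepl("-", a, fixed = TRUE) | grepl("-", b, fixed = TRUE)
  a <- a[!gap]; b <- b[!gap]
  if (length(a) == 0) stopf("codon_alignment: no gap-free codon columns")
  tab <- codon_tables()
  ia <- match(a, tab$codons); ib <- match(b, tab$codons)
  if (anyNA(ia) || anyNA(ib)) {
    stopf("codon_alignment: ambiguous or non-DNA codon (e.g. '%s')",
          c(a[is.na(ia)], b[is.na(ib)])[1])
  }
  if (any(!tab$sense[ia]) || any(!tab$sense[ib])) {
    stopf("codon_alignment: internal stop codon at codon %d",
          which(!tab$sense[ia] | !tab$sense[ib])[1])
  }
  structure(list(a = a, b = b, ia = ia, ib = ib, n_codons = length(a),
                 ids = ids),
            class = "codon_alignment")
}

#' Ka/Ks for one aligned ortholog CDS pair
#'
#' Counting estimator: expected synonymous sites `S` are the per-codon
#' synonymous site counts summed along each sequence and averaged between
#' the two; `N = 3 L - S`. Observed synonymous/nonsynonymous differences
#' `Sd`, `Nd` are pathway-averaged per codon pair. Proportions
#' `p_s = Sd / S` and `p_n = Nd / N` are corrected for multiple hits with
#' `d = -(3/4) log(1 - 4 p / 3)`, giving `Ks` and `Ka`; `omega = Ka / Ks`
#' when `Ks > 0`. A proportion `>= 3/4` makes the correction undefined and
#' flags the estimate as saturated.
#'
#' @param alignment A `codon_alignment`, or a nucleotide string (then
#'   `cds_b` must be given and the pair is aligned codon-wise as-is).
#' @param cds_b Second sequence when `alignment` is a string.
#' @param min_codons Minimum gap-free codon columns (default 30); shorter
#'   alignments are refused.
#' @return A `divergence_estimate`: list with `ka`, `ks`, `omega`,
#'   `s_sites`, `n_sites`, `sd`, `nd`, `ps`, `pn`, `n_codons`, `saturated`,
#'   `ids`.
#' @export
kaks_pair <- function(alignment, cds_b = NULL, min_codons = 30) {
  if (!inherits(alignment, "codon_alignment")) {
    alignment <- codon_alignment(alignment, cds_b)
  }
  aln <- alignment
  if (aln$n_codons < min_codons) {
    stopf("kaks_pair: alignment has %d codons, fewer than min_codons = %d",
          aln$n_codons, min_codons)
  }
  tab <- codon_tables()
  S <- (sum(tab$site_s[aln$ia]) + sum(tab$site_s[aln$ib])) / 2
  N <- 3 * aln$n_codons - S
  Sd <- sum(tab$sd[cbind(aln$ia, aln$ib)])
  Nd <- sum(tab$nd[cbind(aln$ia, aln$ib)])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps)
  ka <- jc(pn)
  saturated <- (!is.na(ps) && ps >= 3 / 4) || (!is.na(pn) && pn >= 3 / 4)
  omega <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(ka = ka, ks = ks, omega = omega,
                 s_sites = S, n_sites = N, sd = Sd, nd = Nd,
                 ps = ps, pn = pn, n_codons = aln$n_codons,
                 saturated = saturated, ids = aln$ids),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("Ka/Ks estimate (%s vs %s, %d codons)\n", x$ids[1], x$ids[2],
              x$n_codons))
  cat(sprintf("  sites: S = %.2f, N = %.2f; differences: Sd = %.2f, Nd = %.2f\n",
              x$s_sites, x$n_sites, x$sd, x$nd))
  cat(sprintf("  Ka = %s, Ks = %s, Ka/Ks = %s%s\n",
              format(x$ka, digits = 4), format(x$ks, digits = 4),
              if (is.na(x$omega)) "undefined" else format(x$omega, digits = 4),
              if (x$saturated) "  [saturated]" else ""))
  invisible(x)
}

#' Load a precomputed per-gene Ka/Ks table
#'
#' Alternative to estimating from CDS sequences: a TSV with header columns
#' `gene_id`, `ka`, `ks` (for instance Biomart-style exports).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `gene_id`, `ka`, `ks`, `omega`
#'   (`NA` where `ks == 0`).
#' @export
read_kaks_table <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "ka", "ks")
  if (!all(need %in% names(x))) {
    stopf("read_kaks_table: header must contain %s", paste(need, collapse = ", "))
  }
  x$ka <- as.numeric(x$ka); x$ks <- as.numeric(x$ks)
  x$omega <- ifelse(!is.na(x$ks) & x$ks > 0 & !is.na(x$ka), x$ka / x$ks,
                    NA_real_)
  x[, c("gene_id", "ka", "ks", "omega")]
}

#' Class-wise Ka/Ks distributions and rank-sum contrast
#'
#' Splits per-gene omega estimates by a class partition, drops undefined or
#' saturated estimates (counts reported) and tests the two omega samples
#' with [rank_sum_test()].
#'
#' @param estimates Either a `data.frame` with columns `gene_id` and
#'   `omega` (e.g. from [read_kaks_table()]), or a named list of
#'   `divergence_estimate`s keyed by gene id.
#' @param partition A `class_partition` over the gene ids.
#' @return A `class_divergence`: list with the two omega vectors,
#'   per-class medians, exclusion counts and the `rank_test`.
#' @export
class_divergence <- function(estimates, partition) {
  stopifnot(inherits(partition, "class_partition"))
  if (is.data.frame(estimates)) {
    df <- estimates[, c("gene_id", "omega")]
  } else {
    df <- data.frame(gene_id = names(estimates),
                     omega = vapply(estimates, function(e)
                       if (isTRUE(e$saturated)) NA_real_ else e$omega,
                       numeric(1)),
                     stringsAsFactors = FALSE)
  }
  pick <- function(ids) {
    v <- df$omega[df$gene_id %in% ids]
    list(omega = v[!is.na(v)], excluded = sum(is.na(v)))
  }
  foc <- pick(partition$focal)
  com <- pick(partition$complement)
  if (length(foc$omega) == 0 || length(com$omega) == 0) {
    stopf("class_divergence: a class is empty after excluding undefined/saturated estimates")
  }
  structure(list(focal_omega = foc$omega, complement_omega = com$omega,
                 median_focal = median(foc$omega),
                 median_complement = median(com$omega),
                 n_excluded_focal = foc$excluded,
                 n_excluded_complement = com$excluded,
                 test = rank_sum_test(foc$omega, com$omega),
                 label = partition$label),
            class = "class_divergence")
}

#' @export
print.class_divergence <- function(x, ...) {
  cat(sprintf("Ka/Ks contrast ('%s' vs complement)\n", x$label))
  cat(sprintf("  focal:      n = %3d, median omega = %.4f (%d excluded)\n",
              length(x$focal_omega), x$median_focal, x$n_excluded_focal))
  cat(sprintf("  complement: n = %3d, median omega = %.4f (%d excluded)\n",
              length(x$complement_omega), x$median_complement,
              x$n_excluded_complement))
  print(x$test)
  invisible(x)
}
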