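# Independent brute-force oracles. These deliberately share no code with
# the package internals: per-base counting for coverage, exhaustive path
# search for DAG depth, full permutation enumeration for the rank-sum
# test, and direct genetic-code enumeration for the Ka/Ks counting pieces.

# covered bases by per-base membership counting
oracle_covered_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(vapply(split(df, df$chrom), function(p) {
    bases <- unlist(Map(function(s, e) seq.int(s, e - 1L), p$start, p$end))
    length(unique(bases))
  }, numeric(1)))
}

# shortest/longest root distance by exhaustive recursive path search;
# `parents` is a named list id -> character vector of parent ids
oracle_depth <- function(parents, id, agg = min) {
  ps <- parents[[id]]
  if (length(ps) == 0) return(0)
  agg(vapply(ps, function(p) oracle_depth(parents, p, agg), numeric(1))) + 1
}

# all descendants of a term (including itself) by exhaustive enumeration
oracle_descendants <- function(parents, id) {
  ids <- names(parents)
  anc <- function(t) {
    ps <- parents[[t]]
    if (length(ps) == 0) return(character(0))
    unique(c(ps, unlist(lapply(ps, anc))))
  }
  c(id, ids[vapply(ids, function(t) id %in% anc(t), logical(1))])
}

# two-sided rank-sum p by full enumeration of all C(n1+n2, n1) assignments
oracle_rank_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  Us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

# synonymous site count of a codon by enumerating its point mutants:
# per position, the synonymous fraction of the viable (non-stop) changes
oracle_site_counts <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    muts <- vapply(nts[nts != ch[pos]], function(b) {
      mut <- ch
      mut[pos] <- b
      code[[paste(mut, collapse = "")]]
    }, character(1))
    viable <- muts[muts != "*"]
    if (length(viable)) s <- s + mean(viable == code[[codon]])
  }
  c(s = s, n = 3 - s)
}

# pathway-averaged (sd, nd) between two sense codons via explicit
# recursion over all step orderings
oracle_diff_counts <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  dpos <- which(ca != cb)
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  walk <- function(cur, remaining) {
    if (length(remaining) == 0) {
      return(list(list(sd = 0, nd = 0, blocked = FALSE)))
    }
    out <- list()
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- cb[p]
      a_cur <- code[[paste(cur, collapse = "")]]
      a_nxt <- code[[paste(nxt, collapse = "")]]
      step_stop <- a_cur == "*" || a_nxt == "*"
      step_syn <- !step_stop && a_cur == a_nxt
      for (tail in walk(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1]] <- list(
          sd = tail$sd + as.numeric(step_syn),
          nd = tail$nd + as.numeric(!step_syn),
          blocked = tail$blocked || step_stop)
      }
    }
    out
  }
  paths <- walk(ca, dpos)
  blocked <- vapply(paths, `[[`, logical(1), "blocked")
  use <- if (all(blocked)) paths else paths[!blocked]
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

# quadratic all-pairs overlap scan: sites overlapping any region by >= 1 bp
oracle_overlap_count <- function(sites, regions) {
  n <- 0
  for (i in seq_len(nrow(sites))) {
    hit <- FALSE
    for (j in seq_len(nrow(regions))) {
      if (sites$chrom[i] == regions$chrom[j] &&
          sites$start[i] < regions$end[j] &&
          sites$end[i] > regions$start[j]) hit <- TRUE
    }
    if (hit) n <- n + 1
  }
  n
}

# random small DAG: term 1 is the root, each later term picks 1-2 parents
# among earlier terms
random_dag_terms <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n))
  terms <- list()
  terms[[ids[1]]] <- list(id = ids[1], name = ids[1], namespace = "bp",
                          parents = character())
  for (i in 2:n) {
    k <- sample.int(min(2L, i - 1L), 1)
    terms[[ids[i]]] <- list(id = ids[i], name = ids[i], namespace = "bp",
                            parents = sample(ids[seq_len(i - 1)], k))
  }
  terms
}
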