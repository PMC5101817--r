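#' Construct a table of genomic intervals
#'
#' All coordinates inside the package are 0-based, half-open `[start, end)`:
#' GFF3 input (1-based, inclusive) is converted on read, BED input is taken
#' as-is. Lengths are therefore always `end - start`.
#'
#' @param chrom Character vector of sequence names.
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, exclusive end; must satisfy `end > start`.
#' @param strand One of `"+"`, `"-"`, `"."` (recycled). Strand is carried
#'   through but never enters length or coverage arithmetic.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", c(0, 30), c(10, 40))
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  if (n == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  x <- data.frame(chrom = as.character(rep_len(chrom, n)),
                  start = as.integer(rep_len(start, n)),
                  end = as.integer(rep_len(end, n)),
                  strand = as.character(rep_len(strand, n)),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, where = "interval") {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$start) || anyNA(x$end)) {
    stopf("%s: NA coordinates", where)
  }
  bad <- x$start < 0 | x$end <= x$start
  if (any(bad)) {
    stopf("%s: invalid interval(s) %s (need 0 <= start < end)", where,
          paste(sprintf("[%d,%d)", x$start[bad], x$end[bad])[seq_len(min(3, sum(bad)))],
                collapse = ", "))
  }
  if (!all(x$strand %in% c("+", "-", ".")))
    stopf("%s: strand must be one of '+', '-', '.'", where)
  invisible(x)
}

interval_length <- function(x) {
  if (nrow(x) == 0) return(0L)
  sum(x$end - x$start)
}

#' Merge intervals into a disjoint sorted union
#'
#' Computes the union of a set of genomic intervals per chromosome. The
#' result is sorted, pairwise disjoint and maximal; the total covered base
#' count `sum(end - start)` equals the number of distinct bases touched by
#' any input interval. Adjacent (book-ended) intervals are joined.
#'
#' @param x An interval `data.frame` as built by [genomic_intervals()].
#' @return An interval `data.frame` with strand set to `"."`.
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(0, 5), c(10, 15)))
#' @export
merge_intervals <- function(x) {
  validate_intervals(x, "merge_intervals")
  if (nrow(x) == 0) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  parts <- split(x, x$chrom)
  out <- lapply(names(parts), function(ch) {
    p <- parts[[ch]]
    red <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(chrom = ch, start = IRanges::start(red) - 1L,
               end = IRanges::end(red), strand = ".",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(parts))])
  rownames(out) <- NULL
  out
}

#' Total bases covered by a set of intervals
#'
#' @param x An interval `data.frame`; overlaps are collapsed before counting.
#' @return Covered base pairs as a numeric scalar.
#' @export
covered_bp <- function(x) {
  m <- merge_intervals(x)
  as.numeric(interval_length(m))
}

# number of site rows (in `sites`) overlapping >= 1 bp of any region;
# each site counted at most once
count_overlapping_sites <- function(sites, regions) {
  if (is.null(sites) || nrow(sites) == 0 || nrow(regions) == 0) return(0L)
  n <- 0L
  for (ch in unique(regions$chrom)) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    r <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) next
    hit <- IRanges::overlapsAny(IRanges::IRanges(s$start + 1L, s$end),
                                IRanges::IRanges(r$start + 1L, r$end))
    n <- n + sum(hit)
  }
  n
}

# subtract sorted disjoint intervals (cd) from sorted disjoint intervals
# (ex) on one chromosome; plain-vector hot path for per-transcript UTR
# derivation (IRanges object construction is too heavy per call)
subtract_sorted_intervals <- function(ex, cd) {
  if (nrow(cd) == 0) return(ex)
  out_s <- integer(0); out_e <- integer(0)
  cs <- cd$start; ce <- cd$end
  for (i in seq_len(nrow(ex))) {
    cur <- ex$start[i]
    hit <- which(cs < ex$end[i] & ce > ex$start[i])
    for (j in hit) {
      if (cs[j] > cur) {
        out_s <- c(out_s, cur); out_e <- c(out_e, cs[j])
      }
      cur <- max(cur, ce[j])
    }
    if (cur < ex$end[i]) {
      out_s <- c(out_s, cur); out_e <- c(out_e, ex$end[i])
    }
  }
  data.frame(chrom = rep(ex$chrom[1], length(out_s)), start = out_s,
             end = out_e, strand = rep(if (nrow(ex)) ex$strand[1] else ".",
                                       length(out_s)),
             stringsAsFactors = FALSE)
}

# per-base set difference a \ b, restricted to a's chromosomes
interval_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(a)
  if (nrow(b) == 0) return(merge_intervals(a))
  out <- lapply(unique(a$chrom), function(ch) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    ira <- IRanges::reduce(IRanges::IRanges(ai$start + 1L, ai$end))
    irb <- IRanges::reduce(IRanges::IRanges(bi$start + 1L, bi$end))
    d <- IRanges::setdiff(ira, irb)
    if (length(d) == 0) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(d) - 1L,
               end = IRanges::end(d), strand = ".",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  rownames(out) <- NULL
  out
}
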