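# Gene Ontology DAG handling: OBO parsing, hierarchical levels, focal-term
# gene sets, class partitions and ortholog-based annotation transfer.
#
# The DAG is built over is_a edges only (child -> parent). "Hierarchical
# level" of a term means the shortest is_a path to its namespace root
# (min-depth) by default; a max-depth mode is available for comparison.

#' Read an ontology from an OBO file
#'
#' Parses `[Term]` stanzas (tags `id`, `name`, `namespace`, `is_a`,
#' `is_obsolete`). Obsolete terms are dropped, only `is_a` edges are used
#' (`part_of` and other relationships are ignored), and an `is_a` reference
#' to an undefined term is dropped with a warning. A cycle among `is_a`
#' edges is fatal and the error names the terms involved.
#'
#' @param path Path to an OBO 1.2/1.4 file.
#' @return An `ontology_dag`: list with `terms` (data.frame `id`, `name`,
#'   `namespace`), `parents` (named list), `graph` (igraph, edges
#'   child -> parent) and `roots` (named list, namespace -> root ids).
#' @export
read_obo <- function(path) {
  lines <- read_text_lines(path)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(NULL)
    cur
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      t <- flush(cur)
      if (!is.null(t)) terms[[t$id]] <- t
      cur <- list(parents = character())
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {  # some other stanza type
      t <- flush(cur)
      if (!is.null(t)) terms[[t$id]] <- t
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([a-zA-Z_]+): *(.*)$", ln))[[1]]
    if (length(kv) < 3) next
    key <- kv[2]; val <- kv[3]
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") {
      cur$parents <- c(cur$parents, trimws(sub("!.*$", "", val)))
    } else if (key == "is_obsolete" && grepl("^true", val)) {
      cur$obsolete <- TRUE
    }
  }
  t <- flush(cur)
  if (!is.null(t)) terms[[t$id]] <- t
  if (length(terms) == 0) stopf("read_obo: no usable [Term] stanzas in '%s'", path)
  ontology_dag(terms)
}

#' Construct an ontology DAG from parsed terms
#'
#' @param terms Named list; each element has `id`, optional `name` and
#'   `namespace`, and a character vector `parents` of is_a parents.
#' @return An `ontology_dag` (see [read_obo()]).
#' @export
ontology_dag <- function(terms) {
  ids <- names(terms)
  ns <- vapply(terms, function(t) t$namespace %||% "default", character(1))
  nm <- vapply(terms, function(t) t$name %||% t$id, character(1))
  parents <- lapply(terms, function(t) {
    p <- unique(t$parents)
    unknown <- setdiff(p, ids)
    if (length(unknown)) {
      warnf("ontology: term '%s' has is_a reference(s) to undefined term(s) %s; edge(s) dropped",
            t$id, paste(unknown, collapse = ", "))
    }
    intersect(p, ids)
  })
  names(parents) <- ids
  edges <- do.call(rbind, lapply(ids, function(i) {
    if (length(parents[[i]]) == 0) return(NULL)
    cbind(i, parents[[i]])
  }))
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(ids)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    if (length(cyc) == 0) {  # self-loop
      loops <- which(igraph::which_loop(g))
      cyc <- unique(igraph::as_ids(igraph::head_of(g, loops)))
    }
    stopf("ontology: cycle among is_a edges involving: %s",
          paste(sort(cyc), collapse = " -> "))
  }
  deg <- igraph::degree(g, mode = "out")  # edges point child -> parent
  roots <- split(ids[deg == 0], ns[deg == 0])
  structure(list(terms = data.frame(id = ids, name = nm, namespace = ns,
                                    stringsAsFactors = FALSE, row.names = NULL),
                 parents = parents, graph = g, roots = roots),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology DAG: %d terms, %d is_a edges, %d namespace(s): %s>\n",
              nrow(x$terms), igraph::ecount(x$graph),
              length(x$roots),
              paste(names(x$roots), collapse = ", ")))
  invisible(x)
}

check_term <- function(dag, term_id) {
  if (!term_id %in% x_ids(dag)) {
    stopf("unknown ontology term: '%s'", term_id)
  }
}

x_ids <- function(dag) dag$terms$id

term_namespace <- function(dag, term_id) {
  dag$terms$namespace[match(term_id, dag$terms$id)]
}

#' Hierarchical level of an ontology term
#'
#' The level is the length of the shortest is_a path from the term to its
#' namespace root (the root itself has level 0). `mode = "max"` instead
#' returns the longest such path.
#'
#' @param dag An `ontology_dag`.
#' @param term_id Term identifier (must exist in the DAG).
#' @param mode `"min"` (default, shortest path) or `"max"` (longest path).
#' @return Non-negative integer level.
#' @export
term_level <- function(dag, term_id, mode = c("min", "max")) {
  mode <- match.arg(mode)
  check_term(dag, term_id)
  lv <- term_levels(dag, term_namespace(dag, term_id), mode)
  unname(lv[term_id])
}

# levels for every term of a namespace at once
term_levels <- function(dag, namespace, mode = c("min", "max")) {
  mode <- match.arg(mode)
  ids <- dag$terms$id[dag$terms$namespace == namespace]
  roots <- dag$roots[[namespace]]
  if (is.null(roots) || length(roots) == 0) {
    stopf("namespace '%s' has no root", namespace)
  }
  if (mode == "min") {
    d <- igraph::distances(dag$graph, v = ids, to = roots, mode = "out")
    lv <- apply(d, 1, min)
  } else {
    # longest path to a root via DP over topological order (leaf-ward first)
    ord <- igraph::as_ids(igraph::topo_sort(dag$graph, mode = "in"))
    ord <- ord[ord %in% ids]  # parents come before children? mode="in": roots first
    lv <- setNames(rep(-Inf, length(ids)), ids)
    lv[roots] <- 0
    for (v in ord) {
      ps <- intersect(dag$parents[[v]], ids)
      if (length(ps)) lv[v] <- max(lv[ps] + 1)
    }
  }
  bad <- !is.finite(lv)
  if (any(bad)) {
    stopf("term(s) %s cannot reach namespace root '%s'",
          paste(names(lv)[bad], collapse = ", "), paste(roots, collapse = ","))
  }
  lv
}

#' All terms at a given hierarchical level
#'
#' @inheritParams term_level
#' @param namespace Namespace name whose terms are sliced.
#' @param level Non-negative integer.
#' @return Character vector of term ids (possibly empty), sorted.
#' @export
terms_at_level <- function(dag, namespace, level, mode = c("min", "max")) {
  stopifnot(is_count(level))
  lv <- term_levels(dag, namespace, match.arg(mode))
  sort(names(lv)[lv == level])
}

#' Descendants of a term (including itself)
#'
#' @inheritParams term_level
#' @return Character vector of term ids.
#' @export
term_descendants <- function(dag, term_id) {
  check_term(dag, term_id)
  sort(igraph::as_ids(igraph::subcomponent(dag$graph, term_id, mode = "in")))
}

#' Construct an annotation set
#'
#' @param map Named list: gene id -> character vector of term ids.
#' @param provenance `"direct"` (native annotation) or `"transferred"`
#'   (inherited through orthologs).
#' @param dag Optional `ontology_dag`; term ids absent from it are dropped
#'   with a warning.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(map, provenance = c("direct", "transferred"),
                           dag = NULL) {
  provenance <- match.arg(provenance)
  map <- lapply(map, function(ts) sort(unique(as.character(ts))))
  if (!is.null(dag)) {
    known <- x_ids(dag)
    dropped <- unique(unlist(lapply(map, setdiff, y = known)))
    if (length(dropped)) {
      warnf("annotation_set: dropped %d term id(s) absent from the DAG (e.g. %s)",
            length(dropped), dropped[1])
      map <- lapply(map, intersect, y = known)
    }
  }
  structure(list(map = map, provenance = provenance),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation set (%s): %d gene(s), %d distinct term(s)>\n",
              x$provenance, length(x$map),
              length(unique(unlist(x$map)))))
  invisible(x)
}

#' Genes annotated to a term under the true-path rule
#'
#' A gene belongs to the term's set if it is annotated to the term itself
#' or to any is_a descendant (annotation to a child implies annotation to
#' every ancestor). The result is intersected with the gene universe.
#'
#' @inheritParams term_level
#' @param annotations An `annotation_set`.
#' @param universe Character vector of all gene ids under study.
#' @return Character vector of gene ids (sorted).
#' @export
genes_for_term <- function(dag, annotations, term_id, universe) {
  check_term(dag, term_id)
  desc <- term_descendants(dag, term_id)
  hit <- vapply(annotations$map, function(ts) any(ts %in% desc), logical(1))
  sort(intersect(names(annotations$map)[hit], universe))
}

#' Partition a gene universe into a focal class and its complement
#'
#' Genes without any annotation fall in the complement: the contrast is
#' focal versus everything else, not focal versus other-annotated.
#'
#' @param focal_genes Character vector, must be a subset of `universe`.
#' @param universe Character vector of all gene ids.
#' @param label Label for the focal class (e.g. the focal term name).
#' @return A `class_partition` with fields `label`, `focal`, `complement`.
#' @export
make_partition <- function(focal_genes, universe, label = "focal") {
  focal_genes <- unique(as.character(focal_genes))
  universe <- unique(as.character(universe))
  outside <- setdiff(focal_genes, universe)
  if (length(outside)) {
    stopf("make_partition: focal gene(s) outside the universe: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  }
  structure(list(label = label,
                 focal = sort(focal_genes),
                 complement = sort(setdiff(universe, focal_genes))),
            class = "class_partition")
}

#' @export
print.class_partition <- function(x, ...) {
  n <- length(x$focal) + length(x$complement)
  cat(sprintf("<partition '%s': %d focal / %d complement (%.1f%% focal of %d genes)>\n",
              x$label, length(x$focal), length(x$complement),
              if (n) 100 * length(x$focal) / n else NA_real_, n))
  invisible(x)
}

#' Transfer annotations to another species through one-to-one orthologs
#'
#' Each target gene inherits the complete term set of its unique source
#' ortholog. Target genes with no one-to-one ortholog receive an empty set
#' (and fall in the complement class downstream).
#'
#' @param source_annotations An `annotation_set` for the source species
#'   (gene ids match `gene_id_a`).
#' @param orthologs Ortholog table as returned by [read_orthologs()]
#'   (one-to-one rows only); a duplicated `gene_id_b` is fatal.
#' @param targets Optional character vector of target gene ids to report;
#'   defaults to the `gene_id_b` column.
#' @return An `annotation_set` with provenance `"transferred"`.
#' @export
transfer_annotations <- function(source_annotations, orthologs,
                                 targets = NULL) {
  stopifnot(inherits(source_annotations, "annotation_set"))
  if (anyDuplicated(orthologs$gene_id_b)) {
    stopf("transfer_annotations: duplicated target id '%s' after one-to-one filtering",
          orthologs$gene_id_b[duplicated(orthologs$gene_id_b)][1])
  }
  targets <- targets %||% orthologs$gene_id_b
  src_of <- setNames(orthologs$gene_id_a, orthologs$gene_id_b)
  map <- lapply(setNames(targets, targets), function(b) {
    a <- src_of[b]
    if (is.na(a)) character(0) else source_annotations$map[[a]] %||% character(0)
  })
  annotation_set(map, provenance = "transferred")
}
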