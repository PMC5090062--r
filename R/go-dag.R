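#' Construct a gene-ontology DAG with true-path-propagated annotations
#'
#' Terms and `is_a` child->parent edges form a directed acyclic graph
#' (cycles are rejected). Gene annotations are propagated along the true
#' path rule: a gene annotated to a term is annotated to every ancestor.
#' Term levels are the longest path from a leaf (leaves = level 0).
#'
#' @param edges data.frame with columns `child`, `parent`.
#' @param annotations data.frame with columns `gene`, `term`, optionally
#'   `evidence`.
#' @param drop_evidence evidence codes to discard before propagation
#'   (e.g. `c("IEA", "RCA", "ND")`); ignored when no evidence column is
#'   present.
#' @return object of class `go_dag`: `terms`, `edges`, `parents`,
#'   `children`, `ancestors` (strict), `annotations` (propagated,
#'   term -> gene vector), `direct` (unpropagated), `genes`, `levels`
#'   (named integer), `graph` (igraph, edges child -> parent).
#' @export
go_dag <- function(edges, annotations, drop_evidence = NULL) {
  stopifnot(all(c("child", "parent") %in% names(edges)),
            all(c("gene", "term") %in% names(annotations)))
  if (!is.null(drop_evidence) && "evidence" %in% names(annotations))
    annotations <- annotations[!annotations$evidence %in% drop_evidence, ,
                               drop = FALSE]
  terms <- unique(c(edges$child, edges$parent, annotations$term))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) stopf("cyclic edge request: term hierarchy must be acyclic")

  vnames <- igraph::V(g)$name
  parents <- lapply(vnames, function(t)
    names(igraph::neighbors(g, t, mode = "out")))
  names(parents) <- vnames
  children <- lapply(vnames, function(t)
    names(igraph::neighbors(g, t, mode = "in")))
  names(children) <- vnames
  ancestors <- lapply(vnames, function(t)
    setdiff(names(igraph::subcomponent(g, t, mode = "out")), t))
  names(ancestors) <- vnames

  direct <- split(annotations$gene, annotations$term)
  ann <- stats::setNames(vector("list", length(vnames)), vnames)
  for (t in vnames) ann[[t]] <- character()
  for (t in names(direct)) {
    gs <- unique(direct[[t]])
    for (a in c(t, ancestors[[t]]))
      ann[[a]] <- union(ann[[a]], gs)
  }

  # levels: longest path from a leaf, computed children-first
  topo <- igraph::topo_sort(g, mode = "out")$name
  lev <- stats::setNames(integer(length(vnames)), vnames)
  for (t in topo) {
    ch <- children[[t]]
    lev[t] <- if (length(ch)) max(lev[ch]) + 1L else 0L
  }

  structure(list(terms = vnames, edges = edges, parents = parents,
                 children = children, ancestors = ancestors,
                 annotations = ann, direct = direct,
                 genes = sort(unique(annotations$gene)), levels = lev,
                 graph = g),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms (max level %d), %d genes annotated\n",
              length(x$terms), max(x$levels), length(x$genes)))
  invisible(x)
}

#' Write / read the toy GO tables (term parents + gene annotations)
#'
#' Plain two-column TSVs: `<prefix>_edges.tsv` (`child`, `parent`) and
#' `<prefix>_annotations.tsv` (`gene`, `term`, direct annotations only).
#'
#' @param dag `go_dag`.
#' @param prefix path prefix.
#' @return prefix (write) or `go_dag` (read).
#' @export
write_go_tables <- function(dag, prefix) {
  write_tsv(dag$edges, paste0(prefix, "_edges.tsv"))
  dd <- do.call(rbind, lapply(names(dag$direct), function(t)
    data.frame(gene = dag$direct[[t]], term = t, stringsAsFactors = FALSE)))
  write_tsv(dd[, c("gene", "term")], paste0(prefix, "_annotations.tsv"))
  invisible(prefix)
}

#' @rdname write_go_tables
#' @export
read_go_tables <- function(prefix) {
  go_dag(read_tsv(paste0(prefix, "_edges.tsv")),
         read_tsv(paste0(prefix, "_annotations.tsv")))
}
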