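#' Per-term Fisher (hypergeometric) over-representation test
#'
#' One-sided upper-tail hypergeometric p-value per term: the probability
#' of drawing at least the observed number of term-annotated genes in a
#' study set of its size from the population. Q-values are BH-adjusted
#' across the tested terms.
#'
#' @param study character vector of study genes (must be a subset of the
#'   population).
#' @param population character vector, the gene universe.
#' @param term_annotations named list term -> annotated genes (use a
#'   [go_dag()]'s propagated `annotations`).
#' @return data.frame: `term`, `annotated` (in population), `in_study`,
#'   `p`, `Q`, ordered by `p`.
#' @export
fisher_enrichment <- function(study, population, term_annotations) {
  missing <- setdiff(study, population)
  if (length(missing))
    stopf("study gene(s) missing from population: %s",
          paste(head(missing, 5), collapse = ", "))
  study <- unique(study); population <- unique(population)
  if (!length(study))
    return(data.frame(term = character(), annotated = integer(),
                      in_study = integer(), p = numeric(), Q = numeric()))
  N <- length(population); n <- length(study)
  res <- lapply(names(term_annotations), function(t) {
    ann <- intersect(term_annotations[[t]], population)
    K <- length(ann)
    if (K == 0) return(NULL)
    k <- length(intersect(ann, study))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, annotated = K, in_study = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(term = character(), annotated = integer(),
                      in_study = integer(), p = numeric(), Q = numeric()))
  out$Q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' GO enrichment with the elim decorrelation algorithm
#'
#' Processes terms from the deepest level upward (children strictly
#' before parents). Each term is tested by the hypergeometric test on
#' its *current* annotation set; when its p-value reaches `elim_alpha`,
#' the term's study-overlapping genes are removed from the annotation
#' sets of all its ancestors before those are tested, decorrelating the
#' hierarchy. With `elim_alpha = 0` nothing is ever eliminated and the
#' result equals [fisher_enrichment()] exactly.
#'
#' @param dag `go_dag`.
#' @param study study genes (subset of the dag's gene universe or of
#'   `population`).
#' @param elim_alpha elimination significance cut-off (default 0.05).
#' @param population gene universe; defaults to the dag's annotated
#'   genes.
#' @return data.frame: `term`, `annotated` (current set size at test
#'   time), `in_study`, `p`, `Q`, `eliminated` (genes removed upstream
#'   of this term), ordered by `p`.
#' @export
elim_enrichment <- function(dag, study, elim_alpha = 0.05,
                            population = NULL) {
  stopifnot(inherits(dag, "go_dag"))
  population <- unique(population %||% dag$genes)
  missing <- setdiff(study, population)
  if (length(missing))
    stopf("study gene(s) missing from population: %s",
          paste(head(missing, 5), collapse = ", "))
  study <- unique(study)
  N <- length(population); n <- length(study)
  current <- lapply(dag$annotations, intersect, population)
  order_terms <- igraph::topo_sort(dag$graph, mode = "out")$name
  rows <- list()
  for (t in order_terms) {
    ann <- current[[t]]
    K <- length(ann)
    if (K == 0) next
    k <- length(intersect(ann, study))
    p <- if (n == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    removed <- length(intersect(dag$annotations[[t]], population)) - K
    rows[[length(rows) + 1]] <- data.frame(
      term = t, annotated = K, in_study = k, p = p, eliminated = removed,
      stringsAsFactors = FALSE)
    if (p <= elim_alpha && elim_alpha > 0) {
      hit <- intersect(ann, study)
      for (a in dag$ancestors[[t]])
        current[[a]] <- setdiff(current[[a]], hit)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), annotated = integer(),
                      in_study = integer(), p = numeric(),
                      eliminated = integer(), Q = numeric()))
  out$Q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Ancestor-collapse redundancy reduction
#'
#' Simple, clearly non-equivalent stand-in for dedicated redundancy
#' removal tools: a reported term is dropped when one of its ancestors is
#' also reported with a smaller p-value.
#'
#' @param enrichment data.frame with `term` and `p` columns.
#' @param dag `go_dag`.
#' @return filtered enrichment data.frame.
#' @export
collapse_ancestors <- function(enrichment, dag) {
  keep <- rep(TRUE, nrow(enrichment))
  p <- stats::setNames(enrichment$p, enrichment$term)
  for (i in seq_len(nrow(enrichment))) {
    anc <- intersect(dag$ancestors[[enrichment$term[i]]], enrichment$term)
    if (length(anc) && any(p[anc] < enrichment$p[i]))
      keep[i] <- FALSE
  }
  enrichment[keep, , drop = FALSE]
}
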