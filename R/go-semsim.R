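#' Wang semantic contribution values of a term's ancestor graph
#'
#' S-value of the term itself is 1; each ancestor's S-value is the
#' maximum over its children inside the ancestor closure of `decay`
#' times the child's S-value.
#'
#' @param dag `go_dag`.
#' @param term term id.
#' @param decay contribution decay per is_a hop (default 0.8).
#' @return named numeric vector over the term and its ancestors.
#' @export
wang_svalues <- function(dag, term, decay = 0.8, topo = NULL) {
  if (!term %in% dag$terms) stopf("unknown term %s", term)
  closure <- c(term, dag$ancestors[[term]])
  sv <- stats::setNames(rep(-Inf, length(closure)), closure)
  sv[term] <- 1
  # children-first topological order restricted to the closure
  if (is.null(topo)) topo <- igraph::topo_sort(dag$graph, mode = "out")$name
  for (t in topo[topo %in% closure]) {
    if (t == term) next
    ch <- intersect(dag$children[[t]], closure)
    sv[t] <- max(decay * sv[ch])
  }
  sv
}

# precompute S-value vectors for every DAG term (used by set scoring and
# the permutation null, where each term recurs many times)
wang_cache <- function(dag, decay = 0.8) {
  topo <- igraph::topo_sort(dag$graph, mode = "out")$name
  sv <- lapply(dag$terms, wang_svalues, dag = dag, decay = decay,
               topo = topo)
  stats::setNames(sv, dag$terms)
}

wang_sim_sv <- function(sa, sb) {
  common <- intersect(names(sa), names(sb))
  if (!length(common)) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

#' Wang graph-based similarity of two GO terms
#'
#' Sum of both terms' S-values over the shared ancestor closure, divided
#' by the sum of all their S-values; lies in \[0, 1\] and equals 1 for
#' identical terms.
#'
#' @param dag `go_dag`.
#' @param a,b term ids.
#' @param decay contribution decay per hop.
#' @return similarity in \[0, 1\].
#' @export
wang_term_sim <- function(dag, a, b, decay = 0.8) {
  sa <- wang_svalues(dag, a, decay)
  sb <- wang_svalues(dag, b, decay)
  common <- intersect(names(sa), names(sb))
  if (!length(common)) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

resnik_ic <- function(dag) {
  n <- length(dag$genes)
  sizes <- vapply(dag$annotations, length, 1L)
  ic <- ifelse(sizes > 0, -log(sizes / n), 0)
  mx <- max(ic[is.finite(ic)])
  if (mx == 0) mx <- 1
  stats::setNames(ic / mx, names(ic))    # normalised to [0,1]
}

resnik_term_sim <- function(dag, a, b, ic) {
  if (!a %in% dag$terms || !b %in% dag$terms)
    stopf("unknown term %s", setdiff(c(a, b), dag$terms)[1])
  ca <- c(a, dag$ancestors[[a]]); cb <- c(b, dag$ancestors[[b]])
  common <- intersect(ca, cb)
  if (!length(common)) return(0)
  max(ic[common])
}

#' Semantic similarity of two GO term sets
#'
#' Pairwise term similarities (Wang by default; Resnik with
#' annotation-frequency information content behind a flag) combined by
#' best-match average: every term of each set is matched to its best
#' counterpart and the matches are averaged over both directions. The
#' score is symmetric and lies in \[0, 1\].
#'
#' @param dag `go_dag`.
#' @param termsA,termsB non-empty character vectors of term ids.
#' @param measure `"wang"` or `"resnik"`.
#' @param decay Wang decay per hop.
#' @return score in \[0, 1\].
#' @export
go_semantic_similarity <- function(dag, termsA, termsB, measure = "wang",
                                   decay = 0.8, cache = NULL) {
  stopifnot(length(termsA) >= 1, length(termsB) >= 1)
  unknown <- setdiff(c(termsA, termsB), dag$terms)
  if (length(unknown)) stopf("unknown term %s", unknown[1])
  termsA <- unique(termsA); termsB <- unique(termsB)
  ic <- if (measure == "resnik") resnik_ic(dag) else NULL
  if (measure == "wang" && is.null(cache)) {
    topo <- igraph::topo_sort(dag$graph, mode = "out")$name
    cache <- stats::setNames(
      lapply(unique(c(termsA, termsB)), wang_svalues, dag = dag,
             decay = decay, topo = topo), unique(c(termsA, termsB)))
  }
  S <- matrix(0, length(termsA), length(termsB))
  for (i in seq_along(termsA)) for (j in seq_along(termsB))
    S[i, j] <- switch(measure,
      wang = wang_sim_sv(cache[[termsA[i]]], cache[[termsB[j]]]),
      resnik = resnik_term_sim(dag, termsA[i], termsB[j], ic),
      stopf("unknown measure %s", measure))
  (sum(apply(S, 1, max)) + sum(apply(S, 2, max))) /
    (length(termsA) + length(termsB))
}

#' Permutation p-value for a GO-set similarity score
#'
#' Draws `n_perm` independent pairs of term sets, sampled uniformly
#' without replacement from all DAG terms with the same sizes as the
#' observed pair, scores each with [go_semantic_similarity()], and
#' estimates p as the frequency of random pairs scoring at least the
#' observed value. The raw frequency estimator (which can return 0) is
#' the default; an add-one-corrected variant (x+1)/(n+1) is available.
#'
#' @param dag `go_dag`.
#' @param observed observed similarity score.
#' @param sizeA,sizeB sizes of the two observed term sets.
#' @param n_perm number of permutations (default 500).
#' @param seed RNG seed.
#' @param add_one use the (x+1)/(n+1) estimator.
#' @param measure,decay passed to [go_semantic_similarity()].
#' @return list of class `semsim_result`: `observed`, `n_perm`,
#'   `perm_scores`, `p_value`, `seed`.
#' @export
permutation_pvalue <- function(dag, observed, sizeA, sizeB, n_perm = 500,
                               seed, add_one = FALSE, measure = "wang",
                               decay = 0.8) {
  if (n_perm <= 0) stopf("n_perm must be > 0")
  if (sizeA > length(dag$terms) || sizeB > length(dag$terms))
    stopf("set size exceeds the number of DAG terms")
  set.seed(derive_seed(seed, "semsim_perm"))
  cache <- if (measure == "wang") wang_cache(dag, decay) else NULL
  scores <- vapply(seq_len(n_perm), function(i) {
    ta <- sample(dag$terms, sizeA)
    tb <- sample(dag$terms, sizeB)
    go_semantic_similarity(dag, ta, tb, measure, decay, cache = cache)
  }, numeric(1))
  x <- sum(scores >= observed)
  p <- if (add_one) (x + 1) / (n_perm + 1) else x / n_perm
  structure(list(observed = observed, n_perm = n_perm,
                 perm_scores = scores, p_value = p, seed = seed),
            class = "semsim_result")
}

#' @export
print.semsim_result <- function(x, ...) {
  cat(sprintf("semantic similarity %.3f; permutation p = %.4g (n = %d)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}
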