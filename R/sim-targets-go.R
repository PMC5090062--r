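#' Simulate a true miRNA -> gene target graph
#'
#' Draws, for each miRNA, a number of target genes (uniform within
#' `targets_per_mirna`) without replacement from the gene universe.
#' Optionally, a designated set of miRNAs targets a designated gene set
#' preferentially (`focus_weight`-fold sampling weight), emulating
#' functionally coherent targeting: groups of such miRNAs hit different
#' genes of the same functional categories.
#'
#' @param mirnas character vector of miRNA ids.
#' @param genes character vector of gene ids.
#' @param targets_per_mirna integer pair, range of true targets per miRNA.
#' @param seed RNG seed.
#' @param focus_mirnas miRNAs with biased targeting (default none).
#' @param focus_genes genes they prefer.
#' @param focus_weight sampling weight of a focus gene for a focus miRNA
#'   relative to any other gene.
#' @return data.frame `mirna`, `gene` (the true bipartite edge list).
#' @export
simulate_true_targets <- function(mirnas, genes,
                                  targets_per_mirna = c(5L, 20L), seed,
                                  focus_mirnas = NULL, focus_genes = NULL,
                                  focus_weight = 10) {
  set.seed(derive_seed(seed, "true_targets"))
  k <- sample_range(targets_per_mirna[1], targets_per_mirna[2],
                    length(mirnas))
  w_focus <- ifelse(genes %in% focus_genes, focus_weight, 1)
  edges <- lapply(seq_along(mirnas), function(i) {
    w <- if (mirnas[i] %in% focus_mirnas) w_focus else rep(1, length(genes))
    data.frame(mirna = mirnas[i],
               gene = sample(genes, min(k[i], length(genes)), prob = w),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, edges)
}

#' Simulate per-algorithm target predictions from a true edge list
#'
#' Each algorithm independently keeps each true edge with probability
#' `sensitivity` and adds each non-edge with probability `fpr`, emulating
#' the noisy, partially overlapping outputs of independent target
#' prediction databases.
#'
#' @param true_edges data.frame `mirna`, `gene`.
#' @param mirnas,genes the full universes (needed to enumerate non-edges).
#' @param n_algorithms number of predictors (>= 2).
#' @param sensitivity per-edge retention probability.
#' @param fpr per-non-edge false positive probability.
#' @param seed RNG seed.
#' @return named list of data.frames (`algo1` ... ), each `mirna`, `gene`.
#' @export
simulate_target_predictions <- function(true_edges, mirnas, genes,
                                        n_algorithms = 5, sensitivity = 0.7,
                                        fpr = 0.01, seed) {
  if (n_algorithms < 2) stopf("need at least two algorithms")
  if (sensitivity < 0 || sensitivity > 1 || fpr < 0 || fpr > 1)
    stopf("sensitivity and fpr must lie in [0,1]")
  set.seed(derive_seed(seed, "target_predictions"))
  all_pairs <- expand.grid(mirna = mirnas, gene = genes,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$mirna, d$gene, sep = "\r")
  is_true <- key(all_pairs) %in% key(true_edges)
  out <- lapply(seq_len(n_algorithms), function(a) {
    keep <- ifelse(is_true, runif(nrow(all_pairs)) < sensitivity,
                   runif(nrow(all_pairs)) < fpr)
    res <- all_pairs[keep, , drop = FALSE]
    rownames(res) <- NULL
    res
  })
  names(out) <- sprintf("algo%d", seq_len(n_algorithms))
  out
}

#' Simulate a toy gene-ontology DAG with annotations and enriched terms
#'
#' Builds a layered acyclic term hierarchy (one root, `levels` layers,
#' each term with one or two parents in the layer above), annotates each
#' gene to a few terminal terms, true-path-propagates the annotation, and
#' designates `n_enriched` terminal terms as truth-enriched: a study set
#' drawn with [simulate_study_set()] over-represents their genes.
#'
#' @param genes character vector of gene ids.
#' @param levels number of layers below the root (depth >= 1).
#' @param terms_per_level integer vector (recycled) of layer widths.
#' @param annotations_per_gene range of terminal terms per gene.
#' @param n_enriched number of truth-enriched terminal terms.
#' @param seed RNG seed.
#' @return list: `dag` (a [go_dag()]), `true_enriched_terms` (character).
#' @export
simulate_go <- function(genes, levels = 3, terms_per_level = c(4, 10, 25),
                        annotations_per_gene = c(1L, 3L), n_enriched = 3,
                        seed) {
  if (levels < 1) stopf("DAG depth must be >= 1")
  set.seed(derive_seed(seed, "go"))
  widths <- rep_len(terms_per_level, levels)
  layers <- list("GO:ROOT")
  edges <- data.frame(child = character(), parent = character(),
                      stringsAsFactors = FALSE)
  tcount <- 0
  for (l in seq_len(levels)) {
    ids <- sprintf("GO:%07d", tcount + seq_len(widths[l]))
    tcount <- tcount + widths[l]
    prev <- layers[[l]]
    for (t in ids) {
      np <- min(sample(1:2, 1), length(prev))
      edges <- rbind(edges, data.frame(child = t,
                                       parent = sample(prev, np),
                                       stringsAsFactors = FALSE))
    }
    layers[[l + 1]] <- ids
  }
  terminal <- layers[[levels + 1]]
  k <- sample_range(annotations_per_gene[1], annotations_per_gene[2],
                    length(genes))
  ann <- do.call(rbind, lapply(seq_along(genes), function(i)
    data.frame(gene = genes[i], term = sample(terminal, k[i]),
               stringsAsFactors = FALSE)))
  dag <- go_dag(edges, ann)
  enriched <- sample(terminal, min(n_enriched, length(terminal)))
  list(dag = dag, true_enriched_terms = enriched)
}

#' Draw a study gene set over-representing truth-enriched terms
#'
#' Genes annotated (after propagation) to a truth-enriched term enter the
#' study set with probability `p_signal`; all other genes with
#' probability `p_background`.
#'
#' @param dag a [go_dag()].
#' @param enriched_terms character vector of truth-enriched term ids.
#' @param p_signal,p_background inclusion probabilities.
#' @param seed RNG seed.
#' @return character vector of study genes.
#' @export
simulate_study_set <- function(dag, enriched_terms, p_signal = 0.8,
                               p_background = 0.05, seed) {
  set.seed(derive_seed(seed, "study_set"))
  genes <- dag$genes
  sig <- unique(unlist(dag$annotations[enriched_terms]))
  p <- ifelse(genes %in% sig, p_signal, p_background)
  genes[runif(length(genes)) < p]
}

#' Partition stress-responsive genes into timing/direction classes
#'
#' Assigns each gene to early-up, early-down or late-up using
#' deterministic largest-remainder apportionment of the proportions,
#' after a seeded shuffle of the gene order.
#'
#' @param genes character vector of stress-responsive gene ids.
#' @param proportions numeric length-3, class proportions (sum <= 1 after
#'   rescaling).
#' @param seed RNG seed.
#' @return named character vector: gene -> class.
#' @export
simulate_stress_classes <- function(genes, proportions = c(1, 1, 1) / 3,
                                    seed) {
  stopifnot(length(proportions) == 3)
  set.seed(derive_seed(seed, "stress_classes"))
  sizes <- largest_remainder(length(genes), proportions)
  cls <- rep(c("early-up", "early-down", "late-up"), times = sizes)
  g <- sample(genes)
  stats::setNames(cls, g)[genes]
}
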