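#' Consensus target voting across prediction algorithms
#'
#' Keeps a miRNA -> gene edge when at least `min_support` of the supplied
#' per-algorithm edge lists predict it. Duplicate edges within one
#' algorithm's list are deduplicated with a warning (they would otherwise
#' inflate support).
#'
#' @param per_algorithm_edges named list of data.frames with columns
#'   `mirna`, `gene`.
#' @param min_support minimal number of supporting algorithms
#'   (default 2).
#' @return data.frame of class `target_graph`: `mirna`, `gene`,
#'   `support` (count), `algorithms` (comma-joined names).
#' @export
consensus_targets <- function(per_algorithm_edges, min_support = 2) {
  if (length(per_algorithm_edges) < min_support)
    stopf("need at least min_support = %d algorithm lists", min_support)
  nms <- names(per_algorithm_edges) %||%
    sprintf("algo%d", seq_along(per_algorithm_edges))
  all_edges <- list()
  for (i in seq_along(per_algorithm_edges)) {
    e <- per_algorithm_edges[[i]]
    stopifnot(all(c("mirna", "gene") %in% names(e)))
    key <- paste(e$mirna, e$gene, sep = "\r")
    if (anyDuplicated(key)) {
      warnf("duplicate edges in %s deduplicated", nms[i])
      e <- e[!duplicated(key), , drop = FALSE]
    }
    e$algorithm <- nms[i]
    all_edges[[i]] <- e[, c("mirna", "gene", "algorithm")]
  }
  ed <- do.call(rbind, all_edges)
  if (is.null(ed) || !nrow(ed))
    return(structure(data.frame(mirna = character(), gene = character(),
                                support = integer(), algorithms = character()),
                     class = c("target_graph", "data.frame")))
  key <- paste(ed$mirna, ed$gene, sep = "\r")
  agg <- tapply(ed$algorithm, key, function(a)
    paste(sort(a), collapse = ","), simplify = TRUE)
  sup <- tapply(ed$algorithm, key, length)
  uk <- names(agg)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- data.frame(
    mirna = vapply(parts, `[`, character(1), 1),
    gene = vapply(parts, `[`, character(1), 2),
    support = as.integer(sup[uk]), algorithms = unname(agg[uk]),
    stringsAsFactors = FALSE)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$mirna, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("target_graph", "data.frame")
  out
}

#' Targets of each miRNA group
#'
#' @param groups named list of miRNA id vectors.
#' @param graph `target_graph` (or any data.frame `mirna`, `gene`).
#' @return named list of gene vectors (union of the group's targets).
#' @export
group_targets <- function(groups, graph) {
  lapply(groups, function(ms)
    sort(unique(graph$gene[graph$mirna %in% ms])))
}

#' Keep only targets unique to one miRNA group
#'
#' A gene is assigned to a group iff it is targeted by that group's
#' miRNAs and by no other group's; genes targeted by several groups are
#' excluded from all of them.
#'
#' @inheritParams group_targets
#' @return named list of gene vectors (the group-unique target sets).
#' @export
unique_group_targets <- function(groups, graph) {
  tg <- group_targets(groups, graph)
  counts <- table(unlist(lapply(tg, unique)))
  shared <- names(counts)[counts > 1]
  lapply(tg, function(g) setdiff(g, shared))
}

#' Exact Venn partition of a small family of sets
#'
#' Enumerates, for every element of the union, its exact membership
#' pattern, and groups the regions into `common` (all sets), `shared`
#' (two or more, but not all) and `unique` (one set).
#'
#' @param sets named list of character vectors.
#' @return list: `regions` (membership-pattern -> elements), `summary`
#'   (data.frame region, kind, size), `common`, `shared`, `unique`
#'   (element vectors).
#' @export
venn_partition <- function(sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  u <- sort(unique(unlist(sets)))
  pattern <- vapply(u, function(e)
    paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
          collapse = "&"), character(1))
  regions <- split(u, pattern)
  nsets <- vapply(strsplit(names(regions), "&", fixed = TRUE), length, 1L)
  kind <- ifelse(nsets == length(sets), "common",
                 ifelse(nsets == 1, "unique", "shared"))
  summary <- data.frame(region = names(regions), kind = kind,
                        size = vapply(regions, length, 1L),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(regions = regions, summary = summary,
       common = unlist(regions[kind == "common"], use.names = FALSE),
       shared = unlist(regions[kind == "shared"], use.names = FALSE),
       unique = unlist(regions[kind == "unique"], use.names = FALSE))
}

#' Crosstab of group targets against stress-responsive gene classes
#'
#' Cell (g, c) counts the distinct class-`c` genes targeted by at least
#' one miRNA of group `g` through consensus edges. The class labels must
#' partition the stress-gene subset: a gene may carry one label only.
#'
#' @param groups named list of miRNA id vectors.
#' @param graph `target_graph`.
#' @param classes named character vector gene -> class label.
#' @return integer matrix, groups x classes.
#' @export
crosstab_targets_by_class <- function(groups, graph, classes) {
  if (anyDuplicated(names(classes)))
    stopf("classes must partition the genes: duplicated gene label")
  cls <- sort(unique(classes))
  tg <- group_targets(groups, graph)
  out <- matrix(0L, length(groups), length(cls),
                dimnames = list(names(groups), cls))
  for (g in names(groups)) {
    hit <- intersect(tg[[g]], names(classes))
    tb <- table(factor(classes[hit], cls))
    out[g, ] <- as.integer(tb)
  }
  out
}
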