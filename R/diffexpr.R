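#' Analysis thresholds for consensus differential expression
#'
#' Houses the pipeline's decision thresholds: BH-adjusted p cut-off,
#' minimal absolute log2 fold-change, the low-count filter, and the
#' pseudo-counts used to stabilise fold-changes and log transforms.
#'
#' @param fdr_alpha adjusted-p threshold (inclusive), default 0.05.
#' @param lfc_min minimal |log2 fold-change| (inclusive), default 1.5.
#' @param count_min low-count filter threshold, default 50.
#' @param prior_count pseudo-count added to normalised group means for
#'   fold-change computation.
#' @param pseudocount_rpm pseudo-count (RPM units) for log2 transforms.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(fdr_alpha = 0.05, lfc_min = 1.5, count_min = 50,
                            prior_count = 0.5, pseudocount_rpm = 1) {
  cfg <- list(fdr_alpha = fdr_alpha, lfc_min = lfc_min,
              count_min = count_min, prior_count = prior_count,
              pseudocount_rpm = pseudocount_rpm)
  if (any(unlist(cfg) < 0)) stopf("all thresholds must be >= 0")
  class(cfg) <- "analysis_config"
  cfg
}

#' Reads-per-million normalisation
#'
#' @param x `count_matrix`.
#' @return numeric matrix of RPM values, same dimnames as the counts.
#' @export
rpm_normalize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (any(x$library_sizes <= 0)) stopf("zero library size")
  sweep(x$counts, 2, x$library_sizes, "/") * 1e6
}

#' Consensus pairwise differential expression for one contrast
#'
#' Compares two (strain, timepoint) groups with the conditional NB exact
#' test and the NB Wald test, BH-adjusts each test across the features
#' that pass the low-count filter, and calls a miRNA differentially
#' expressed only when *both* adjusted p-values reach `fdr_alpha` and the
#' prior-stabilised |log2 fold-change| reaches `lfc_min` (all thresholds
#' inclusive).
#'
#' @param x `count_matrix`.
#' @param strainA,strainB strains to compare (A over B in the
#'   fold-change).
#' @param timepoint_h timepoint at which to compare them.
#' @param config [analysis_config()].
#' @param dispersions optional named per-miRNA dispersion vector; computed
#'   with [estimate_dispersion()] when absent.
#' @return data.frame of class `de_result`: `mirna`, `baseMeanA`,
#'   `baseMeanB` (RPM), `log2FC`, `p_exact`, `p_wald`, `padj_exact`,
#'   `padj_wald`, `is_de`; contrast metadata in attributes.
#' @export
pairwise_de <- function(x, strainA, strainB, timepoint_h,
                        config = analysis_config(), dispersions = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  d <- x$design
  sA <- condition_samples(d, strainA, timepoint_h)
  sB <- condition_samples(d, strainB, timepoint_h)
  if (!length(sA) || !length(sB))
    stopf("empty contrast: %s vs %s at %g h", strainA, strainB, timepoint_h)
  contrast <- list(list(strain = strainA, timepoint_h = timepoint_h),
                   list(strain = strainB, timepoint_h = timepoint_h))
  xf <- filter_low_counts(x, config$count_min, "contrast", contrast)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(x)
  sf <- x$library_sizes / mean(x$library_sizes)
  rpm <- rpm_normalize(x)
  ids <- rownames(xf$counts)

  res <- data.frame(mirna = ids, stringsAsFactors = FALSE)
  res$baseMeanA <- rowMeans(rpm[ids, sA, drop = FALSE])
  res$baseMeanB <- rowMeans(rpm[ids, sB, drop = FALSE])
  normA <- sweep(x$counts[ids, sA, drop = FALSE], 2, sf[sA], "/")
  normB <- sweep(x$counts[ids, sB, drop = FALSE], 2, sf[sB], "/")
  res$log2FC <- log2((rowMeans(normA) + config$prior_count) /
                     (rowMeans(normB) + config$prior_count))
  phi <- dispersions[ids]
  res$p_exact <- vapply(seq_along(ids), function(i)
    nb_exact_test(x$counts[ids[i], sA], x$counts[ids[i], sB],
                  sf[sA], sf[sB], phi[i]), numeric(1))
  res$p_wald <- vapply(seq_along(ids), function(i)
    nb_wald_test(x$counts[ids[i], sA], x$counts[ids[i], sB],
                 sf[sA], sf[sB], phi[i], config$prior_count), numeric(1))
  res$padj_exact <- bh_adjust(res$p_exact)
  res$padj_wald <- bh_adjust(res$p_wald)
  res$is_de <- res$padj_exact <= config$fdr_alpha &
    res$padj_wald <= config$fdr_alpha &
    abs(res$log2FC) >= config$lfc_min
  attr(res, "contrast") <- list(strainA = strainA, strainB = strainB,
                                timepoint_h = timepoint_h)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Run every strain-pair contrast at every timepoint
#'
#' @param x `count_matrix`.
#' @param config [analysis_config()].
#' @return data.frame stacking all [pairwise_de()] results with columns
#'   `strainA`, `strainB`, `timepoint_h` prepended.
#' @export
pairwise_de_all <- function(x, config = analysis_config()) {
  d <- x$design
  strains <- unique(d$strain); tps <- sort(unique(d$timepoint_h))
  disp <- estimate_dispersion(x)
  out <- list()
  for (i in seq_along(strains)) for (j in seq_along(strains)) {
    if (j <= i) next
    for (tp in tps) {
      r <- pairwise_de(x, strains[i], strains[j], tp, config, disp)
      r$strainA <- strains[i]; r$strainB <- strains[j]; r$timepoint_h <- tp
      out[[length(out) + 1]] <- as.data.frame(r)
    }
  }
  do.call(rbind, out)
}

#' Classify miRNAs into levelled (class #1) and divergent (class #2)
#'
#' Works from the stacked pairwise DE table. For each strain pair, a
#' miRNA is *class #1* (levelled) when it is differentially expressed at
#' the control timepoint but not at any timepoint of the levelling
#' window; it is *class #2* when it is not differentially expressed at
#' control but is at one or more post-shock timepoints. miRNAs are then
#' grouped by the pattern of supporting strain pairs: levelled in every
#' pair = `common`; in exactly one pair = `shared` (by those two
#' strains); in the two pairs containing one pivot strain = `unique` (to
#' that strain, the one whose level deviates from the others).
#'
#' @param de_table output of [pairwise_de_all()].
#' @param levelling_window post-shock timepoints (hours) that must show no
#'   interstrain difference for class #1; default `1` (the immediate
#'   post-shock uniform pattern), extendable to `c(1, 6)`.
#' @return data.frame of class `level_class`: `mirna`, `class`
#'   (`class1`/`class2`), `group` (`common`/`shared`/`unique`/`mixed`),
#'   `strains` (comma-joined members), `n_pairs`.
#' @export
classify_levelled <- function(de_table, levelling_window = 1) {
  need <- c("mirna", "strainA", "strainB", "timepoint_h", "is_de")
  stopifnot(all(need %in% names(de_table)))
  strains <- unique(c(de_table$strainA, de_table$strainB))
  tps <- sort(unique(de_table$timepoint_h))
  if (!0 %in% tps) stopf("missing control timepoint in DE table")
  if (!all(levelling_window %in% tps))
    stopf("levelling window timepoint absent from DE table")
  post <- tps[tps > 0]

  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  de_table$pair <- pair_key(de_table$strainA, de_table$strainB)
  pairs <- unique(de_table$pair)

  rows <- list()
  for (m in unique(de_table$mirna)) {
    dm <- de_table[de_table$mirna == m, ]
    p1 <- character(); p2 <- character()
    for (pr in pairs) {
      dp <- dm[dm$pair == pr, ]
      de_at <- function(t) any(dp$is_de[dp$timepoint_h %in% t])
      tested <- function(t) any(dp$timepoint_h %in% t)
      if (tested(0) && de_at(0) && tested(levelling_window) &&
          !de_at(levelling_window))
        p1 <- c(p1, pr)
      if (tested(0) && !de_at(0) && de_at(post))
        p2 <- c(p2, pr)
    }
    grp <- function(pp) {
      members <- unique(unlist(strsplit(pp, "|", fixed = TRUE)))
      if (length(pp) == choose(length(strains), 2) &&
          setequal(members, strains))
        list("common", strains)
      else if (length(pp) == 1) list("shared", members)
      else {
        pl <- strsplit(pp, "|", fixed = TRUE)
        pivot <- Reduce(intersect, pl)
        if (length(pivot) == 1) list("unique", pivot) else list("mixed", members)
      }
    }
    if (length(p1)) {
      g <- grp(p1)
      rows[[length(rows) + 1]] <- data.frame(
        mirna = m, class = "class1", group = g[[1]],
        strains = paste(sort(g[[2]]), collapse = ","),
        n_pairs = length(p1), stringsAsFactors = FALSE)
    } else if (length(p2)) {
      g <- grp(p2)
      rows[[length(rows) + 1]] <- data.frame(
        mirna = m, class = "class2", group = g[[1]],
        strains = paste(sort(g[[2]]), collapse = ","),
        n_pairs = length(p2), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), class = character(), group = character(),
               strains = character(), n_pairs = integer())
  class(out) <- c("level_class", "data.frame")
  out
}

#' Interstrain levelling index at one timepoint
#'
#' Mean over miRNAs of the maximal pairwise absolute difference of the
#' strains' condition-mean log2(RPM + pseudocount). A drop of the index
#' right after heat shock, relative to control, quantifies the levelling
#' of interstrain differences.
#'
#' @param x `count_matrix`.
#' @param timepoint_h timepoint (hours).
#' @param pseudocount RPM pseudo-count for the log transform.
#' @return scalar index (log2 units).
#' @export
levelling_index <- function(x, timepoint_h, pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  d <- x$design
  strains <- unique(d$strain)
  if (length(strains) < 2) stopf("need >= 2 strains")
  rpm <- rpm_normalize(x)
  means <- vapply(strains, function(s)
    rowMeans(rpm[, condition_samples(d, s, timepoint_h), drop = FALSE]),
    numeric(nrow(rpm)))
  lg <- log2(means + pseudocount)
  maxdiff <- apply(lg, 1, function(v) max(stats::dist(v)))
  mean(maxdiff)
}
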