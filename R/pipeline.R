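#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage's thresholds with the pipeline's standard
#' defaults (low-count filter 50, adjusted-p 0.05, |log2FC| 1.5, global
#' regression Q 0.05, stepwise alpha 0.05, R^2 0.6, 500 permutations, 6
#' clusters) plus the simulation parameters and the global seed. The
#' configuration is echoed verbatim into the run summary.
#'
#' @param out_dir output directory (created if missing).
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @param sim [sim_params()] for the synthetic inputs; when NULL a
#'   default parameter set (with one arm-switch and two editing sites) is
#'   built from `seed`.
#' @param count_min,fdr_alpha,lfc_min consensus DE thresholds.
#' @param levelling_window post-shock timepoints that must show no
#'   interstrain difference for class #1.
#' @param q_alpha,step_alpha,r2_min,degree time-course selection
#'   thresholds.
#' @param k_clusters number of YS1 clusters.
#' @param delta_min,count_floor arm-switch thresholds.
#' @param min_cov,min_freq editing-call thresholds.
#' @param n_algorithms,target_sensitivity,target_fpr,min_support target
#'   prediction simulation and consensus voting.
#' @param n_genes size of the simulated gene universe.
#' @param elim_alpha,n_perm GO enrichment / similarity settings.
#' @param align_reads_per_sample alignment simulation depth cap.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("miRheat_run_"), seed = 1,
                       sim = NULL, count_min = 50, fdr_alpha = 0.05,
                       lfc_min = 1.5, levelling_window = 1,
                       q_alpha = 0.05, step_alpha = 0.05, r2_min = 0.6,
                       degree = 2, k_clusters = 6, delta_min = 1,
                       count_floor = 50, min_cov = 10, min_freq = 0.1,
                       n_algorithms = 5, target_sensitivity = 0.7,
                       target_fpr = 0.01, min_support = 2, n_genes = 299,
                       elim_alpha = 0.05, n_perm = 500,
                       align_reads_per_sample = 2e4) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  v <- validate_config(cfg)
  if (length(v)) stopf("invalid config: %s", paste(v, collapse = "; "))
  cfg
}

#' Validate a run configuration
#'
#' @param config a `run_config` (or plain list with the same keys).
#' @return character vector of violations; empty when valid.
#' @export
validate_config <- function(config) {
  known <- names(formals(run_config))
  v <- character()
  extra <- setdiff(names(config), known)
  if (length(extra))
    v <- c(v, sprintf("unknown key: %s", paste(extra, collapse = ", ")))
  num <- c("count_min", "fdr_alpha", "lfc_min", "q_alpha", "step_alpha",
           "r2_min", "degree", "k_clusters", "delta_min", "count_floor",
           "min_cov", "min_freq", "n_algorithms", "target_sensitivity",
           "target_fpr", "min_support", "n_genes", "elim_alpha", "n_perm",
           "align_reads_per_sample")
  for (k in intersect(num, names(config)))
    if (!is.numeric(config[[k]]) || any(config[[k]] < 0))
      v <- c(v, sprintf("negative or non-numeric threshold: %s", k))
  for (k in c("fdr_alpha", "q_alpha", "step_alpha", "elim_alpha",
              "target_sensitivity", "target_fpr"))
    if (is.numeric(config[[k]]) && any(config[[k]] > 1))
      v <- c(v, sprintf("%s must lie in [0,1]", k))
  if (!is.null(config$sim) && !inherits(config$sim, "sim_params"))
    v <- c(v, "sim must be a sim_params object")
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    v <- c(v, "seed must be a single number")
  v
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full synthetic heat-shock miRNA pipeline
#'
#' Executes simulate -> quantify -> consensus DE -> levelling
#' classification -> time-course selection -> YS1 clustering ->
#' arm-switch detection -> editing calls -> consensus targets -> GO
#' enrichment (elim) -> semantic similarity with permutation p ->
#' stress-class crosstab. Per-stage tables are written as TSV under
#' `config$out_dir` and one machine-readable JSON summary (with the
#' config echoed) is written as `summary.json`. A stage failure aborts
#' with the stage name.
#'
#' @param config [run_config()].
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config = run_config()) {
  v <- validate_config(config)
  if (length(v)) stopf("invalid config: %s", paste(v, collapse = "; "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  summary <- list(config = config[setdiff(names(config), "sim")])
  stage <- "init"
  res <- tryCatch({
    stage <- "simulate"
    params <- config$sim %||% sim_params(
      seed = config$seed, arm_switch_events = default_arm_switch(),
      editing_sites = default_editing_sites())
    summary$sim_params <- params[setdiff(names(params),
                                         c("arm_switch_events",
                                           "editing_sites"))]
    ann <- generate_annotation(params)
    sim <- simulate_counts(ann, params)
    write_mirna_gff3(ann, out("annotation.gff3"))
    write_genome_fasta(ann, out("genome.fa"))
    write_count_matrix(sim$counts, out("simulated"))
    stage_log(stage, "%d matures, %d samples", nrow(sim$counts$counts),
              ncol(sim$counts$counts))

    stage <- "quantify"
    aln <- simulate_alignments(
      ann, sim$counts, params,
      max_reads_per_sample = config$align_reads_per_sample)
    write_bed6(aln, out("alignments.bed"))
    cm_q <- count_overlaps(aln, ann, sim$counts$design)
    write_count_matrix(cm_q, out("quantified"))
    summary$quantify <- attr(cm_q, "report")
    stage_log(stage, "%d/%d reads assigned", attr(cm_q, "report")$n_assigned,
              attr(cm_q, "report")$n_input)

    stage <- "diffexpr"
    acfg <- analysis_config(config$fdr_alpha, config$lfc_min,
                            config$count_min)
    de <- pairwise_de_all(sim$counts, acfg)
    write_tsv(de, out("pairwise_de.tsv"))
    classes <- classify_levelled(de, config$levelling_window)
    write_tsv(as.data.frame(classes), out("level_classes.tsv"))
    tps <- sort(unique(sim$counts$design$timepoint_h))
    lev_idx <- vapply(tps, function(t)
      levelling_index(sim$counts, t), numeric(1))
    names(lev_idx) <- paste0("t", tps)
    summary$diffexpr <- list(
      n_tested = length(unique(de$mirna)),
      n_de_mirnas = length(unique(de$mirna[de$is_de])),
      n_class1 = sum(classes$class == "class1"),
      n_class2 = sum(classes$class == "class2"),
      class1_groups = as.list(table(classes$group[classes$class == "class1"])),
      levelling_index = as.list(lev_idx))
    stage_log(stage, "%d DE miRNAs; %d class1, %d class2",
              summary$diffexpr$n_de_mirnas, summary$diffexpr$n_class1,
              summary$diffexpr$n_class2)

    stage <- "timecourse"
    cm_f <- filter_low_counts(sim$counts, config$count_min)
    pm <- profile_normalize(cm_f)
    sel <- timecourse_select(pm, config$degree, config$q_alpha,
                             config$step_alpha, config$r2_min)
    write_tsv(sel$table, out("timecourse_selection.tsv"))
    summary$timecourse <- list(
      n_profiled = nrow(sel$table),
      n_significant = sum(sel$table$n_strains_significant > 0),
      strain_partition = as.list(sel$partition))

    stage <- "cluster"
    to_cluster <- sel$table$mirna[sel$table$n_strains_significant >= 2]
    if (length(to_cluster) < config$k_clusters)
      to_cluster <- sel$table$mirna[sel$table$n_strains_significant >= 1]
    cl <- NULL
    if (length(to_cluster) >= config$k_clusters) {
      cl <- hierarchical_cluster(pm, config$k_clusters, ids = to_cluster)
      write_tsv(data.frame(mirna = names(cl$assignment),
                           cluster = cl$assignment),
                out("clusters.tsv"))
      prof_fit <- do.call(rbind, lapply(seq_len(config$k_clusters),
        function(k) {
          mem <- names(cl$assignment)[cl$assignment == k]
          cbind(cluster = k, cluster_mean_profile(pm, mem))
        }))
      write_tsv(prof_fit, out("cluster_profiles.tsv"))
      summary$cluster <- list(k = config$k_clusters,
                              sizes = as.list(table(cl$assignment)))
    } else {
      summary$cluster <- list(k = 0, sizes = list())
    }

    stage <- "arms"
    art <- arm_ratio_table(sim$counts, ann)
    events <- detect_arm_switch(art, config$delta_min, config$count_floor)
    write_tsv(events, out("arm_switch_events.tsv"))
    summary$arms <- list(n_events = nrow(events),
                         hairpins = unique(events$hairpin),
                         strains = unique(events$strain))

    stage <- "editing"
    calls <- call_editing(aln, ann, config$min_cov, config$min_freq,
                          params$seq_error_rate)
    write_tsv(calls, out("editing_calls.tsv"))
    summary$editing <- list(n_calls = nrow(calls),
                            n_in_seed = sum(calls$in_seed),
                            matures = unique(calls$mature_id))

    stage <- "targets"
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    goo <- simulate_go(genes, seed = params$seed)
    write_go_tables(goo$dag, out("go"))
    # levelled miRNAs target functionally coherent genes: bias their true
    # edges toward the genes of the truth-enriched terms
    focus_genes <- unique(unlist(goo$dag$annotations[
      goo$true_enriched_terms]))
    c1_mirnas <- classes$mirna[classes$class == "class1"]
    true_edges <- simulate_true_targets(rownames(sim$counts$counts), genes,
                                        seed = params$seed,
                                        focus_mirnas = c1_mirnas,
                                        focus_genes = focus_genes)
    preds <- simulate_target_predictions(
      true_edges, rownames(sim$counts$counts), genes, config$n_algorithms,
      config$target_sensitivity, config$target_fpr, seed = params$seed)
    cons <- consensus_targets(preds, config$min_support)
    write_tsv(as.data.frame(cons), out("consensus_targets.tsv"))
    # miRNA groups: levelled (class #1) miRNAs split by their Venn group
    c1 <- classes[classes$class == "class1", , drop = FALSE]
    groups <- split(c1$mirna, paste(c1$group, c1$strains, sep = ":"))
    utg <- unique_group_targets(groups, cons)
    summary$targets <- list(
      n_consensus_edges = nrow(cons),
      group_sizes = lapply(groups, length),
      unique_target_sizes = lapply(utg, length))

    stage <- "go"
    enr <- lapply(utg, function(g)
      if (length(g)) elim_enrichment(goo$dag, g, config$elim_alpha)
      else NULL)
    top_terms <- lapply(enr, function(e)
      if (!is.null(e)) e$term[e$p <= 0.05] else character())
    gset <- names(top_terms)[vapply(top_terms, length, 1L) > 0]
    semsim <- list()
    if (length(gset) >= 2) {
      for (i in seq_along(gset)) for (j in seq_along(gset)) {
        if (j <= i) next
        s <- go_semantic_similarity(goo$dag, top_terms[[gset[i]]],
                                    top_terms[[gset[j]]])
        pp <- permutation_pvalue(goo$dag, s, length(top_terms[[gset[i]]]),
                                 length(top_terms[[gset[j]]]),
                                 config$n_perm, seed = params$seed)
        semsim[[paste(gset[i], gset[j], sep = " vs ")]] <-
          list(score = s, p = pp$p_value)
      }
    }
    summary$go <- list(
      n_terms = length(goo$dag$terms),
      enriched_terms = lapply(top_terms, length),
      semantic_similarity = semsim,
      mean_similarity = if (length(semsim))
        mean(vapply(semsim, `[[`, numeric(1), "score")) else NA)

    stage <- "crosstab"
    cls <- simulate_stress_classes(genes, seed = params$seed)
    if (!is.null(cl)) {
      tc_groups <- split(names(cl$assignment), cl$assignment)
      names(tc_groups) <- paste0("cluster", names(tc_groups))
    } else tc_groups <- groups
    xt <- crosstab_targets_by_class(tc_groups, cons, cls)
    write_tsv(data.frame(group = rownames(xt), xt, check.names = FALSE),
              out("stress_crosstab.tsv"))
    summary$crosstab <- as.data.frame(xt)
    summary
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  jsonlite::write_json(res, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  stage_log("report", "summary written to %s", out("summary.json"))
  invisible(res)
}
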