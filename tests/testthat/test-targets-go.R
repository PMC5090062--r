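test_that("consensus voting counts algorithm support exactly", {
  e <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(mirna = m[, 1], gene = m[, 2], stringsAsFactors = FALSE)
  }
  lists <- list(a1 = e("m1", "g1", "m1", "g2"),
                a2 = e("m1", "g1"),
                a3 = e("m2", "g3"))
  cons <- consensus_targets(lists, min_support = 2)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$mirna, "m1"); expect_equal(cons$gene, "g1")
  expect_equal(cons$support, 2L)

  uni <- consensus_targets(lists, min_support = 1)
  expect_equal(nrow(uni), 3)     # union of all distinct edges

  expect_warning(consensus_targets(list(a1 = e("m1", "g1", "m1", "g1"),
                                        a2 = e("m1", "g1"))),
                 "duplicate")

  # brute-force support counting on a random instance
  set.seed(14)
  mk_rand <- function() {
    n <- 300
    data.frame(mirna = sample(sprintf("m%02d", 1:20), n, TRUE),
               gene = sample(sprintf("g%03d", 1:100), n, TRUE),
               stringsAsFactors = FALSE)
  }
  lists2 <- lapply(1:4, function(i) {
    d <- mk_rand(); d[!duplicated(paste(d$mirna, d$gene)), ]
  })
  names(lists2) <- paste0("a", 1:4)
  cons2 <- consensus_targets(lists2, 2)
  key <- function(d) paste(d$mirna, d$gene)
  support_bf <- table(unlist(lapply(lists2, key)))
  expect_setequal(key(cons2), names(support_bf)[support_bf >= 2])
  expect_equal(cons2$support,
               as.integer(support_bf[key(cons2)]))
})

test_that("group-unique targets exclude genes shared between groups", {
  graph <- data.frame(
    mirna = c("m1", "m2", "m3", "m3"),
    gene = c("gA", "gA", "gB", "gC"), stringsAsFactors = FALSE)
  groups <- list(G1 = c("m1"), G2 = c("m2", "m3"))
  utg <- unique_group_targets(groups, graph)
  expect_length(utg$G1, 0)                  # gA targeted by both groups
  expect_setequal(utg$G2, c("gB", "gC"))
  # single group: identity
  expect_setequal(unique_group_targets(groups["G2"], graph)$G2,
                  c("gA", "gB", "gC"))
  # partition: uniques plus shared recover the union of all targets
  tg <- group_targets(groups, graph)
  shared <- intersect(tg$G1, tg$G2)
  expect_setequal(c(unlist(utg), shared), unique(graph$gene))
})

test_that("Venn partition matches brute-force membership enumeration", {
  same <- list(a = c("x", "y"), b = c("x", "y"), c = c("x", "y"))
  v1 <- venn_partition(same)
  expect_setequal(v1$common, c("x", "y"))
  expect_length(v1$shared, 0); expect_length(v1$unique, 0)

  disj <- list(a = "x", b = "y", c = "z")
  v2 <- venn_partition(disj)
  expect_setequal(v2$unique, c("x", "y", "z"))
  expect_length(v2$common, 0)

  set.seed(19)
  sets <- lapply(1:3, function(i) sample(letters, 12))
  names(sets) <- c("A", "B", "C")
  v <- venn_partition(sets)
  u <- unique(unlist(sets))
  expect_equal(sum(v$summary$size), length(u))
  for (el in u) {
    n_in <- sum(vapply(sets, function(s) el %in% s, logical(1)))
    expect_true(el %in% switch(as.character(n_in), "1" = v$unique,
                               "2" = v$shared, "3" = v$common))
  }
})

test_that("Fisher enrichment equals the hypergeometric tail sum", {
  population <- sprintf("g%03d", 1:100)
  study <- population[1:10]
  ann <- list(T1 = population[1:10],      # 5 of 10 in study? no: all 10
              T2 = population[6:15],      # 5 in study
              T3 = population)            # whole population
  res <- fisher_enrichment(study, population, ann)
  p_of <- function(t) res$p[res$term == t]
  # direct tail-sum oracle
  tail_sum <- function(k, K, n, N)
    sum(dhyper(k:min(K, n), K, N - K, n))
  expect_equal(p_of("T2"), tail_sum(5, 10, 10, 100), tolerance = 1e-12)
  expect_equal(p_of("T1"), tail_sum(10, 10, 10, 100), tolerance = 1e-12)
  expect_equal(p_of("T3"), 1)

  expect_equal(nrow(fisher_enrichment(character(), population, ann)), 0)
  expect_error(fisher_enrichment(c("ghost"), population, ann), "missing")
})

test_that("elim equals Fisher on flat ontologies and decorrelates parents", {
  genes <- sprintf("g%03d", 1:80)
  goo <- simulate_go(genes, levels = 1, terms_per_level = 8, seed = 23)
  study <- simulate_study_set(goo$dag, goo$true_enriched_terms, seed = 24)
  fis <- fisher_enrichment(study, goo$dag$genes, goo$dag$annotations)
  eli <- elim_enrichment(goo$dag, study)
  # every leaf term: no descendants, so nothing can be eliminated below it
  leaves <- setdiff(fis$term, "GO:ROOT")
  expect_equal(fis$p[match(leaves, fis$term)],
               eli$p[match(leaves, eli$term)], tolerance = 1e-12)
  # the root is the whole-population term under plain Fisher
  expect_equal(fis$p[fis$term == "GO:ROOT"], 1)

  # elim_alpha = 0: no elimination on a deep DAG either
  goo3 <- simulate_go(genes, levels = 3, seed = 25)
  study3 <- simulate_study_set(goo3$dag, goo3$true_enriched_terms, seed = 26)
  fis3 <- fisher_enrichment(study3, goo3$dag$genes, goo3$dag$annotations)
  eli3 <- elim_enrichment(goo3$dag, study3, elim_alpha = 0)
  m3 <- match(fis3$term, eli3$term)
  expect_equal(fis3$p, eli3$p[m3], tolerance = 1e-12)

  # hand-built parent/child: the child soaks up the signal
  edges <- data.frame(child = c("C", "P"), parent = c("P", "R"))
  ann <- data.frame(gene = c(sprintf("g%03d", 1:10), sprintf("g%03d", 11:15),
                             sprintf("g%03d", 16:80)),
                    term = c(rep("C", 10), rep("P", 5), rep("R", 65)))
  dag <- go_dag(edges, ann)
  study_h <- sprintf("g%03d", 1:8)          # all signal inside C
  fis_h <- fisher_enrichment(study_h, dag$genes, dag$annotations)
  eli_h <- elim_enrichment(dag, study_h, elim_alpha = 0.05)
  expect_gt(eli_h$p[eli_h$term == "P"], fis_h$p[fis_h$term == "P"])
  expect_equal(eli_h$p[eli_h$term == "C"], fis_h$p[fis_h$term == "C"],
               tolerance = 1e-12)
})

test_that("Wang similarity matches hand-evaluated S-values and is bounded", {
  edges <- data.frame(child = c("P", "A", "B", "C", "D"),
                      parent = c("R", "P", "P", "R", "A"))
  ann <- data.frame(gene = paste0("g", 1:5), term = c("A", "B", "C", "D", "P"))
  dag <- go_dag(edges, ann)

  expect_equal(go_semantic_similarity(dag, "A", "A"), 1)
  # A and B share P (0.8 each) and R (0.64 each):
  # sim = (0.8+0.8+0.64+0.64) / (2.44 + 2.44)
  expect_equal(wang_term_sim(dag, "A", "B"), 2.88 / 4.88, tolerance = 1e-12)
  # A and C share only R: (0.64 + 0.8) / (2.44 + 1.8)
  expect_equal(wang_term_sim(dag, "A", "C"), 1.44 / 4.24, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:20) {
    ta <- sample(dag$terms, 2); tb <- sample(dag$terms, 3)
    s <- go_semantic_similarity(dag, ta, tb)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, go_semantic_similarity(dag, tb, ta), tolerance = 1e-12)
  }
  expect_error(go_semantic_similarity(dag, "A", "ghost"), "unknown term")
})

test_that("permutation p-values are seeded, monotone, and zero at the maximum", {
  genes <- sprintf("g%03d", 1:100)
  goo <- simulate_go(genes, seed = 33)
  r1 <- permutation_pvalue(goo$dag, 0.5, 4, 4, n_perm = 100, seed = 7)
  r2 <- permutation_pvalue(goo$dag, 0.5, 4, 4, n_perm = 100, seed = 7)
  expect_identical(r1$perm_scores, r2$perm_scores)

  # monotone non-increasing in the observed score (same permutations)
  ps <- vapply(c(0.2, 0.5, 0.8, 1), function(o)
    permutation_pvalue(goo$dag, o, 4, 4, n_perm = 100, seed = 7)$p_value,
    numeric(1))
  expect_true(all(diff(ps) <= 0))
  # nothing exceeds the maximal score
  expect_equal(ps[4], 0)
  # add-one variant never returns zero
  expect_gt(permutation_pvalue(goo$dag, 1, 4, 4, n_perm = 100, seed = 7,
                               add_one = TRUE)$p_value, 0)
  expect_error(permutation_pvalue(goo$dag, 0.5, 4, 4, n_perm = 0, seed = 1),
               "n_perm")
})

test_that("stress-class crosstab equals brute-force enumeration and validates classes", {
  set.seed(37)
  graph <- data.frame(
    mirna = sample(sprintf("m%d", 1:6), 60, TRUE),
    gene = sample(sprintf("g%03d", 1:40), 60, TRUE), stringsAsFactors = FALSE)
  graph <- graph[!duplicated(graph), ]
  groups <- list(early = c("m1", "m2"), late = c("m3", "m4"), other = "m5")
  classes <- stats::setNames(sample(c("early-up", "early-down", "late-up"),
                                    40, TRUE), sprintf("g%03d", 1:40))
  xt <- crosstab_targets_by_class(groups, graph, classes)
  for (g in names(groups)) for (cl in colnames(xt)) {
    hit <- unique(graph$gene[graph$mirna %in% groups[[g]]])
    expect_equal(xt[g, cl],
                 sum(classes[intersect(hit, names(classes))] == cl))
  }
  # empty group: zero row
  xt2 <- crosstab_targets_by_class(c(groups, list(empty = character())),
                                   graph, classes)
  expect_true(all(xt2["empty", ] == 0))
  # duplicated gene label violates the partition requirement
  expect_error(crosstab_targets_by_class(groups, graph,
    stats::setNames(c("early-up", "late-up"), c("g001", "g001"))),
    "partition")
})
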