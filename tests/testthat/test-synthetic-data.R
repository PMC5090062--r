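test_that("annotation generator respects the requested structure and round-trips through GFF3", {
  p <- sim_params(n_mirnas = 4, n_clusters = 1, cluster_size_range = c(2, 2),
                  seed = 11)
  ann <- generate_annotation(p)
  expect_equal(nrow(ann$hairpins), 4)
  expect_equal(nrow(ann$matures), 8)
  expect_equal(sum(!is.na(ann$hairpins$cluster_id)), 2)
  expect_equal(length(unique(na.omit(ann$hairpins$cluster_id))), 1)

  idx <- match(ann$matures$hairpin_id, ann$hairpins$id)
  expect_true(all(ann$matures$start >= ann$hairpins$start[idx]))
  expect_true(all(ann$matures$end <= ann$hairpins$end[idx]))
  expect_true(all(ann$matures$strand == ann$hairpins$strand[idx]))

  gff <- tempfile(fileext = ".gff3")
  write_mirna_gff3(ann, gff)
  back <- read_mirna_gff3(gff)
  for (col in c("id", "start", "end", "strand"))
    expect_equal(back$hairpins[[col]][order(back$hairpins$id)],
                 ann$hairpins[[col]][order(ann$hairpins$id)])
  om <- order(back$matures$id); om0 <- order(ann$matures$id)
  for (col in c("start", "end", "strand", "hairpin_id"))
    expect_equal(back$matures[[col]][om], ann$matures[[col]][om0])

  # clusters must fit
  expect_error(sim_params(n_mirnas = 3, n_clusters = 2,
                          cluster_size_range = c(2, 2), seed = 1),
               "fit")
  expect_error(generate_annotation(p, chrom_length = 100), "infeasible")
})

test_that("count simulation is deterministic and follows the configured mean structure", {
  p <- sim_params(n_mirnas = 40, depth = 2e5, seed = 5)
  ann <- generate_annotation(p)
  s1 <- simulate_counts(ann, p)
  s2 <- simulate_counts(ann, p)
  expect_identical(s1$counts$counts, s2$counts$counts)

  # zero-effect case: class1 ids exist but interstrain control log2FC is 0
  p0 <- sim_params(n_mirnas = 40, depth = 2e5, level_effect_log2 = 0,
                   seed = 5)
  s0 <- simulate_counts(generate_annotation(p0), p0)
  expect_gt(length(s0$truth$class1_ids), 0)
  mu <- s0$truth$mean_counts[s0$truth$class1_ids, , 1]   # control means
  lfc <- apply(log2(mu), 1, function(v) max(v) - min(v))
  expect_equal(max(lfc), 0, tolerance = 1e-12)

  # class1/class2 disjoint and resolvable against the annotation
  expect_length(intersect(s1$truth$class1_ids, s1$truth$class2_ids), 0)
  expect_true(all(c(s1$truth$class1_ids, s1$truth$class2_ids,
                    names(s1$truth$cluster_membership)) %in%
                    ann$matures$id))

  # truth effect directions match the realised mean structure
  off <- s1$truth$class1_offsets
  mu1 <- s1$truth$mean_counts[rownames(off), , 1]
  for (m in rownames(off)) {
    expect_equal(order(off[m, ]), order(mu1[m, ]))
  }
})

test_that("simulated counts have NB moments and near-conserved library sizes", {
  # moment oracle: standardised residuals (x - mu) / sqrt(mu + phi mu^2)
  # must have unit variance; >= 10,000 draws
  p <- sim_params(n_mirnas = 250, depth = 2e6, dispersion = 0.1,
                  frac_class1 = 0, frac_class2 = 0, n_clusters = 0,
                  seed = 21)
  sim <- simulate_counts(generate_annotation(p), p)
  cm <- sim$counts; tr <- sim$truth
  z <- cm$counts
  for (j in seq_len(ncol(z))) {
    mu <- tr$mean_counts[, match(cm$design$strain[j], tr$strains),
                         match(cm$design$timepoint_h[j], tr$timepoints_h)] *
      tr$size_factors[cm$design$sample[j]]
    z[, j] <- (cm$counts[, j] - mu) / sqrt(mu + 0.1 * mu^2)
  }
  expect_gt(length(z), 10000)
  expect_equal(var(as.vector(z)), 1, tolerance = 0.05)

  # column sums concentrate on depth x size factor
  expected <- 2e6 * tr$size_factors
  sdv <- sqrt(colSums(tr$mean_counts[, 1, 1] %o% tr$size_factors +
                        0.1 * (tr$mean_counts[, 1, 1] %o% tr$size_factors)^2))
  expect_true(all(abs(colSums(cm$counts) - expected) < 4 * sdv))

  expect_error(sim_params(n_mirnas = 10, depth = 0, seed = 1), "depth")
  expect_error(sim_params(n_mirnas = 10, dispersion = -1, seed = 1),
               "dispersion")
})

test_that("simulated reads are placed within their mature, stranded, and edited at the binomial rate", {
  ann <- tiny_annotation()
  design <- tiny_design()[1, , drop = FALSE]
  counts <- matrix(50L, 4, 1, dimnames = list(ann$matures$id, design$sample))
  cm <- count_matrix(counts, design)
  p <- sim_params(n_mirnas = 2, n_clusters = 0, seq_error_rate = 0, seed = 3)

  aln <- simulate_alignments(ann, cm, p, jitter = 0)
  expect_equal(nrow(aln), 200)
  one <- aln[aln$mature_id == "hp1-5p", ]
  expect_equal(nrow(one), 50)
  expect_true(all(one$start == 1005 & one$end == 1026))
  # strand always matches the feature
  idx <- match(aln$mature_id, ann$matures$id)
  expect_true(all(aln$strand == ann$matures$strand[idx]))
  # minus-strand read sequence is the mature-sense (reverse complement)
  minus <- aln[aln$mature_id == "hp2-5p", ][1, ]
  ref <- substr(as.character(ann$genome[["chrT"]]), minus$start, minus$end)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(ref, "")[[1]]),
                                     collapse = ""))
  expect_equal(minus$seq, rc)

  # binomial editing oracle: freq 0.3, 100 reads, mean over 200 seeds
  ann_e <- tiny_annotation()
  site <- data.frame(mature_id = "hp1-5p", position = 12L, type = "A>G",
                     frequency = 0.3, stringsAsFactors = FALSE)
  # force the reference base so the injected substitution is well defined
  g <- as.character(ann_e$genome[["chrT"]])
  substr(g, 1005 + 12 - 1, 1005 + 12 - 1) <- "A"
  ann_e$genome <- Biostrings::DNAStringSet(g); names(ann_e$genome) <- "chrT"
  counts100 <- matrix(c(100L, 0L, 0L, 0L), 4, 1,
                      dimnames = list(ann_e$matures$id, design$sample))
  cm100 <- count_matrix(counts100, design)
  edited <- vapply(1:200, function(s) {
    ps <- sim_params(n_mirnas = 2, n_clusters = 0, seq_error_rate = 0, editing_sites = site,
                     seed = s)
    a <- simulate_alignments(ann_e, cm100, ps, jitter = 0)
    sum(substr(a$seq, 12, 12) == "G")
  }, numeric(1))
  expect_equal(mean(edited), 30, tolerance = 1 / 30)

  bad <- data.frame(mature_id = "hp1-5p", position = 40L, type = "A>G",
                    frequency = 0.3)
  pb <- sim_params(n_mirnas = 2, n_clusters = 0, editing_sites = bad, seed = 1)
  expect_error(simulate_alignments(ann_e, cm100, pb), "outside mature")
})

test_that("target prediction noise matches its Bernoulli rates", {
  mirnas <- sprintf("mir%02d", 1:10)
  genes <- sprintf("g%03d", 1:50)
  true <- simulate_true_targets(mirnas, genes, c(5, 10), seed = 2)

  perfect <- simulate_target_predictions(true, mirnas, genes, 3, 1, 0,
                                         seed = 4)
  for (a in perfect) {
    expect_setequal(paste(a$mirna, a$gene), paste(true$mirna, true$gene))
  }
  none <- simulate_target_predictions(true, mirnas, genes, 3, 0, 0, seed = 4)
  expect_true(all(vapply(none, nrow, 1L) == 0))

  recalls <- vapply(1:500, function(s) {
    pr <- simulate_target_predictions(true, mirnas, genes, 2, 0.7, 0,
                                      seed = s)[[1]]
    mean(paste(true$mirna, true$gene) %in% paste(pr$mirna, pr$gene))
  }, numeric(1))
  expect_equal(mean(recalls), 0.7, tolerance = 0.03 / 0.7)
})

test_that("toy ontology obeys the true-path rule; class sizes follow largest-remainder", {
  genes <- sprintf("g%03d", 1:60)
  goo <- simulate_go(genes, levels = 1, terms_per_level = 6, seed = 8)
  dag <- goo$dag
  root_ann <- dag$annotations[["GO:ROOT"]]
  for (t in setdiff(dag$terms, "GO:ROOT"))
    expect_true(all(dag$annotations[[t]] %in% root_ann))
  # no term is its own ancestor
  expect_true(all(vapply(dag$terms, function(t)
    !(t %in% dag$ancestors[[t]]), logical(1))))
  expect_error(
    go_dag(data.frame(child = c("a", "b"), parent = c("b", "a")),
           data.frame(gene = "g1", term = "a")),
    "acyclic")

  sizes <- largest_remainder(299, c(1, 1, 1) / 3)
  expect_equal(sizes, c(100L, 100L, 99L))
  cls <- simulate_stress_classes(sprintf("g%03d", 1:299), seed = 3)
  expect_equal(sort(as.integer(table(cls))), c(99L, 100L, 100L))
  expect_setequal(unique(cls), c("early-up", "early-down", "late-up"))
})
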