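test_that("coordinate conventions are converted exactly once at the file boundary", {
  rec <- data.frame(chrom = "chrT", start = 101L, end = 122L, name = "r1",
                    score = 0L, strand = "+", stringsAsFactors = FALSE)
  bed <- tempfile(fileext = ".bed")
  write_bed6(rec, bed)
  raw <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(raw[2:3]), c(100L, 122L))   # 0-based half-open
  back <- read_bed6(bed, sample = "s")
  expect_equal(back$start, 101L)
  expect_equal(back$end, 122L)

  # GFF3 keeps 1-based inclusive coordinates verbatim
  ann <- tiny_annotation()
  gff <- tempfile(fileext = ".gff3")
  write_mirna_gff3(ann, gff)
  lines <- readLines(gff)
  hp1 <- strsplit(grep("ID=hp1;", lines, value = TRUE, fixed = TRUE),
                  "\t")[[1]]
  expect_equal(as.integer(hp1[4:5]), c(1001L, 1090L))

  # dangling Derives_from names the offending mature
  bad <- c("##gff-version 3",
           "chrT\t.\tmiRNA_primary_transcript\t10\t99\t.\t+\t.\tID=hpX",
           "chrT\t.\tmiRNA\t12\t33\t.\t+\t.\tID=mirX-5p;Derives_from=ghost")
  f <- tempfile(fileext = ".gff3")
  writeLines(bad, f)
  expect_error(read_mirna_gff3(f), "mirX-5p")

  expect_error(read_bed6({
    f2 <- tempfile(fileext = ".bed")
    writeLines("chrT\t0\t22\tr\t0\t?", f2); f2
  }), "strand")
})

test_that("reads are assigned to the unique best-overlapping mature", {
  hairpins <- data.frame(id = "hp", chrom = "c", start = 1L, end = 200L,
                         strand = "+", cluster_id = NA, stringsAsFactors = FALSE)
  matures <- data.frame(id = c("mA", "mB"), arm = c("5p", "3p"), chrom = "c",
                        start = c(10L, 36L), end = c(31L, 61L), strand = "+",
                        hairpin_id = "hp", stringsAsFactors = FALSE)
  ann <- mirna_annotation(hairpins, matures)
  design <- data.frame(sample = "s1", strain = "x", timepoint_h = 0,
                       replicate = 1)
  reads <- data.frame(
    chrom = "c", start = c(12L, 20L, 24L), end = c(30L, 43L, 43L),
    name = c("inside", "best12v8", "tie8v8"), score = 0L, strand = "+",
    seq = NA, sample = "s1", stringsAsFactors = FALSE)
  # inside (12-30): fully within mA
  # best12v8 (20-43): overlaps mA by 12 nt, mB by 8 nt -> the 12-nt one
  # tie8v8 (24-43): overlaps both by 8 nt -> leftmost feature start (mA)
  cm <- count_overlaps(reads, ann, design, min_overlap_frac = 0.3)
  expect_equal(unname(cm$counts[, "s1"]), c(3L, 0L))
  expect_equal(attr(cm, "report")$n_assigned, 3L)

  # opposite-strand read never counts
  reads$strand <- "-"
  cm2 <- count_overlaps(reads, ann, design, min_overlap_frac = 0.3)
  expect_equal(sum(cm2$counts), 0L)
  expect_equal(attr(cm2, "report")$n_unassigned, 3L)

  expect_error(count_overlaps(reads, mirna_annotation(
    hairpins, matures[0, , drop = FALSE]), design), "empty annotation")
})

test_that("counting equals brute force, is read-order invariant, and conserves reads", {
  p <- sim_params(n_mirnas = 50, depth = 1e5, seed = 13)
  ann <- generate_annotation(p)
  sim <- simulate_counts(ann, p)
  smp <- colnames(sim$counts$counts)[1]
  aln <- simulate_alignments(ann, sim$counts, p, samples = smp,
                             max_reads_per_sample = 800)
  # add off-feature and off-chromosome noise reads
  noise <- data.frame(chrom = c(rep("chrS", 20), rep("chrZ", 5)),
                      start = c(seq(1, 400, 20), seq(1, 100, 20)),
                      end = c(seq(1, 400, 20), seq(1, 100, 20)) + 21L,
                      name = "noise", score = 0L,
                      strand = rep(c("+", "-"), length.out = 25),
                      seq = NA_character_, mature_id = NA, sample = smp)
  aln <- rbind(aln, noise)

  cm <- count_overlaps(aln, ann, sim$counts$design)

  # brute force O(reads x features)
  mat <- ann$matures
  bf <- stats::setNames(rep(0L, nrow(mat)), mat$id)
  unassigned <- 0L
  for (i in seq_len(nrow(aln))) {
    rl <- aln$end[i] - aln$start[i] + 1L
    if (rl < 18 || rl > 26) { unassigned <- unassigned + 1L; next }
    best <- NULL; bestov <- -1
    for (j in seq_len(nrow(mat))) {
      if (mat$chrom[j] != aln$chrom[i] || mat$strand[j] != aln$strand[i])
        next
      ov <- min(aln$end[i], mat$end[j]) - max(aln$start[i], mat$start[j]) + 1L
      if (ov < 0.5 * rl) next
      better <- ov > bestov ||
        (ov == bestov && (mat$start[j] < mat$start[best] ||
          (mat$start[j] == mat$start[best] && mat$id[j] < mat$id[best])))
      if (better) { best <- j; bestov <- ov }
    }
    if (is.null(best)) unassigned <- unassigned + 1L
    else bf[mat$id[best]] <- bf[mat$id[best]] + 1L
  }
  expect_equal(unname(cm$counts[names(bf), smp]), unname(bf))
  expect_equal(attr(cm, "report")$n_unassigned, unassigned)
  expect_equal(attr(cm, "report")$n_assigned + attr(cm, "report")$n_unassigned,
               nrow(aln))

  # permutation invariance
  set.seed(1)
  cm_p <- count_overlaps(aln[sample(nrow(aln)), ], ann, sim$counts$design)
  expect_identical(cm$counts, cm_p$counts)
})

test_that("low-count filter keeps condition means at or above the threshold", {
  design <- tiny_design()
  cond_means <- cbind("s1@0" = c(49.5, 50, 200, 10),
                      "s1@1" = c(49.5, 10, 200, 10),
                      "s2@0" = c(49.5, 10, 200, 10),
                      "s2@1" = c(49.5, 10, 200, 10))
  rownames(cond_means) <- paste0("m", 1:4)
  counts <- matrix(0, 4, nrow(design),
                   dimnames = list(rownames(cond_means), design$sample))
  for (j in seq_len(nrow(design))) {
    key <- sprintf("%s@%g", design$strain[j], design$timepoint_h[j])
    counts[, j] <- cond_means[, key] + c(0.5, 0, 0, 0) * (-1)^design$replicate[j]
  }
  cm <- count_matrix(counts, design)
  kept <- filter_low_counts(cm, 50)
  # m1: replicate mean exactly 49.5 -> removed; m2: mean exactly 50 in one
  # condition -> retained; m3 retained; m4 removed
  expect_setequal(rownames(kept$counts), c("m2", "m3"))
  log <- attr(kept, "filter_log")
  expect_equal(log$kept, c(FALSE, TRUE, TRUE, FALSE))

  expect_identical(rownames(filter_low_counts(cm, 0)$counts),
                   rownames(cm$counts))

  # contrast scope looks only at the two contrast conditions
  kept_c <- filter_low_counts(cm, 50, "contrast",
    list(list(strain = "s1", timepoint_h = 1),
         list(strain = "s2", timepoint_h = 1)))
  expect_setequal(rownames(kept_c$counts), "m3")
})
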