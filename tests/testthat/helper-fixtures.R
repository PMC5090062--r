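# shared fixtures, all built in code

# a small annotation with two hairpins on both strands, built by hand so
# coordinates are known exactly
tiny_annotation <- function() {
  hairpins <- data.frame(
    id = c("hp1", "hp2"), chrom = "chrT",
    start = c(1001L, 2001L), end = c(1090L, 2090L),
    strand = c("+", "-"), cluster_id = NA_character_,
    stringsAsFactors = FALSE)
  matures <- data.frame(
    id = c("hp1-5p", "hp1-3p", "hp2-5p", "hp2-3p"),
    arm = c("5p", "3p", "5p", "3p"), chrom = "chrT",
    start = c(1005L, 1065L, 2065L, 2005L),
    end = c(1026L, 1086L, 2086L, 2026L),
    strand = c("+", "+", "-", "-"),
    hairpin_id = c("hp1", "hp1", "hp2", "hp2"), stringsAsFactors = FALSE)
  set.seed(99)
  genome <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = ""))
  names(genome) <- "chrT"
  mirna_annotation(hairpins, matures, genome)
}

# minimal design for two strains / two timepoints / two replicates
tiny_design <- function(strains = c("s1", "s2"), tps = c(0, 1), reps = 2) {
  d <- expand.grid(replicate = seq_len(reps), timepoint_h = tps,
                   strain = strains, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$sample <- sprintf("%s_t%g_r%d", d$strain, d$timepoint_h, d$replicate)
  d[, c("sample", "strain", "timepoint_h", "replicate")]
}

# count matrix with given per-condition means (features x conditions), NB
# noise optional
make_counts <- function(cond_means, design, phi = 0, seed = 1) {
  set.seed(seed)
  n <- nrow(cond_means)
  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(rownames(cond_means), design$sample))
  for (j in seq_len(nrow(design))) {
    key <- sprintf("%s@%g", design$strain[j], design$timepoint_h[j])
    mu <- cond_means[, key]
    counts[, j] <- if (phi > 0) rnbinom(n, mu = mu, size = 1 / phi)
      else rpois(n, mu)
  }
  count_matrix(counts, design)
}

# a profile_matrix built directly from a replicate-value matrix (columns
# must match the design's samples)
make_profile_matrix <- function(rep_values, design, strains, tps) {
  structure(list(
    values = NULL, rep_values = rep_values, strains = strains,
    timepoints_h = tps, design = design,
    degenerate = stats::setNames(rep(FALSE, nrow(rep_values)),
                                 rownames(rep_values)),
    pseudocount = 1), class = "profile_matrix")
}

# adjusted Rand index (independent of any clustering package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- ai * bj / n2
  (nij - exp_idx) / ((ai + bj) / 2 - exp_idx)
}
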