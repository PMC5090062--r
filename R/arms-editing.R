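#' Log2 arm ratio of a hairpin
#'
#' log2 of (mean 5p + prior) over (mean 3p + prior). The sign names the
#' dominant arm (positive: 5p dominates); it is antisymmetric in the two
#' arms.
#'
#' @param counts5p,counts3p replicate counts (or normalised counts) of
#'   the two arms in one condition.
#' @param prior pseudo-count (default 0.5).
#' @return log2 ratio.
#' @export
arm_ratio <- function(counts5p, counts3p, prior = 0.5) {
  if (any(counts5p < 0) || any(counts3p < 0)) stopf("counts must be >= 0")
  log2((mean(counts5p) + prior) / (mean(counts3p) + prior))
}

#' Per-condition arm ratio table for every hairpin
#'
#' Means are computed on size-factor-normalised counts (library size over
#' its mean), so jointly rescaling all libraries leaves the table
#' unchanged.
#'
#' @param x `count_matrix`.
#' @param annotation `mirna_annotation`.
#' @param prior pseudo-count for the ratio.
#' @return data.frame: `hairpin`, `strain`, `timepoint_h`, `mean_5p`,
#'   `mean_3p`, `log2_ratio`.
#' @export
arm_ratio_table <- function(x, annotation, prior = 0.5) {
  stopifnot(inherits(x, "count_matrix"), inherits(annotation, "mirna_annotation"))
  mat <- annotation$matures
  sf <- x$library_sizes / mean(x$library_sizes)
  norm <- sweep(x$counts, 2, sf, "/")
  d <- x$design
  conds <- unique(d[, c("strain", "timepoint_h")])
  rows <- list()
  for (h in unique(mat$hairpin_id)) {
    id5 <- mat$id[mat$hairpin_id == h & mat$arm == "5p"]
    id3 <- mat$id[mat$hairpin_id == h & mat$arm == "3p"]
    if (!length(id5) || !length(id3)) next
    if (!(id5 %in% rownames(norm)) || !(id3 %in% rownames(norm))) next
    for (i in seq_len(nrow(conds))) {
      smp <- condition_samples(d, conds$strain[i], conds$timepoint_h[i])
      m5 <- mean(norm[id5, smp]); m3 <- mean(norm[id3, smp])
      rows[[length(rows) + 1]] <- data.frame(
        hairpin = h, strain = conds$strain[i],
        timepoint_h = conds$timepoint_h[i], mean_5p = m5, mean_3p = m3,
        log2_ratio = log2((m5 + prior) / (m3 + prior)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Detect arm-switching events
#'
#' Within each strain, compares the arm ratio at every post-shock
#' timepoint against the control. An event is emitted when the absolute
#' change in log2 arm ratio reaches `delta_min` (inclusive) AND either
#' arm dominance flips sign or the minor arm's mean count rises across
#' `count_floor`. Hairpin/condition pairs where no condition has both
#' arms at or above the floor are not considered.
#'
#' @param ratios data.frame from [arm_ratio_table()].
#' @param delta_min minimal |delta log2 ratio| (default 1).
#' @param count_floor minimal mean count for an expressed arm
#'   (default 50).
#' @return data.frame of events: `hairpin`, `strain`, `timepoint_h`,
#'   `ratio_control`, `ratio`, `delta_log2`, `dominance_flip`,
#'   `minor_arm_rises`, plus the per-arm means in both conditions.
#' @export
detect_arm_switch <- function(ratios, delta_min = 1, count_floor = 50) {
  need <- c("hairpin", "strain", "timepoint_h", "mean_5p", "mean_3p",
            "log2_ratio")
  stopifnot(all(need %in% names(ratios)))
  if (length(unique(ratios$timepoint_h)) < 2)
    stopf("need >= 2 conditions to detect switching")
  rows <- list()
  for (h in unique(ratios$hairpin)) for (s in unique(ratios$strain)) {
    rc <- ratios[ratios$hairpin == h & ratios$strain == s &
                   ratios$timepoint_h == 0, ]
    if (nrow(rc) != 1) next
    post <- ratios[ratios$hairpin == h & ratios$strain == s &
                     ratios$timepoint_h > 0, ]
    for (i in seq_len(nrow(post))) {
      rt <- post[i, ]
      both_pass <- (rc$mean_5p >= count_floor && rc$mean_3p >= count_floor) ||
        (rt$mean_5p >= count_floor && rt$mean_3p >= count_floor)
      if (!both_pass) next
      delta <- rt$log2_ratio - rc$log2_ratio
      if (abs(delta) < delta_min) next
      flip <- sign(rc$log2_ratio) * sign(rt$log2_ratio) < 0
      minor_c <- if (rc$mean_5p <= rc$mean_3p) "5p" else "3p"
      minor_before <- rc[[paste0("mean_", minor_c)]]
      minor_after <- rt[[paste0("mean_", minor_c)]]
      rises <- minor_before < count_floor && minor_after >= count_floor
      if (!flip && !rises) next
      rows[[length(rows) + 1]] <- data.frame(
        hairpin = h, strain = s, timepoint_h = rt$timepoint_h,
        ratio_control = rc$log2_ratio, ratio = rt$log2_ratio,
        delta_log2 = delta, dominance_flip = flip, minor_arm_rises = rises,
        mean_5p_control = rc$mean_5p, mean_3p_control = rc$mean_3p,
        mean_5p = rt$mean_5p, mean_3p = rt$mean_3p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(hairpin = character(), strain = character(),
                      timepoint_h = numeric(), ratio_control = numeric(),
                      ratio = numeric(), delta_log2 = numeric(),
                      dominance_flip = logical(), minor_arm_rises = logical(),
                      mean_5p_control = numeric(), mean_3p_control = numeric(),
                      mean_5p = numeric(), mean_3p = numeric()))
  do.call(rbind, rows)
}

#' Call A-to-G / T-to-C editing sites from aligned reads
#'
#' Builds a strand-resolved pileup over every mature interval: read bases
#' are expressed on the mature sense strand (reads of minus-strand
#' matures are reverse-complemented by construction of the input), and
#' each covered mature position accumulates coverage and mismatch counts
#' against the mature-sense reference. A site is called when coverage
#' reaches `min_cov`, the mismatch frequency reaches `min_freq`, and the
#' substitution (on the mature sense) is A->G or T->C. Positions 2-8
#' are flagged as seed-region. A binomial tail p-value against the
#' background error rate is attached as metadata only — presence/absence
#' is decided by the frequency rule.
#'
#' @param alignments data.frame with `chrom`, `start`, `end`, `strand`,
#'   `seq` (read bases in read orientation), e.g. from [read_bed6()] or
#'   [simulate_alignments()]; subset it per condition to obtain
#'   per-condition calls.
#' @param annotation `mirna_annotation` with genome sequence.
#' @param min_cov minimal coverage (default 10).
#' @param min_freq minimal mismatch frequency (default 0.1).
#' @param err_rate assumed background per-base error rate for the
#'   metadata p-value.
#' @param min_overlap_frac read-to-mature assignment threshold.
#' @return data.frame: `mature_id`, `position`, `type`, `ref`, `alt`,
#'   `coverage`, `mismatches`, `frequency`, `in_seed`, `p_error`.
#' @export
call_editing <- function(alignments, annotation, min_cov = 10,
                         min_freq = 0.1, err_rate = 0.001,
                         min_overlap_frac = 0.5) {
  stopifnot(inherits(annotation, "mirna_annotation"))
  if (is.null(annotation$genome)) stopf("annotation carries no reference genome")
  mat <- annotation$matures
  chrseq <- as.character(annotation$genome)
  rows <- list()
  for (mi in seq_len(nrow(mat))) {
    m <- mat[mi, ]
    L <- m$end - m$start + 1L
    if (!m$chrom %in% names(chrseq)) stopf("chromosome %s missing from genome",
                                           m$chrom)
    ref <- substr(chrseq[[m$chrom]], m$start, m$end)
    if (nchar(ref) != L) stopf("reference/pileup length mismatch for %s", m$id)
    if (m$strand == "-")
      ref <- chartr("ACGT", "TGCA",
                    paste(rev(strsplit(ref, "")[[1]]), collapse = ""))
    refv <- strsplit(ref, "")[[1]]

    al <- alignments[alignments$chrom == m$chrom &
                       alignments$strand == m$strand &
                       alignments$start <= m$end &
                       alignments$end >= m$start, , drop = FALSE]
    if (!nrow(al)) next
    rl <- al$end - al$start + 1L
    ov <- pmin(al$end, m$end) - pmax(al$start, m$start) + 1L
    al <- al[ov >= min_overlap_frac * rl, , drop = FALSE]
    if (!nrow(al)) next
    # vectorised pileup: coverage by difference array; only reads whose
    # bases differ from the mature-sense reference are walked base by base
    p0 <- if (m$strand == "+") al$start - m$start else m$end - al$end
    plen <- nchar(al$seq)
    ps <- pmax(p0 + 1L, 1L); pe <- pmin(p0 + plen, L)
    ok <- ps <= pe
    covd <- integer(L + 1L)
    for (i in which(ok)) {
      covd[ps[i]] <- covd[ps[i]] + 1L
      covd[pe[i] + 1L] <- covd[pe[i] + 1L] - 1L
    }
    cov <- cumsum(covd[seq_len(L)])
    expected <- substring(ref, p0 + 1L, p0 + plen)
    mm <- matrix(0L, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    for (i in which(al$seq != expected & ok)) {
      bases <- strsplit(al$seq[i], "")[[1]]
      refs <- strsplit(expected[i], "")[[1]]
      nb <- min(length(bases), length(refs))
      for (j in which(bases[seq_len(nb)] != refs[seq_len(nb)])) {
        p <- p0[i] + j
        if (p >= 1 && p <= L && bases[j] %in% colnames(mm))
          mm[p, bases[j]] <- mm[p, bases[j]] + 1L
      }
    }
    for (p in which(cov >= min_cov)) {
      alt <- if (refv[p] == "A") "G" else if (refv[p] == "T") "C" else next
      n_alt <- mm[p, alt]
      freq <- n_alt / cov[p]
      if (freq < min_freq) next
      rows[[length(rows) + 1]] <- data.frame(
        mature_id = m$id, position = p,
        type = paste0(refv[p], ">", alt), ref = refv[p], alt = alt,
        coverage = cov[p], mismatches = n_alt, frequency = freq,
        in_seed = p >= 2 && p <= 8,
        p_error = stats::pbinom(n_alt - 1, cov[p], err_rate,
                                lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mature_id = character(), position = integer(),
                      type = character(), ref = character(),
                      alt = character(), coverage = integer(),
                      mismatches = integer(), frequency = numeric(),
                      in_seed = logical(), p_error = numeric()))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
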