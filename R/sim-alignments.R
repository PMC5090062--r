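#' Simulate aligned small-RNA reads as BED-style records
#'
#' For each mature miRNA and each requested sample, emits one alignment
#' record per counted read. Reads are 19-23 nt, lie within the mature
#' interval (inward 5'/3' jitter of at most `jitter` nt), and match the
#' feature strand. Requested editing sites inject the configured
#' substitution (read on the mature sense strand) into each read covering
#' the site with the configured per-read frequency; independent background
#' mismatches occur at `seq_error_rate` per base. Read sequences are
#' carried in the BED name field as `readid|SEQ` so a BED6 file remains a
#' complete input for the editing caller.
#'
#' @param annotation `mirna_annotation` with genome.
#' @param counts a [count_matrix()] for this annotation.
#' @param params [sim_params()] (supplies editing sites, error rate, seed).
#' @param samples sample ids to simulate; default all columns.
#' @param max_reads_per_sample if a sample's total count exceeds this,
#'   reads are binomially thinned to approximately this depth (counts are
#'   kept intact; only the emitted alignments shrink).
#' @param jitter maximal inward trim at each read end (0 = every read
#'   spans its mature exactly).
#' @return data.frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `name`, `score`, `strand`, `seq`, `mature_id`, `sample`.
#' @export
simulate_alignments <- function(annotation, counts, params, samples = NULL,
                                max_reads_per_sample = 5e4, jitter = 1) {
  stopifnot(inherits(annotation, "mirna_annotation"),
            inherits(counts, "count_matrix"))
  set.seed(derive_seed(params$seed, "alignments"))
  samples <- samples %||% colnames(counts$counts)
  mat <- annotation$matures
  chrs <- as.character(annotation$genome)

  es <- params$editing_sites
  if (!is.null(es) && nrow(es)) {
    mlen <- mat$end[match(es$mature_id, mat$id)] -
      mat$start[match(es$mature_id, mat$id)] + 1L
    if (any(es$position < 1 | es$position > mlen))
      stopf("editing position outside mature length")
  }

  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    smp <- samples[si]
    k_all <- counts$counts[, smp]
    tot <- sum(k_all)
    if (tot > max_reads_per_sample) {
      k_all <- rbinom(length(k_all), k_all, max_reads_per_sample / tot)
      names(k_all) <- rownames(counts$counts)
    }
    recs <- vector("list", nrow(mat))
    for (mi in seq_len(nrow(mat))) {
      m <- mat[mi, ]
      k <- k_all[[m$id]] %||% 0L
      if (is.na(k) || k == 0) next
      L <- m$end - m$start + 1L
      a <- if (jitter > 0) sample(0:jitter, k, TRUE) else rep(0L, k)
      b <- if (jitter > 0) sample(0:jitter, k, TRUE) else rep(0L, k)
      # genome coordinates of the trimmed read
      if (m$strand == "+") {
        gs <- m$start + a; ge <- m$end - b
      } else {
        gs <- m$start + b; ge <- m$end - a
      }
      # mature-sense reference of the full mature
      if (!m$chrom %in% names(chrs))
        stopf("chromosome %s missing from genome", m$chrom)
      ref <- substr(chrs[[m$chrom]], m$start, m$end)
      if (m$strand == "-")
        ref <- chartr("ACGT", "TGCA", paste(rev(strsplit(ref, "")[[1]]),
                                            collapse = ""))
      seqs <- substring(ref, 1L + a, L - b)

      site <- if (!is.null(es)) es[es$mature_id == m$id, , drop = FALSE] else NULL
      if (!is.null(site) && nrow(site)) {
        for (r in seq_len(nrow(site))) {
          p <- site$position[r]
          covered <- p > a & p <= (L - b)
          hit <- covered & (runif(k) < site$frequency[r])
          to <- substr(site$type[r], 3, 3)
          for (i in which(hit))
            substr(seqs[i], p - a[i], p - a[i]) <- to
        }
      }
      if (params$seq_error_rate > 0) {
        lens <- ge - gs + 1L
        nerr <- rbinom(k, lens, params$seq_error_rate)
        for (i in which(nerr > 0)) {
          pos <- sample.int(lens[i], nerr[i])
          for (p in pos) {
            cur <- substr(seqs[i], p, p)
            substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                    cur), 1)
          }
        }
      }
      rid <- sprintf("%s_%s_r%d", m$id, smp, seq_len(k))
      recs[[mi]] <- data.frame(
        chrom = m$chrom, start = gs, end = ge,
        name = paste0(rid, "|", seqs), score = 0L, strand = m$strand,
        seq = seqs, mature_id = m$id, sample = smp,
        stringsAsFactors = FALSE
      )
    }
    out[[si]] <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), seq = character(),
                      mature_id = character(), sample = character())
  rownames(res) <- NULL
  res
}

#' Write alignment records as BED6
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention. The name column keeps the `readid|SEQ` payload.
#'
#' @param alignments data.frame from [simulate_alignments()] (or any frame
#'   with `chrom`, `start`, `end`, `name`, `score`, `strand`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed6 <- function(alignments, path) {
  bed <- data.frame(alignments$chrom, alignments$start - 1L, alignments$end,
                    alignments$name, alignments$score, alignments$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
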