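#' Read a miRBase-dialect GFF3 annotation
#'
#' Expects `miRNA_primary_transcript` features for hairpins and `miRNA`
#' features carrying a `Derives_from` attribute for matures. GFF
#' coordinates (1-based inclusive) are kept as the internal convention;
#' BED input is converted on read. The mature arm is taken from a
#' `-5p`/`-3p` id suffix when present, otherwise inferred from the
#' feature's position within its hairpin and the strand.
#'
#' @param path GFF3 file.
#' @return `mirna_annotation` (without genome; attach via
#'   [Biostrings::readDNAStringSet()] if needed).
#' @export
read_mirna_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  is_h <- type == "miRNA_primary_transcript"
  is_m <- type == "miRNA"
  if (!any(is_h)) stopf("no miRNA_primary_transcript features in %s", path)
  flat <- function(x) vapply(x, function(v)
    if (length(v)) as.character(v)[1] else NA_character_, character(1))
  get_attr <- function(sub, field) {
    v <- mc[[field]]
    if (is.null(v)) return(rep(NA_character_, sum(sub)))
    v <- v[sub]
    if (is.list(v) || methods::is(v, "List")) flat(v) else as.character(v)
  }
  hairpins <- data.frame(
    id = get_attr(is_h, "ID"),
    chrom = as.character(GenomicRanges::seqnames(gr))[is_h],
    start = GenomicRanges::start(gr)[is_h],
    end = GenomicRanges::end(gr)[is_h],
    strand = as.character(GenomicRanges::strand(gr))[is_h],
    cluster_id = get_attr(is_h, "cluster"), stringsAsFactors = FALSE
  )
  m_id <- get_attr(is_m, "ID")
  m_parent <- get_attr(is_m, "Derives_from")
  if (anyNA(m_parent))
    stopf("mature feature(s) lacking Derives_from: %s",
          paste(m_id[is.na(m_parent)], collapse = ", "))
  m_start <- GenomicRanges::start(gr)[is_m]
  m_end <- GenomicRanges::end(gr)[is_m]
  m_strand <- as.character(GenomicRanges::strand(gr))[is_m]
  arm <- ifelse(grepl("-5p$", m_id), "5p",
                ifelse(grepl("-3p$", m_id), "3p", NA_character_))
  if (anyNA(arm)) {                     # positional fallback
    hi <- match(m_parent, hairpins$id)
    mid_h <- (hairpins$start[hi] + hairpins$end[hi]) / 2
    left <- (m_start + m_end) / 2 < mid_h
    arm[is.na(arm)] <- ifelse((left == (m_strand == "+"))[is.na(arm)],
                              "5p", "3p")
  }
  matures <- data.frame(
    id = m_id, arm = arm, chrom = as.character(GenomicRanges::seqnames(gr))[is_m],
    start = m_start, end = m_end, strand = m_strand,
    hairpin_id = m_parent, stringsAsFactors = FALSE
  )
  mirna_annotation(hairpins, matures)
}

#' Read a BED6 alignment file
#'
#' BED's 0-based half-open coordinates become 1-based inclusive
#' internally. A `readid|SEQ` payload in the name column (the package's
#' dialect for carrying read bases) is split into `name` and `seq`.
#'
#' @param path BED6 file.
#' @param sample sample id to stamp on the records (default: file name
#'   without extension).
#' @return data.frame `chrom`, `start`, `end`, `name`, `score`, `strand`,
#'   `seq`, `sample`.
#' @export
read_bed6 <- function(path, sample = NULL) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stopf("%s is not BED6", path)
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(bed$strand %in% c("+", "-")))
    stopf("unknown strand in %s", path)
  bed$start <- bed$start + 1L
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  bed$seq <- vapply(parts, function(p)
    if (length(p) > 1) p[2] else NA_character_, character(1))
  bed$name <- vapply(parts, `[`, character(1), 1)
  bed$sample <- sample %||% sub("\\.bed$", "", basename(path))
  bed[, c("chrom", "start", "end", "name", "score", "strand", "seq", "sample")]
}

#' Count reads per mature miRNA by unique best overlap
#'
#' A read is assigned to a mature feature iff it lies on the same strand,
#' its length is within `length_range`, and the overlap covers at least
#' `min_overlap_frac` of the read length. A read qualifying for several
#' features goes to the one with maximal overlap, ties broken by leftmost
#' feature start then lexicographic id, so no read is ever counted twice.
#'
#' @param alignments data.frame as returned by [read_bed6()] /
#'   [simulate_alignments()]; the `sample` column defines the columns of
#'   the result.
#' @param annotation `mirna_annotation`.
#' @param design design data.frame covering every sample present.
#' @param min_overlap_frac minimal overlap as a fraction of read length
#'   (in (0, 1]).
#' @param length_range integer pair of acceptable read lengths.
#' @return a [count_matrix()]; the counting report (assigned/unassigned
#'   tallies) is attached as attribute `"report"`.
#' @export
count_overlaps <- function(alignments, annotation, design,
                           min_overlap_frac = 0.5,
                           length_range = c(18L, 26L)) {
  stopifnot(inherits(annotation, "mirna_annotation"))
  if (nrow(annotation$matures) == 0) stopf("empty annotation")
  if (min_overlap_frac <= 0 || min_overlap_frac > 1)
    stopf("min_overlap_frac must lie in (0, 1]")
  mat <- annotation$matures
  samples <- unique(alignments$sample %||% "sample1")
  if (is.null(alignments$sample)) alignments$sample <- "sample1"

  counts <- matrix(0L, nrow(mat), length(samples),
                   dimnames = list(mat$id, samples))
  report <- list(n_input = nrow(alignments), n_assigned = 0L,
                 n_unassigned = 0L, n_length_filtered = 0L)
  if (nrow(alignments)) {
    readlen <- alignments$end - alignments$start + 1L
    len_ok <- readlen >= length_range[1] & readlen <= length_range[2]
    report$n_length_filtered <- sum(!len_ok)
    al <- alignments[len_ok, , drop = FALSE]
    if (nrow(al)) {
      lv <- unique(c(al$chrom, mat$chrom))
      gr_r <- GenomicRanges::GRanges(
        factor(al$chrom, lv), IRanges::IRanges(al$start, al$end),
        strand = al$strand)
      gr_m <- GenomicRanges::GRanges(
        factor(mat$chrom, lv), IRanges::IRanges(mat$start, mat$end),
        strand = mat$strand)
      hits <- GenomicRanges::findOverlaps(gr_r, gr_m, ignore.strand = FALSE)
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ow <- GenomicRanges::width(IRanges::pintersect(
        IRanges::ranges(gr_r)[qh], IRanges::ranges(gr_m)[sh]))
      rl <- GenomicRanges::width(gr_r)[qh]
      keep <- ow >= min_overlap_frac * rl
      qh <- qh[keep]; sh <- sh[keep]; ow <- ow[keep]
      if (length(qh)) {
        ord <- order(qh, -ow, mat$start[sh], mat$id[sh])
        first <- !duplicated(qh[ord])
        qh <- qh[ord][first]; sh <- sh[ord][first]
        tab <- table(factor(mat$id[sh], rownames(counts)),
                     factor(al$sample[qh], samples))
        counts <- counts + as.integer(tab)
        dim(counts) <- c(nrow(mat), length(samples))
        dimnames(counts) <- list(mat$id, samples)
        report$n_assigned <- length(qh)
      }
    }
  }
  report$n_unassigned <- report$n_input - report$n_assigned
  cm <- count_matrix(counts, design[design$sample %in% samples, , drop = FALSE],
                     colSums(counts))
  attr(cm, "report") <- report
  cm
}

#' Discard lowly expressed miRNAs
#'
#' Retains miRNAs whose replicate-mean raw count reaches `threshold` in
#' at least one condition of the chosen scope: every (strain, timepoint)
#' condition (`scope = "any_condition"`, the time-course reading) or only
#' the two groups of a pairwise contrast (`scope = "contrast"`). The
#' boundary is inclusive: a replicate-mean of exactly `threshold` is
#' kept.
#'
#' @param x `count_matrix`.
#' @param threshold minimal replicate-mean raw count (default 50).
#' @param scope `"any_condition"` or `"contrast"`.
#' @param contrast for `scope = "contrast"`: list of two lists, each with
#'   `strain` and `timepoint_h`.
#' @return filtered `count_matrix`; decisions attached as attribute
#'   `"filter_log"` (data.frame miRNA, max condition mean, kept flag).
#' @export
filter_low_counts <- function(x, threshold = 50,
                              scope = c("any_condition", "contrast"),
                              contrast = NULL) {
  stopifnot(inherits(x, "count_matrix"), threshold >= 0)
  scope <- match.arg(scope)
  d <- x$design
  if (scope == "any_condition") {
    groups <- split(d$sample, paste(d$strain, d$timepoint_h))
  } else {
    if (is.null(contrast)) stopf("scope='contrast' needs a contrast")
    groups <- lapply(contrast, function(g)
      condition_samples(d, g$strain, g$timepoint_h))
  }
  cond_means <- vapply(groups, function(s)
    rowMeans(x$counts[, s, drop = FALSE]), numeric(nrow(x$counts)))
  if (is.null(dim(cond_means))) cond_means <- matrix(cond_means, nrow = 1)
  max_mean <- apply(cond_means, 1, max)
  keep <- max_mean >= threshold
  out <- count_matrix(x$counts[keep, , drop = FALSE], x$design,
                      x$library_sizes)
  attr(out, "filter_log") <- data.frame(
    mirna = rownames(x$counts), max_condition_mean = unname(max_mean),
    kept = unname(keep), stringsAsFactors = FALSE)
  out
}
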