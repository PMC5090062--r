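#' Construct and validate a miRNA annotation
#'
#' Hairpins (primary transcripts) each contain one 5p and one 3p mature
#' feature. Coordinates are 1-based inclusive (GFF / GRanges convention);
#' conversion from 0-based half-open BED happens at the file boundary.
#'
#' @param hairpins data.frame: `id`, `chrom`, `start`, `end`, `strand`,
#'   `cluster_id` (NA when not part of a polycistron).
#' @param matures data.frame: `id`, `arm` ("5p"/"3p"), `chrom`, `start`,
#'   `end`, `strand`, `hairpin_id`.
#' @param genome optional [Biostrings::DNAStringSet] holding the reference
#'   sequence of every chromosome used.
#' @return object of class `mirna_annotation`.
#' @export
mirna_annotation <- function(hairpins, matures, genome = NULL) {
  need_h <- c("id", "chrom", "start", "end", "strand", "cluster_id")
  need_m <- c("id", "arm", "chrom", "start", "end", "strand", "hairpin_id")
  stopifnot(all(need_h %in% names(hairpins)), all(need_m %in% names(matures)))
  if (anyDuplicated(hairpins$id) || anyDuplicated(matures$id))
    stopf("annotation ids must be unique")
  bad_strand <- setdiff(unique(c(hairpins$strand, matures$strand)), c("+", "-"))
  if (length(bad_strand))
    stopf("unknown strand value(s): %s", paste(bad_strand, collapse = ", "))
  dangling <- setdiff(matures$hairpin_id, hairpins$id)
  if (length(dangling))
    stopf("mature feature(s) with missing parent hairpin: %s",
          paste(matures$id[matures$hairpin_id %in% dangling], collapse = ", "))
  idx <- match(matures$hairpin_id, hairpins$id)
  inside <- matures$chrom == hairpins$chrom[idx] &
    matures$start >= hairpins$start[idx] & matures$end <= hairpins$end[idx] &
    matures$strand == hairpins$strand[idx]
  if (!all(inside))
    stopf("mature feature(s) outside their hairpin span: %s",
          paste(matures$id[!inside], collapse = ", "))
  # arms of one hairpin must not overlap
  for (h in unique(matures$hairpin_id)) {
    mm <- matures[matures$hairpin_id == h, ]
    if (nrow(mm) == 2 &&
        mm$start[1] <= mm$end[2] && mm$start[2] <= mm$end[1])
      stopf("overlapping arms in hairpin %s", h)
  }
  structure(list(hairpins = hairpins, matures = matures, genome = genome),
            class = "mirna_annotation")
}

#' @export
print.mirna_annotation <- function(x, ...) {
  cat(sprintf("miRNA annotation: %d hairpins, %d matures, %d cluster(s)\n",
              nrow(x$hairpins), nrow(x$matures),
              length(unique(stats::na.omit(x$hairpins$cluster_id)))))
  invisible(x)
}

#' Generate a synthetic miRNA annotation with reference sequence
#'
#' Places `n_mirnas` hairpins on one synthetic chromosome, each with a 5p
#' and a 3p mature arm of 21-23 nt, non-overlapping, with polycistronic
#' clusters laid out as consecutive same-strand hairpins separated by short
#' gaps. The chromosome sequence is random; at every requested editing
#' site the reference base is set to the substitution's source base (read
#' on the mature sense strand) so injected mismatches are well defined.
#'
#' @param params [sim_params()] object.
#' @param chrom_length optional fixed chromosome length; an error is
#'   raised when the features do not fit.
#' @return `mirna_annotation` with a `genome` slot.
#' @export
generate_annotation <- function(params, chrom_length = NULL) {
  validate_sim_params(params)
  set.seed(derive_seed(params$seed, "annotation"))
  n <- params$n_mirnas
  # clusters occupy consecutive hairpins at the tail of the index range
  sizes <- if (params$n_clusters > 0)
    sample_range(params$cluster_size_range[1], params$cluster_size_range[2],
                 params$n_clusters) else integer(0)
  cluster_of <- rep(NA_character_, n)
  pos <- n
  for (k in rev(seq_along(sizes))) {
    cluster_of[(pos - sizes[k] + 1):pos] <- sprintf("cl-%d", k)
    pos <- pos - sizes[k]
  }
  if (pos < 0) stopf("clusters do not fit within n_mirnas")

  strand <- sample(c("+", "-"), n, replace = TRUE)
  for (k in unique(stats::na.omit(cluster_of)))
    strand[cluster_of == k] <- strand[which(cluster_of == k)[1]]

  hlen <- sample(80:100, n, replace = TRUE)
  gap_far <- sample(2000:5000, n, replace = TRUE)
  gap_near <- sample(100:500, n, replace = TRUE)
  start <- integer(n); cursor <- 1000L
  for (i in seq_len(n)) {
    same_cl <- i > 1 && !is.na(cluster_of[i]) &&
      identical(cluster_of[i], cluster_of[i - 1])
    cursor <- cursor + if (same_cl) gap_near[i] else gap_far[i]
    start[i] <- cursor
    cursor <- cursor + hlen[i]
  }
  total_len <- cursor + 2000L
  if (!is.null(chrom_length)) {
    if (total_len > chrom_length)
      stopf("infeasible packing: %d features need %d bp > chrom_length %d",
            n, total_len, chrom_length)
    total_len <- as.integer(chrom_length)
  }
  end <- start + hlen - 1L

  hairpins <- data.frame(
    id = sprintf("sim-mir-%d", seq_len(n)), chrom = "chrS",
    start = start, end = end, strand = strand, cluster_id = cluster_of,
    stringsAsFactors = FALSE
  )

  o5 <- sample(3:6, n, TRUE); l5 <- sample(21:23, n, TRUE)
  o3 <- sample(3:6, n, TRUE); l3 <- sample(21:23, n, TRUE)
  plus <- strand == "+"
  # the 5p arm sits at the hairpin 5' side: genomic left on +, right on -
  m5_start <- ifelse(plus, start + o5, end - o5 - l5 + 1L)
  m5_end <- m5_start + l5 - 1L
  m3_start <- ifelse(plus, end - o3 - l3 + 1L, start + o3)
  m3_end <- m3_start + l3 - 1L
  matures <- data.frame(
    id = c(sprintf("sim-miR-%d-5p", seq_len(n)),
           sprintf("sim-miR-%d-3p", seq_len(n))),
    arm = rep(c("5p", "3p"), each = n), chrom = "chrS",
    start = as.integer(c(m5_start, m3_start)),
    end = as.integer(c(m5_end, m3_end)),
    strand = c(strand, strand),
    hairpin_id = rep(hairpins$id, 2), stringsAsFactors = FALSE
  )
  matures <- matures[order(matures$start), ]
  rownames(matures) <- NULL

  seqchars <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  es <- params$editing_sites
  if (!is.null(es) && nrow(es)) {
    for (i in seq_len(nrow(es))) {
      m <- matures[matures$id == es$mature_id[i], ]
      if (nrow(m) != 1) stopf("editing site names unknown mature %s",
                              es$mature_id[i])
      if (es$position[i] < 1 || es$position[i] > m$end - m$start + 1)
        stopf("editing position %d outside mature %s", es$position[i], m$id)
      from <- substr(es$type[i], 1, 1)      # base on the mature sense strand
      if (m$strand == "+") {
        g <- m$start + es$position[i] - 1L
        seqchars[g] <- from
      } else {
        g <- m$end - es$position[i] + 1L
        seqchars[g] <- chartr("ACGT", "TGCA", from)
      }
    }
  }
  genome <- Biostrings::DNAStringSet(paste(seqchars, collapse = ""))
  names(genome) <- "chrS"

  mirna_annotation(hairpins, matures, genome)
}

#' Write a miRNA annotation as miRBase-dialect GFF3
#'
#' Hairpins become `miRNA_primary_transcript` features; matures become
#' `miRNA` features carrying a `Derives_from` attribute naming their
#' hairpin.
#'
#' @param annotation `mirna_annotation`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_mirna_gff3 <- function(annotation, path) {
  h <- annotation$hairpins; m <- annotation$matures
  gr_h <- GenomicRanges::GRanges(
    h$chrom, IRanges::IRanges(h$start, h$end), strand = h$strand,
    type = "miRNA_primary_transcript", ID = h$id, Name = h$id,
    cluster = ifelse(is.na(h$cluster_id), NA_character_, h$cluster_id)
  )
  gr_m <- GenomicRanges::GRanges(
    m$chrom, IRanges::IRanges(m$start, m$end), strand = m$strand,
    type = "miRNA", ID = m$id, Name = m$id, cluster = NA_character_,
    Derives_from = m$hairpin_id
  )
  S4Vectors::mcols(gr_h)$Derives_from <- NA_character_
  gr <- c(gr_h, gr_m)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write the reference genome as FASTA
#'
#' @param annotation `mirna_annotation` with a genome slot.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_genome_fasta <- function(annotation, path) {
  if (is.null(annotation$genome)) stopf("annotation has no genome sequence")
  Biostrings::writeXStringSet(annotation$genome, path)
  invisible(path)
}
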