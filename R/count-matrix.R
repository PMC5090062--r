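#' Construct a miRNA count matrix with sample design
#'
#' The central container of the pipeline: a miRNA x sample matrix of
#' non-negative integer read counts, per-sample library sizes (total
#' counted reads), and a design table mapping each sample to its strain,
#' heat-shock recovery timepoint and replicate.
#'
#' @param counts integer matrix, miRNAs in rows (rownames = miRNA ids),
#'   samples in columns (colnames = sample ids).
#' @param design data.frame with columns `sample`, `strain`,
#'   `timepoint_h`, `replicate`; one row per column of `counts`.
#' @param library_sizes numeric vector of total counted reads per sample;
#'   defaults to the column sums.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, design, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("negative counts are not allowed")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry row and column names")
  need <- c("sample", "strain", "timepoint_h", "replicate")
  stopifnot(all(need %in% names(design)))
  if (!setequal(design$sample, colnames(counts)) ||
      anyDuplicated(design$sample))
    stopf("design must cover every sample column exactly once")
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  library_sizes <- library_sizes[colnames(counts)] %||% library_sizes
  if (is.null(names(library_sizes))) names(library_sizes) <- colnames(counts)
  if (any(library_sizes < colSums(counts) - 1e-8))
    stopf("library_sizes must be >= column sums of retained features")
  structure(list(counts = counts, design = design,
                 library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d miRNAs x %d samples (%d strains, %d timepoints)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$design$strain)),
              length(unique(x$design$timepoint_h))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by feature and/or sample
#'
#' @param x `count_matrix`.
#' @param features row selector (ids or logical/integer index).
#' @param samples column selector.
#' @return `count_matrix`.
#' @export
subset_counts <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  if (!is.null(features)) m <- m[features, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  count_matrix(m, x$design[x$design$sample %in% colnames(m), , drop = FALSE],
               x$library_sizes[colnames(m)])
}

#' Sample ids belonging to one (strain, timepoint) condition
#'
#' @param design design data.frame.
#' @param strain strain id.
#' @param timepoint_h timepoint in hours.
#' @return character vector of sample ids.
#' @export
condition_samples <- function(design, strain, timepoint_h) {
  design$sample[design$strain == strain & design$timepoint_h == timepoint_h]
}

#' Write / read a count matrix as TSV pair
#'
#' `write_count_matrix()` writes `<prefix>_counts.tsv` (miRNA rows, sample
#' columns, first column `mirna`) and `<prefix>_design.tsv` (with a
#' `library_size` column); `read_count_matrix()` reads them back.
#'
#' @param x `count_matrix`.
#' @param prefix path prefix.
#' @return the prefix (write) or a `count_matrix` (read), invisibly for
#'   write.
#' @export
write_count_matrix <- function(x, prefix) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(mirna = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, paste0(prefix, "_counts.tsv"))
  d <- x$design
  d$library_size <- unname(x$library_sizes[d$sample])
  write_tsv(d, paste0(prefix, "_design.tsv"))
  invisible(prefix)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(prefix) {
  df <- read_tsv(paste0(prefix, "_counts.tsv"))
  d <- read_tsv(paste0(prefix, "_design.tsv"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$mirna
  ls <- d$library_size
  names(ls) <- d$sample
  count_matrix(m, d[setdiff(names(d), "library_size")], ls)
}
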