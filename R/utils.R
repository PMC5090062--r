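#' @importFrom stats rnbinom rbinom rlnorm runif rnorm sd var lm anova
#'   pf pnorm phyper p.adjust cutree hclust as.dist cor predict qt dnbinom
#'   coef complete.cases setNames
#' @importFrom utils read.delim write.table head tail
NULL

#' Derive a reproducible sub-seed for a pipeline stage
#'
#' One global seed deterministically spawns independent per-stage seeds so
#' that a stage rerun in isolation reproduces its in-pipeline output.
#' Kept strictly below 2^31 so the value is always a valid R integer.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # small deterministic string hash (polynomial rolling, modulo prime < 2^31)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483587
  as.integer((as.numeric(seed) %% 2147483587 * 7919 + h) %% 2147483587 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as a TSV file
#'
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV file written by this package
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# sample n values uniformly from lo:hi, immune to R's scalar-x sample()
sample_range <- function(lo, hi, n) {
  v <- seq.int(lo, hi)
  v[sample.int(length(v), n, replace = TRUE)]
}
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Largest-remainder apportionment of n items into proportions
#'
#' Deterministic partition used for stress-gene class sizes: each class gets
#' floor(n * p) items, and the classes with the largest fractional
#' remainders receive the leftover items (ties broken by class order).
#'
#' @param n total count.
#' @param proportions numeric vector summing to <= 1 (rescaled to 1).
#' @return integer vector of class sizes summing to `n`.
#' @export
largest_remainder <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions >= 0), sum(proportions) > 0)
  p <- proportions / sum(proportions)
  raw <- n * p
  base <- floor(raw)
  left <- round(n - sum(base))
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
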