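#' Build normalized time-course expression profiles
#'
#' Per miRNA: replicate-mean RPM per (strain, timepoint) condition, then
#' log2(RPM + pseudocount), then z-scaling with the mean and SD of that
#' miRNA's full profile (all strains x timepoints pooled), then anchoring
#' each strain at its control value so every profile starts at 0.
#' Replicate-level values are normalized with the same per-miRNA z
#' parameters and strain anchors, so condition means of the replicate
#' values reproduce the profile exactly; the regression stage fits on
#' replicates to keep residual degrees of freedom.
#'
#' A miRNA whose log2 expression is constant across the whole profile has
#' zero variance: its profile is set to all zeros and flagged degenerate.
#'
#' @param x `count_matrix` covering every (strain, timepoint).
#' @param pseudocount RPM pseudo-count for the log2 transform (default 1).
#' @return object of class `profile_matrix`: `values` (miRNA x
#'   "strain@t" condition matrix), `rep_values` (miRNA x sample matrix),
#'   `strains`, `timepoints_h`, `design`, `degenerate` (logical per
#'   miRNA), `pseudocount`.
#' @export
profile_normalize <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  d <- x$design
  strains <- unique(d$strain)
  tps <- sort(unique(d$timepoint_h))
  for (s in strains) for (t in tps)
    if (!length(condition_samples(d, s, t)))
      stopf("missing condition %s @ %g h", s, t)
  rpm <- rpm_normalize(x)
  conds <- expand.grid(strain = strains, timepoint_h = tps,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cond_names <- sprintf("%s@%g", conds$strain, conds$timepoint_h)
  cm <- vapply(seq_len(nrow(conds)), function(i)
    rowMeans(rpm[, condition_samples(d, conds$strain[i],
                                     conds$timepoint_h[i]), drop = FALSE]),
    numeric(nrow(rpm)))
  dimnames(cm) <- list(rownames(rpm), cond_names)

  lg <- log2(cm + pseudocount)
  mu <- rowMeans(lg)
  sdv <- apply(lg, 1, sd)
  degenerate <- sdv == 0
  sdv[degenerate] <- 1                       # profile becomes all zero anyway
  z <- (lg - mu) / sdv

  ctrl_cols <- match(sprintf("%s@%g", conds$strain, 0), cond_names)
  anchored <- z
  for (i in seq_len(nrow(conds)))
    anchored[, i] <- z[, i] - z[, ctrl_cols[i]]
  anchored[degenerate, ] <- 0

  lr <- log2(rpm + pseudocount)
  zr <- (lr - mu) / sdv
  ctrl_of_sample <- match(sprintf("%s@%g", d$strain, 0), cond_names)
  rep_anch <- zr
  for (j in seq_len(ncol(zr)))
    rep_anch[, j] <- zr[, j] - z[, ctrl_of_sample[j]]
  rep_anch[degenerate, ] <- 0

  structure(list(values = anchored, rep_values = rep_anch,
                 strains = strains, timepoints_h = tps, design = d,
                 degenerate = stats::setNames(degenerate, rownames(rpm)),
                 pseudocount = pseudocount),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d miRNAs, %d strains, timepoints %s h (%d degenerate)\n",
              nrow(x$values), length(x$strains),
              paste(x$timepoints_h, collapse = "/"), sum(x$degenerate)))
  invisible(x)
}

#' Extract one miRNA's per-strain profile vectors
#'
#' @param pm `profile_matrix`.
#' @param mirna miRNA id.
#' @return matrix strains x timepoints of anchored profile values.
#' @export
profile_of <- function(pm, mirna) {
  stopifnot(inherits(pm, "profile_matrix"))
  out <- matrix(NA_real_, length(pm$strains), length(pm$timepoints_h),
                dimnames = list(pm$strains, paste0("t", pm$timepoints_h)))
  for (i in seq_along(pm$strains)) for (j in seq_along(pm$timepoints_h))
    out[i, j] <- pm$values[mirna, sprintf("%s@%g", pm$strains[i],
                                          pm$timepoints_h[j])]
  out
}
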