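#' YS1 composite time-course dissimilarity
#'
#' Similarity of two equal-length profiles is the equally weighted mean
#' of three components (weights configurable):
#' * `rho*`: Spearman rank correlation rescaled to \[0, 1\];
#' * `A`: fraction of adjacent time intervals on which the two profiles'
#'   slopes have the same sign (a zero slope is its own sign);
#' * `M`: average of two indicators — maxima at the same position,
#'   minima at the same position (first occurrence on ties).
#'
#' The distance is 1 - S. For a constant profile the rank correlation is
#' undefined; its component is set to the neutral 0.5 and the result is
#' flagged via attribute `"constant_input"`.
#'
#' @param x,y numeric profiles, equal length >= 3.
#' @param weights numeric length-3 weights for (rho*, A, M); normalised
#'   to sum 1.
#' @return distance in \[0, 1\].
#' @export
ys1_distance <- function(x, y, weights = c(1, 1, 1)) {
  if (length(x) != length(y)) stopf("profiles must have equal length")
  if (length(x) < 3) stopf("profiles must have length >= 3")
  w <- weights / sum(weights)
  const <- sd(x) == 0 || sd(y) == 0
  rho_star <- if (const) 0.5 else
    (stats::cor(x, y, method = "spearman") + 1) / 2
  sx <- sign(diff(x)); sy <- sign(diff(y))
  A <- mean(sx == sy)
  M <- (as.numeric(which.max(x) == which.max(y)) +
        as.numeric(which.min(x) == which.min(y))) / 2
  s <- w[1] * rho_star + w[2] * A + w[3] * M
  out <- 1 - s
  if (const) attr(out, "constant_input") <- TRUE
  out
}

#' YS1 distance matrix
#'
#' For a plain matrix, rows are items and each row is one profile. For a
#' [profile_normalize()] result, each miRNA's distance to another is the
#' mean of the per-strain YS1 distances between their anchored profiles,
#' so clustering respects the shape in every strain.
#'
#' @param x numeric matrix (rows = items) or `profile_matrix`.
#' @param ids for a `profile_matrix`: which miRNAs (default all).
#' @param weights passed to [ys1_distance()].
#' @return symmetric distance matrix with zero diagonal.
#' @export
ys1_dist_matrix <- function(x, ids = NULL, weights = c(1, 1, 1)) {
  if (inherits(x, "profile_matrix")) {
    ids <- ids %||% rownames(x$values)
    profs <- lapply(ids, function(m) profile_of(x, m))
    n <- length(ids)
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      dv <- mean(vapply(seq_along(x$strains), function(s)
        as.numeric(ys1_distance(profs[[i]][s, ], profs[[j]][s, ], weights)),
        numeric(1)))
      D[i, j] <- D[j, i] <- dv
    }
    return(D)
  }
  n <- nrow(x)
  nm <- rownames(x) %||% as.character(seq_len(n))
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    D[i, j] <- D[j, i] <- as.numeric(ys1_distance(x[i, ], x[j, ], weights))
  }
  D
}

#' Complete-linkage hierarchical clustering on the YS1 distance
#'
#' Items are ordered lexicographically by id before linkage so that ties
#' in the distance matrix are broken deterministically; the tree is cut
#' into `k` clusters (default 6, the expected number of heat-shock
#' response profile families).
#'
#' @param x matrix of profiles (rows = items), `profile_matrix`, or a
#'   precomputed symmetric distance matrix (set `is_dist = TRUE`).
#' @param k number of clusters.
#' @param ids for `profile_matrix` input: miRNAs to cluster.
#' @param is_dist treat `x` as a precomputed distance matrix.
#' @param weights passed to [ys1_distance()].
#' @return list of class `ys1_clustering`: `assignment` (named integer
#'   vector), `tree` (`hclust`), `distance` (the matrix), `k`.
#' @export
hierarchical_cluster <- function(x, k = 6, ids = NULL, is_dist = FALSE,
                                 weights = c(1, 1, 1)) {
  D <- if (is_dist) x else ys1_dist_matrix(x, ids = ids, weights = weights)
  if (k > nrow(D)) stopf("k = %d exceeds the %d items", k, nrow(D))
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tree <- hclust(as.dist(D), method = "complete")
  assignment <- cutree(tree, k = k)
  structure(list(assignment = assignment, tree = tree, distance = D, k = k),
            class = "ys1_clustering")
}

#' @export
print.ys1_clustering <- function(x, ...) {
  cat(sprintf("YS1 complete-linkage clustering: %d items in %d clusters\n",
              length(x$assignment), x$k))
  print(table(x$assignment))
  invisible(x)
}

#' Per-cluster mean profile as a fitted line with 95% CI
#'
#' For each strain, ordinary least squares of the cluster members'
#' anchored profile values on time (hours), with the pointwise 95%
#' confidence interval of the mean response at each timepoint.
#'
#' @param pm `profile_matrix`.
#' @param members miRNA ids of one cluster (non-empty).
#' @return data.frame: `strain`, `timepoint_h`, `fit`, `lwr`, `upr`,
#'   `slope`, `intercept`.
#' @export
cluster_mean_profile <- function(pm, members) {
  stopifnot(inherits(pm, "profile_matrix"), length(members) >= 1)
  out <- list()
  for (s in pm$strains) {
    cols <- sprintf("%s@%g", s, pm$timepoints_h)
    y <- as.vector(pm$values[members, cols, drop = FALSE])
    t <- rep(pm$timepoints_h, each = length(members))
    fit <- stats::lm(y ~ t)
    nd <- data.frame(t = pm$timepoints_h)
    pr <- predict(fit, nd, interval = "confidence", level = 0.95)
    out[[s]] <- data.frame(
      strain = s, timepoint_h = pm$timepoints_h,
      fit = pr[, "fit"], lwr = pr[, "lwr"], upr = pr[, "upr"],
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
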