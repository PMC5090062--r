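#' Conditional negative-binomial exact test
#'
#' Two-sided exact test of equal means between two groups of NB counts,
#' conditional on the pooled total. Replicate counts are first equalised
#' by their size factors and summed; group sums are then NB with shape
#' n_A / phi and n_B / phi and a common probability parameter, so the
#' conditional law of the group-A sum given the total is negative
#' hypergeometric and free of the unknown mean. The p-value is the sum of
#' conditional probabilities of all outcomes as or less likely than the
#' observed one. At phi = 0 this reduces to the binomial (conditional
#' Poisson) test.
#'
#' @param countsA,countsB integer replicate counts.
#' @param size_factorsA,size_factorsB relative size factors (defaults 1).
#' @param phi NB dispersion (variance mu + phi mu^2), >= 0.
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(countsA, countsB,
                          size_factorsA = rep(1, length(countsA)),
                          size_factorsB = rep(1, length(countsB)),
                          phi = 0) {
  if (phi < 0) stopf("phi must be >= 0")
  if (any(countsA < 0) || any(countsB < 0)) stopf("counts must be >= 0")
  nA <- length(countsA); nB <- length(countsB)
  kA <- round(sum(countsA / size_factorsA))
  kB <- round(sum(countsB / size_factorsB))
  total <- kA + kB
  if (total == 0) return(1)
  # unnormalised conditional pmf via the ratio recurrence, anchored at
  # the mode so nothing overflows (far tails underflow harmlessly to 0)
  k <- 0:(total - 1)
  r <- if (phi == 0) {
    (nA / nB) * (total - k) / (k + 1)
  } else {
    rA <- nA / phi; rB <- nB / phi
    ((k + rA) / (k + 1)) * ((total - k) / (total - k + rB - 1))
  }
  m <- sum(r >= 1)                      # mode index (0-based)
  v <- numeric(total + 1)
  v[m + 1] <- 1
  if (m < total) v[(m + 2):(total + 1)] <- cumprod(r[(m + 1):total])
  if (m > 0) v[m:1] <- cumprod(1 / r[m:1])
  v_obs <- v[kA + 1]
  p <- sum(v[v <= v_obs * (1 + 1e-10)]) / sum(v)
  min(1, max(p, 5e-324))
}

#' Wald test on the negative-binomial log2 fold-change
#'
#' Second, methodologically independent test of the consensus pair: a
#' z-statistic on the difference of log group means, with a delta-method
#' variance built from the NB mean-variance relation
#' Var(K_i) = s_i mu + phi (s_i mu)^2.
#'
#' @inheritParams nb_exact_test
#' @param prior prior count added to each size-factor-normalised group
#'   mean before taking logs (stabilises fold-changes at zero counts).
#' @return two-sided p-value.
#' @export
nb_wald_test <- function(countsA, countsB,
                         size_factorsA = rep(1, length(countsA)),
                         size_factorsB = rep(1, length(countsB)),
                         phi = 0, prior = 0.5) {
  if (phi < 0) stopf("phi must be >= 0")
  nA <- length(countsA); nB <- length(countsB)
  muA <- mean(countsA / size_factorsA)
  muB <- mean(countsB / size_factorsB)
  if (muA == 0 && muB == 0) return(1)
  mA <- muA + prior; mB <- muB + prior
  vA <- sum(mA / size_factorsA + phi * mA^2) / nA^2
  vB <- sum(mB / size_factorsB + phi * mB^2) / nB^2
  se <- sqrt(vA / mA^2 + vB / mB^2)
  if (se == 0) return(1)
  z <- (log(mA) - log(mB)) / se
  2 * stats::pnorm(-abs(z))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, named for the
#' pipeline's vocabulary.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values (Q-values), capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Estimate per-miRNA NB dispersion
#'
#' Method-of-moments residual dispersion from size-factor-normalised
#' replicate counts within each (strain, timepoint) condition, pooled
#' over replicated conditions with degree-of-freedom weights. Features
#' whose pooled estimate does not exceed twice its standard error under
#' the Poisson null are set to the floor (no detectable overdispersion);
#' the rest are shrunk 50/50 toward the trimmed-mean common dispersion
#' of the detected features and floored at `floor`.
#'
#' @param x `count_matrix`.
#' @param prior_dispersion fallback when no condition has >= 2 replicates.
#' @param floor minimal reported dispersion (default 1e-4).
#' @return named numeric vector of per-miRNA dispersions.
#' @export
estimate_dispersion <- function(x, prior_dispersion = 0.1, floor = 1e-4) {
  stopifnot(inherits(x, "count_matrix"))
  d <- x$design
  sf <- x$library_sizes / mean(x$library_sizes)
  norm <- sweep(x$counts, 2, sf, "/")
  groups <- split(seq_len(ncol(norm)), paste(d$strain, d$timepoint_h))
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (!length(groups)) {
    warnf("no replicated condition; using prior dispersion %g",
          prior_dispersion)
    return(stats::setNames(rep(prior_dispersion, nrow(norm)),
                           rownames(norm)))
  }
  nr <- nrow(norm)
  num <- den <- nullvar <- rep(0, nr)
  for (g in groups) {
    m <- rowMeans(norm[, g, drop = FALSE])
    v <- apply(norm[, g, drop = FALSE], 1, var)
    inv_s <- mean(1 / sf[g])
    ok <- m > 0
    est <- ifelse(ok, (v - m * inv_s) / m^2, 0)
    w <- length(g) - 1
    num <- num + ifelse(ok, w * est, 0)
    den <- den + ifelse(ok, w, 0)
    # variance of the per-condition estimate when the truth is Poisson
    nullvar <- nullvar + ifelse(ok, w^2 * (2 / w) * (inv_s / m)^2, 0)
  }
  est <- ifelse(den > 0, num / den, NA_real_)
  se0 <- ifelse(den > 0, sqrt(nullvar) / den, Inf)
  detected <- !is.na(est) & est > 2 * se0
  common <- mean(est[detected], trim = 0.2)
  if (!is.finite(common) || common < 0) common <- prior_dispersion
  phi <- ifelse(detected, pmax(floor, 0.5 * est + 0.5 * common), floor)
  phi[is.na(est)] <- pmax(floor, common)
  stats::setNames(phi, rownames(norm))
}
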