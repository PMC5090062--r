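#' Build the polynomial time-course design matrix
#'
#' Columns: time powers `t1 ... t<degree>` (hours, not ranks), indicator
#' dummies `str:<s>` for every strain except the reference, and their
#' interactions `str:<s>:t<k>`. Each column carries the polynomial order
#' of its time component (0 for pure dummies) used for stepwise
#' tie-breaking.
#'
#' @param strain character vector per observation.
#' @param time_h numeric hours per observation.
#' @param ref_strain reference strain (absorbed by the intercept/time
#'   terms).
#' @param degree polynomial degree (must be < number of distinct
#'   timepoints).
#' @return numeric matrix with attribute `"degrees"`.
#' @export
timecourse_design <- function(strain, time_h, ref_strain, degree = 2) {
  if (degree >= length(unique(time_h)))
    stopf("degree must be < number of timepoints")
  others <- setdiff(unique(strain), ref_strain)
  cols <- list(); degs <- integer()
  for (k in seq_len(degree)) {
    cols[[sprintf("t%d", k)]] <- time_h^k
    degs <- c(degs, k)
  }
  for (s in others) {
    d <- as.numeric(strain == s)
    cols[[sprintf("str:%s", s)]] <- d
    degs <- c(degs, 0L)
    for (k in seq_len(degree)) {
      cols[[sprintf("str:%s:t%d", s, k)]] <- d * time_h^k
      degs <- c(degs, k)
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "degrees") <- stats::setNames(degs, colnames(X))
  X
}

fit_ls <- function(y, X) {
  df <- data.frame(y = y, X, check.names = FALSE)
  stats::lm(y ~ ., data = df)
}

#' Global polynomial regression screen across miRNAs
#'
#' For each miRNA, regresses its normalized time-course values (replicate
#' level) on the polynomial time terms, strain dummies versus the
#' reference strain, and their interactions, and tests the full model
#' against the intercept-only model with an F-test. P-values are
#' BH-adjusted across miRNAs; a miRNA passes when Q <= `q_alpha`.
#'
#' @param pm `profile_matrix` from [profile_normalize()].
#' @param ref_strain reference strain; default the first.
#' @param degree polynomial degree (default 2 over four timepoints).
#' @param q_alpha Q-value cut-off (default 0.05).
#' @return data.frame: `mirna`, `p_F`, `r2_full`, `Q`, `q_pass`.
#' @export
fit_global_regression <- function(pm, ref_strain = NULL, degree = 2,
                                  q_alpha = 0.05) {
  stopifnot(inherits(pm, "profile_matrix"))
  ref_strain <- ref_strain %||% pm$strains[1]
  d <- pm$design
  X <- timecourse_design(d$strain, d$timepoint_h, ref_strain, degree)
  ids <- rownames(pm$rep_values)
  p <- r2 <- rep(NA_real_, length(ids))
  warned <- FALSE
  for (i in seq_along(ids)) {
    if (pm$degenerate[ids[i]]) { p[i] <- 1; r2[i] <- 0; next }
    fit <- fit_ls(pm$rep_values[ids[i], ], X)
    if (anyNA(coef(fit)) && !warned) {
      warnf("rank-deficient design: aliased columns dropped")
      warned <- TRUE
    }
    fs <- summary(fit)$fstatistic
    if (is.null(fs) || fit$df.residual == 0) {
      if (!warned) { warnf("saturated fit: no residual df"); warned <- TRUE }
      p[i] <- 1; r2[i] <- 0
    } else {
      p[i] <- pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
      r2[i] <- summary(fit)$r.squared
    }
  }
  out <- data.frame(mirna = ids, p_F = p, r2_full = r2,
                    stringsAsFactors = FALSE)
  out$Q <- bh_adjust(out$p_F)
  out$q_pass <- out$Q <= q_alpha
  out
}

#' Backward stepwise term elimination
#'
#' Starting from the full model, repeatedly refits and removes the
#' non-intercept term with the largest coefficient p-value above `alpha`
#' until every remaining term has p <= `alpha`. Aliased (inestimable)
#' terms are removed first. Ties on p are broken by removing the
#' higher-order term first, then the later design column. May reduce to
#' the intercept-only model (R^2 reported as 0).
#'
#' @param y response vector.
#' @param X design matrix from [timecourse_design()].
#' @param alpha per-term p cut-off (default 0.05).
#' @return list: `terms` (retained column names), `r2`, `fit` (the final
#'   `lm`), `term_p` (named p-values of retained terms).
#' @export
backward_stepwise <- function(y, X, alpha = 0.05) {
  degrees <- attr(X, "degrees")
  keep <- colnames(X)
  repeat {
    if (!length(keep)) {
      fit <- stats::lm(y ~ 1)
      return(list(terms = character(), r2 = 0, fit = fit,
                  term_p = numeric()))
    }
    Xc <- X[, keep, drop = FALSE]
    fit <- fit_ls(y, Xc)
    cf <- coef(fit)[-1]
    aliased <- names(cf)[is.na(cf)]
    aliased <- gsub("^`|`$", "", aliased)
    if (length(aliased)) {
      drop1 <- order_candidates(aliased, degrees, keep)[1]
      keep <- setdiff(keep, drop1)
      next
    }
    sm <- summary(fit)$coefficients
    pv <- sm[-1, 4]
    names(pv) <- gsub("^`|`$", "", rownames(sm)[-1])
    worst <- max(pv)
    if (worst <= alpha) {
      r2 <- if (fit$df.residual == 0) 1 else summary(fit)$r.squared
      return(list(terms = keep, r2 = r2, fit = fit, term_p = pv))
    }
    cand <- names(pv)[pv >= worst - 1e-12]
    keep <- setdiff(keep, order_candidates(cand, degrees, keep)[1])
  }
}

# tie-break: higher polynomial order first, then the later design column
order_candidates <- function(cand, degrees, keep) {
  cand[order(-degrees[cand], -match(cand, keep))]
}

#' Select miRNAs with significantly changed profiles across reference
#' rotations
#'
#' Runs the full selection path (global F screen with BH, backward
#' stepwise, R^2 gate) once per reference strain. The pure polynomial
#' time terms of a rotation describe the reference strain's own temporal
#' profile, while dummy/interaction terms describe differences from the
#' reference; a strain's own profile change is therefore judged in the
#' rotation where it is the reference. A miRNA is profile-significant
#' for strain s when the rotation with reference s passes the Q gate,
#' retains at least one pure-time term after stepwise elimination, and
#' reaches `r2_min` with its selected model.
#'
#' @param pm `profile_matrix`.
#' @param degree polynomial degree.
#' @param q_alpha BH Q cut-off for the global screen.
#' @param alpha stepwise per-term cut-off.
#' @param r2_min minimal selected-model R^2 (default 0.6).
#' @return list: `table` (data.frame mirna, per-strain logical columns,
#'   `n_strains_significant`), `rotations` (per-reference detail),
#'   `partition` (named counts of miRNAs significant in exactly 1, 2, ...
#'   strains).
#' @export
timecourse_select <- function(pm, degree = 2, q_alpha = 0.05, alpha = 0.05,
                              r2_min = 0.6) {
  stopifnot(inherits(pm, "profile_matrix"))
  ids <- rownames(pm$rep_values)
  d <- pm$design
  flags <- matrix(FALSE, length(ids), length(pm$strains),
                  dimnames = list(ids, pm$strains))
  rotations <- list()
  for (ref in pm$strains) {
    glob <- fit_global_regression(pm, ref, degree, q_alpha)
    X <- timecourse_design(d$strain, d$timepoint_h, ref, degree)
    detail <- data.frame(mirna = ids, ref = ref, q_pass = glob$q_pass,
                         r2 = NA_real_, terms = NA_character_,
                         stringsAsFactors = FALSE)
    for (i in seq_along(ids)) {
      if (!glob$q_pass[i] || pm$degenerate[ids[i]]) next
      st <- backward_stepwise(pm$rep_values[ids[i], ], X, alpha)
      detail$r2[i] <- st$r2
      detail$terms[i] <- paste(st$terms, collapse = ";")
      if (st$r2 < r2_min || !length(st$terms)) next
      if (any(grepl("^t[0-9]+$", st$terms))) flags[ids[i], ref] <- TRUE
    }
    rotations[[ref]] <- detail
  }
  n_sig <- rowSums(flags)
  tab <- data.frame(mirna = ids, flags, n_strains_significant = n_sig,
                    check.names = FALSE, stringsAsFactors = FALSE)
  part <- table(factor(n_sig[n_sig > 0], levels = seq_along(pm$strains)))
  list(table = tab, rotations = rotations,
       partition = stats::setNames(as.integer(part), names(part)))
}
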