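test_that("profile normalisation anchors at control and z-scales the full profile", {
  design <- tiny_design(strains = c("a", "b"), tps = c(0, 1, 6, 24))
  set.seed(2)
  counts <- matrix(rpois(3 * nrow(design), lambda = rep(c(500, 900, 300),
                                                        nrow(design))),
                   3, nrow(design),
                   dimnames = list(paste0("m", 1:3), design$sample))
  counts["m3", ] <- 400L                       # constant everywhere
  cm <- count_matrix(counts, design,
                     stats::setNames(rep(1e6, nrow(design)), design$sample))
  pm <- profile_normalize(cm)

  # control anchoring
  for (s in pm$strains)
    expect_equal(unname(pm$values[, sprintf("%s@0", s)]), rep(0, 3))
  # degenerate profile flagged and zeroed
  expect_true(pm$degenerate["m3"])
  expect_true(all(pm$values["m3", ] == 0))

  # direct recomputation oracle for one miRNA
  rpm <- rpm_normalize(cm)
  conds <- expand.grid(strain = pm$strains, timepoint_h = pm$timepoints_h,
                       stringsAsFactors = FALSE)
  cmn <- vapply(seq_len(nrow(conds)), function(i)
    mean(rpm["m1", condition_samples(design, conds$strain[i],
                                     conds$timepoint_h[i])]), numeric(1))
  lg <- log2(cmn + 1)
  z <- (lg - mean(lg)) / sd(lg)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  anchored <- z - z[match(sprintf("%s@0", conds$strain),
                          sprintf("%s@%g", conds$strain, conds$timepoint_h))]
  got <- pm$values["m1", sprintf("%s@%g", conds$strain, conds$timepoint_h)]
  expect_equal(unname(got), anchored)

  # replicate-level values use the same z parameters and strain anchor
  cond_key <- sprintf("%s@%g", conds$strain, conds$timepoint_h)
  for (smp1 in design$sample[c(1, 5, 12)]) {
    z_ctrl <- z[match(sprintf("%s@0",
                              design$strain[design$sample == smp1]),
                      cond_key)]
    expect_equal(unname(pm$rep_values["m1", smp1]),
                 (log2(rpm["m1", smp1] + 1) - mean(lg)) / sd(lg) - z_ctrl,
                 tolerance = 1e-12)
  }

  # a strain missing one timepoint is rejected
  drop <- design$sample[!(design$strain == "a" & design$timepoint_h == 6)]
  expect_error(profile_normalize(subset_counts(cm, samples = drop)),
               "missing condition")
})

test_that("backward stepwise keeps exact signals, drops noise, and matches best subset on a toy", {
  tps <- c(0, 1, 6, 24)
  design <- tiny_design(strains = "a", tps = tps, reps = 2)
  X <- timecourse_design(design$strain, design$timepoint_h, "a", degree = 2)

  # exact linear profile: linear term retained, R^2 = 1
  y_lin <- 0.1 * design$timepoint_h
  st <- suppressWarnings(backward_stepwise(y_lin, X, alpha = 0.05))
  expect_true("t1" %in% st$terms)
  expect_equal(st$r2, 1, tolerance = 1e-9)

  # pure noise: reduces to intercept-only
  set.seed(5)
  st0 <- backward_stepwise(rnorm(nrow(design)), X, alpha = 0.01)
  expect_length(st0$terms, 0)
  expect_equal(st0$r2, 0)

  # toy with three candidate terms: stepwise equals exhaustive search for
  # the largest subset whose terms are all significant
  set.seed(7)
  y <- 0.3 * design$timepoint_h + rnorm(nrow(design), 0, 0.3)
  st2 <- backward_stepwise(y, X, alpha = 0.05)
  subsets <- unlist(lapply(seq_along(colnames(X)), function(k)
    combn(colnames(X), k, simplify = FALSE)), recursive = FALSE)
  ok <- Filter(function(ss) {
    fit <- stats::lm(y ~ ., data.frame(y = y, X[, ss, drop = FALSE],
                                       check.names = FALSE))
    all(summary(fit)$coefficients[-1, 4] <= 0.05)
  }, subsets)
  best <- ok[[which.max(vapply(ok, length, 1L))]]
  expect_setequal(st2$terms, best)
})

test_that("the global screen is calibrated, powered, and warns on saturated designs", {
  strains <- c("a", "b", "c"); tps <- c(0, 1, 6, 24)
  design <- tiny_design(strains = strains, tps = tps, reps = 2)
  sigma <- 0.4
  n <- 120
  set.seed(31)
  flat <- t(sapply(seq_len(n), function(i) rnorm(nrow(design), 0, sigma)))
  rownames(flat) <- paste0("m", 1:n); colnames(flat) <- design$sample
  pm0 <- make_profile_matrix(flat, design, strains, tps)
  expect_lte(mean(fit_global_regression(pm0)$q_pass), 0.05)

  # quadratic signal with SD twice the noise SD across the design points
  q <- (design$timepoint_h / 24)^2
  q <- (q - mean(q)) / sd(q)
  sig <- t(sapply(seq_len(n), function(i)
    2 * sigma * q + rnorm(nrow(design), 0, sigma)))
  dimnames(sig) <- dimnames(flat)
  pm1 <- make_profile_matrix(sig, design, strains, tps)
  expect_gte(mean(fit_global_regression(pm1)$q_pass), 0.9)

  # saturated design: one strain, degree 1, two points, one replicate
  d2 <- tiny_design(strains = "a", tps = c(0, 1), reps = 1)
  y2 <- matrix(c(0, 1), 1, 2, dimnames = list("m1", d2$sample))
  pm2 <- make_profile_matrix(y2, d2, "a", c(0, 1))
  expect_warning(g2 <- fit_global_regression(pm2, degree = 1), "saturated")
  expect_equal(g2$p_F, 1)

  expect_error(timecourse_design("a", c(0, 1), "a", degree = 2), "degree")
})

test_that("profile selection recovers per-strain memberships and respects thresholds", {
  # per-strain injected trends on normalized profiles
  strains <- c("a", "b", "c"); tps <- c(0, 1, 6, 24)
  design <- tiny_design(strains = strains, tps = tps, reps = 2)
  set.seed(41)
  n <- 60; sigma <- 0.35
  truth <- matrix(FALSE, n, 3, dimnames = list(paste0("m", 1:n), strains))
  truth[1:20, "a"] <- TRUE
  truth[21:30, ] <- TRUE
  shape <- 2 * log2(1 + design$timepoint_h / 6) / log2(5)  # 0 -> 2
  vals <- matrix(0, n, nrow(design),
                 dimnames = list(rownames(truth), design$sample))
  for (j in seq_len(nrow(design)))
    vals[, j] <- ifelse(truth[, design$strain[j]], shape[j], 0)
  vals <- vals + rnorm(length(vals), 0, sigma)
  pm <- make_profile_matrix(vals, design, strains, tps)
  sel <- timecourse_select(pm)
  flags <- as.matrix(sel$table[, strains])
  acc <- mean(flags[1:30, ] == truth[1:30, ])
  expect_gte(acc, 0.85)
  # partition sizes sum to the number of significant miRNAs
  expect_equal(sum(sel$partition),
               sum(sel$table$n_strains_significant > 0))

  # thresholds off: every non-degenerate miRNA is significant everywhere
  sel_all <- timecourse_select(pm, q_alpha = 1, alpha = 1, r2_min = 0)
  expect_true(all(sel_all$table$n_strains_significant == 3))
})

test_that("cluster mean profiles follow the OLS confidence-interval geometry", {
  design <- tiny_design(strains = c("a", "b"), tps = c(0, 1, 6, 24))
  strains <- c("a", "b"); tps <- c(0, 1, 6, 24)
  conds <- as.vector(outer(strains, tps, function(s, t)
    sprintf("%s@%g", s, t)))
  # identical, exactly linear members
  lin <- 0.1 * rep(tps, each = 2)
  vals <- matrix(rep(lin, 3), 3, 8, byrow = TRUE,
                 dimnames = list(paste0("m", 1:3),
                                 sprintf("%s@%g", rep(strains, 4),
                                         rep(tps, each = 2))))
  pm <- list(values = vals, rep_values = NULL, strains = strains,
             timepoints_h = tps, design = design,
             degenerate = stats::setNames(rep(FALSE, 3), rownames(vals)),
             pseudocount = 1)
  class(pm) <- "profile_matrix"
  prof <- cluster_mean_profile(pm, paste0("m", 1:3))
  expect_equal(unique(prof$slope), 0.1, tolerance = 1e-12)
  expect_equal(unique(prof$intercept), 0, tolerance = 1e-12)
  expect_true(all(abs(prof$upr - prof$lwr) < 1e-9))

  # CI half-widths shrink with member count
  set.seed(9)
  noisy <- function(k) {
    m <- t(sapply(seq_len(k), function(i)
      0.1 * rep(tps, each = 2) + rnorm(8, 0, 0.3)))
    rownames(m) <- paste0("x", seq_len(k)); colnames(m) <- colnames(vals)
    m
  }
  pm2 <- pm; pm2$values <- noisy(2)
  pm2$degenerate <- stats::setNames(rep(FALSE, 2), rownames(pm2$values))
  pm20 <- pm; pm20$values <- noisy(20)
  pm20$degenerate <- stats::setNames(rep(FALSE, 20), rownames(pm20$values))
  w2 <- mean(with(cluster_mean_profile(pm2, rownames(pm2$values)),
                  upr - lwr))
  w20 <- mean(with(cluster_mean_profile(pm20, rownames(pm20$values)),
                   upr - lwr))
  expect_lt(w20, w2)
})
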