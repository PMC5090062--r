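#' Simulate miRNA read counts with ground truth
#'
#' Draws negative-binomial counts for every mature miRNA in every sample
#' of the strain x timepoint x replicate design. Expression means are
#' built on a log2 scale:
#'
#' Class effects are drawn per hairpin (both arms of a hairpin share
#' them, as expected for effects acting on the primary transcript):
#'
#' * class #1 hairpins receive strain-specific control offsets (a shuffled
#'   symmetric spread of magnitude `level_effect_log2`) that vanish at the
#'   early recovery timepoints — all strains converge to the common level —
#'   and return `recovery_frac` of the way toward the strain baseline at
#'   the last timepoint;
#' * class #2 hairpins share the control mean and diverge between strains
#'   at the intermediate recovery timepoints, retaining
#'   `class2_recovery_frac` of the divergence at the last timepoint;
#' * matures of a polycistronic cluster share a per-cluster primary-
#'   transcript log2 fold-change trajectory plus independent per-mature
#'   deviations (identical across strains);
#' * arm-switch events add the configured per-arm log2 shifts.
#'
#' Per-sample expected totals are anchored at `depth` times a log-normal
#' (sdlog 0.1) size factor, so downstream normalisation has real work to
#' do. Counts are NB with variance mu + phi * mu^2 (Poisson when phi = 0).
#'
#' @param annotation `mirna_annotation` from [generate_annotation()].
#' @param params [sim_params()] object.
#' @return list with `counts` (a [count_matrix()]) and `truth` (class ids,
#'   cluster membership, per-condition expected mean counts at nominal
#'   depth, class offsets, the event tables).
#' @export
simulate_counts <- function(annotation, params) {
  validate_sim_params(params)
  if (params$depth <= 0) stopf("zero depth")
  if (params$dispersion < 0) stopf("dispersion must be >= 0")
  set.seed(derive_seed(params$seed, "counts"))

  mat <- annotation$matures
  ids <- mat$id
  nm <- length(ids)
  strains <- params$strains
  tps <- params$timepoints_h
  ntp <- length(tps)

  design <- expand.grid(replicate = seq_len(params$replicates),
                        timepoint_h = tps, strain = strains,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("strain", "timepoint_h", "replicate")]
  design$sample <- sprintf("%s_t%g_r%d", design$strain, design$timepoint_h,
                           design$replicate)
  design <- design[, c("sample", "strain", "timepoint_h", "replicate")]

  base <- runif(nm, log2(50), log2(4000))
  names(base) <- ids
  # arm-switch hairpins start from a miR-14-like configuration: the 5p
  # arm clearly dominant, the 3p arm near the detection floor, so a
  # strain-specific 3p induction flips dominance in that strain only
  for (h in unique(params$arm_switch_events$hairpin)) {
    m5 <- mat$id[mat$hairpin_id == h & mat$arm == "5p"]
    m3 <- mat$id[mat$hairpin_id == h & mat$arm == "3p"]
    if (length(m5)) base[m5] <- log2(2000)
    if (length(m3)) base[m3] <- log2(1.5)
  }
  delta <- array(0, dim = c(nm, length(strains), ntp),
                 dimnames = list(ids, strains, paste0("t", tps)))

  hp_of <- mat$hairpin_id
  names(hp_of) <- ids
  clustered_hp <- annotation$hairpins$id[!is.na(annotation$hairpins$cluster_id)]
  switch_hp <- unique(params$arm_switch_events$hairpin)
  eligible_hp <- setdiff(annotation$hairpins$id, c(clustered_hp, switch_hp))

  # class effects act on the primary transcript: both arms of a chosen
  # hairpin share the strain offsets
  nh <- nrow(annotation$hairpins)
  n1 <- round(params$frac_class1 * nh)
  n2 <- round(params$frac_class2 * nh)
  if (n1 + n2 > length(eligible_hp))
    stopf("class fractions too large for the unclustered hairpin pool")
  hp1 <- sample(eligible_hp, n1)
  hp2 <- sample(setdiff(eligible_hp, hp1), n2)
  class1 <- ids[hp_of %in% hp1]
  class2 <- ids[hp_of %in% hp2]

  spread <- function(k) sample(seq(-1, 1, length.out = k))
  post_mid <- which(tps > 0 & tps < max(tps))
  post_last <- which(tps == max(tps))

  off1 <- matrix(0, length(class1), length(strains),
                 dimnames = list(class1, strains))
  for (h in hp1) {
    off <- params$level_effect_log2 * spread(length(strains))
    for (m in ids[hp_of == h]) {
      off1[m, ] <- off
      delta[m, , 1] <- off
      delta[m, , post_last] <- params$recovery_frac * off
    }
  }
  off2 <- matrix(0, length(class2), length(strains),
                 dimnames = list(class2, strains))
  for (h in hp2) {
    div <- params$level_effect_log2 * spread(length(strains))
    for (m in ids[hp_of == h]) {
      off2[m, ] <- div
      for (j in post_mid) delta[m, , j] <- div
      delta[m, , post_last] <- params$class2_recovery_frac * div
    }
  }

  cluster_of <- annotation$hairpins$cluster_id[
    match(mat$hairpin_id, annotation$hairpins$id)]
  names(cluster_of) <- ids
  for (k in unique(stats::na.omit(cluster_of))) {
    traj <- c(0, rnorm(ntp - 1, 0, 1.2))      # shared pri-miRNA trajectory
    members <- ids[!is.na(cluster_of) & cluster_of == k]
    for (m in members) {
      dev <- c(0, rnorm(ntp - 1, 0, 0.25))    # per-mature deviation
      for (j in seq_len(ntp)) delta[m, , j] <- delta[m, , j] + traj[j] + dev[j]
    }
  }

  ev <- params$arm_switch_events
  if (!is.null(ev) && nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      mid <- mat$id[mat$hairpin_id == ev$hairpin[i] & mat$arm == ev$arm[i]]
      if (!length(mid)) stopf("arm-switch event names unknown hairpin/arm %s/%s",
                              ev$hairpin[i], ev$arm[i])
      ss <- if (is.na(ev$strain[i])) strains else ev$strain[i]
      j <- match(ev$timepoint_h[i], tps)
      if (is.na(j)) stopf("arm-switch event at unknown timepoint %g",
                          ev$timepoint_h[i])
      delta[mid, ss, j] <- delta[mid, ss, j] + ev$delta_log2[i]
    }
  }

  # expected counts: per condition, renormalise feature weights to depth
  mu_cond <- array(0, dim = dim(delta), dimnames = dimnames(delta))
  for (s in seq_along(strains)) for (j in seq_len(ntp)) {
    w <- 2^(base + delta[, s, j])
    mu_cond[, s, j] <- params$depth * w / sum(w)
  }

  sf <- rlnorm(nrow(design), 0, 0.1)
  names(sf) <- design$sample
  counts <- matrix(0L, nm, nrow(design), dimnames = list(ids, design$sample))
  for (i in seq_len(nrow(design))) {
    mu <- mu_cond[, match(design$strain[i], strains),
                  match(design$timepoint_h[i], tps)] * sf[i]
    counts[, i] <- if (params$dispersion > 0)
      rnbinom(nm, mu = mu, size = 1 / params$dispersion)
    else stats::rpois(nm, mu)
  }

  truth <- list(
    class1_ids = class1, class2_ids = class2,
    cluster_membership = cluster_of[!is.na(cluster_of)],
    class1_offsets = off1, class2_offsets = off2,
    mean_counts = mu_cond, size_factors = sf,
    arm_switch_events = ev, editing_sites = params$editing_sites,
    strains = strains, timepoints_h = tps
  )
  list(counts = count_matrix(counts, design), truth = truth)
}
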