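#' Simulation parameters for the synthetic heat-shock miRNA study
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the study design the pipeline targets: three fly strains, a control
#' sample at 25 degrees C plus 1 h, 6 h and 24 h heat-shock recovery
#' timepoints, two biological replicates, and deeply sequenced small-RNA
#' libraries. A subset of miRNAs carries strain-specific control baselines
#' that converge to a common level right after heat shock ("class #1",
#' levelled miRNAs); a second subset shares control levels but diverges
#' between strains during recovery ("class #2"). Polycistronic clusters
#' share a primary-transcript fold-change trajectory.
#'
#' @param n_mirnas number of hairpins (each contributes a 5p and a 3p
#'   mature miRNA).
#' @param n_clusters number of polycistronic clusters.
#' @param cluster_size_range integer pair, hairpins per cluster.
#' @param strains character vector of strain identifiers.
#' @param timepoints_h ordered numeric hours; first must be 0 (control).
#' @param replicates replicates per (strain, timepoint).
#' @param depth expected library size in reads.
#' @param dispersion negative-binomial dispersion phi >= 0
#'   (variance = mu + phi * mu^2).
#' @param frac_class1 fraction of matures with strain-specific control
#'   baselines levelled after heat shock.
#' @param frac_class2 fraction of matures diverging only after heat shock.
#' @param level_effect_log2 magnitude of the interstrain control offset
#'   (log2 units) for class #1, and of the post-shock divergence for
#'   class #2.
#' @param recovery_frac fraction of the class #1 control offset restored
#'   at 24 h (0.7: strain differences largely reappear late in recovery).
#' @param class2_recovery_frac fraction of the class #2 divergence still
#'   present at 24 h.
#' @param arm_switch_events data.frame with columns `hairpin`, `arm`
#'   ("5p"/"3p"), `strain` (NA = every strain), `timepoint_h`,
#'   `delta_log2`: additive log2 shifts of single-arm means that create
#'   arm-switching patterns. NULL for none.
#' @param editing_sites data.frame with columns `mature_id`, `position`
#'   (1-based on the mature, 5' to 3'), `type` ("A>G" or "T>C"),
#'   `frequency`. NULL for none.
#' @param seq_error_rate per-base background mismatch probability in
#'   simulated reads.
#' @param seed integer RNG seed; mandatory, no implicit entropy.
#' @return object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_mirnas = 120,
                       n_clusters = 3,
                       cluster_size_range = c(2L, 4L),
                       strains = c("w1118", "hsp70d", "yw"),
                       timepoints_h = c(0, 1, 6, 24),
                       replicates = 2,
                       depth = 2e6,
                       dispersion = 0.1,
                       frac_class1 = 0.1,
                       frac_class2 = 0.1,
                       level_effect_log2 = 2,
                       recovery_frac = 0.7,
                       class2_recovery_frac = 0.3,
                       arm_switch_events = NULL,
                       editing_sites = NULL,
                       seq_error_rate = 0.001,
                       seed) {
  if (missing(seed)) stopf("sim_params: 'seed' is mandatory")
  p <- list(
    n_mirnas = as.integer(n_mirnas), n_clusters = as.integer(n_clusters),
    cluster_size_range = as.integer(cluster_size_range),
    strains = as.character(strains), timepoints_h = as.numeric(timepoints_h),
    replicates = as.integer(replicates), depth = depth,
    dispersion = dispersion, frac_class1 = frac_class1,
    frac_class2 = frac_class2, level_effect_log2 = level_effect_log2,
    recovery_frac = recovery_frac,
    class2_recovery_frac = class2_recovery_frac,
    arm_switch_events = arm_switch_events, editing_sites = editing_sites,
    seq_error_rate = seq_error_rate, seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_mirnas < 2) stopf("n_mirnas must be >= 2")
  if (p$dispersion < 0) stopf("dispersion must be >= 0")
  if (p$depth <= 0) stopf("depth must be > 0")
  if (p$frac_class1 < 0 || p$frac_class1 > 1 ||
      p$frac_class2 < 0 || p$frac_class2 > 1 ||
      p$frac_class1 + p$frac_class2 > 1)
    stopf("class fractions must lie in [0,1] and sum to <= 1")
  tp <- p$timepoints_h
  if (length(tp) < 2 || tp[1] != 0 || any(diff(tp) <= 0))
    stopf("timepoints_h must be strictly increasing and start at 0")
  if (length(p$cluster_size_range) != 2 ||
      p$cluster_size_range[1] < 2 ||
      p$cluster_size_range[1] > p$cluster_size_range[2])
    stopf("cluster_size_range must be an increasing pair with min >= 2")
  if (p$n_clusters * p$cluster_size_range[2] > p$n_mirnas)
    stopf("clusters do not fit: %d clusters of up to %d hairpins > %d hairpins",
          p$n_clusters, p$cluster_size_range[2], p$n_mirnas)
  if (p$seq_error_rate < 0 || p$seq_error_rate > 1)
    stopf("seq_error_rate must lie in [0,1]")
  if (length(p$strains) < 2) stopf("need at least two strains")
  invisible(p)
}

#' Default arm-switch events mimicking a strain-specific switch
#'
#' The canonical pattern: the 5p arm drops at 1 h in every strain while the
#' 3p arm rises at 1 h in a single strain, flipping arm dominance there
#' only.
#'
#' @param hairpin hairpin id carrying the event.
#' @param strain strain in which the 3p arm is induced.
#' @return data.frame in the `arm_switch_events` layout of [sim_params()].
#' @export
default_arm_switch <- function(hairpin = "sim-mir-1", strain = "w1118") {
  data.frame(
    hairpin = hairpin, arm = c("5p", "3p"),
    strain = c(NA, strain), timepoint_h = 1,
    delta_log2 = c(-1.5, 2.5), stringsAsFactors = FALSE
  )
}

#' Default editing sites (outside the seed region)
#'
#' @return data.frame in the `editing_sites` layout of [sim_params()].
#' @export
default_editing_sites <- function() {
  data.frame(
    mature_id = c("sim-miR-2-5p", "sim-miR-3-3p"),
    position = c(12L, 15L), type = c("A>G", "T>C"),
    frequency = c(0.3, 0.3), stringsAsFactors = FALSE
  )
}
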