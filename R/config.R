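#' Analysis configuration
#'
#' Bundles the statistical thresholds used throughout the pipeline. Defaults
#' follow the published HIPHOP analysis conventions: one-tailed standard
#' normal P <= 0.001 for significant chemical-genetic interactions (fitness
#' defect, FD, of at least \eqn{\Phi^{-1}(0.999) \approx 3.09}), a gene-wise
#' z cutoff of -5 for the replicate-adjusted (NIBR-style) scores in their
#' native sensitivity-negative orientation, and a clearance threshold of 5.75
#' for designating HIP hits.
#'
#' @param alpha_significant One-tailed normal P threshold for significant
#'   interactions (default 0.001).
#' @param alpha_signature_combined Relaxed threshold used for signature genes
#'   when two datasets are combined (default 0.05).
#' @param nibr_z_cutoff Gene-wise z cutoff in sensitivity-negative
#'   orientation; scores strictly below it are significant (default -5).
#' @param clearance_threshold Minimum clearance for a HIP hit (default 5.75).
#' @param top_variable_fraction Fraction of genes kept by
#'   [top_variable_genes()] (default 0.05).
#' @param quantile_window Central fraction of a strain's scores used to
#'   estimate its scale sigma (default 0.70, i.e. the 15th-85th percentiles).
#' @param min_shared_obs Minimum pairwise-complete observations for a Pearson
#'   correlation to be reported (default 30).
#' @param overlap_match_threshold Overlap coefficient at or above which a
#'   signature counts as detected in the other dataset (default 0.5).
#' @param mad_scaled Use the 1.4826 normal-consistency factor in MADs?
#'   Default `FALSE`: the robust-z convention divides by the raw MAD.
#' @param clearance_positive_only Restrict clearance gaps to strains with
#'   FD > 0 (default `TRUE`).
#' @param random_seed Integer seed recorded in manifests.
#'
#' @return A list of class `analysis_config`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$clearance_threshold
analysis_config <- function(alpha_significant = 0.001,
                            alpha_signature_combined = 0.05,
                            nibr_z_cutoff = -5,
                            clearance_threshold = 5.75,
                            top_variable_fraction = 0.05,
                            quantile_window = 0.70,
                            min_shared_obs = 30,
                            overlap_match_threshold = 0.5,
                            mad_scaled = FALSE,
                            clearance_positive_only = TRUE,
                            random_seed = 1L) {
  for (p in c("alpha_significant", "alpha_signature_combined",
              "quantile_window", "top_variable_fraction",
              "overlap_match_threshold")) {
    v <- get(p)
    stopifnot_scalar_number(v, p)
    if (v <= 0 || v > 1) abort(sprintf("`%s` must lie in (0, 1].", p))
  }
  stopifnot_scalar_number(clearance_threshold, "clearance_threshold",
                          positive = TRUE)
  stopifnot_scalar_number(nibr_z_cutoff, "nibr_z_cutoff")
  stopifnot_scalar_number(min_shared_obs, "min_shared_obs", positive = TRUE)
  structure(
    list(
      alpha_significant = alpha_significant,
      alpha_signature_combined = alpha_signature_combined,
      nibr_z_cutoff = nibr_z_cutoff,
      clearance_threshold = clearance_threshold,
      top_variable_fraction = top_variable_fraction,
      quantile_window = quantile_window,
      min_shared_obs = min_shared_obs,
      overlap_match_threshold = overlap_match_threshold,
      mad_scaled = isTRUE(mad_scaled),
      clearance_positive_only = isTRUE(clearance_positive_only),
      random_seed = as.integer(random_seed)
    ),
    class = "analysis_config"
  )
}

#' Dynamic branch cut parameters
#'
#' Parameter presets mirror the published runs: `deep_split = 4,
#' min_cluster_size = 3` for the exhaustive pass; `deep_split = 2,
#' cut_height = 20, min_cluster_size = 3` for the consolidated pass; and
#' `min_gap = 0.098, deep_split = 2, min_cluster_size = 3` for the combined
#' two-dataset matrix.
#'
#' @param deep_split Integer 0-4; larger values split more aggressively.
#' @param min_cluster_size Minimum members for a cluster (>= 2, default 3).
#' @param cut_height Optional absolute merge-height ceiling; branches joining
#'   above it are never in the same cluster. Default: the 99th percentile of
#'   merge heights.
#' @param min_gap Optional fraction (0, 1) of the dendrogram height range; a
#'   branch is split where the merge-height drop exceeds it. Default derived
#'   from `deep_split`.
#'
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(deep_split = 2,
                           min_cluster_size = 3,
                           cut_height = NULL,
                           min_gap = NULL) {
  if (!deep_split %in% 0:4) abort("`deep_split` must be an integer in 0..4.")
  if (!is.numeric(min_cluster_size) || min_cluster_size < 2) {
    abort("`min_cluster_size` must be >= 2.")
  }
  if (!is.null(cut_height)) {
    stopifnot_scalar_number(cut_height, "cut_height")
  }
  if (!is.null(min_gap)) {
    stopifnot_scalar_number(min_gap, "min_gap")
    if (min_gap <= 0 || min_gap >= 1) abort("`min_gap` must lie in (0, 1).")
  }
  structure(
    list(
      deep_split = as.integer(deep_split),
      min_cluster_size = as.integer(min_cluster_size),
      cut_height = cut_height,
      min_gap = min_gap
    ),
    class = "cluster_params"
  )
}
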