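#' Study configuration
#'
#' Bundles file paths, analysis thresholds and the master random seed for a
#' multi-species heat-stress study. Thresholds default to the values used
#' throughout the package: consensus fold-change cut 2 (log2), consensus
#' FDR cut 1e-3, Monte-Carlo overlap alpha 0.01 with 10,000 iterations,
#' survival decline thresholds 0.90/0.05, and response-profile cut points
#' 0.3% / 5% of the transcriptome.
#'
#' @param survival_path,counts_paths,sample_meta_paths,annotation_paths,orthogroups_path,species_meta_path
#'   optional file paths; `counts_paths`, `sample_meta_paths` and
#'   `annotation_paths` are named by species.
#' @param fc_cut minimum mean absolute log2 fold change for the consensus
#'   differential-expression filter.
#' @param fdr_cut maximum Benjamini-Hochberg FDR in both callers.
#' @param overlap_alpha significance level for the resampling overlap test.
#' @param mc_iterations Monte-Carlo iterations for the overlap null.
#' @param survival_upper,survival_lower mean-survival thresholds defining
#'   the decline width.
#' @param profile_cuts length-2 numeric, percentage cut points separating
#'   weak / medium / strong response profiles.
#' @param utl_alpha significance level for the Tukey comparisons defining
#'   the upper thermal limit.
#' @param seed master random seed; per-stage seeds are derived from it by
#'   [stage_seed()].
#' @return an object of class `study_config` (a validated list).
#' @export
study_config <- function(survival_path = NULL,
                         counts_paths = NULL,
                         sample_meta_paths = NULL,
                         annotation_paths = NULL,
                         orthogroups_path = NULL,
                         species_meta_path = NULL,
                         fc_cut = 2,
                         fdr_cut = 1e-3,
                         overlap_alpha = 0.01,
                         mc_iterations = 10000L,
                         survival_upper = 0.90,
                         survival_lower = 0.05,
                         profile_cuts = c(0.3, 5.0),
                         utl_alpha = 0.05,
                         seed = 1L) {
  thr <- c(fc_cut = fc_cut, fdr_cut = fdr_cut, overlap_alpha = overlap_alpha,
           mc_iterations = mc_iterations, survival_upper = survival_upper,
           survival_lower = survival_lower, utl_alpha = utl_alpha,
           profile_cuts)
  if (any(!is.finite(thr)) || any(thr <= 0))
    stop("all thresholds must be positive and finite")
  if (mc_iterations < 1) stop("mc_iterations must be >= 1")
  if (length(profile_cuts) != 2L || profile_cuts[1] >= profile_cuts[2])
    stop("profile_cuts must be two increasing percentages")
  if (survival_lower >= survival_upper)
    stop("survival_lower must be below survival_upper")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(
    survival_path = survival_path, counts_paths = counts_paths,
    sample_meta_paths = sample_meta_paths,
    annotation_paths = annotation_paths,
    orthogroups_path = orthogroups_path,
    species_meta_path = species_meta_path,
    fc_cut = fc_cut, fdr_cut = fdr_cut, overlap_alpha = overlap_alpha,
    mc_iterations = as.integer(mc_iterations),
    survival_upper = survival_upper, survival_lower = survival_lower,
    profile_cuts = profile_cuts, utl_alpha = utl_alpha, seed = seed),
    class = "study_config")
}

# Fixed stage vocabulary for deterministic per-stage seed derivation.
.antherm_stages <- c("survival", "transcriptomes", "counts", "orthogroups",
                     "overlap", "de", "audit", "misc")

#' Derive a per-stage seed from the master seed
#'
#' Each simulation or resampling stage uses its own seed derived
#' deterministically from the master seed, so a stage can be regenerated
#' independently of the others. The derivation is
#' `(seed + 97561 * (index(stage) + offset)) mod (2^31 - 1)`, with stages
#' indexed in a fixed internal vocabulary; results always fit a 32-bit
#' integer.
#'
#' @param seed master integer seed.
#' @param stage one of `"survival"`, `"transcriptomes"`, `"counts"`,
#'   `"orthogroups"`, `"overlap"`, `"de"`, `"audit"`, `"misc"`.
#' @param offset optional non-negative integer distinguishing repeated
#'   uses of a stage (one per species, say).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage, offset = 0L) {
  stage <- match.arg(stage, .antherm_stages)
  idx <- match(stage, .antherm_stages)
  s <- (as.numeric(seed) + 97561 * (idx + 16 * as.numeric(offset))) %% 2147483647
  as.integer(s)
}
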