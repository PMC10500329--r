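# End-to-end analysis of a multi-species study: thermal tolerance,
# expression response, cross-species overlap and orthology.

#' Run the full comparative heat-stress analysis
#'
#' Executes every stage on a study bundle (simulated via
#' [simulate_study()] or assembled from files): per-species dose-response
#' fits, UTL and decline width; TMM normalization, the two-caller
#' consensus differential-expression filter (built-in NB test + edgeR
#' exact test), HSP panel, response profile and strategy call;
#' cross-species unique-name overlap with the Monte-Carlo resampling
#' null; orthogroup classification with restricted-gene enrichment and
#' the orthology summary; plus the transcriptome-size vs DET-count
#' correlation.
#'
#' @param study an `antherm_study`.
#' @param config a [study_config()]; its `seed` drives the resampling
#'   stages.
#' @param callers two differential-expression callers to intersect.
#' @param verbose log one line per stage.
#' @return an object of class `antherm_results`.
#' @export
run_study <- function(study, config = study_config(seed = study$seed),
                      callers = c("builtin", "edger"), verbose = FALSE) {
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) {
    if (verbose)
      message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0)),
              sprintf(fmt, ...))
  }
  ids <- study$species_meta$species
  habitats <- setNames(study$species_meta$habitat, ids)

  # --- thermal tolerance ---------------------------------------------
  thermal <- lapply(ids, function(sp) {
    obs <- study$survival[study$survival$species == sp, , drop = FALSE]
    list(fit = fit_dose_response(obs),
         utl = determine_utl(obs, alpha = config$utl_alpha),
         decline = decline_width(obs, config$survival_upper,
                                 config$survival_lower))
  })
  names(thermal) <- ids
  log_stage("thermal tolerance: %d species, %d observations", length(ids),
            nrow(study$survival))

  # --- expression response -------------------------------------------
  expression <- lapply(ids, function(sp) {
    cm <- study$counts[[sp]]
    factors <- tmm_factors(cm)
    norm <- normalize_tmm(cm, factors)
    tab_a <- run_de(cm, callers[1])
    tab_b <- run_de(cm, callers[2])
    cons <- consensus_det(tab_a, tab_b, config$fc_cut, config$fdr_cut)
    panel <- suppressWarnings(
      find_hsp_transcripts(study$catalogs[[sp]], norm, cons))
    prof <- classify_profile(nrow(cons$det), nrow(study$catalogs[[sp]]),
                             config$profile_cuts)
    strat <- call_strategy(prof, habitats[[sp]], panel,
                           thermal[[sp]]$decline)
    list(factors = factors, consensus = cons, hsp = panel,
         profile = prof, strategy = strat)
  })
  names(expression) <- ids
  log_stage("expression: consensus DET per species = %s",
            paste(vapply(expression, function(e) nrow(e$consensus$det),
                         0L), collapse = "/"))

  # --- cross-species overlap -----------------------------------------
  det_ids <- lapply(expression, function(e) e$consensus$det$transcript_id)
  pairs <- utils::combn(ids, 2)
  overlap <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    resampling_null(study$catalogs[[a]], study$catalogs[[b]],
                    det_a = det_ids[[a]], det_b = det_ids[[b]],
                    iterations = config$mc_iterations,
                    seed = stage_seed(config$seed, "overlap",
                                      which(ids == a) * 8 +
                                        which(ids == b)),
                    alpha = config$overlap_alpha)
  })
  pair_table <- data.frame(
    species_a = pairs[1, ], species_b = pairs[2, ],
    observed = vapply(overlap, function(o) as.integer(o$observed), 0L),
    null_mean = vapply(overlap, `[[`, 0, "null_mean"),
    null_sd = vapply(overlap, `[[`, 0, "null_sd"),
    p = vapply(overlap, `[[`, 0, "p"),
    significant = vapply(overlap, `[[`, NA, "significant"),
    stringsAsFactors = FALSE)
  log_stage("overlap: %d pairs x %d iterations", ncol(pairs),
            config$mc_iterations)

  sizes <- vapply(ids, function(sp) nrow(study$catalogs[[sp]]), 0L)
  det_counts <- vapply(det_ids, length, 0L)[ids]
  correlation <- correlate_size_det(sizes, det_counts)

  # --- orthology ------------------------------------------------------
  assignments <- classify_orthogroups(study$og_table, study$species_meta)
  status <- lapply(ids, function(sp)
    gene_status(assignments, study$og_table, sp, study$species_meta,
                study$catalogs[[sp]]))
  names(status) <- ids
  enrichment <- lapply(ids, function(sp)
    suppressWarnings(restricted_enrichment(status[[sp]], det_ids[[sp]],
                                           species = sp)))
  names(enrichment) <- ids
  ortho_summary <- summarize_orthology(study$og_table, study$catalogs)
  log_stage("orthology: %d orthogroups, %d categories",
            length(study$og_table$orthogroups),
            length(unique(assignments$category)))

  species_table <- data.frame(
    species = ids,
    habitat = unname(habitats[ids]),
    lt50 = vapply(thermal, function(t) t$fit$lt50, 0)[ids],
    se_lt50 = vapply(thermal, function(t) t$fit$se_lt50, 0)[ids],
    utl = vapply(thermal, function(t) t$utl$utl, 0)[ids],
    decline_width = vapply(thermal, function(t) t$decline$width, 0)[ids],
    det_count = det_counts,
    transcriptome_size = sizes,
    det_fraction = vapply(expression, function(e)
      e$profile$det_fraction, 0)[ids],
    profile = vapply(expression, function(e) e$profile$profile, "")[ids],
    strategy = vapply(expression, function(e)
      e$strategy$strategy, "")[ids],
    stringsAsFactors = FALSE)
  rownames(species_table) <- NULL

  structure(list(
    config = config, species_list = ids, thermal = thermal,
    expression = expression, overlap = list(tests = overlap,
                                            pairs = pair_table),
    correlation = correlation,
    orthology = list(assignments = assignments, status = status,
                     enrichment = enrichment, summary = ortho_summary),
    species_table = species_table,
    thermal_report = lapply(thermal, function(t) list(
      lt50 = t$fit$lt50, se_lt50 = t$fit$se_lt50, ci95 = t$fit$ci95,
      method = t$fit$method, utl = t$utl$utl,
      decline_width = t$decline$width)),
    expression_report = lapply(expression, function(e) list(
      det_count = nrow(e$consensus$det), n_up = e$consensus$n_up,
      n_down = e$consensus$n_down, profile = e$profile$profile,
      det_fraction = e$profile$det_fraction,
      strategy = e$strategy$strategy)),
    overlap_report = list(pairs = pair_table,
                          correlation = list(r = correlation$r,
                                             p = correlation$p)),
    orthology_report = list(
      category_counts = as.list(table(assignments$category)),
      totals = ortho_summary$totals,
      enrichment = lapply(enrichment, function(e) list(
        odds_ratio = e$odds_ratio, p = e$p, direction = e$direction)))),
    class = "antherm_results")
}

#' @export
print.antherm_results <- function(x, ...) {
  cat("Comparative heat-stress study results\n")
  print(x$species_table, digits = 4)
  cat(sprintf("\nSize~DET correlation: r = %.3f (p = %.3g)\n",
              x$correlation$r, x$correlation$p))
  invisible(x)
}

#' Assemble a study bundle from files
#'
#' Reads every input named in a [study_config()] and returns the same
#' `antherm_study` structure [simulate_study()] produces (without ground
#' truth).
#'
#' @param config a `study_config` with all paths set.
#' @return an `antherm_study` (with `truth = NULL`).
#' @export
read_study <- function(config) {
  species_meta <- read_species_meta(config$species_meta_path)
  ids <- species_meta$species
  catalogs <- lapply(ids, function(sp)
    read_annotations(config$annotation_paths[[sp]], sp))
  names(catalogs) <- ids
  counts <- lapply(ids, function(sp)
    read_counts(config$counts_paths[[sp]],
                config$sample_meta_paths[[sp]]))
  names(counts) <- ids
  structure(list(
    specs = NULL, species_meta = species_meta,
    survival = read_survival_table(config$survival_path),
    catalogs = catalogs, counts = counts,
    og_table = read_orthogroups(config$orthogroups_path, ids),
    truth = NULL, seed = config$seed), class = "antherm_study")
}
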