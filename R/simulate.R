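# Synthetic multi-species heat-stress studies with known ground truth.
# The default study emulates a six-species desert/temperate comparison
# (two subfamilies, three desert genera) at 1/20 transcriptome scale.

#' Simulation specification for one species
#'
#' @param species_id short species label.
#' @param subfamily `"Formicinae"` or `"Myrmicinae"`.
#' @param genus genus name (two same-genus species enable the
#'   genus-restricted orthogroup category).
#' @param habitat `"desert"` or `"temperate"`.
#' @param true_lt50 true median lethal temperature (degrees C).
#' @param logit_slope logistic slope of death probability per degree C
#'   (positive; ~4 gives a two-degree 100%-to-0% survival decline, ~0.8 a
#'   six-degree decline).
#' @param transcriptome_size number of transcripts in the reference
#'   catalog.
#' @param unique_name_count number of distinct meaningful annotation
#'   names in the catalog.
#' @param shared_pool_fraction proportion of names drawn from the
#'   cross-species shared (conserved) pool.
#' @param uncharacterized_fraction proportion of transcripts annotated
#'   "uncharacterized protein".
#' @param strategy `"constitutive"`, `"reactive"` or `"temperate_like"`.
#' @param n_stress_genes number of stress-responsive transcripts
#'   (HSP-like archetypes).
#' @param induced_log2fc heat-induced log2 fold change for reactive /
#'   temperate-like stress genes (>= 0).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of
#'   gene-wise baseline means.
#' @param dispersion common negative-binomial dispersion of counts.
#' @param constitutive_lift multiplicative elevation of stress-gene means
#'   in *both* conditions for the constitutive strategy.
#' @return a validated `species_sim_spec`.
#' @export
species_sim_spec <- function(species_id, subfamily, genus, habitat,
                             true_lt50, logit_slope,
                             transcriptome_size = 2000L,
                             unique_name_count = round(0.6 * transcriptome_size),
                             shared_pool_fraction = 0.7,
                             uncharacterized_fraction = 0.25,
                             strategy = c("reactive", "constitutive",
                                          "temperate_like"),
                             n_stress_genes = 50L,
                             induced_log2fc = 3,
                             baseline_meanlog = 4,
                             baseline_sdlog = 1.5,
                             dispersion = 0.1,
                             constitutive_lift = 8) {
  strategy <- match.arg(strategy)
  fr <- c(shared_pool_fraction, uncharacterized_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (logit_slope <= 0) stop("logit_slope must be positive")
  if (induced_log2fc < 0) stop("induced_log2fc must be >= 0")
  if (transcriptome_size < unique_name_count)
    stop("transcriptome_size must be at least unique_name_count")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(species_id = species_id, subfamily = subfamily,
                 genus = genus, habitat = habitat,
                 true_lt50 = true_lt50, logit_slope = logit_slope,
                 transcriptome_size = as.integer(transcriptome_size),
                 unique_name_count = as.integer(unique_name_count),
                 shared_pool_fraction = shared_pool_fraction,
                 uncharacterized_fraction = uncharacterized_fraction,
                 strategy = strategy,
                 n_stress_genes = as.integer(n_stress_genes),
                 induced_log2fc = induced_log2fc,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 constitutive_lift = constitutive_lift),
            class = "species_sim_spec")
}

#' Default six-species study specifications
#'
#' Four desert species (three genera, two survival archetypes) and two
#' temperate outgroups across the Formicinae and Myrmicinae subfamilies.
#' True LT50s, response strategies, decline steepness and relative
#' transcriptome sizes mirror a published six-species ant comparison;
#' transcriptomes are scaled down (default 1/20) for desk-scale runtime,
#' with stress-gene counts scaled alongside.
#'
#' @param scale transcriptome scale factor relative to the full-size
#'   study.
#' @return named list of `species_sim_spec` objects, with the matching
#'   `species_meta` data.frame as attribute `species_meta`.
#' @export
default_study_specs <- function(scale = 1 / 20) {
  base <- data.frame(
    species_id = c("Cbom", "Chol", "Mbag", "Orob", "Ffus", "Msab"),
    subfamily = c("Formicinae", "Formicinae", "Formicinae", "Myrmicinae",
                  "Formicinae", "Myrmicinae"),
    genus = c("Cataglyphis", "Cataglyphis", "Melophorus", "Ocymyrmex",
              "Formica", "Myrmica"),
    habitat = c("desert", "desert", "desert", "desert", "temperate",
                "temperate"),
    true_lt50 = c(44.83, 46.0, 49.83, 46.8, 42.0, 39.91),
    logit_slope = c(0.8, 4.0, 5.0, 0.8, 4.0, 4.0),
    full_size = c(41912, 44525, 38726, 45701, 62416, 84784),
    full_det = c(253, 54, 53, 698, 4991, 10778),
    strategy = c("reactive", "constitutive", "constitutive", "reactive",
                 "temperate_like", "temperate_like"),
    stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(base)), function(i) {
    b <- base[i, ]
    n_stress <- if (b$strategy == "constitutive")
      max(20L, round(scale * 1000)) else max(5L, round(scale * b$full_det))
    species_sim_spec(
      species_id = b$species_id, subfamily = b$subfamily, genus = b$genus,
      habitat = b$habitat, true_lt50 = b$true_lt50,
      logit_slope = b$logit_slope,
      transcriptome_size = round(scale * b$full_size),
      strategy = b$strategy, n_stress_genes = n_stress)
  })
  names(specs) <- base$species_id
  attr(specs, "species_meta") <- new_species_meta(
    data.frame(species = base$species_id, subfamily = base$subfamily,
               genus = base$genus, habitat = base$habitat,
               stringsAsFactors = FALSE))
  specs
}

.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  expr
}

#' Simulate a heat-survival assay
#'
#' Per tube, the number of dead workers is
#' `Binomial(workers_per_tube, plogis(logit_slope * (T - true_lt50)))`,
#' i.e. a logistic death curve centered on the species' true LT50.
#'
#' @param spec a `species_sim_spec`.
#' @param temperatures assay temperatures (degrees C; default the
#'   standard 39-51 C series).
#' @param tubes_per_temp tubes per temperature.
#' @param workers_per_tube workers per tube.
#' @param seed integer seed.
#' @return a `survival_table`.
#' @export
simulate_survival <- function(spec, temperatures = seq(39, 51, by = 2),
                              tubes_per_temp = 6L, workers_per_tube = 10L,
                              seed = 1L) {
  if (workers_per_tube <= 0) stop("workers_per_tube must be positive")
  if (!length(temperatures)) stop("temperatures must be non-empty")
  if (spec$logit_slope <= 0) stop("logit_slope must be positive")
  .with_seed(seed, {
    p <- plogis(spec$logit_slope * (temperatures - spec$true_lt50))
    rows <- lapply(seq_along(temperatures), function(i) {
      data.frame(species = spec$species_id,
                 temperature = temperatures[i],
                 tube_id = paste0("tube", seq_len(tubes_per_temp)),
                 n_total = as.integer(workers_per_tube),
                 n_dead = rbinom(tubes_per_temp, workers_per_tube, p[i]),
                 stringsAsFactors = FALSE)
    })
    new_survival_table(do.call(rbind, rows))
  })
}

# Shared-pool name generator ("conserved protein NNNN"-style, with the
# chaperone families always first so every species carries them).
.shared_name_pool <- function(size) {
  stopifnot(size >= 2)
  c("Heat shock protein 70 cognate", "Heat shock protein 90 alpha",
    sprintf("conserved protein %05d", seq_len(size - 2)))
}

#' Simulate per-species annotation catalogs
#'
#' Each species' catalog has `transcriptome_size` rows. A stated fraction
#' of transcripts is annotated "uncharacterized protein"; the rest carry
#' names from the species' meaningful name set, which mixes draws from a
#' global shared pool (conserved genes, always including the HSP70 and
#' HSP90 family names) with species-private names, in proportion
#' `shared_pool_fraction`. Names are reused across transcripts (isoform
#' redundancy): every name appears at least once and surplus transcripts
#' resample names uniformly.
#'
#' @param specs list of `species_sim_spec` objects.
#' @param shared_pool_size size of the global shared name pool.
#' @param seed integer seed.
#' @return list with `catalogs` (named list of `annotation_catalog`) and
#'   `truth` (per-species name sets and the pairwise true shared-name
#'   count matrix).
#' @export
simulate_transcriptomes <- function(specs, shared_pool_size = 5000L,
                                    seed = 1L) {
  if (shared_pool_size < 1) stop("shared_pool_size must be >= 1")
  pool <- .shared_name_pool(shared_pool_size)
  .with_seed(seed, {
    name_sets <- list()
    catalogs <- list()
    for (spec in specs) {
      sp <- spec$species_id
      n_unchar <- round(spec$uncharacterized_fraction *
                          spec$transcriptome_size)
      n_named <- spec$transcriptome_size - n_unchar
      n_names <- min(spec$unique_name_count, n_named)
      n_shared <- round(spec$shared_pool_fraction * n_names)
      if (n_shared > shared_pool_size)
        stop(sprintf(
          "species '%s' requests %d shared names from a pool of %d",
          sp, n_shared, shared_pool_size))
      shared <- if (n_shared >= 2)
        c(pool[1:2], sample(pool[-(1:2)], n_shared - 2))
      else if (n_shared == 1) pool[1] else character()
      private <- sprintf("%s private protein %05d", sp,
                         seq_len(n_names - n_shared))
      names_sp <- c(shared, private)
      ann <- c(names_sp,
               if (n_named > n_names)
                 sample(names_sp, n_named - n_names, replace = TRUE),
               sprintf("uncharacterized protein %s-LOC%06d", sp,
                       seq_len(n_unchar)))
      ann <- sample(ann)  # shuffle transcript order
      catalogs[[sp]] <- new_annotation_catalog(
        data.frame(transcript_id = sprintf("%s_t%06d", sp,
                                           seq_along(ann)),
                   annotation = ann, stringsAsFactors = FALSE),
        species_id = sp)
      name_sets[[sp]] <- tolower(names_sp)
    }
    ids <- names(catalogs)
    shared_counts <- matrix(0L, length(ids), length(ids),
                            dimnames = list(ids, ids))
    for (i in seq_along(ids))
      for (j in seq_along(ids))
        shared_counts[i, j] <- length(intersect(name_sets[[i]],
                                                name_sets[[j]]))
    list(catalogs = catalogs,
         truth = list(name_sets = name_sets,
                      shared_names = shared_counts))
  })
}

#' Simulate an orthogroup table with known categories
#'
#' Draws orthogroups whose species-presence pattern realizes an assigned
#' taxonomic category (I all species, II Myrmicinae-only, III
#' Formicinae-only, IV the two same-genus *Cataglyphis*-like species, V
#' species-specific, plus cross-subfamily `mixed` patterns). Gene ids are
#' drawn from the species catalogs without reuse; each present species
#' contributes `1 + Poisson(genes_per_species_lambda)` genes.
#'
#' @param catalogs named list of `annotation_catalog` objects supplying
#'   gene ids.
#' @param species_meta a `species_meta`.
#' @param n_orthogroups number of orthogroups to draw.
#' @param category_mixture named proportions over
#'   `c("I","II","III","IV","V","mixed")`, summing to 1. The default
#'   mirrors a published six-species orthology table.
#' @param genes_per_species_lambda Poisson rate of extra genes per
#'   present species (isoform multiplicity).
#' @param seed integer seed.
#' @return list with `og_table` (an `orthogroup_table`) and `truth`
#'   (data.frame `orthogroup`, `category`).
#' @export
simulate_orthogroups <- function(catalogs, species_meta,
                                 n_orthogroups = 1700L,
                                 category_mixture = c(I = 0.256,
                                                      II = 0.031,
                                                      III = 0.010,
                                                      IV = 0.026,
                                                      V = 0.269,
                                                      mixed = 0.408),
                                 genes_per_species_lambda = 0.8,
                                 seed = 1L) {
  cats <- c("I", "II", "III", "IV", "V", "mixed")
  if (!all(names(category_mixture) %in% cats))
    stop("category_mixture names must be I, II, III, IV, V, mixed")
  mix <- setNames(numeric(length(cats)), cats)
  mix[names(category_mixture)] <- category_mixture
  if (abs(sum(mix) - 1) > 1e-8)
    stop("category_mixture must sum to 1")
  species <- species_meta$species
  myrm <- species[species_meta$subfamily == "Myrmicinae"]
  form <- species[species_meta$subfamily == "Formicinae"]
  genus_tab <- split(species, species_meta$genus)
  genus_pairs <- genus_tab[lengths(genus_tab) >= 2]
  if (mix["IV"] > 0 && !length(genus_pairs))
    stop("category IV requested but no genus has two or more species")
  catag <- if (length(genus_pairs)) genus_pairs[[1]] else character()
  if (mix["II"] > 0 && length(myrm) < 2)
    stop("category II requested but fewer than two Myrmicinae species")
  if (mix["III"] > 0 && length(form) < 2)
    stop("category III requested but fewer than two Formicinae species")
  .with_seed(seed, {
    pools <- lapply(catalogs, function(cc) sample(cc$transcript_id))
    cursor <- setNames(rep(1L, length(pools)), names(pools))
    draw_genes <- function(sp, n) {
      avail <- length(pools[[sp]]) - cursor[[sp]] + 1L
      if (avail < n)
        stop(sprintf(
          "species '%s' has too few unused genes for the requested orthogroups",
          sp))
      g <- pools[[sp]][cursor[[sp]]:(cursor[[sp]] + n - 1L)]
      cursor[[sp]] <<- cursor[[sp]] + n
      g
    }
    assigned <- sample(cats, n_orthogroups, replace = TRUE, prob = mix)
    rows <- vector("list", n_orthogroups)
    for (i in seq_len(n_orthogroups)) {
      cat_i <- assigned[i]
      present <- switch(
        cat_i,
        I = species,
        II = sample(myrm, 2 + sample.int(length(myrm) - 1, 1) - 1),
        III = {
          repeat {
            k <- 2 + sample.int(length(form) - 1, 1) - 1
            cand <- sample(form, k)
            if (!(length(catag) && setequal(cand, catag))) break
          }
          cand
        },
        IV = catag,
        V = sample(species, 1),
        mixed = {
          repeat {
            k <- sample(2:(length(species) - 1), 1)
            cand <- sample(species, k)
            if (any(cand %in% myrm) && any(cand %in% form)) break
          }
          cand
        })
      n_genes <- 1L + rpois(length(present), genes_per_species_lambda)
      genes <- unlist(lapply(seq_along(present), function(j)
        draw_genes(present[j], n_genes[j])), use.names = FALSE)
      rows[[i]] <- data.frame(
        orthogroup = sprintf("OG%07d", i),
        species = rep(present, n_genes), gene = genes,
        stringsAsFactors = FALSE)
    }
    # II with exactly the full Myrmicinae set of a 2-species subfamily is
    # fine; but a 1-species draw cannot happen (guarded above).
    long <- do.call(rbind, rows)
    og_ids <- sprintf("OG%07d", seq_len(n_orthogroups))
    list(og_table = new_orthogroup_table(long, species = species,
                                         orthogroups = og_ids),
         truth = data.frame(orthogroup = og_ids,
                            category = ifelse(assigned == "mixed",
                                              "mixed_partial", assigned),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate an RNA-seq count matrix with known differential expression
#'
#' Baseline gene means are log-normal
#' (`meanlog = baseline_meanlog`, `sdlog = baseline_sdlog`); counts are
#' negative binomial with common dispersion, library sizes varying
#' uniformly within +/-30%. Stress genes (HSP70/HSP90-annotated
#' transcripts first, then additional random transcripts up to
#' `n_stress_genes`) follow the species' strategy:
#'
#' * `reactive` / `temperate_like`: heat-stressed (HS) means shifted by
#'   `2^induced_log2fc`; these are the true DE genes.
#' * `constitutive`: means elevated by `constitutive_lift` in *both*
#'   conditions; no true DE.
#'
#' @param spec a `species_sim_spec`.
#' @param catalog the species' `annotation_catalog`.
#' @param reps_per_condition replicates per condition (>= 2).
#' @param seed integer seed.
#' @return list with `counts` (a `count_matrix`) and `truth` (data.frame
#'   `transcript_id`, `is_stress`, `true_de`, `true_log2fc`, plus the
#'   baseline means as attribute `mu`).
#' @export
simulate_counts <- function(spec, catalog, reps_per_condition = 4L,
                            seed = 1L) {
  if (reps_per_condition < 2L) stop("reps_per_condition must be >= 2")
  if (spec$dispersion <= 0) stop("dispersion must be positive")
  n <- nrow(catalog)
  .with_seed(seed, {
    mu <- rlnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)
    hsp_like <- grepl("heat shock protein", tolower(catalog$annotation),
                      fixed = TRUE)
    stress <- which(hsp_like)
    extra <- setdiff(sample.int(n), stress)
    stress <- c(stress, extra[seq_len(max(0, spec$n_stress_genes -
                                            length(stress)))])
    stress <- sort(stress[seq_len(min(length(stress),
                                      spec$n_stress_genes))])
    mu_nhs <- mu
    mu_hs <- mu
    true_fc <- numeric(n)
    if (spec$strategy == "constitutive") {
      mu_nhs[stress] <- mu_nhs[stress] * spec$constitutive_lift
      mu_hs[stress] <- mu_hs[stress] * spec$constitutive_lift
    } else {
      mu_hs[stress] <- mu_hs[stress] * 2^spec$induced_log2fc
      true_fc[stress] <- spec$induced_log2fc
    }
    conds <- rep(c("HS", "NHS"), each = reps_per_condition)
    lib_fac <- runif(length(conds), 0.7, 1.3)
    counts <- vapply(seq_along(conds), function(s) {
      m_s <- (if (conds[s] == "HS") mu_hs else mu_nhs) * lib_fac[s]
      as.numeric(rnbinom(n, size = 1 / spec$dispersion, mu = m_s))
    }, numeric(n))
    storage.mode(counts) <- "integer"
    samples <- sprintf("%s_%s_%d", spec$species_id, conds,
                       rep(seq_len(reps_per_condition), 2))
    dimnames(counts) <- list(catalog$transcript_id, samples)
    meta <- data.frame(sample = samples, condition = conds,
                       replicate = rep(seq_len(reps_per_condition), 2),
                       stringsAsFactors = FALSE)
    truth <- data.frame(transcript_id = catalog$transcript_id,
                        is_stress = seq_len(n) %in% stress,
                        true_de = spec$strategy != "constitutive" &
                          seq_len(n) %in% stress,
                        true_log2fc = true_fc, stringsAsFactors = FALSE)
    attr(truth, "mu") <- mu
    list(counts = new_count_matrix(counts, meta), truth = truth)
  })
}

#' Simulate a complete multi-species study
#'
#' Runs every generator with per-stage seeds derived from the master
#' seed, audits the emitted objects against the recorded ground truth,
#' and returns the bundle the analysis pipeline ([run_study()]) consumes.
#'
#' @param specs list of `species_sim_spec` (default
#'   [default_study_specs()]).
#' @param seed master integer seed.
#' @param n_orthogroups orthogroups to draw.
#' @param shared_pool_size shared annotation-name pool size.
#' @param reps_per_condition RNA-seq replicates per condition.
#' @param audit run the generator audit pass (consistency of truth and
#'   emitted files).
#' @return an object of class `antherm_study`: `specs`, `species_meta`,
#'   `survival`, `catalogs`, `counts` (per species), `og_table`, `truth`.
#' @export
simulate_study <- function(specs = default_study_specs(), seed = 1L,
                           n_orthogroups = 1700L,
                           shared_pool_size = 5000L,
                           reps_per_condition = 4L, audit = TRUE) {
  species_meta <- attr(specs, "species_meta")
  if (is.null(species_meta))
    species_meta <- new_species_meta(data.frame(
      species = vapply(specs, `[[`, "", "species_id"),
      subfamily = vapply(specs, `[[`, "", "subfamily"),
      genus = vapply(specs, `[[`, "", "genus"),
      habitat = vapply(specs, `[[`, "", "habitat"),
      stringsAsFactors = FALSE))
  surv <- do.call(rbind, lapply(seq_along(specs), function(i)
    simulate_survival(specs[[i]],
                      seed = stage_seed(seed, "survival", i))))
  surv <- new_survival_table(surv)
  tr <- simulate_transcriptomes(specs, shared_pool_size,
                                seed = stage_seed(seed, "transcriptomes"))
  og <- simulate_orthogroups(tr$catalogs, species_meta,
                             n_orthogroups = n_orthogroups,
                             seed = stage_seed(seed, "orthogroups"))
  counts <- list()
  count_truth <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]$species_id
    cc <- simulate_counts(specs[[i]], tr$catalogs[[sp]],
                          reps_per_condition,
                          seed = stage_seed(seed, "counts", i))
    counts[[sp]] <- cc$counts
    count_truth[[sp]] <- cc$truth
  }
  study <- structure(list(
    specs = specs, species_meta = species_meta, survival = surv,
    catalogs = tr$catalogs, counts = counts, og_table = og$og_table,
    truth = list(survival = data.frame(
      species = vapply(specs, `[[`, "", "species_id"),
      true_lt50 = vapply(specs, `[[`, 0, "true_lt50"),
      logit_slope = vapply(specs, `[[`, 0, "logit_slope"),
      strategy = vapply(specs, `[[`, "", "strategy"),
      stringsAsFactors = FALSE),
      shared_names = tr$truth$shared_names,
      name_sets = tr$truth$name_sets,
      orthogroups = og$truth,
      counts = count_truth),
    seed = as.integer(seed)), class = "antherm_study")
  if (audit) audit_study(study)
  study
}

#' Audit a simulated study against its ground truth
#'
#' Verifies that the emitted objects are consistent with the recorded
#' ground truth: catalog sizes match the specs, realized shared-name
#' counts match the truth matrix, orthogroup categories recomputed from
#' the emitted table match the assigned truth, true-DE transcripts exist
#' in the corresponding count matrices, and survival tables are complete.
#'
#' @param study an `antherm_study`.
#' @return invisibly `TRUE`; stops with a message on any inconsistency.
#' @export
audit_study <- function(study) {
  for (spec in study$specs) {
    sp <- spec$species_id
    if (nrow(study$catalogs[[sp]]) != spec$transcriptome_size)
      stop(sprintf("audit: catalog size mismatch for '%s'", sp))
    if (!identical(rownames(study$counts[[sp]]$counts),
                   study$catalogs[[sp]]$transcript_id))
      stop(sprintf("audit: count rows do not match catalog for '%s'", sp))
  }
  ids <- names(study$catalogs)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    realized <- observed_overlap(
      unique_meaningful_names(study$catalogs[[ids[i]]]),
      unique_meaningful_names(study$catalogs[[ids[j]]]))
    if (realized != study$truth$shared_names[ids[i], ids[j]])
      stop(sprintf("audit: shared-name count mismatch for %s vs %s",
                   ids[i], ids[j]))
  }
  assigned <- classify_orthogroups(study$og_table, study$species_meta)
  if (!identical(assigned$category, study$truth$orthogroups$category))
    stop("audit: recomputed orthogroup categories disagree with truth")
  for (sp in ids) {
    tt <- study$truth$counts[[sp]]
    if (!all(tt$transcript_id[tt$true_de] %in%
             rownames(study$counts[[sp]]$counts)))
      stop(sprintf("audit: true-DE transcripts missing from counts '%s'",
                   sp))
  }
  if (nrow(study$survival) !=
      length(study$specs) * length(unique(study$survival$temperature)) *
      length(unique(study$survival$tube_id)))
    stop("audit: survival table incomplete")
  invisible(TRUE)
}

#' Write all study files to a directory
#'
#' Emits exactly the file formats the readers consume: `survival.csv`,
#' per-species `counts_<sp>.tsv` / `samples_<sp>.tsv` /
#' `annotations_<sp>.tsv`, `orthogroups.tsv`, `species_meta.tsv`, and a
#' `ground_truth.json`.
#'
#' @param study an `antherm_study`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_survival_table(study$survival, file.path(dir, "survival.csv"))
  for (sp in names(study$catalogs)) {
    write_counts(study$counts[[sp]],
                 file.path(dir, sprintf("counts_%s.tsv", sp)),
                 file.path(dir, sprintf("samples_%s.tsv", sp)))
    write_annotations(study$catalogs[[sp]],
                      file.path(dir, sprintf("annotations_%s.tsv", sp)))
  }
  write_orthogroups(study$og_table, file.path(dir, "orthogroups.tsv"))
  write_species_meta(study$species_meta,
                     file.path(dir, "species_meta.tsv"))
  truth <- study$truth
  truth$shared_names <- as.data.frame(truth$shared_names)
  truth$counts <- lapply(truth$counts, function(d)
    d[, c("transcript_id", "is_stress", "true_de", "true_log2fc")])
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
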