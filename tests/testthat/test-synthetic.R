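test_that("simulated death counts follow the logistic curve", {
  spec <- species_sim_spec("sp", "Formicinae", "Cataglyphis", "desert",
                           true_lt50 = 45, logit_slope = 1.5,
                           transcriptome_size = 100)
  # logistic midpoint: expected death probability exactly 0.5 at LT50
  expect_equal(plogis(spec$logit_slope * (45 - spec$true_lt50)), 0.5)

  surv <- simulate_survival(spec, seed = 1)
  temps <- sort(unique(surv$temperature))
  p_true <- plogis(1.5 * (temps - 45))
  for (i in seq_along(temps)) {
    sub <- surv[surv$temperature == temps[i], ]
    frac <- sum(sub$n_dead) / sum(sub$n_total)
    se <- sqrt(p_true[i] * (1 - p_true[i]) / sum(sub$n_total))
    expect_lt(abs(frac - p_true[i]), 3 * se + 1e-9)
  }

  # step-function limit at extreme slope
  steep <- species_sim_spec("sp", "Formicinae", "Cataglyphis", "desert",
                            true_lt50 = 45, logit_slope = 50,
                            transcriptome_size = 100)
  s2 <- simulate_survival(steep, temperatures = c(44, 46), seed = 2)
  expect_equal(sum(s2$n_dead[s2$temperature == 44]), 0)
  expect_equal(sum(s2$n_dead[s2$temperature == 46]),
               sum(s2$n_total[s2$temperature == 46]))

  expect_error(simulate_survival(spec, workers_per_tube = 0), "positive")
})

test_that("generators are bit-reproducible given the seed", {
  s1 <- tiny_study(seed = 5)
  s2 <- tiny_study(seed = 5)
  expect_identical(s1$survival, s2$survival)
  expect_identical(s1$catalogs, s2$catalogs)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$og_table, s2$og_table)
  s3 <- tiny_study(seed = 6)
  expect_false(identical(s1$survival$n_dead, s3$survival$n_dead))
})

test_that("shared annotation pools produce the expected name overlap", {
  mk <- function(frac, n_names = 500) {
    species_sim_spec("A", "Formicinae", "Cataglyphis", "desert", 45, 1,
                     transcriptome_size = 800,
                     unique_name_count = n_names,
                     shared_pool_fraction = frac,
                     uncharacterized_fraction = 0)
  }
  # fraction 0: no shared names between the species
  tr0 <- simulate_transcriptomes(
    list(mk(0), within_id(mk(0), "B")), shared_pool_size = 1000, seed = 3)
  expect_equal(tr0$truth$shared_names["A", "B"], 0L)

  # fraction 1 with a pool smaller than both name sets: overlap = pool
  mkp <- function(id) {
    sp <- species_sim_spec(id, "Formicinae", "Cataglyphis", "desert", 45,
                           1, transcriptome_size = 800,
                           unique_name_count = 500,
                           shared_pool_fraction = 1,
                           uncharacterized_fraction = 0)
    sp
  }
  expect_error(
    simulate_transcriptomes(list(mkp("A"), mkp("B")),
                            shared_pool_size = 300, seed = 3),
    "pool")

  # half-shared names: overlap near the sampling expectation
  tr <- simulate_transcriptomes(
    list(mk(0.5), within_id(mk(0.5), "B")), shared_pool_size = 1000,
    seed = 7)
  k <- tr$truth$shared_names["A", "B"]
  # expectation ~ 250*250/1000; hypergeometric SE
  se <- sqrt(250 * 0.25 * 0.75 * 750 / 999)
  expect_lt(abs(k - 62.5), 3 * se + 2)
  # audit invariant: truth matches realized catalogs
  expect_equal(observed_overlap(unique_meaningful_names(tr$catalogs$A),
                                unique_meaningful_names(tr$catalogs$B)),
               k)
})

test_that("uncharacterized fraction and isoform redundancy are realized", {
  spec <- species_sim_spec("A", "Formicinae", "Cataglyphis", "desert",
                           45, 1, transcriptome_size = 1000,
                           unique_name_count = 400,
                           uncharacterized_fraction = 0.25)
  tr <- simulate_transcriptomes(list(spec), shared_pool_size = 2000,
                                seed = 2)
  ann <- tr$catalogs$A$annotation
  expect_equal(sum(grepl("uncharacterized protein", ann)), 250)
  ns <- unique_meaningful_names(tr$catalogs$A)
  expect_equal(length(ns$names), 400)  # redundancy: 750 rows, 400 names
})

test_that("orthogroup generator realizes the assigned categories", {
  study <- tiny_study(seed = 11)
  sim <- simulate_orthogroups(study$catalogs, study$species_meta,
                              n_orthogroups = 100,
                              category_mixture = c(I = 0.5, V = 0.5),
                              seed = 3)
  got <- classify_orthogroups(sim$og_table, study$species_meta)
  expect_identical(got$category, sim$truth$category)
  expect_setequal(unique(got$category), c("I", "V"))
  n_sp <- got$n_species
  expect_true(all(n_sp[got$category == "I"] == 6))
  expect_true(all(n_sp[got$category == "V"] == 1))

  sim2 <- simulate_orthogroups(study$catalogs, study$species_meta,
                               n_orthogroups = 120, seed = 4)
  got2 <- classify_orthogroups(sim2$og_table, study$species_meta)
  expect_identical(got2$category, sim2$truth$category)

  meta_nogenus <- study$species_meta
  meta_nogenus$genus <- paste0("G", seq_len(nrow(meta_nogenus)))
  expect_error(
    simulate_orthogroups(study$catalogs, meta_nogenus,
                         category_mixture = c(I = 0.5, IV = 0.5),
                         seed = 1),
    "genus")
})

test_that("count simulation matches its archetypes and moments", {
  cat_a <- toy_catalog("A", 600, shared_names =
                         c("Heat shock protein 70 cognate",
                           "Heat shock protein 90 alpha"))
  base <- function(strategy, fc) {
    species_sim_spec("A", "Formicinae", "Cataglyphis", "desert", 45, 1,
                     transcriptome_size = 600, strategy = strategy,
                     n_stress_genes = 40, induced_log2fc = fc)
  }
  # no induction anywhere -> empty true DE set
  sim0 <- simulate_counts(base("reactive", 0), cat_a, seed = 1)
  expect_equal(sum(sim0$truth$true_de & sim0$truth$true_log2fc != 0), 0)

  # near-zero dispersion, factor-free design: estimated log2fc -> 2
  # few DE genes keep the library-composition shift negligible, so raw
  # CPM ratios recover the induced fold change
  spec2 <- species_sim_spec("A", "Formicinae", "Cataglyphis", "desert",
                            45, 1, transcriptome_size = 600,
                            strategy = "reactive", n_stress_genes = 5,
                            induced_log2fc = 2, dispersion = 1e-6,
                            baseline_meanlog = 6, baseline_sdlog = 0.5)
  sim2 <- simulate_counts(spec2, cat_a, reps_per_condition = 4, seed = 2)
  cm <- sim2$counts
  de_idx <- which(sim2$truth$true_de)
  hs <- cm$samples$condition == "HS"
  lib <- colSums(cm$counts)
  cpm <- sweep(cm$counts, 2, lib, "/")
  est_fc <- log2(rowMeans(cpm[de_idx, hs, drop = FALSE]) /
                   rowMeans(cpm[de_idx, !hs, drop = FALSE]))
  expect_true(all(abs(est_fc - 2) < 0.2))

  # constitutive: elevated in both conditions, no true DE
  simc <- simulate_counts(base("constitutive", 3), cat_a, seed = 3)
  expect_equal(sum(simc$truth$true_de), 0)
  stress <- simc$truth$is_stress
  nhs_mean <- rowMeans(simc$counts$counts[, !hs, drop = FALSE])
  expect_gt(median(nhs_mean[stress]), 2 * median(nhs_mean[!stress]))

  expect_error(species_sim_spec("A", "Formicinae", "Cataglyphis",
                                "desert", 45, 1, dispersion = 0),
               "dispersion")
})

test_that("the audit pass accepts its own output and flags corruption", {
  study <- tiny_study(seed = 13)
  expect_true(audit_study(study))
  broken <- study
  broken$truth$orthogroups$category[1] <-
    setdiff(c("I", "V"), broken$truth$orthogroups$category[1])[1]
  expect_error(audit_study(broken), "categories")
})
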