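six_meta <- function() {
  new_species_meta(data.frame(
    species = c("Cbom", "Chol", "Mbag", "Orob", "Ffus", "Msab"),
    subfamily = c("Formicinae", "Formicinae", "Formicinae", "Myrmicinae",
                  "Formicinae", "Myrmicinae"),
    genus = c("Cataglyphis", "Cataglyphis", "Melophorus", "Ocymyrmex",
              "Formica", "Myrmica"),
    habitat = c("desert", "desert", "desert", "desert", "temperate",
                "temperate"), stringsAsFactors = FALSE))
}

og_from_presence <- function(patterns) {
  rows <- do.call(rbind, lapply(seq_along(patterns), function(i) {
    sps <- patterns[[i]]
    data.frame(orthogroup = sprintf("OG%03d", i), species = sps,
               gene = sprintf("OG%03d_%s_g", i, sps),
               stringsAsFactors = FALSE)
  }))
  new_orthogroup_table(rows, species = six_meta()$species,
                       orthogroups = sprintf("OG%03d",
                                             seq_along(patterns)))
}

test_that("presence patterns map to categories with the right precedence", {
  meta <- six_meta()
  og <- og_from_presence(list(
    c("Cbom", "Chol", "Mbag", "Orob", "Ffus", "Msab"),  # I
    c("Orob", "Msab"),                                  # II
    c("Cbom", "Mbag", "Ffus"),                          # III
    c("Cbom", "Chol"),                                  # IV (not III)
    "Msab",                                             # V
    c("Cbom", "Orob"),                                  # mixed_partial
    c("Cbom", "Chol", "Mbag", "Ffus")))                 # III (all Formicinae)
  got <- classify_orthogroups(og, meta)
  expect_equal(got$category,
               c("I", "II", "III", "IV", "V", "mixed_partial", "III"))

  # category counts invariant to row order and within-cell gene order
  og_rev <- new_orthogroup_table(og$long[rev(seq_len(nrow(og$long))), ],
                                 species = og$species,
                                 orthogroups = rev(og$orthogroups))
  got_rev <- classify_orthogroups(og_rev, meta)
  expect_equal(table(got_rev$category), table(got$category))
})

test_that("simulated orthogroups are classified back to their true labels", {
  study <- tiny_study(seed = 17)
  got <- classify_orthogroups(study$og_table, study$species_meta)
  expect_identical(got$category, study$truth$orthogroups$category)
  expect_equal(mean(got$category == study$truth$orthogroups$category), 1)
})

test_that("gene status partitions the catalog and honors the category map", {
  meta <- six_meta()
  og <- og_from_presence(list(
    c("Cbom", "Chol", "Mbag", "Orob", "Ffus", "Msab"),
    c("Cbom", "Chol"),
    "Cbom"))
  assignments <- classify_orthogroups(og, meta)
  catalog <- new_annotation_catalog(data.frame(
    transcript_id = c(og$long$gene[og$long$species == "Cbom"],
                      "lonely_gene"),
    annotation = "x"), "Cbom")
  st <- gene_status(assignments, og, "Cbom", meta, catalog)
  expect_equal(sum(st$status == "conserved"), 1L)   # category I gene
  expect_equal(sum(st$status == "restricted"), 2L)  # IV and V genes
  expect_equal(sum(st$status == "unassigned"), 1L)
  expect_equal(nrow(st), nrow(catalog))

  # a Formicinae gene inside a Myrmicinae-only orthogroup is impossible
  bad <- new_orthogroup_table(data.frame(
    orthogroup = c("OG1", "OG1", "OG1"),
    species = c("Orob", "Msab", "Cbom"),
    gene = c("g1", "g2", "g3")), species = meta$species,
    orthogroups = "OG1")
  bad_assign <- data.frame(orthogroup = "OG1", category = "II")
  expect_error(gene_status(bad_assign, bad, "Cbom", meta), "integrity")
})

test_that("Fisher enrichment equals enumeration and detects direction", {
  st <- data.frame(gene = paste0("g", 1:100),
                   orthogroup = "OG", category = "V",
                   status = rep(c("restricted", "conserved"),
                                c(13, 87)))
  # 2x2 = [[3,7],[10,80]]
  det <- c(paste0("g", 1:3), paste0("g", 14:20))
  er <- restricted_enrichment(st, det, "sp")
  expect_equal(unname(er$table[1, ]), c(3, 7))
  expect_equal(unname(er$table[2, ]), c(10, 80))
  expect_equal(er$p, fisher_enum_oracle(er$table), tolerance = 1e-12)
  expect_equal(er$p, fisher.test(er$table)$p.value, tolerance = 1e-10)
  expect_equal(er$direction, "increase")

  # no association: proportions equal -> OR 1, p 1
  st2 <- data.frame(gene = paste0("g", 1:1100), orthogroup = "OG",
                    category = "V",
                    status = rep(c("restricted", "conserved", "restricted",
                                   "conserved"), c(10, 90, 100, 900)))
  det2 <- paste0("g", 1:100)
  er2 <- restricted_enrichment(st2, det2, "sp")
  expect_equal(er2$odds_ratio, 1)
  expect_equal(er2$p, 1)

  er0 <- restricted_enrichment(st, character(), "sp")
  expect_true(er0$degenerate)
  expect_equal(er0$p, 1)
})

test_that("Fisher p is symmetric under simultaneous row/column swap", {
  tabs <- list(matrix(c(3, 7, 10, 80), 2, byrow = TRUE),
               matrix(c(12, 3, 5, 20), 2, byrow = TRUE),
               matrix(c(0, 9, 4, 11), 2, byrow = TRUE))
  for (m in tabs) {
    swapped <- m[2:1, 2:1]
    expect_equal(antherm:::.fisher_p_two_sided(m),
                 antherm:::.fisher_p_two_sided(swapped),
                 tolerance = 1e-12)
    expect_equal(antherm:::.fisher_p_two_sided(m),
                 fisher_enum_oracle(m), tolerance = 1e-12)
  }
})

test_that("enrichment detects restricted-gene oversampling among DET", {
  set.seed(23)
  n_genes <- 5000
  status <- data.frame(
    gene = paste0("g", 1:n_genes), orthogroup = "OG", category = "V",
    status = sample(rep(c("restricted", "conserved"),
                        c(1000, 4000))))
  restricted <- status$gene[status$status == "restricted"]
  conserved <- status$gene[status$status == "conserved"]
  hits <- vapply(1:60, function(i) {
    # DET over-sample restricted genes at twice their base rate
    n_res <- rbinom(1, 500, 0.4)
    det <- c(sample(restricted, n_res), sample(conserved, 500 - n_res))
    er <- restricted_enrichment(status, det, "sp")
    er$direction == "increase" && er$p < 0.01
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("orthology summaries reproduce the published percentages", {
  counts <- read.delim(system.file("extdata", "ant_orthology_counts.tsv",
                                   package = "antherm"))
  totals <- jsonlite::read_json(system.file("extdata",
                                            "ant_study_totals.json",
                                            package = "antherm"))
  s <- orthology_summary_from_counts(
    counts, totals$n_orthogroups,
    n_specific_og_total = totals$n_species_specific_orthogroups)
  expect_equal(s$totals$pct_assigned_r, 91.1)
  expect_equal(s$totals$pct_specific_og_r, 26.9)
  expect_equal(s$totals$pct_genes_in_specific_r, 10.1)
  per <- s$per_species
  expect_equal(per$pct_assigned_r[per$species == "Cbom"], 94.2)
  expect_equal(per$pct_unassigned_r[per$species == "Msab"], 14.8)
  expect_equal(per$pct_assigned_r,
               c(94.2, 93.8, 92.2, 91.9, 91.4, 85.2))
  expect_equal(per$pct_genes_specific_r,
               c(5.0, 5.6, 7.7, 11.4, 11.0, 17.5))
})

test_that("summarize_orthology agrees with direct counting on simulated data", {
  study <- tiny_study(seed = 19)
  s <- summarize_orthology(study$og_table, study$catalogs)
  long <- study$og_table$long
  for (sp in study$species_meta$species) {
    row <- s$per_species[s$per_species$species == sp, ]
    expect_equal(row$n_genes, nrow(study$catalogs[[sp]]))
    expect_equal(row$n_assigned, sum(long$species == sp))
  }
  truth_v <- study$truth$orthogroups$category == "V"
  expect_equal(s$totals$n_specific_og, sum(truth_v))
  # partition: conserved + restricted + unassigned = catalog size
  assignments <- classify_orthogroups(study$og_table, study$species_meta)
  for (sp in study$species_meta$species) {
    st <- gene_status(assignments, study$og_table, sp,
                      study$species_meta, study$catalogs[[sp]])
    expect_equal(nrow(st), nrow(study$catalogs[[sp]]))
    expect_setequal(st$gene, study$catalogs[[sp]]$transcript_id)
  }

  # one species holding everything in one orthogroup
  one <- new_orthogroup_table(data.frame(
    orthogroup = "OG1", species = "solo", gene = paste0("g", 1:10)),
    species = "solo", orthogroups = "OG1")
  cat_solo <- list(solo = new_annotation_catalog(data.frame(
    transcript_id = paste0("g", 1:10), annotation = "x"), "solo"))
  s1 <- summarize_orthology(one, cat_solo)
  expect_equal(s1$totals$pct_assigned, 100)
  expect_equal(s1$totals$pct_specific_og, 100)
  expect_equal(s1$totals$pct_genes_in_specific, 100)
})
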