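# Orthogroup taxonomic categories, conserved/restricted gene status,
# restricted-gene enrichment among DETs, and orthology summary tables.

#' Classify orthogroups into taxonomic categories
#'
#' Categories are determined solely by the species-presence pattern and
#' the clade map, with precedence resolving containment:
#'
#' * `V` - exactly one species present (species-specific);
#' * `IV` - the present species are exactly the two *Cataglyphis*-genus
#'   species (intra-genus restricted);
#' * `II` - all present species are Myrmicinae, at least two of them;
#' * `III` - all present species are Formicinae, at least two of them;
#' * `I` - every study species is present;
#' * `mixed_partial` - anything else (spanning both subfamilies but
#'   missing some species). Treated downstream as conserved, since
#'   cross-subfamily presence implies conservation.
#'
#' @param og_table an `orthogroup_table`.
#' @param species_meta a `species_meta` covering every species in the
#'   table.
#' @return data.frame of class `category_assignment` with columns
#'   `orthogroup`, `category`, `n_species`.
#' @export
classify_orthogroups <- function(og_table, species_meta) {
  if (!all(og_table$species %in% species_meta$species))
    stop("species metadata does not cover every species in the table")
  all_sp <- og_table$species
  myrm <- species_meta$species[species_meta$subfamily == "Myrmicinae"]
  form <- species_meta$species[species_meta$subfamily == "Formicinae"]
  catag <- species_meta$species[species_meta$genus == "Cataglyphis"]
  pres <- table(factor(og_table$long$orthogroup,
                       levels = og_table$orthogroups),
                factor(og_table$long$species, levels = all_sp)) > 0
  n_present <- rowSums(pres)
  if (any(n_present == 0))
    stop(sprintf("orthogroup '%s' has zero genes in every species",
                 og_table$orthogroups[which(n_present == 0)[1]]))
  categories <- vapply(seq_along(og_table$orthogroups), function(i) {
    present <- colnames(pres)[pres[i, ]]
    .categorize_presence(present, all_sp, myrm, form, catag)
  }, "")
  out <- data.frame(orthogroup = og_table$orthogroups, category = categories,
                    n_species = as.integer(n_present),
                    stringsAsFactors = FALSE)
  class(out) <- c("category_assignment", "data.frame")
  out
}

.categorize_presence <- function(present, all_sp, myrm, form, catag) {
  if (length(present) == 1L) return("V")
  if (length(catag) >= 2L && setequal(present, catag)) return("IV")
  if (length(present) >= 2L && all(present %in% myrm)) return("II")
  if (length(present) >= 2L && all(present %in% form)) return("III")
  if (setequal(present, all_sp)) return("I")
  "mixed_partial"
}

#' Conserved / restricted status of each gene of a species
#'
#' Every assigned gene inherits its orthogroup's category, mapped to
#' `restricted` for categories IV and V (taxonomically restricted genes)
#' and `conserved` for I, II, III and `mixed_partial`. Catalog genes in
#' no orthogroup are `unassigned`. An integrity check rejects category
#' assignments impossible for the species' subfamily (a Formicinae gene
#' in a Myrmicinae-only orthogroup, say).
#'
#' @param assignments a `category_assignment` from
#'   [classify_orthogroups()].
#' @param og_table the `orthogroup_table` the assignments cover.
#' @param species species id.
#' @param species_meta a `species_meta` (used for the integrity check).
#' @param catalog optional `annotation_catalog`; its transcripts missing
#'   from every orthogroup are labeled `unassigned`.
#' @return data.frame of class `gene_ortho_status` with columns `gene`,
#'   `orthogroup`, `category`, `status`.
#' @export
gene_status <- function(assignments, og_table, species, species_meta = NULL,
                        catalog = NULL) {
  sub <- og_table$long[og_table$long$species == species, , drop = FALSE]
  cat_of <- assignments$category[match(sub$orthogroup,
                                       assignments$orthogroup)]
  if (anyNA(cat_of))
    stop("assignments do not cover every orthogroup in the table")
  if (!is.null(species_meta)) {
    subfam <- species_meta$subfamily[species_meta$species == species]
    impossible <- (subfam == "Formicinae" & cat_of == "II") |
      (subfam == "Myrmicinae" & cat_of %in% c("III", "IV"))
    if (any(impossible))
      stop(sprintf(
        "integrity: species '%s' (%s) holds genes in a category-%s orthogroup",
        species, subfam, cat_of[which(impossible)[1]]))
  }
  status <- ifelse(cat_of %in% c("IV", "V"), "restricted", "conserved")
  out <- data.frame(gene = sub$gene, orthogroup = sub$orthogroup,
                    category = cat_of, status = status,
                    stringsAsFactors = FALSE)
  if (!is.null(catalog)) {
    unassigned <- setdiff(catalog$transcript_id, sub$gene)
    if (length(unassigned))
      out <- rbind(out, data.frame(gene = unassigned,
                                   orthogroup = NA_character_,
                                   category = NA_character_,
                                   status = "unassigned",
                                   stringsAsFactors = FALSE))
  }
  class(out) <- c("gene_ortho_status", "data.frame")
  out
}

# Two-sided Fisher exact p by summing hypergeometric point probabilities
# no larger than the observed table's (with the conventional 1e-7
# relative tolerance for ties).
.fisher_p_two_sided <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ])
  r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(support, c1, r2 + r1 - c1, r1)
  p_obs <- dhyper(a, c1, r2 + r1 - c1, r1)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Enrichment of taxonomically restricted genes among DETs
#'
#' Builds the 2x2 table of DET / non-DET by restricted / conserved over
#' the species' assigned genes and applies a two-sided Fisher exact test
#' (hypergeometric point-probability summation). The odds ratio is the
#' sample odds ratio, with a Haldane 0.5 correction applied (and flagged)
#' only when a table cell is zero. Unassigned genes are excluded by
#' default, since restricted status is defined through lineage-specific
#' orthogroups, not singletons; set `include_unassigned` to count them as
#' restricted.
#'
#' @param status a `gene_ortho_status` for the species.
#' @param det_genes character vector of DET gene ids.
#' @param species species id (recorded in the result).
#' @param include_unassigned count unassigned genes as restricted.
#' @return an object of class `enrichment_result` with elements `table`
#'   (2x2: rows DET/non-DET, columns restricted/conserved), `odds_ratio`,
#'   `p`, `direction`, `haldane`, `degenerate`.
#' @export
restricted_enrichment <- function(status, det_genes, species = NA,
                                  include_unassigned = FALSE) {
  st <- status
  if (include_unassigned)
    st$status[st$status == "unassigned"] <- "restricted"
  st <- st[st$status %in% c("restricted", "conserved"), , drop = FALSE]
  unknown <- setdiff(det_genes, status$gene)
  if (length(unknown))
    warning(sprintf("%d DET gene(s) absent from the gene status table",
                    length(unknown)))
  is_det <- st$gene %in% det_genes
  is_res <- st$status == "restricted"
  m <- matrix(c(sum(is_det & is_res), sum(is_det & !is_res),
                sum(!is_det & is_res), sum(!is_det & !is_res)),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("DET", "non_DET"),
                              c("restricted", "conserved")))
  if (sum(m[1, ]) == 0) {
    return(structure(list(species = species, table = m,
                          odds_ratio = NA_real_, p = 1,
                          direction = NA_character_, haldane = FALSE,
                          degenerate = TRUE),
                     class = "enrichment_result"))
  }
  haldane <- any(m == 0)
  mm <- if (haldane) m + 0.5 else m
  or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
  p <- .fisher_p_two_sided(m)
  frac_det <- m[1, 1] / sum(m[1, ])
  frac_bg <- m[2, 1] / sum(m[2, ])
  structure(list(species = species, table = m, odds_ratio = or, p = p,
                 direction = if (frac_det >= frac_bg) "increase" else
                   "decrease",
                 haldane = haldane, degenerate = FALSE),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Restricted-gene enrichment%s: OR = %.3f, p = %.3g (%s among DET)\n",
    if (is.na(x$species)) "" else paste0(" [", x$species, "]"),
    x$odds_ratio, x$p, x$direction %||% "NA"))
  invisible(x)
}

#' Orthology summary statistics
#'
#' Per species: gene totals, genes in orthogroups, unassigned genes,
#' species-specific orthogroup counts and genes therein, with the
#' corresponding percentages; study-wide: totals, orthogroup counts and
#' the species-specific shares. Percentages are carried unrounded with a
#' 1-decimal rounded companion column.
#'
#' @param og_table an `orthogroup_table`.
#' @param catalogs named list of `annotation_catalog` objects (gene
#'   totals per species).
#' @return an `ortho_summary`; see [orthology_summary_from_counts()].
#' @export
summarize_orthology <- function(og_table, catalogs) {
  species <- og_table$species
  pres <- table(factor(og_table$long$orthogroup,
                       levels = og_table$orthogroups),
                factor(og_table$long$species, levels = species)) > 0
  n_present <- rowSums(pres)
  specific_of <- colSums(pres[n_present == 1L, , drop = FALSE])
  genes_in_specific <- vapply(species, function(sp) {
    ogs <- og_table$orthogroups[n_present == 1L & pres[, sp]]
    sum(og_table$long$species == sp & og_table$long$orthogroup %in% ogs)
  }, 0L)
  per_species <- data.frame(
    species = species,
    n_genes = vapply(species, function(sp) nrow(catalogs[[sp]]), 0L),
    n_assigned = vapply(species, function(sp)
      sum(og_table$long$species == sp), 0L),
    n_specific_og = as.integer(specific_of[species]),
    n_genes_specific = as.integer(genes_in_specific[species]),
    n_og_containing = as.integer(colSums(pres)[species]),
    stringsAsFactors = FALSE)
  orthology_summary_from_counts(per_species,
                                n_orthogroups = length(og_table$orthogroups))
}

#' Orthology percentages from count inputs
#'
#' The arithmetic layer of [summarize_orthology()], usable directly on a
#' published per-species count table: computes assignment and
#' species-specific percentages per species and study-wide.
#'
#' @param per_species data.frame with columns `species`, `n_genes`,
#'   `n_assigned`, `n_specific_og`, `n_genes_specific` and optionally
#'   `n_og_containing`.
#' @param n_orthogroups total number of orthogroups in the study.
#' @param n_specific_og_total study-wide species-specific orthogroup
#'   count; defaults to the per-species column sum, but is acceptable as
#'   an independent input because published study-wide counts need not
#'   equal the per-species breakdown (orthology tools deduplicate
#'   differently at the two levels).
#' @return an object of class `ortho_summary` with elements `per_species`
#'   (the input plus percentage columns, unrounded and rounded to 1
#'   decimal) and `totals`.
#' @export
orthology_summary_from_counts <- function(per_species, n_orthogroups,
                                          n_specific_og_total = NULL) {
  ps <- per_species
  if (any(ps$n_assigned > ps$n_genes))
    stop("assigned genes exceed gene totals")
  ps$pct_assigned <- 100 * ps$n_assigned / ps$n_genes
  ps$pct_unassigned <- 100 * (ps$n_genes - ps$n_assigned) / ps$n_genes
  ps$pct_genes_specific <- 100 * ps$n_genes_specific / ps$n_genes
  for (col in c("pct_assigned", "pct_unassigned", "pct_genes_specific"))
    ps[[paste0(col, "_r")]] <- round(ps[[col]], 1)
  if (!is.null(ps$n_og_containing)) {
    ps$pct_og_containing <- 100 * ps$n_og_containing / n_orthogroups
    ps$pct_og_containing_r <- round(ps$pct_og_containing, 1)
  }
  tot_genes <- sum(ps$n_genes)
  tot_assigned <- sum(ps$n_assigned)
  tot_specific_og <- n_specific_og_total %||% sum(ps$n_specific_og)
  tot_genes_specific <- sum(ps$n_genes_specific)
  totals <- list(
    total_genes = tot_genes,
    total_assigned = tot_assigned,
    pct_assigned = 100 * tot_assigned / tot_genes,
    pct_assigned_r = round(100 * tot_assigned / tot_genes, 1),
    n_orthogroups = n_orthogroups,
    n_specific_og = tot_specific_og,
    pct_specific_og = 100 * tot_specific_og / n_orthogroups,
    pct_specific_og_r = round(100 * tot_specific_og / n_orthogroups, 1),
    genes_in_specific = tot_genes_specific,
    pct_genes_in_specific = 100 * tot_genes_specific / tot_genes,
    pct_genes_in_specific_r = round(100 * tot_genes_specific / tot_genes,
                                    1))
  structure(list(per_species = ps, totals = totals),
            class = "ortho_summary")
}

#' @export
print.ortho_summary <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "Orthology: %d genes, %d (%.1f%%) assigned to %d orthogroups; %d (%.1f%%) species-specific orthogroups holding %d genes (%.1f%%)\n",
    t$total_genes, t$total_assigned, t$pct_assigned, t$n_orthogroups,
    t$n_specific_og, t$pct_specific_og, t$genes_in_specific,
    t$pct_genes_in_specific))
  invisible(x)
}
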