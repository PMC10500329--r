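# Expression response: TMM normalization, a lightweight NB exact-style
# differential-expression test, the two-caller consensus filter, HSP
# panel extraction, and response-profile / strategy classification.

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes between-sample scaling factors by the standard TMM recipe:
#' the reference sample is the one whose 75th-percentile count fraction is
#' closest to the mean across samples; for each sample, genes with a zero
#' count in either the sample or the reference are excluded; M-values
#' (log2 ratio of count fractions) are trimmed by 30% on each side and
#' A-values (average log2 abundance) by 5%; the factor is two to the
#' power of the weighted mean of the remaining M-values, with inverse
#' asymptotic-binomial-variance weights. Factors are rescaled so their
#' geometric mean is exactly 1.
#'
#' @param counts non-negative count matrix (transcripts x samples) or a
#'   `count_matrix` object.
#' @param logratio_trim,sum_trim trim fractions for M and A values.
#' @param ref_column optional reference sample index (chosen
#'   automatically when `NULL`).
#' @return data.frame of class `normalization_factors` with columns
#'   `sample`, `lib_size`, `factor`, `effective_lib_size`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, sum_trim = 0.05,
                        ref_column = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (ncol(m) < 2L) stop("TMM needs at least two samples")
  lib <- colSums(m)
  if (any(lib <= 0)) stop("every sample needs a positive library size")
  f75 <- vapply(seq_len(ncol(m)),
                function(j) quantile(m[, j], 0.75, names = FALSE), 0) / lib
  if (is.null(ref_column)) ref_column <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    .tmm_pair(m[, j], m[, ref_column], lib[j], lib[ref_column],
              logratio_trim, sum_trim,
              sample_name = colnames(m)[j] %||% as.character(j))
  }, 0)
  f <- f / exp(mean(log(f)))
  out <- data.frame(sample = colnames(m) %||% as.character(seq_len(ncol(m))),
                    lib_size = unname(lib), factor = unname(f),
                    effective_lib_size = unname(lib * f),
                    stringsAsFactors = FALSE)
  attr(out, "ref_column") <- ref_column
  class(out) <- c("normalization_factors", "data.frame")
  out
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim,
                      sample_name = "") {
  keep <- obs > 0 & ref > 0
  if (!any(keep))
    stop(sprintf("sample '%s' shares no nonzero genes with the reference",
                 sample_name))
  o <- obs[keep]
  r <- ref[keep]
  logR <- log2((o / n_obs) / (r / n_ref))
  absE <- (log2(o / n_obs) + log2(r / n_ref)) / 2
  v <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  rL <- rank(logR)
  rS <- rank(absE)
  sel <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
  fac <- 2^(sum(logR[sel] / v[sel]) / sum(1 / v[sel]))
  if (!is.finite(fac)) fac <- 1
  fac
}

#' TMM-normalized expression values (CPM on effective library sizes)
#'
#' `value = count / (lib_size * factor) * 1e6`.
#'
#' @param counts count matrix or `count_matrix` object.
#' @param factors `normalization_factors` from [tmm_factors()] on the same
#'   samples.
#' @return numeric matrix of normalized values, same dimnames as the
#'   input.
#' @export
normalize_tmm <- function(counts, factors) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  idx <- match(colnames(m) %||% as.character(seq_len(ncol(m))),
               factors$sample)
  if (anyNA(idx))
    stop(sprintf("normalization factor missing for sample(s): %s",
                 paste(colnames(m)[is.na(idx)], collapse = ", ")))
  eff <- factors$effective_lib_size[idx]
  sweep(m, 2, eff, "/") * 1e6
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

# Method-of-moments common dispersion on library-size-equalized counts.
.common_dispersion <- function(pseudo, groups, floor = 1e-4) {
  ests <- unlist(lapply(unique(groups), function(g) {
    y <- pseudo[, groups == g, drop = FALSE]
    if (ncol(y) < 2L) return(numeric())
    mu <- rowMeans(y)
    s2 <- apply(y, 1, var)
    keep <- mu > 0
    (s2[keep] - mu[keep]) / mu[keep]^2
  }))
  ests <- ests[is.finite(ests)]
  max(floor, if (length(ests)) mean(ests) else floor)
}

#' Lightweight negative-binomial differential-expression test
#'
#' A self-contained caller for heat-stress (HS) versus control (NHS)
#' comparisons: log2 fold changes are computed from TMM-normalized
#' condition means with a 0.5 pseudo-value; p-values come from an
#' exact-style conditional test on the library-size-equalized condition
#' sums under a negative-binomial model with a single common dispersion
#' estimated by the method of moments (floored at 1e-4); FDR by
#' Benjamini-Hochberg. All-zero transcripts get `log2fc = 0, p = 1`.
#'
#' @param counts a `count_matrix` object, or a count matrix.
#' @param conditions character vector (`"HS"`/`"NHS"` per sample);
#'   taken from the object metadata when `counts` is a `count_matrix`.
#' @param factors optional precomputed [tmm_factors()].
#' @return data.frame of class `differential_table` with columns
#'   `transcript_id`, `log2fc` (HS over NHS), `pvalue`, `fdr`, `caller`.
#' @export
de_test <- function(counts, conditions = NULL, factors = NULL) {
  if (inherits(counts, "count_matrix")) {
    conditions <- counts$samples$condition
    m <- counts$counts
  } else m <- counts
  if (is.null(conditions)) stop("conditions are required")
  if (!all(conditions %in% c("HS", "NHS")))
    stop("conditions must be 'HS' or 'NHS'")
  n_hs <- sum(conditions == "HS")
  n_nhs <- sum(conditions == "NHS")
  if (n_hs < 2L || n_nhs < 2L)
    stop("de_test needs at least two replicates per condition")
  if (is.null(factors)) factors <- tmm_factors(m)
  eff <- factors$effective_lib_size[
    match(colnames(m) %||% as.character(seq_len(ncol(m))), factors$sample)]
  cpm <- sweep(m, 2, eff, "/") * 1e6
  mean_hs <- rowMeans(cpm[, conditions == "HS", drop = FALSE])
  mean_nhs <- rowMeans(cpm[, conditions == "NHS", drop = FALSE])
  log2fc <- log2((mean_hs + 0.5) / (mean_nhs + 0.5))
  # equalize library sizes so condition sums are NB-comparable
  lbar <- exp(mean(log(eff)))
  pseudo <- sweep(m, 2, eff, "/") * lbar
  phi <- .common_dispersion(pseudo, conditions)
  s_hs <- round(rowSums(pseudo[, conditions == "HS", drop = FALSE]))
  s_nhs <- round(rowSums(pseudo[, conditions == "NHS", drop = FALSE]))
  pv <- .exact_nb_double_tail(s_hs, s_nhs, n_hs, n_nhs, phi)
  allzero <- rowSums(m) == 0
  log2fc[allzero] <- 0
  pv[allzero] <- 1
  out <- data.frame(transcript_id = rownames(m) %||%
                      as.character(seq_len(nrow(m))),
                    log2fc = unname(log2fc), pvalue = unname(pv),
                    fdr = bh_fdr(unname(pv)), caller = "builtin",
                    stringsAsFactors = FALSE)
  attr(out, "dispersion") <- phi
  class(out) <- c("differential_table", "data.frame")
  out
}

# Double-tail exact test on two NB sums conditioned on their total:
# SA ~ NB(mu_A, size nA/phi), SB ~ NB(mu_B, size nB/phi) under H0 of a
# shared relative abundance; p = sum of partition probabilities no larger
# than the observed one. Enumerates the full partition range, windowed
# for very large totals.
.exact_nb_double_tail <- function(s_a, s_b, n_a, n_b, phi,
                                  window_limit = 1e5) {
  size_a <- n_a / phi
  size_b <- n_b / phi
  frac_a <- n_a / (n_a + n_b)
  vapply(seq_along(s_a), function(i) {
    s <- s_a[i] + s_b[i]
    if (s == 0) return(1)
    mu_a <- s * frac_a
    mu_b <- s - mu_a
    if (s <= window_limit) {
      a <- 0:s
    } else {
      sd_a <- sqrt(mu_a + mu_a^2 / size_a)
      a <- max(0, floor(mu_a - 40 * sd_a)):min(s, ceiling(mu_a + 40 * sd_a))
      a <- unique(c(a, s_a[i]))
    }
    pr <- dnbinom(a, size = size_a, mu = mu_a) *
      dnbinom(s - a, size = size_b, mu = mu_b)
    tot <- sum(pr)
    obs <- pr[match(s_a[i], a)]
    if (!is.finite(obs) || tot <= 0) return(1)
    min(1, sum(pr[pr <= obs * (1 + 1e-8)]) / tot)
  }, 0)
}

#' Run a differential-expression caller
#'
#' Dispatches either the package's built-in NB test ([de_test()]) or the
#' standard edgeR classic pipeline (TMM normalization, common + tagwise
#' dispersion, exact test), returning a uniformly shaped table so callers
#' can be intersected by [consensus_det()].
#'
#' @param counts a `count_matrix` object.
#' @param caller `"builtin"` or `"edger"`.
#' @return a `differential_table` (columns `transcript_id`, `log2fc`,
#'   `pvalue`, `fdr`, `caller`).
#' @export
run_de <- function(counts, caller = c("builtin", "edger")) {
  caller <- match.arg(caller)
  if (caller == "builtin") return(de_test(counts))
  group <- factor(counts$samples$condition, levels = c("NHS", "HS"))
  y <- edgeR::DGEList(counts = counts$counts, group = group)
  y <- edgeR::calcNormFactors(y)
  y <- suppressMessages(edgeR::estimateDisp(y))
  et <- edgeR::exactTest(y, pair = c("NHS", "HS"))
  tab <- et$table
  out <- data.frame(transcript_id = rownames(tab),
                    log2fc = tab$logFC, pvalue = tab$PValue,
                    fdr = bh_fdr(tab$PValue), caller = "edger",
                    stringsAsFactors = FALSE)
  out <- out[match(rownames(counts$counts), out$transcript_id), ]
  rownames(out) <- NULL
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Consensus differentially expressed transcripts (DET)
#'
#' Intersects two caller tables under the study's stringent rule: a
#' transcript is a consensus DET iff its FDR is at or below `fdr_cut` in
#' *both* tables, the two log2 fold changes share a sign, and the mean of
#' their absolute values is at least `fc_cut`. The direction (`up_HS` /
#' `down_HS`) is the shared sign. Transcripts present in only one table
#' are excluded (their count is recorded in the result).
#'
#' @param table_a,table_b `differential_table` data.frames.
#' @param fc_cut minimum mean absolute log2 fold change.
#' @param fdr_cut maximum FDR in both tables.
#' @return an object of class `consensus_det` with elements `det`
#'   (data.frame `transcript_id`, `log2fc_a`, `log2fc_b`, `direction`),
#'   `n_up`, `n_down`, `n_unmatched`.
#' @export
consensus_det <- function(table_a, table_b, fc_cut = 2, fdr_cut = 1e-3) {
  idx <- match(table_a$transcript_id, table_b$transcript_id)
  matched <- !is.na(idx)
  n_unmatched <- sum(!matched) +
    sum(!table_b$transcript_id %in% table_a$transcript_id)
  a <- table_a[matched, , drop = FALSE]
  b <- table_b[idx[matched], , drop = FALSE]
  same_sign <- sign(a$log2fc) == sign(b$log2fc) & a$log2fc != 0
  pass <- a$fdr <= fdr_cut & b$fdr <= fdr_cut & same_sign &
    (abs(a$log2fc) + abs(b$log2fc)) / 2 >= fc_cut
  det <- data.frame(transcript_id = a$transcript_id[pass],
                    log2fc_a = a$log2fc[pass], log2fc_b = b$log2fc[pass],
                    direction = ifelse(a$log2fc[pass] > 0, "up_HS",
                                       "down_HS"),
                    stringsAsFactors = FALSE)
  structure(list(det = det,
                 n_up = sum(det$direction == "up_HS"),
                 n_down = sum(det$direction == "down_HS"),
                 n_unmatched = n_unmatched,
                 fc_cut = fc_cut, fdr_cut = fdr_cut),
            class = "consensus_det")
}

#' @export
print.consensus_det <- function(x, ...) {
  cat(sprintf("Consensus DET: %d (%d up_HS, %d down_HS) at mean |log2FC| >= %g, FDR <= %g\n",
              nrow(x$det), x$n_up, x$n_down, x$fc_cut, x$fdr_cut))
  invisible(x)
}

#' Default HSP70/HSP90 annotation search terms
#' @return character vector of the six search terms.
#' @export
hsp_search_terms <- function() {
  c("Hsp70", "Hsp 70", "Heat shock protein 70",
    "Hsp90", "Hsp 90", "Heat shock protein 90")
}

#' Extract the HSP70/HSP90 transcript panel
#'
#' Matches each search term as a case-insensitive literal substring of
#' the annotation text; terms containing "70" define the HSP70 family and
#' terms containing "90" the HSP90 family. Within each family, the top
#' isoform is the matching transcript with the highest mean normalized
#' value across all samples; its per-sample values are returned. The
#' differential flag marks transcripts present in the consensus DET set.
#'
#' @param annotations an `annotation_catalog`.
#' @param normalized TMM-normalized matrix from [normalize_tmm()].
#' @param consensus optional `consensus_det`; transcripts in it are
#'   flagged differential.
#' @param terms search terms (defaults to [hsp_search_terms()]).
#' @return an object of class `hsp_panel`: per family, `members`
#'   (data.frame with `transcript_id`, `annotation`, `mean_value`,
#'   `differential`), `top_isoform`, `top_values`, `differential` (any
#'   member differential).
#' @export
find_hsp_transcripts <- function(annotations, normalized, consensus = NULL,
                                 terms = hsp_search_terms()) {
  fam_of <- ifelse(grepl("70", terms, fixed = TRUE), "HSP70", "HSP90")
  det_ids <- if (!is.null(consensus)) consensus$det$transcript_id else
    character()
  ann_lc <- tolower(annotations$annotation)
  panel <- lapply(c(HSP70 = "HSP70", HSP90 = "HSP90"), function(fam) {
    hit <- rep(FALSE, nrow(annotations))
    for (tm in terms[fam_of == fam])
      hit <- hit | grepl(tolower(tm), ann_lc, fixed = TRUE)
    ids <- annotations$transcript_id[hit]
    ids <- ids[ids %in% rownames(normalized)]
    if (!length(ids)) {
      return(list(members = data.frame(transcript_id = character(),
                                       annotation = character(),
                                       mean_value = numeric(),
                                       differential = logical()),
                  top_isoform = NA_character_, top_values = NULL,
                  differential = FALSE))
    }
    mv <- rowMeans(normalized[ids, , drop = FALSE])
    members <- data.frame(
      transcript_id = ids,
      annotation = annotations$annotation[match(ids,
                                                annotations$transcript_id)],
      mean_value = unname(mv),
      differential = ids %in% det_ids,
      stringsAsFactors = FALSE)
    top <- ids[which.max(mv)]
    list(members = members, top_isoform = top,
         top_values = normalized[top, ],
         differential = any(members$differential))
  })
  if (!length(panel$HSP70$members$transcript_id) &&
      !length(panel$HSP90$members$transcript_id))
    warning("no transcripts matched the HSP search terms")
  structure(panel, class = "hsp_panel")
}

#' Classify a species' heat-stress response profile
#'
#' The DET fraction is `100 * det_count / transcriptome_size` (percent).
#' Profiles: `weak` below `cuts[1]` percent, `strong` above `cuts[2]`
#' percent, `medium` in between.
#'
#' @param det_count number of consensus DET.
#' @param transcriptome_size total transcripts in the reference
#'   transcriptome.
#' @param cuts percentage cut points (default `c(0.3, 5)`).
#' @return an object of class `response_profile` with elements
#'   `det_count`, `transcriptome_size`, `det_fraction` (percent),
#'   `profile`.
#' @export
classify_profile <- function(det_count, transcriptome_size,
                             cuts = c(0.3, 5.0)) {
  if (transcriptome_size <= 0) stop("transcriptome_size must be positive")
  frac <- 100 * det_count / transcriptome_size
  profile <- if (frac < cuts[1]) "weak" else if (frac > cuts[2]) "strong"
  else "medium"
  structure(list(det_count = det_count,
                 transcriptome_size = transcriptome_size,
                 det_fraction = frac, profile = profile, cuts = cuts),
            class = "response_profile")
}

#' Call a species' heat-stress strategy
#'
#' Desert species with a weak response profile and no HSP70/HSP90
#' differential expression are called `constitutive` (chaperones already
#' high in controls); desert species with a medium or strong profile and
#' at least one differential HSP family are `reactive`; temperate species
#' are `temperate_like`; anything else is `unclassified` with the
#' evidence listed.
#'
#' @param profile a `response_profile` (or its `profile` string).
#' @param habitat `"desert"` or `"temperate"`.
#' @param hsp_differential logical vector or `hsp_panel`; whether HSP70 /
#'   HSP90 are differentially expressed.
#' @param decline_width optional `decline_width` result (recorded as
#'   evidence).
#' @return an object of class `strategy_call` with elements `strategy`
#'   and `evidence`.
#' @export
call_strategy <- function(profile, habitat, hsp_differential,
                          decline_width = NULL) {
  prof <- if (inherits(profile, "response_profile")) profile$profile
  else as.character(profile)
  hsp <- if (inherits(hsp_differential, "hsp_panel"))
    c(HSP70 = hsp_differential$HSP70$differential,
      HSP90 = hsp_differential$HSP90$differential)
  else hsp_differential
  width <- if (inherits(decline_width, "decline_width"))
    decline_width$width else decline_width
  strategy <- if (habitat == "temperate") "temperate_like"
  else if (habitat == "desert" && prof == "weak" && !any(hsp)) "constitutive"
  else if (habitat == "desert" && prof %in% c("medium", "strong") &&
           any(hsp)) "reactive"
  else "unclassified"
  structure(list(strategy = strategy,
                 evidence = list(profile = prof, habitat = habitat,
                                 hsp_differential = hsp,
                                 decline_width = width)),
            class = "strategy_call")
}

#' @export
print.strategy_call <- function(x, ...) {
  cat(sprintf("Strategy: %s (profile %s, habitat %s, HSP differential %s)\n",
              x$strategy, x$evidence$profile, x$evidence$habitat,
              paste(names(x$evidence$hsp_differential)[
                x$evidence$hsp_differential], collapse = "+")))
  invisible(x)
}
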