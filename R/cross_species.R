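# Cross-species comparison: unique meaningful annotation names, the
# Monte-Carlo resampling null for pairwise DET overlap, and the
# transcriptome-size vs DET-count correlation.

# Normalized meaningful names for a vector of annotations: trimmed,
# case-folded; empty and "uncharacterized protein" entries -> NA.
.meaningful_names <- function(annotation) {
  nm <- tolower(trimws(annotation))
  nm[!nzchar(nm) | grepl("uncharacterized protein", nm, fixed = TRUE)] <-
    NA_character_
  nm
}

#' Reduce transcripts to unique meaningful annotation names
#'
#' Annotation names are trimmed of flanking whitespace and compared
#' case-insensitively; unannotated transcripts and annotations containing
#' the phrase "uncharacterized protein" are dropped; the remainder is
#' deduplicated. Only these unique, nonredundant, meaningful names enter
#' cross-species overlap comparisons.
#'
#' @param catalog an `annotation_catalog`.
#' @param transcripts optional character vector restricting the reduction
#'   to a transcript subset (a DET list, say); must be contained in the
#'   catalog.
#' @return an object of class `name_set` with elements `species`, `names`
#'   (normalized, unique), `source_size` (transcripts reduced from).
#' @export
unique_meaningful_names <- function(catalog, transcripts = NULL) {
  if (!is.null(transcripts)) {
    missing <- setdiff(transcripts, catalog$transcript_id)
    if (length(missing))
      stop(sprintf("%d transcript(s) not present in the catalog",
                   length(missing)))
    ann <- catalog$annotation[match(transcripts, catalog$transcript_id)]
  } else {
    transcripts <- catalog$transcript_id
    ann <- catalog$annotation
  }
  nm <- .meaningful_names(ann)
  structure(list(species = attr(catalog, "species"),
                 names = unique(nm[!is.na(nm)]),
                 source_size = length(transcripts)),
            class = "name_set")
}

#' Observed overlap between two name sets
#'
#' Count of exact (case-insensitive, whitespace-trimmed) name matches.
#'
#' @param set_a,set_b `name_set` objects (or character vectors, which are
#'   normalized the same way).
#' @return integer overlap count.
#' @export
observed_overlap <- function(set_a, set_b) {
  norm <- function(s) {
    if (inherits(s, "name_set")) return(s$names)
    unique(tolower(trimws(s)))
  }
  length(intersect(norm(set_a), norm(set_b)))
}

#' Monte-Carlo resampling null for cross-species DET overlap
#'
#' Each iteration samples `n_a` transcripts uniformly without replacement
#' from species A's full transcriptome and `n_b` from species B's,
#' reduces each sample to its unique meaningful annotation names, and
#' records the overlap of the two name sets. The empirical p-value of the
#' observed overlap is `(1 + #{null >= observed}) / (iterations + 1)`
#' (never exactly zero); the null mean and SD (denominator
#' `iterations - 1`) are the "expected" and "(sd)" of a pairwise overlap
#' summary table.
#'
#' @param catalog_a,catalog_b `annotation_catalog` objects (full
#'   transcriptomes).
#' @param n_a,n_b number of transcripts to resample per iteration,
#'   normally the species' DET counts.
#' @param iterations Monte-Carlo iterations (default 10,000).
#' @param seed integer seed for reproducibility.
#' @param observed observed overlap count; computed from `det_a`/`det_b`
#'   when those are given.
#' @param det_a,det_b optional DET transcript id vectors from which the
#'   observed overlap (and, if missing, `n_a`/`n_b`) are derived.
#' @param alpha significance cut-off for the `significant` flag.
#' @return an object of class `overlap_test` with elements `species`,
#'   `observed`, `null_mean`, `null_sd`, `iterations`, `seed`, `p`,
#'   `alpha`, `significant`.
#' @export
resampling_null <- function(catalog_a, catalog_b, n_a = NULL, n_b = NULL,
                            iterations = 10000L, seed = 1L,
                            observed = NULL, det_a = NULL, det_b = NULL,
                            alpha = 0.01) {
  if (!is.null(det_a)) {
    n_a <- n_a %||% length(det_a)
    if (is.null(observed) && !is.null(det_b))
      observed <- observed_overlap(
        unique_meaningful_names(catalog_a, det_a),
        unique_meaningful_names(catalog_b, det_b))
  }
  if (!is.null(det_b)) n_b <- n_b %||% length(det_b)
  if (is.null(n_a) || is.null(n_b))
    stop("n_a and n_b (or det_a and det_b) are required")
  if (n_a > nrow(catalog_a) || n_b > nrow(catalog_b))
    stop("resample size exceeds catalog size")
  # integer-coded names over the union of both catalogs' meaningful names
  nm_a <- .meaningful_names(catalog_a$annotation)
  nm_b <- .meaningful_names(catalog_b$annotation)
  universe <- unique(c(nm_a, nm_b))
  universe <- universe[!is.na(universe)]
  id_a <- match(nm_a, universe)
  id_b <- match(nm_b, universe)
  null_k <- integer(iterations)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n_univ <- length(universe)
  seen <- logical(n_univ)
  for (it in seq_len(iterations)) {
    ua <- id_a[sample.int(length(id_a), n_a)]
    ua <- ua[!is.na(ua)]
    ub <- id_b[sample.int(length(id_b), n_b)]
    ub <- ub[!is.na(ub)]
    seen[ua] <- TRUE
    null_k[it] <- sum(seen[unique(ub)])
    seen[ua] <- FALSE
  }
  p <- if (is.null(observed)) NA_real_ else
    (1 + sum(null_k >= observed)) / (iterations + 1)
  structure(list(
    species = c(attr(catalog_a, "species"), attr(catalog_b, "species")),
    observed = observed, null_mean = mean(null_k), null_sd = sd(null_k),
    iterations = as.integer(iterations), seed = as.integer(seed),
    p = p, alpha = alpha,
    significant = if (is.null(observed)) NA else p < alpha,
    null_draws = null_k),
    class = "overlap_test")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Overlap %s vs %s: observed %s, null %.2f (sd %.2f), p = %.4g%s\n",
    x$species[1] %||% "A", x$species[2] %||% "B",
    format(x$observed), x$null_mean, x$null_sd, x$p,
    if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Pearson correlation between transcriptome size and DET count
#'
#' @param sizes,det_counts equal-length paired numeric vectors
#'   (one entry per species, n >= 3).
#' @return an object of class `correlation_result` with elements `r`,
#'   `p` (two-sided t test), `n`.
#' @export
correlate_size_det <- function(sizes, det_counts) {
  if (length(sizes) != length(det_counts) || length(sizes) < 3L)
    stop("need at least 3 paired values")
  if (var(sizes) == 0 || var(det_counts) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(sizes, det_counts, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n = length(sizes)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.3g)\n", x$r, x$n, x$p))
  invisible(x)
}

#' DET percentage of the transcriptome
#'
#' @param det_count number of differentially expressed transcripts.
#' @param transcriptome_size reference transcriptome size.
#' @return list with `percent` (unrounded) and `percent_rounded`
#'   (2 decimals).
#' @export
det_percentage <- function(det_count, transcriptome_size) {
  if (transcriptome_size <= 0) stop("transcriptome_size must be positive")
  pct <- 100 * det_count / transcriptome_size
  list(percent = pct, percent_rounded = round(pct, 2))
}
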