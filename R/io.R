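# Readers and writers for the tabular formats the pipeline touches.
# Conventions: survival assays are comma-separated; count matrices,
# annotation catalogs, orthogroup tables and species metadata are
# tab-separated (the orthology tool's native dialect). UTF-8, '.' decimal.

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")))
  invisible(df)
}

.check_integer_column <- function(x, col, what) {
  bad <- which(is.na(x) | x != floor(x) | !is.finite(x))
  if (length(bad))
    stop(sprintf("%s: non-integer value in column '%s' at data row %d",
                 what, col, bad[1]))
  as.integer(x)
}

#' Read a survival assay table
#'
#' Reads per-tube survival observations: for each species, temperature and
#' tube, the number of workers tested and the number dead after the
#' exposure. Temperatures are decimal degrees Celsius.
#'
#' @param path CSV file with header columns `species`, `temperature_c`,
#'   `tube_id`, `n_total`, `n_dead`.
#' @return a `data.frame` of class `survival_table` with columns
#'   `species`, `temperature` (numeric, degrees C), `tube_id`, `n_total`,
#'   `n_dead`.
#' @export
read_survival_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("species", "temperature_c", "tube_id",
                         "n_total", "n_dead"), "survival table")
  suppressWarnings(temp <- as.numeric(df$temperature_c))
  if (anyNA(temp))
    stop(sprintf("survival table: unparseable temperature at data row %d",
                 which(is.na(temp))[1]))
  out <- data.frame(species = as.character(df$species),
                    temperature = temp,
                    tube_id = as.character(df$tube_id),
                    n_total = .check_integer_column(df$n_total, "n_total",
                                                    "survival table"),
                    n_dead = .check_integer_column(df$n_dead, "n_dead",
                                                   "survival table"),
                    stringsAsFactors = FALSE)
  new_survival_table(out)
}

#' Construct and validate a survival table
#'
#' @param df data.frame with columns `species`, `temperature`, `tube_id`,
#'   `n_total`, `n_dead`.
#' @return the validated `survival_table`.
#' @export
new_survival_table <- function(df) {
  .require_columns(df, c("species", "temperature", "tube_id",
                         "n_total", "n_dead"), "survival table")
  if (any(df$n_total <= 0))
    stop("survival table: n_total must be positive")
  bad <- which(df$n_dead > df$n_total | df$n_dead < 0)
  if (length(bad))
    stop(sprintf("survival table: n_dead outside [0, n_total] at data row %d",
                 bad[1]))
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Write a survival assay table
#' @param x a `survival_table`.
#' @param path output CSV path.
#' @export
write_survival_table <- function(x, path) {
  out <- data.frame(species = x$species, temperature_c = x$temperature,
                    tube_id = x$tube_id, n_total = x$n_total,
                    n_dead = x$n_dead)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transcript count matrix with sample metadata
#'
#' @param path TSV with a `transcript_id` column followed by one integer
#'   column per sample.
#' @param meta_path TSV with columns `sample`, `condition` (`HS` or `NHS`)
#'   and `replicate`.
#' @return list of class `count_matrix` with elements `counts` (integer
#'   matrix, transcripts x samples) and `samples` (metadata data.frame,
#'   ordered as the matrix columns).
#' @export
read_counts <- function(path, meta_path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, "transcript_id", "count matrix")
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  .require_columns(meta, c("sample", "condition", "replicate"),
                   "sample metadata")
  samples <- setdiff(names(df), "transcript_id")
  only_matrix <- setdiff(samples, meta$sample)
  only_meta <- setdiff(meta$sample, samples)
  if (length(only_matrix) || length(only_meta))
    stop(sprintf(
      "sample mismatch between matrix and metadata: matrix-only {%s}, metadata-only {%s}",
      paste(only_matrix, collapse = ", "), paste(only_meta, collapse = ", ")))
  m <- as.matrix(df[, samples, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m) | m < 0 | m != floor(m)))
    stop("count matrix: counts must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- df$transcript_id
  new_count_matrix(m, meta[match(samples, meta$sample), , drop = FALSE])
}

#' Construct and validate a count matrix object
#'
#' @param counts non-negative integer matrix, transcripts x samples.
#' @param samples data.frame with columns `sample`, `condition`,
#'   `replicate`; one row per matrix column, in order.
#' @return a `count_matrix` list.
#' @export
new_count_matrix <- function(counts, samples) {
  if (anyDuplicated(rownames(counts)))
    stop("count matrix: duplicate transcript ids")
  if (anyDuplicated(colnames(counts)))
    stop("count matrix: duplicate sample ids")
  if (!identical(as.character(samples$sample), colnames(counts)))
    stop("count matrix: metadata rows must match matrix columns in order")
  if (!all(samples$condition %in% c("HS", "NHS")))
    stop("count matrix: condition must be 'HS' or 'NHS'")
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples),
            class = "count_matrix")
}

#' Write a count matrix and its sample metadata
#' @param x a `count_matrix`.
#' @param path,meta_path output TSV paths.
#' @export
write_counts <- function(x, path, meta_path) {
  df <- data.frame(transcript_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(x$samples, meta_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a transcript annotation catalog
#'
#' @param path TSV with columns `transcript_id` and `annotation`.
#' @param species_id optional species label attached to the catalog.
#' @return data.frame of class `annotation_catalog` with attribute
#'   `species`.
#' @export
read_annotations <- function(path, species_id = NA_character_) {
  df <- read.delim(path, stringsAsFactors = FALSE, quote = "",
                   na.strings = character())
  .require_columns(df, c("transcript_id", "annotation"),
                   "annotation catalog")
  new_annotation_catalog(df, species_id)
}

#' Construct an annotation catalog
#' @param df data.frame with `transcript_id`, `annotation`.
#' @param species_id species label.
#' @return an `annotation_catalog`.
#' @export
new_annotation_catalog <- function(df, species_id = NA_character_) {
  if (anyDuplicated(df$transcript_id))
    stop("annotation catalog: duplicate transcript ids")
  df$annotation[is.na(df$annotation)] <- ""
  attr(df, "species") <- species_id
  class(df) <- c("annotation_catalog", "data.frame")
  df
}

#' Write an annotation catalog
#' @param x an `annotation_catalog`.
#' @param path output TSV path.
#' @export
write_annotations <- function(x, path) {
  write.table(as.data.frame(x)[, c("transcript_id", "annotation")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read species metadata
#'
#' @param path TSV with columns `species`, `subfamily` (`Formicinae` or
#'   `Myrmicinae`), `genus` and `habitat` (`desert` or `temperate`).
#' @return data.frame of class `species_meta`.
#' @export
read_species_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("species", "subfamily", "genus", "habitat"),
                   "species metadata")
  new_species_meta(df)
}

#' Construct species metadata
#' @param df data.frame with `species`, `subfamily`, `genus`, `habitat`.
#' @return a `species_meta` data.frame.
#' @export
new_species_meta <- function(df) {
  if (anyDuplicated(df$species))
    stop("species metadata: duplicate species ids")
  if (!all(df$subfamily %in% c("Formicinae", "Myrmicinae")))
    stop("species metadata: subfamily must be Formicinae or Myrmicinae")
  if (!all(df$habitat %in% c("desert", "temperate")))
    stop("species metadata: habitat must be desert or temperate")
  class(df) <- c("species_meta", "data.frame")
  df
}

#' Write species metadata
#' @param x a `species_meta`.
#' @param path output TSV path.
#' @export
write_species_meta <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read an orthogroup table
#'
#' Reads the orthology tool's tab-separated dialect: the first column is
#' the orthogroup id, then one column per species whose cells are
#' comma-separated gene id lists (possibly empty).
#'
#' @param path TSV file.
#' @param species_list optional character vector of expected species
#'   columns; an unexpected column is an error.
#' @return an `orthogroup_table` (see [new_orthogroup_table()]).
#' @export
read_orthogroups <- function(path, species_list = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = character(), quote = "")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    warning("orthogroup table is empty")
    return(new_orthogroup_table(
      data.frame(orthogroup = character(), species = character(),
                 gene = character(), stringsAsFactors = FALSE),
      species = species_list %||% character()))
  }
  species <- names(df)[-1L]
  if (!is.null(species_list)) {
    unknown <- setdiff(species, species_list)
    if (length(unknown))
      stop(sprintf("orthogroup table: unknown species column(s): %s",
                   paste(unknown, collapse = ", ")))
    species <- species_list[species_list %in% species]
  }
  og <- df[[1L]]
  rows <- lapply(species, function(sp) {
    cells <- as.character(df[[sp]])
    cells[is.na(cells)] <- ""
    genes <- strsplit(cells, ",", fixed = TRUE)
    genes <- lapply(genes, function(g) {
      g <- trimws(g)
      g[nzchar(g)]
    })
    n <- lengths(genes)
    data.frame(orthogroup = rep(og, n), species = rep(sp, sum(n)),
               gene = unlist(genes, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  new_orthogroup_table(long, species = species, orthogroups = og)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an orthogroup table
#'
#' @param long data.frame with columns `orthogroup`, `species`, `gene`
#'   (one row per gene membership).
#' @param species character vector of species covered by the table.
#' @param orthogroups optional vector of orthogroup ids (to keep empty
#'   orthogroups and row order); defaults to those present in `long`.
#' @return list of class `orthogroup_table` with elements `long`,
#'   `species`, `orthogroups`.
#' @export
new_orthogroup_table <- function(long, species, orthogroups = NULL) {
  orthogroups <- orthogroups %||% unique(long$orthogroup)
  for (sp in unique(long$species)) {
    g <- long$gene[long$species == sp]
    if (anyDuplicated(g)) {
      dup <- g[duplicated(g)][1]
      stop(sprintf(
        "orthogroup table integrity: gene '%s' of species '%s' appears in more than one orthogroup",
        dup, sp))
    }
  }
  structure(list(long = long, species = species,
                 orthogroups = orthogroups),
            class = "orthogroup_table")
}

#' Write an orthogroup table
#' @param x an `orthogroup_table`.
#' @param path output TSV path.
#' @export
write_orthogroups <- function(x, path) {
  ogs <- x$orthogroups
  cols <- lapply(x$species, function(sp) {
    sub <- x$long[x$long$species == sp, , drop = FALSE]
    cells <- vapply(split(sub$gene, factor(sub$orthogroup, levels = ogs)),
                    paste, "", collapse = ", ")
    cells
  })
  df <- data.frame(Orthogroup = ogs, stats::setNames(cols, x$species),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a machine-readable study report
#'
#' Writes `report.json` (nested key-value report including the seed and
#' thresholds used) plus TSV summary tables: `overlap_pairs.tsv`
#' (observed / expected / SD / p per species pair), `orthology_summary.tsv`
#' and `species_results.tsv`. Re-running on identical results produces
#' byte-identical files.
#'
#' @param results an `antherm_results` object from [run_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  ok <- file.access(dir, 2) == 0
  if (!ok) stop(sprintf("report directory '%s' is not writable", dir))
  paths <- c(json = file.path(dir, "report.json"),
             overlap = file.path(dir, "overlap_pairs.tsv"),
             ortho = file.path(dir, "orthology_summary.tsv"),
             species = file.path(dir, "species_results.tsv"))
  jsonlite::write_json(.report_payload(results), paths["json"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_tsv0 <- function(df, p) {
    write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  .write_tsv0(results$overlap$pairs %||%
                data.frame(species_a = character(), species_b = character(),
                           observed = integer(), null_mean = numeric(),
                           null_sd = numeric(), p = numeric(),
                           significant = logical()),
              paths["overlap"])
  .write_tsv0(if (!is.null(results$orthology$summary))
                results$orthology$summary$per_species
              else data.frame(), paths["ortho"])
  .write_tsv0(results$species_table %||% data.frame(), paths["species"])
  invisible(paths)
}

.report_payload <- function(results) {
  cfg <- results$config
  list(
    seed = cfg$seed,
    config = cfg[c("fc_cut", "fdr_cut", "overlap_alpha", "mc_iterations",
                   "survival_upper", "survival_lower", "profile_cuts",
                   "utl_alpha")],
    species = results$species_list %||% list(),
    thermal = results$thermal_report %||% list(),
    expression = results$expression_report %||% list(),
    overlap = results$overlap_report %||% list(),
    orthology = results$orthology_report %||% list())
}
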