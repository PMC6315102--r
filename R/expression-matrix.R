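#' Construct an expression matrix with diel sample annotation
#'
#' The central container of the package: an entities-by-samples intensity
#' matrix (probes or genes in rows) together with a sample table carrying the
#' parsed diel time annotation, and a scale flag distinguishing raw linear
#' intensities from log2 values.
#'
#' @param values Numeric matrix, entities in rows and samples in columns. Row
#'   names are the entity ids (unique), column names the sample ids (unique).
#' @param samples Data frame with one row per column of `values`, containing
#'   at least `sample_id`, `label`, `replicate`, `organism`, `absolute_hour`
#'   and `phase`. Typically built by [read_expression_matrix()] or
#'   [diel_design()].
#' @param scale `"linear"` (non-negative intensities) or `"log2"`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, samples, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values), is.data.frame(samples))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique row names (entity ids)")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("values must have unique column names (sample ids)")
  }
  if (!all(is.finite(values))) stop("all expression values must be finite")
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale intensities must be non-negative")
  }
  needed <- c("sample_id", "label", "replicate", "organism", "absolute_hour", "phase")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    stop("sample table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(samples) != ncol(values) ||
    !identical(as.character(samples$sample_id), colnames(values))) {
    stop("sample table must match the matrix columns (same ids, same order)")
  }
  rep_hours <- tapply(samples$absolute_hour, samples$label, function(h) length(unique(h)))
  if (any(rep_hours != 1L)) {
    stop("replicate samples sharing a label must share the same time point")
  }
  structure(
    list(values = values, samples = samples, scale = scale),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d entities x %d samples (%s scale), %d time point(s)\n",
    nrow(x$values), ncol(x$values), x$scale, length(unique(x$samples$label))
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by entity and/or sample
#'
#' @param em An `expr_matrix`.
#' @param entities Character vector of entity ids (default: all).
#' @param sample_ids Character vector of sample ids (default: all).
#' @return A new `expr_matrix`.
#' @export
subset_matrix <- function(em, entities = NULL, sample_ids = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (is.null(entities)) entities <- rownames(em$values)
  if (is.null(sample_ids)) sample_ids <- colnames(em$values)
  missing_e <- setdiff(entities, rownames(em$values))
  if (length(missing_e)) stop("unknown entity id(s): ", paste(missing_e, collapse = ", "))
  keep <- match(sample_ids, em$samples$sample_id)
  if (anyNA(keep)) stop("unknown sample id(s)")
  expression_matrix(
    em$values[entities, sample_ids, drop = FALSE],
    em$samples[keep, , drop = FALSE],
    em$scale
  )
}

#' Build a sample table for a diel design
#'
#' @param labels Diel time labels in sampling order (one entry per chip; a
#'   label may repeat for replicate chips).
#' @param organism Organism tag stored with each sample.
#' @inheritParams parse_time_label
#' @return Data frame usable as the `samples` argument of
#'   [expression_matrix()], with replicate ids numbered within each label.
#' @export
diel_design <- function(labels, organism = "unknown", photoperiod_hours = 12,
                        dark_first = FALSE) {
  tt <- parse_time_series(labels,
    photoperiod_hours = photoperiod_hours, dark_first = dark_first
  )
  replicate <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  data.frame(
    sample_id = paste0(labels, "_", replicate),
    label = labels,
    replicate = as.character(replicate),
    organism = organism,
    absolute_hour = tt$absolute_hour,
    phase = tt$phase,
    cycle_index = tt$cycle_index,
    hour_in_phase = tt$hour_in_phase,
    stringsAsFactors = FALSE
  )
}

#' Read an expression matrix from a tab-separated table
#'
#' Expects a header row of sample ids of the form `<label>_<replicate>`
#' (e.g. `"L6_1"`, `"L6_2"`; the replicate suffix may be omitted for singleton
#' chips) and a first column of entity ids. Cells must be numeric; `NA`,
#' non-numeric cells, ragged rows and duplicate entity ids are rejected.
#'
#' @param path Path to a UTF-8, tab-delimited file with `.` decimal marks.
#' @param scale `"linear"` or `"log2"` (stored, not checked against content
#'   beyond the non-negativity rule for linear data).
#' @param organism Organism tag for the sample table.
#' @inheritParams parse_time_label
#' @return An `expr_matrix`.
#' @export
read_expression_matrix <- function(path, scale = c("log2", "linear"),
                                   organism = "unknown",
                                   photoperiod_hours = 12, dark_first = FALSE) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    colClasses = "character", stringsAsFactors = FALSE
  )
  if (ncol(raw) < 2L) stop("matrix file needs an id column plus >= 1 sample column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop(
      "duplicate entity id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  num <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(vals <- matrix(as.numeric(num), nrow = nrow(num)))
  bad <- which(is.na(vals) & !is.na(num), arr.ind = TRUE)
  bad <- rbind(bad, which(is.na(num), arr.ind = TRUE))
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric cell(s), e.g. entity '%s', sample '%s'",
      ids[bad[1, 1]], colnames(num)[bad[1, 2]]
    ))
  }
  dimnames(vals) <- list(ids, colnames(num))
  header <- colnames(num)
  has_rep <- grepl("_", header)
  labels <- ifelse(has_rep, sub("_[^_]*$", "", header), header)
  replicate <- ifelse(has_rep, sub("^.*_", "", header), "1")
  tt <- parse_time_series(labels,
    photoperiod_hours = photoperiod_hours, dark_first = dark_first
  )
  samples <- data.frame(
    sample_id = header,
    label = labels,
    replicate = replicate,
    organism = organism,
    absolute_hour = tt$absolute_hour,
    phase = tt$phase,
    cycle_index = tt$cycle_index,
    hour_in_phase = tt$hour_in_phase,
    stringsAsFactors = FALSE
  )
  expression_matrix(vals, samples, scale)
}

#' Write an expression matrix as a tab-separated table
#'
#' Inverse of [read_expression_matrix()]: column headers are the sample ids,
#' the first column holds the entity ids.
#'
#' @param em An `expr_matrix`.
#' @param path Output path.
#' @param id_column Name for the entity-id column (default `"id"`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, id_column = "id") {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(rownames(em$values), em$values,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(df)[1L] <- id_column
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column tab-separated table (`probe_id`, `gene_id`). Every probe must
#' map to exactly one gene.
#'
#' @param path Path to the table.
#' @return Data frame with columns `probe_id` and `gene_id`.
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.delim(path,
    header = TRUE, sep = "\t",
    colClasses = "character", stringsAsFactors = FALSE
  )
  if (!all(c("probe_id", "gene_id") %in% names(pm))) {
    stop("probe map needs columns probe_id and gene_id")
  }
  validate_probe_map(pm[, c("probe_id", "gene_id")])
}

validate_probe_map <- function(pm) {
  if (anyDuplicated(pm$probe_id)) {
    stop("probe map assigns some probe to more than one gene")
  }
  pm
}

#' Write a result table as TSV
#'
#' Plain tab-separated output for any per-gene/per-probe result data frame;
#' an empty result writes a header-only file. Use [read_report()] to load it
#' back.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(x, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write run metadata (parameters, seed, thresholds) as JSON
#'
#' Every analysis driver records the full parameter set it ran with, so any
#' number in the outputs can be traced to a configuration value.
#'
#' @param metadata Named list (nested lists allowed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(metadata, path) {
  stopifnot(is.list(metadata), !is.null(names(metadata)))
  jsonlite::write_json(metadata, path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
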