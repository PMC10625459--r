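#' Construct an expression matrix
#'
#' The central container of the package: an `N` cells by `M` markers matrix
#' of nonnegative staining intensities, with unique cell identifiers, unique
#' marker names, and (optionally) manually curated per-cell annotations used
#' for evaluation. Intensities are taken as provided; the package applies no
#' normalization or transformation, so inputs should be preprocessed the way
#' the source study preprocessed them (e.g. arcsinh transformation and
#' cross-image normalization).
#'
#' @param values numeric `N x M` matrix, no missing values.
#' @param cell_ids character vector of `N` unique cell identifiers
#'   (defaults to `cell1..cellN`).
#' @param marker_names character vector of `M` unique marker names
#'   (defaults to the column names of `values`).
#' @param annotations optional character vector of `N` curated cell-type
#'   labels.
#' @return An object of class `expression_matrix`: a list with fields
#'   `values`, `cell_ids`, `marker_names`, `annotations`.
#' @export
expression_matrix <- function(values, cell_ids = NULL, marker_names = NULL,
                              annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  n <- nrow(values); m <- ncol(values)
  if (n < 2L || m < 2L)
    stop("expression matrix needs at least 2 cells and 2 markers", call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)
  cell_ids <- cell_ids %||% rownames(values) %||% paste0("cell", seq_len(n))
  marker_names <- marker_names %||% colnames(values) %||% paste0("marker", seq_len(m))
  if (length(cell_ids) != n || anyDuplicated(cell_ids))
    stop("`cell_ids` must be ", n, " unique strings", call. = FALSE)
  if (length(marker_names) != m || anyDuplicated(marker_names))
    stop("duplicate or wrong-length marker names", call. = FALSE)
  if (!is.null(annotations)) {
    if (length(annotations) != n)
      stop("`annotations` must have one entry per cell", call. = FALSE)
    annotations <- as.character(annotations)
  }
  dimnames(values) <- list(cell_ids, marker_names)
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 marker_names = as.character(marker_names),
                 annotations = annotations),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d markers%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$annotations)) "" else
                sprintf(" (%d annotated classes)", length(unique(x$annotations)))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a cell-by-marker expression matrix from delimited text
#'
#' Expects one header row of marker names and one row per segmented cell.
#' The delimiter (comma or tab) is auto-detected from the header line. A
#' named annotation column is split out of the numeric block and kept as
#' per-cell labels. Rows containing empty/missing fields are rejected (with
#' a warning), never imputed; non-numeric text in a marker column is a parse
#' error naming the offending row and column.
#'
#' @param path file path to a CSV/TSV matrix.
#' @param annotation_column optional name of a column holding curated
#'   cell-type labels.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, annotation_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, quote = "\"", comment.char = "")
  if (nrow(raw) < 1L) stop("no data rows in ", path, call. = FALSE)
  ann <- NULL
  if (!is.null(annotation_column)) {
    if (!annotation_column %in% names(raw))
      stop("annotation column '", annotation_column, "' not found", call. = FALSE)
    ann <- raw[[annotation_column]]
    raw <- raw[setdiff(names(raw), annotation_column)]
  }
  if (anyDuplicated(names(raw)))
    stop("duplicate marker name in header: ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  num <- matrix(NA_real_, nrow(raw), ncol(raw),
                dimnames = list(NULL, names(raw)))
  for (j in seq_along(raw)) {
    col <- trimws(raw[[j]])
    col[col == ""] <- NA_character_
    vals <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(vals))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   col[bad[1L]], bad[1L], names(raw)[j]), call. = FALSE)
    num[, j] <- vals
  }
  drop <- which(rowSums(is.na(num)) > 0L)
  if (length(drop)) {
    warning(length(drop), " row(s) with missing entries rejected")
    num <- num[-drop, , drop = FALSE]
    if (!is.null(ann)) ann <- ann[-drop]
  }
  expression_matrix(num, annotations = ann)
}

#' Construct a run configuration
#'
#' Holds every tunable of the clustering pipeline. The defaults reproduce
#' the reference configuration: the four fused views are Pearson, Spearman,
#' cosine and Euclidean distance, 20000-cell subsamples, five repeats, and
#' a 0.05 significance level for the eigenvalue test that sizes the SOM
#' grid.
#'
#' @param metric_set character vector of metric names, each one of
#'   `"euclidean"`, `"manhattan"`, `"maximum"`, `"pearson"`, `"spearman"`,
#'   `"cosine"`.
#' @param k optional number of clusters (can also be passed per call).
#' @param grid_side optional SOM grid side; when given, eigenvalue-based
#'   estimation is bypassed.
#' @param seed integer master seed.
#' @param subsample_size cells per benchmark subsample.
#' @param n_repeats benchmark repeats.
#' @param alpha significance level in (0,1).
#' @param epochs SOM training epochs.
#' @return A `run_config` list.
#' @export
run_config <- function(metric_set = c("pearson", "spearman", "cosine", "euclidean"),
                       k = NULL, grid_side = NULL, seed = 42L,
                       subsample_size = 20000L, n_repeats = 5L,
                       alpha = 0.05, epochs = 10L) {
  known <- c("euclidean", "manhattan", "maximum", "pearson", "spearman", "cosine")
  bad <- setdiff(metric_set, known)
  if (length(bad))
    stop("unknown metric(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(k)) k <- stopifnot_scalar_int(k, "k", 1L)
  if (!is.null(grid_side)) grid_side <- stopifnot_scalar_int(grid_side, "grid_side", 2L)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop("`alpha` must be in (0,1)", call. = FALSE)
  structure(list(metric_set = metric_set, k = k, grid_side = grid_side,
                 seed = stopifnot_scalar_int(seed, "seed", -.Machine$integer.max),
                 subsample_size = stopifnot_scalar_int(subsample_size, "subsample_size"),
                 n_repeats = stopifnot_scalar_int(n_repeats, "n_repeats"),
                 alpha = alpha,
                 epochs = stopifnot_scalar_int(epochs, "epochs")),
            class = "run_config")
}

#' Write a partition to delimited text
#'
#' Two-column CSV (`cell_id`, `cluster_label`); [read_partition()] restores
#' it losslessly.
#'
#' @param partition a `partition` object or integer label vector.
#' @param path output file path.
#' @param ids optional cell ids when `partition` is a bare vector.
#' @export
write_partition <- function(partition, path, ids = NULL) {
  labels <- if (inherits(partition, "partition")) partition$labels else partition
  if (length(labels) == 0L) stop("empty partition", call. = FALSE)
  ids <- ids %||%
    (if (inherits(partition, "partition")) partition$ids else NULL) %||%
    paste0("cell", seq_along(labels))
  df <- data.frame(cell_id = ids, cluster_label = as.integer(labels))
  ok <- try(write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write partition to ", path, call. = FALSE)
  invisible(path)
}

#' Read a partition written by [write_partition()]
#' @param path file path.
#' @return A `partition` object with `ids` and integer `labels`.
#' @export
read_partition <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", colClasses = c("character", "integer"))
  new_partition(df$cluster_label, method = "file", ids = df$cell_id)
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write a structured evaluation report
#'
#' Serializes a report (scores keyed by method/metric/repeat plus run
#' metadata) as schema-versioned JSON. The report must carry a `seed` field
#' so that any score in it can be recomputed.
#'
#' @param report a named list; must contain `seed`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  if (!is.list(report)) stop("`report` must be a list", call. = FALSE)
  if (is.null(report$seed))
    stop("report is missing required 'seed' field", call. = FALSE)
  report$schema_version <- report$schema_version %||% REPORT_SCHEMA_VERSION
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = I(17),
                           null = "null")
  ok <- try(writeLines(json, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write report to ", path, call. = FALSE)
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path file path.
#' @return The report list.
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  if (is.null(rep$schema_version))
    stop("not a fusecyto report (no schema_version)", call. = FALSE)
  rep
}
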