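#' Construct an expression matrix with group labels
#'
#' The basic substrate of the pipeline: a features x samples matrix of
#' non-negative intensities, with every sample assigned to exactly one of two
#' groups (`case`, typically the mutant/knockout, and `control`).
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry rownames (feature ids) and colnames (sample ids).
#' @param groups named character vector or factor mapping every sample id to
#'   `"case"` or `"control"`.
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `groups` (a factor aligned with `colnames(values)`).
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("intensities must be finite and >= 0")
  groups <- unlist_groups(groups, colnames(values))
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

unlist_groups <- function(groups, sample_ids) {
  g <- as.character(groups)
  names(g) <- names(groups)
  if (is.null(names(g))) {
    if (length(g) != length(sample_ids))
      stop("unnamed group vector must match the number of samples")
    names(g) <- sample_ids
  }
  missing <- setdiff(sample_ids, names(g))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  g <- g[sample_ids]
  bad <- setdiff(unique(g), c("case", "control"))
  if (length(bad))
    stop("group labels must be 'case' or 'control', got: ",
         paste(bad, collapse = ", "))
  factor(g, levels = c("case", "control"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample ids and feature
#' ids in the first column. Parsing is strict: ragged rows, non-numeric cells
#' and duplicated feature ids are errors reported with their line number.
#'
#' @param path path to the TSV file.
#' @param group_map named character vector mapping sample ids to
#'   `"case"`/`"control"`. Samples present in the file but absent from the
#'   map are an error.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, group_map) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- trimws(header[-1L])
  n_col <- length(header)
  vals <- matrix(NA_real_, nrow = length(fields) - 1L, ncol = length(sample_ids))
  ids <- character(nrow(vals))
  for (i in seq_len(length(fields) - 1L)) {
    row <- fields[[i + 1L]]
    if (length(row) != n_col)
      stop(sprintf("%s line %d: expected %d fields, found %d",
                   path, i + 1L, n_col, length(row)))
    ids[i] <- trimws(row[1L])
    x <- suppressWarnings(as.numeric(row[-1L]))
    if (any(is.na(x)))
      stop(sprintf("%s line %d: non-numeric intensity value", path, i + 1L))
    vals[i, ] <- x
  }
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicated feature id '%s'", path, ids[duplicated(ids)][1L]))
  rownames(vals) <- ids
  colnames(vals) <- sample_ids
  unknown <- setdiff(sample_ids, names(group_map))
  if (length(unknown))
    stop(path, ": samples missing from group map: ", paste(unknown, collapse = ", "))
  expression_matrix(vals, group_map[sample_ids])
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips byte-identically for
#' values written with full precision.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
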