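#' Gene-set annotation container
#'
#' A local stand-in for a GO-style annotation resource: a list of terms, each
#' with an id, a human-readable name and a member gene set, plus the gene
#' universe used as the background for enrichment tests.
#'
#' @param terms named list of character vectors of member gene ids; names are
#'   term ids.
#' @param term_names optional named character vector of descriptions, keyed
#'   by term id; defaults to the term ids themselves.
#' @param universe optional character vector; defaults to the union of all
#'   members. Every member of every term must be in the universe.
#' @return object of class `annotation_set` with elements `terms`,
#'   `term_names`, `universe`.
#' @export
annotation_set <- function(terms, term_names = NULL, universe = NULL) {
  stopifnot(is.list(terms))
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (is.null(universe)) universe <- unique(unlist(terms, use.names = FALSE))
  universe <- unique(as.character(universe))
  stray <- setdiff(unlist(terms, use.names = FALSE), universe)
  if (length(stray))
    stop("term members outside the universe: ", paste(utils::head(stray, 5), collapse = ", "))
  if (is.null(term_names)) {
    term_names <- names(terms)
    names(term_names) <- names(terms)
  }
  structure(list(terms = terms,
                 term_names = term_names[names(terms)],
                 universe = universe),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d terms over a universe of %d genes\n",
              length(x$terms), length(x$universe)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one term per line, tab-separated, with term id,
#' description, then member gene ids. Lines with fewer than three fields are
#' a parse error (a term must have at least one member).
#'
#' @param path path to a GMT file.
#' @param universe optional background gene set; defaults to the union of all
#'   members.
#' @return an [annotation_set()]; an empty file yields an empty (valid) set.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(annotation_set(stats::setNames(list(), character(0)),
                          universe = if (is.null(universe)) character(0) else universe))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("%s line %d: GMT line needs >= 3 tab-separated fields",
                 path, short[1L]))
  ids <- vapply(fields, `[[`, "", 1L)
  descs <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  names(members) <- ids
  annotation_set(members, stats::setNames(descs, ids), universe = universe)
}

#' Write an annotation set in GMT format
#' @param x an `annotation_set`.
#' @param path output path.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "annotation_set"))
  lines <- vapply(names(x$terms), function(id) {
    paste(c(id, x$term_names[[id]], x$terms[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
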