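#' Hypergeometric term enrichment over a gene-set annotation
#'
#' For every term, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap when `n_query` genes are sampled without
#' replacement from a universe containing `n_term` term members, i.e.
#' `P(X >= k)` with `X ~ Hypergeometric(n_term, n_universe - n_term,
#' n_query)`. Benjamini-Hochberg adjustment is applied across all tested
#' terms. Query genes outside the universe are dropped with a warning.
#'
#' @param query character vector of gene ids.
#' @param annotation an [annotation_set()].
#' @return data.frame with columns `term_id`, `term_name`, `n_universe`,
#'   `n_term`, `n_query`, `n_overlap`, `p`, `q`, `overlap_genes`
#'   (semicolon-joined), ordered by ascending `p`.
#' @export
term_enrichment <- function(query, annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  if (!length(annotation$universe)) stop("empty annotation universe")
  key <- function(x) tolower(trimws(x))
  uni <- annotation$universe
  uni_key <- key(uni)
  q_in <- unique(key(query))
  outside <- setdiff(q_in, uni_key)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    q_in <- setdiff(q_in, outside)
  }
  N <- length(uni)
  n_query <- length(q_in)
  rows <- lapply(names(annotation$terms), function(id) {
    members <- key(annotation$terms[[id]])
    ov <- intersect(members, q_in)
    k <- length(ov)
    m <- length(members)
    p <- stats::phyper(k - 1L, m, N - m, n_query, lower.tail = FALSE)
    data.frame(term_id = id,
               term_name = unname(annotation$term_names[[id]]),
               n_universe = N, n_term = m, n_query = n_query,
               n_overlap = k, p = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$p, out$term_id),
             c("term_id", "term_name", "n_universe", "n_term", "n_query",
               "n_overlap", "p", "q", "overlap_genes")]
  row.names(out) <- NULL
  out
}

#' Group enriched terms into functional clusters
#'
#' Greedy single-linkage clustering of terms whose member-gene Jaccard
#' similarity meets a threshold, in the spirit of functional-annotation
#' clustering tools: related GO terms (which share most of their genes)
#' collapse into one cluster scored by the negative log10 of the geometric
#' mean of its members' p-values. Clusters are returned sorted by score,
#' and those with `enrichment_score > score_floor` are flagged as top
#' clusters.
#'
#' @param terms data.frame from [term_enrichment()].
#' @param annotation the [annotation_set()] supplying member genes.
#' @param similarity_threshold Jaccard cutoff for linking two terms
#'   (default 0.5).
#' @param score_floor threshold above which a cluster is flagged `top`
#'   (default 1.0, i.e. geometric-mean p below 0.1).
#' @return data.frame with one row per cluster: `cluster`, `n_terms`,
#'   `enrichment_score`, `top`, `term_ids` (semicolon-joined, ordered by
#'   member p), `best_term_name`.
#' @export
cluster_terms <- function(terms, annotation, similarity_threshold = 0.5,
                          score_floor = 1.0) {
  stopifnot(inherits(annotation, "annotation_set"))
  n <- nrow(terms)
  if (!n)
    return(data.frame(cluster = integer(0), n_terms = integer(0),
                      enrichment_score = numeric(0), top = logical(0),
                      term_ids = character(0), best_term_name = character(0),
                      stringsAsFactors = FALSE))
  sets <- lapply(terms$term_id, function(id)
    unique(tolower(annotation$terms[[id]])))
  # single linkage: union-find over pairs with Jaccard >= threshold
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    jac <- length(intersect(sets[[i]], sets[[j]])) /
           length(union(sets[[i]], sets[[j]]))
    if (is.finite(jac) && jac >= similarity_threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  rows <- lapply(unique(comp), function(cid) {
    idx <- which(comp == cid)
    idx <- idx[order(terms$p[idx])]
    score <- mean(-log10(terms$p[idx]))
    data.frame(n_terms = length(idx),
               enrichment_score = score,
               top = score > score_floor,
               term_ids = paste(terms$term_id[idx], collapse = ";"),
               best_term_name = terms$term_name[idx[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$enrichment_score), , drop = FALSE]
  out <- cbind(cluster = seq_len(nrow(out)), out)
  row.names(out) <- NULL
  out
}
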