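#' Derive the signed regulatory module downstream of the perturbed gene
#'
#' Edge signs are expressed in the wild-type frame: what the regulator does
#' in the normal tissue. A miRNA elevated in the knockout is normally
#' repressed by the regulator (repressive regulator->miRNA edge); a miRNA
#' reduced in the knockout is normally activated (activating edge). Every
#' miRNA->mRNA edge is repressive, since miRNAs silence their targets; the
#' knockout-side observation (targets of elevated miRNAs go down, targets of
#' reduced miRNAs go up) is derived from these signs rather than stored.
#'
#' @param mirna_de miRNA DE table; only rows with direction `up`/`down` and
#'   at least one pair contribute.
#' @param pairs pair table from [pair_inverse()].
#' @param regulator node name of the perturbed upstream gene
#'   (default `"Tdrd7"`).
#' @return data.frame of edges: `source`, `target`, `sign`
#'   (`activating`/`repressive`), `provenance`. One regulator->miRNA edge
#'   per retained miRNA plus one miRNA->mRNA edge per pair.
#' @export
build_module <- function(mirna_de, pairs, regulator = "Tdrd7") {
  key <- function(x) tolower(trimws(x))
  dir_of <- stats::setNames(mirna_de$direction, key(mirna_de$feature))
  retained <- unique(pairs$mirna)
  mi_dir <- unname(dir_of[key(retained)])
  if (any(is.na(mi_dir)))
    stop("pairs reference miRNAs absent from the DE table")
  top <- data.frame(source = rep(regulator, length(retained)),
                    target = retained,
                    # elevated in the knockout => normally repressed
                    sign = ifelse(mi_dir == "up", "repressive", "activating"),
                    provenance = rep("reference", length(retained)),
                    stringsAsFactors = FALSE)
  bottom <- if (nrow(pairs)) data.frame(source = pairs$mirna,
                                        target = pairs$mrna,
                                        sign = "repressive",
                                        provenance = "reference",
                                        stringsAsFactors = FALSE)
            else top[0, ]
  edges <- rbind(top, bottom)
  edges <- unique(edges)
  row.names(edges) <- NULL
  edges
}

#' Direction concordance of network targets across perturbation datasets
#'
#' For every network target mRNA, finds the perturbation datasets in which
#' it is misexpressed (`abs(fc) >= fc_threshold` and `p <= alpha`) and
#' whether that call has the same direction as in the reference knockout.
#' For gain-of-function datasets the reference direction is inverted before
#' comparison (overexpressing a regulator moves its downstream genes
#' opposite to deleting it). Targets absent from every dataset are excluded
#' from denominators.
#'
#' @param network_targets character vector of target mRNA ids.
#' @param perturbation_de named list of DE tables (columns `feature`, `fc`,
#'   `p`), one per dataset.
#' @param reference_directions named character vector (`up`/`down`), the
#'   targets' directions in the reference knockout.
#' @param perturbation_kind named character vector, `"loss"` or `"gain"` per
#'   dataset; defaults to all-loss.
#' @param fc_threshold,alpha misexpression thresholds (defaults 1.2, 0.05).
#' @return list of class `concordance_report`: `per_target` data.frame
#'   (`target`, `n_datasets_present`, `n_misexpressed`, `n_same_direction`,
#'   `concordant`), and the summary counts/fractions
#'   `n_targets`, `n_present`, `n_misexpressed`, `frac_misexpressed`,
#'   `n_concordant`, `frac_concordant` (fraction of misexpressed targets
#'   with >= 1 same-direction call).
#' @export
concordance <- function(network_targets, perturbation_de,
                        reference_directions,
                        perturbation_kind = NULL,
                        fc_threshold = 1.2, alpha = 0.05) {
  key <- function(x) tolower(trimws(x))
  targets <- unique(network_targets)
  if (is.null(perturbation_kind))
    perturbation_kind <- stats::setNames(rep("loss", length(perturbation_de)),
                                         names(perturbation_de))
  stopifnot(all(names(perturbation_de) %in% names(perturbation_kind)),
            all(perturbation_kind %in% c("loss", "gain")))
  ref <- stats::setNames(as.character(reference_directions),
                         key(names(reference_directions)))
  miss <- setdiff(key(targets), names(ref))
  if (length(miss))
    stop("no reference direction for: ", paste(utils::head(miss, 5), collapse = ", "))

  per <- lapply(targets, function(tg) {
    k <- key(tg)
    present <- 0L; mis <- 0L; same <- 0L
    for (ds in names(perturbation_de)) {
      de <- perturbation_de[[ds]]
      i <- match(k, key(de$feature))
      if (is.na(i)) next
      present <- present + 1L
      if (abs(de$fc[i]) >= fc_threshold && de$p[i] <= alpha) {
        mis <- mis + 1L
        call_dir <- if (de$fc[i] > 0) "up" else "down"
        expect <- ref[[k]]
        if (perturbation_kind[[ds]] == "gain")
          expect <- if (expect == "up") "down" else "up"
        if (call_dir == expect) same <- same + 1L
      }
    }
    data.frame(target = tg, n_datasets_present = present,
               n_misexpressed = mis, n_same_direction = same,
               concordant = same >= 1L, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  present <- per[per$n_datasets_present > 0L, ]
  misexp <- present[present$n_misexpressed > 0L, ]
  structure(list(
    per_target = per,
    n_targets = nrow(per),
    n_present = nrow(present),
    n_misexpressed = nrow(misexp),
    frac_misexpressed = if (nrow(present)) nrow(misexp) / nrow(present) else NA_real_,
    n_concordant = sum(misexp$concordant),
    frac_concordant = if (nrow(misexp)) sum(misexp$concordant) / nrow(misexp)
                      else NA_real_),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance: %d targets, %d present, %d misexpressed (%.0f%%), %d concordant (%.0f%%)\n",
    x$n_targets, x$n_present, x$n_misexpressed, 100 * x$frac_misexpressed,
    x$n_concordant, 100 * x$frac_concordant))
  invisible(x)
}

#' Export a signed network
#'
#' SIF: one `source<TAB>relation<TAB>target` line per edge with relation
#' `activates`/`represses`. GraphML: nodes plus edges with a `sign`
#' attribute, readable by standard graph tooling.
#'
#' @param edges edge table from [build_module()].
#' @param path output path.
#' @param format `"sif"` or `"graphml"`.
#' @export
export_graph <- function(edges, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  relation <- ifelse(edges$sign == "activating", "activates", "represses")
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", edges$source, relation, edges$target),
               path)
    return(invisible(path))
  }
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key", id = "sign", `for` = "edge",
                      attr.name = "sign", attr.type = "string")
  g <- xml2::xml_add_child(doc, "graph", id = "net", edgedefault = "directed")
  for (node in unique(c(edges$source, edges$target)))
    xml2::xml_add_child(g, "node", id = node)
  for (i in seq_len(nrow(edges))) {
    e <- xml2::xml_add_child(g, "edge", source = edges$source[i],
                             target = edges$target[i])
    d <- xml2::xml_add_child(e, "data", key = "sign")
    xml2::xml_text(d) <- edges$sign[i]
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a SIF file back into an edge table
#' @param path SIF path written by [export_graph()].
#' @return edge data.frame (`source`, `target`, `sign`).
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(source = character(0), target = character(0),
                      sign = character(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 3L)) stop(path, ": malformed SIF line")
  data.frame(source = vapply(f, `[[`, "", 1L),
             target = vapply(f, `[[`, "", 3L),
             sign = ifelse(vapply(f, `[[`, "", 2L) == "activates",
                           "activating", "repressive"),
             stringsAsFactors = FALSE)
}
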