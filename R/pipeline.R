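#' Read a pipeline run configuration
#'
#' Flat `key: value` text. Path keys (`mirna_matrix`, `groups`,
#' `mrna_de_p4`, `mrna_de_p30`, `target_map`, `enrichment_p4`,
#' `enrichment_p30`, `annotation`, `perturbation_manifest`, `qpcr`,
#' `tier_rules`) are resolved relative to the config file's directory;
#' threshold keys (`fc`, `alpha`, `min_score`, `expression_floor`,
#' `intensity_high`, `seed`) override the defaults, which are the standard
#' values for this analysis (fc 1.2, alpha 0.05, min_score 50,
#' expression_floor 100, intensity_high 500). Every referenced path must
#' exist at validation time; `mrna_de_p30`, `annotation`,
#' `perturbation_manifest`, `qpcr` and `tier_rules` are optional.
#'
#' @param path config file path.
#' @return list of class `run_config` with `paths` and `thresholds`.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop(path, ": cannot parse config line: ", lines[bad[1L]])
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  if (anyDuplicated(keys)) stop(path, ": duplicated config key")
  conf <- stats::setNames(as.list(vals), keys)

  path_keys <- c("mirna_matrix", "groups", "mrna_de_p4", "mrna_de_p30",
                 "target_map", "enrichment_p4", "enrichment_p30",
                 "annotation", "perturbation_manifest", "qpcr", "tier_rules")
  required <- c("mirna_matrix", "groups", "mrna_de_p4", "target_map",
                "enrichment_p4", "enrichment_p30")
  miss <- setdiff(required, keys)
  if (length(miss))
    stop(path, ": missing required config keys: ", paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  paths <- lapply(conf[intersect(path_keys, keys)], function(p)
    if (grepl("^/", p)) p else file.path(base, p))
  gone <- !vapply(paths, file.exists, logical(1))
  if (any(gone))
    stop(path, ": configured input(s) do not exist: ",
         paste(unlist(paths[gone]), collapse = ", "))

  thr <- list(fc = 1.2, alpha = 0.05, min_score = 50,
              expression_floor = 100, intensity_high = 500, seed = 1L)
  for (k in names(thr)) if (k %in% keys) thr[[k]] <- as.numeric(conf[[k]])
  if (any(unlist(thr[c("fc", "alpha", "min_score", "expression_floor",
                       "intensity_high")]) <= 0))
    stop(path, ": thresholds must be positive")
  structure(list(paths = paths, thresholds = thr), class = "run_config")
}

#' Run the full analysis from a configuration
#'
#' Orchestrates every stage: quantile normalization and differential miRNA
#' calling, detection summary and highly-expressed catalog, score-filtered
#' inverse pairing, two-stage lens-enrichment flagging and tier assignment,
#' Pearson inverse correlation, GO-term enrichment with cluster scoring
#' (when an annotation is configured), regulatory-module derivation with
#' SIF/GraphML export and perturbation concordance (when a perturbation
#' manifest is configured), and qPCR quantification (when a Ct table is
#' configured). Deterministic given the config. Any stage failure aborts
#' with the stage name.
#'
#' @param config a [read_run_config()] result.
#' @param out_dir output directory for stage TSVs, graph exports and the
#'   summary report.
#' @param quiet suppress per-stage progress messages.
#' @return invisible list with every stage result (`de`, `detection`,
#'   `highly_expressed`, `pairs`, `tiers`, `correlation`, `enrichment`,
#'   `clusters`, `edges`, `concordance`, `qpcr`, `summary`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  thr <- config$thresholds
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  say("differential expression")
  de <- stage("differential_expression", {
    gr <- utils::read.delim(config$paths$groups, stringsAsFactors = FALSE)
    mat <- read_expression_matrix(config$paths$mirna_matrix,
                                  stats::setNames(gr$group, gr$sample))
    norm <- quantile_normalize(mat)
    list(mat = norm,
         de = differential_test(norm, fc_threshold = thr$fc, alpha = thr$alpha))
  })
  wt(de$de, "mirna_de.tsv")
  detection <- summarize_detection(de$mat)
  hi <- highly_expressed(de$de, thr$intensity_high)
  wt(hi, "highly_expressed.tsv")

  say("target pairing")
  pairs <- stage("target_pairing", {
    targets <- filter_targets(read_target_map(config$paths$target_map),
                              thr$min_score)
    mrna_p4 <- utils::read.delim(config$paths$mrna_de_p4, stringsAsFactors = FALSE)
    mrna_p30 <- if (!is.null(config$paths$mrna_de_p30))
      utils::read.delim(config$paths$mrna_de_p30, stringsAsFactors = FALSE)
    withCallingHandlers(
      pair_inverse(de$de, mrna_p4, targets, mrna_p30),
      warning = function(w) { say("  note: ", conditionMessage(w))
                              invokeRestart("muffleWarning") })
  })

  say("prioritization")
  tiers <- stage("prioritization", {
    p <- enrichment_filter(pairs, read_enrichment_table(config$paths$enrichment_p4),
                           "p4", thr$expression_floor)
    p <- enrichment_filter(p, read_enrichment_table(config$paths$enrichment_p30),
                           "p30", thr$expression_floor)
    rules <- if (!is.null(config$paths$tier_rules))
      read_tier_rules(config$paths$tier_rules) else tier_rules()
    assign_tiers(p, rules)
  })
  wt(tiers, "pairs_tiered.tsv")
  corr <- stage("correlation", {
    mrna_p4 <- utils::read.delim(config$paths$mrna_de_p4, stringsAsFactors = FALSE)
    inverse_correlation(tiers, de$de, mrna_p4)
  })

  enrich <- clusters <- NULL
  if (!is.null(config$paths$annotation)) {
    say("GO enrichment")
    enrich <- stage("enrichment", {
      annot <- read_gmt(config$paths$annotation)
      query <- unique(tiers$mrna[tiers$tier != "unranked"])
      suppressWarnings(term_enrichment(query, annot))
    })
    clusters <- stage("clustering",
                      cluster_terms(enrich[enrich$p <= 0.05, ],
                                    read_gmt(config$paths$annotation)))
    wt(enrich, "go_terms.tsv"); wt(clusters, "go_clusters.tsv")
  }

  say("regulatory network")
  edges <- stage("network", build_module(de$de, tiers))
  export_graph(edges, file.path(out_dir, "network.sif"), "sif")
  export_graph(edges, file.path(out_dir, "network.graphml"), "graphml")

  conc <- NULL
  if (!is.null(config$paths$perturbation_manifest)) {
    conc <- stage("concordance", {
      man <- utils::read.delim(config$paths$perturbation_manifest,
                               stringsAsFactors = FALSE)
      base <- dirname(config$paths$perturbation_manifest)
      tables <- stats::setNames(lapply(man$path, function(p)
        utils::read.delim(if (grepl("^/", p)) p else file.path(base, p),
                          stringsAsFactors = FALSE)), man$dataset_id)
      mrna_p4 <- utils::read.delim(config$paths$mrna_de_p4,
                                   stringsAsFactors = FALSE)
      refd <- stats::setNames(mrna_p4$direction, mrna_p4$feature)
      targets <- unique(tiers$mrna)
      concordance(targets, tables, refd[targets],
                  stats::setNames(man$perturbation_kind, man$dataset_id),
                  fc_threshold = thr$fc, alpha = thr$alpha)
    })
    wt(conc$per_target, "concordance.tsv")
  }

  qp <- NULL
  if (!is.null(config$paths$qpcr)) {
    say("qPCR")
    qp <- stage("qpcr", {
      ct <- read_qpcr_table(config$paths$qpcr)
      refs <- intersect(c("miR-17", "Gapdh", "Actb"), unique(ct$assay))
      targets <- setdiff(unique(ct$assay), refs)
      qpcr_panel(ct, targets, refs)
    })
    wt(qp, "qpcr_results.tsv")
  }

  ts <- attr(tiers, "tier_summary")
  summary <- c(
    sprintf("n_mirnas_tested: %d", nrow(de$de)),
    sprintf("n_detected: %d", detection$n_detected),
    sprintf("n_de_up: %d", sum(de$de$direction == "up")),
    sprintf("n_de_down: %d", sum(de$de$direction == "down")),
    sprintf("n_highly_expressed: %d", nrow(hi)),
    sprintf("n_pairs: %d", nrow(tiers)),
    sprintf("n_unique_mrnas: %d", length(unique(tolower(tiers$mrna)))),
    sprintf("tiers_up_group: top=%d high=%d promising=%d",
            ts$top[ts$mirna_direction == "up"],
            ts$high[ts$mirna_direction == "up"],
            ts$promising[ts$mirna_direction == "up"]),
    sprintf("tiers_down_group: top=%d high=%d promising=%d",
            ts$top[ts$mirna_direction == "down"],
            ts$high[ts$mirna_direction == "down"],
            ts$promising[ts$mirna_direction == "down"]),
    sprintf("pearson_r: %.6f", corr$r),
    sprintf("pearson_p: %.3g", corr$p),
    if (!is.null(conc)) sprintf("frac_misexpressed: %.4f", conc$frac_misexpressed),
    if (!is.null(conc)) sprintf("frac_concordant: %.4f", conc$frac_concordant),
    sprintf("n_network_edges: %d", nrow(edges)))
  writeLines(summary, file.path(out_dir, "summary.txt"))
  say("done")

  invisible(list(de = de$de, detection = detection, highly_expressed = hi,
                 pairs = pairs, tiers = tiers, correlation = corr,
                 enrichment = enrich, clusters = clusters, edges = edges,
                 concordance = conc, qpcr = qp, summary = summary))
}
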