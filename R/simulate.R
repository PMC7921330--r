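#' Design of a synthetic lens miRNA study
#'
#' Describes every knob of the synthetic-data generator. The defaults
#' emulate the study conditions of a knockout-vs-control lens miRNA
#' profiling experiment: three biological replicates per group, 700 miRNA
#' features on an intensity scale spanning roughly 1 to 16000, 8 planted
#' reduced and 14 planted elevated miRNAs whose effect magnitudes and
#' control-side intensities span the 1.2-2.2-fold / 4-630-intensity range
#' typical of such arrays, log-normal multiplicative noise, a miRDB-style
#' target map in which true targets score in \[50, 100\] and decoys below
#' 50, inverse suppression of true targets in the mRNA DE tables, 50% of
#' target genes lens-enriched per stage, and seven perturbation DE datasets
#' whose per-target direction agreement with the reference knockout is
#' planted at 80%.
#'
#' @param n_mirnas,n_mrnas feature-space sizes.
#' @param n_samples_per_group biological replicates per group.
#' @param up_effects,down_effects multiplicative effect sizes (> 1) of the
#'   planted elevated/reduced miRNAs; lengths set the planted counts.
#' @param up_bases,down_bases control-group mean intensities of the planted
#'   features; recycled against the effect vectors.
#' @param sigma log-normal noise sd (natural-log scale) on intensities.
#' @param target_density probability that a given (planted miRNA, mRNA of
#'   the matching pool) pair is a true target.
#' @param decoy_fraction fraction of the written target map that is decoy
#'   entries scoring below the retention floor.
#' @param inverse_jitter log-scale sd of the pair-level jitter on the
#'   planted mRNA suppression.
#' @param enrichment_fraction fraction of true-target genes marked
#'   lens-enriched, independently per stage.
#' @param p30_de_fraction fraction of true-target genes also differentially
#'   expressed (same direction) at the later stage.
#' @param direction_agreement probability a network target's perturbation
#'   calls agree in direction with the reference knockout.
#' @param perturb_coverage probability a target gene appears in a given
#'   perturbation dataset.
#' @param perturb_misexpression probability a covered target is called
#'   misexpressed in that dataset.
#' @param seed integer seed; identical seeds give identical outputs.
#' @return object of class `synthetic_design` (a validated list).
#' @export
synthetic_design <- function(
    n_mirnas = 700, n_mrnas = 4000, n_samples_per_group = 3,
    up_effects = c(1.2, 1.3, 1.4, 1.4, 1.5, 1.5, 1.6, 1.6, 1.6,
                   1.7, 1.8, 1.9, 2.1, 2.2),
    down_effects = c(1.7, 1.7, 1.5, 1.4, 1.4, 1.3, 1.3, 1.2),
    up_bases = c(75.7, 21.3, 20.4, 5.2, 6.5, 12.2, 7.0, 16.4, 12.5,
                 8.2, 4.4, 7.4, 7.5, 7.2),
    down_bases = c(30.6, 28.6, 45.1, 80.6, 20.1, 627.0, 99.5, 120.5),
    sigma = 0.1,
    target_density = 0.02,
    decoy_fraction = 0.3,
    inverse_jitter = 0.15,
    enrichment_fraction = 0.5,
    p30_de_fraction = 0.5,
    direction_agreement = 0.8,
    perturb_coverage = 0.4,
    perturb_misexpression = 0.6,
    seed = 1L) {
  d <- list(n_mirnas = as.integer(n_mirnas), n_mrnas = as.integer(n_mrnas),
            n_samples_per_group = as.integer(n_samples_per_group),
            up_effects = up_effects, down_effects = down_effects,
            up_bases = rep_len(up_bases, length(up_effects)),
            down_bases = rep_len(down_bases, length(down_effects)),
            sigma = sigma, target_density = target_density,
            decoy_fraction = decoy_fraction,
            inverse_jitter = inverse_jitter,
            enrichment_fraction = enrichment_fraction,
            p30_de_fraction = p30_de_fraction,
            direction_agreement = direction_agreement,
            perturb_coverage = perturb_coverage,
            perturb_misexpression = perturb_misexpression,
            seed = as.integer(seed))
  stopifnot(d$n_mirnas >= 1, d$n_mrnas >= 1, d$n_samples_per_group >= 1,
            all(d$up_effects > 1), all(d$down_effects > 1),
            length(d$up_effects) + length(d$down_effects) <= d$n_mirnas,
            d$sigma >= 0, d$target_density > 0, d$target_density <= 1,
            d$decoy_fraction >= 0, d$decoy_fraction < 1,
            d$enrichment_fraction >= 0, d$enrichment_fraction <= 1,
            d$p30_de_fraction >= 0, d$p30_de_fraction <= 1,
            d$direction_agreement >= 0, d$direction_agreement <= 1)
  structure(d, class = "synthetic_design")
}

# run code under a fixed RNG state, restoring the caller's state afterwards
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a full synthetic study with planted ground truth
#'
#' Writes every input the pipeline consumes -- miRNA intensity matrix with
#' group labels, two-stage mRNA DE tables, a scored target map with decoys,
#' two lens-enrichment tables, seven perturbation DE tables (one
#' gain-of-function), a GO-style annotation GMT and a qPCR Ct table --
#' together with ground-truth tables listing the planted differential
#' miRNAs, true target pairs, per-stage enrichment flags, per-target
#' concordance flags and planted ddCt values, plus a flat `manifest.txt`
#' with file names and md5 checksums. Output is bit-identical for a given
#' design (including its seed).
#'
#' @param design a [synthetic_design()].
#' @param out_dir output directory, created if needed.
#' @return invisible list: `dir`, `files` (named paths), `truth` (in-memory
#'   ground-truth tables), `groups` (sample group map).
#' @export
generate_study <- function(design, out_dir) {
  stopifnot(inherits(design, "synthetic_design"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  with_rng(design$seed, generate_study_impl(design, out_dir))
}

generate_study_impl <- function(d, out_dir) {
  n_up <- length(d$up_effects); n_down <- length(d$down_effects)
  mirna_ids <- sprintf("mir-s%04d", seq_len(d$n_mirnas))
  up_ids <- mirna_ids[seq_len(n_up)]
  down_ids <- mirna_ids[n_up + seq_len(n_down)]
  mrna_ids <- sprintf("Gene%04d", seq_len(d$n_mrnas))
  n <- d$n_samples_per_group
  sample_ids <- c(paste0("T", seq_len(n)), paste0("C", seq_len(n)))
  groups <- stats::setNames(rep(c("case", "control"), each = n), sample_ids)

  ## miRNA intensity matrix: base * effect^(case) * lognormal noise
  base <- stats::rlnorm(d$n_mirnas, meanlog = log(3), sdlog = 1.2)
  base[seq_len(n_up)] <- d$up_bases
  base[n_up + seq_len(n_down)] <- d$down_bases
  effect <- rep(1, d$n_mirnas)
  effect[seq_len(n_up)] <- d$up_effects
  effect[n_up + seq_len(n_down)] <- 1 / d$down_effects
  noise <- matrix(stats::rlnorm(d$n_mirnas * 2L * n, 0, d$sigma),
                  nrow = d$n_mirnas)
  vals <- (base * cbind(matrix(effect, d$n_mirnas, n), matrix(1, d$n_mirnas, n))) * noise
  dimnames(vals) <- list(mirna_ids, sample_ids)
  mat <- expression_matrix(vals, groups)

  ## true targets: each mRNA belongs to one direction pool so planted
  ## inverse effects never conflict
  pool <- sample(c("up", "down"), d$n_mrnas, replace = TRUE)
  truth_pairs <- list()
  for (mi in c(up_ids, down_ids)) {
    mdir <- if (mi %in% up_ids) "up" else "down"
    cand <- mrna_ids[pool == mdir]
    hit <- cand[stats::runif(length(cand)) < 2 * d$target_density]
    if (length(hit))
      truth_pairs[[mi]] <- data.frame(mirna = mi, mrna = hit,
                                      mirna_direction = mdir,
                                      stringsAsFactors = FALSE)
  }
  truth_pairs <- if (length(truth_pairs)) do.call(rbind, truth_pairs) else
    data.frame(mirna = character(0), mrna = character(0),
               mirna_direction = character(0), stringsAsFactors = FALSE)
  row.names(truth_pairs) <- NULL
  mir_effect <- stats::setNames(c(d$up_effects, d$down_effects),
                                c(up_ids, down_ids))

  ## mRNA DE tables: true targets suppressed (elevated-miRNA targets) or
  ## released (reduced-miRNA targets) with pair-level jitter; averaged per
  ## gene when several miRNAs share it
  jit <- exp(stats::rnorm(nrow(truth_pairs), 0, d$inverse_jitter))
  pair_l2 <- log2(unname(mir_effect[truth_pairs$mirna])) * jit *
             ifelse(truth_pairs$mirna_direction == "up", -1, 1)
  gene_l2 <- if (nrow(truth_pairs))
    vapply(split(pair_l2, truth_pairs$mrna), mean, numeric(1))
  else stats::setNames(numeric(0), character(0))
  target_genes <- names(gene_l2)

  mk_de <- function(genes, l2fc_map, de_p) {
    l2 <- unname(l2fc_map[genes])
    is_t <- !is.na(l2)
    l2[!is_t] <- stats::runif(sum(!is_t), -0.18, 0.18)   # |fc| < 1.14
    fc <- ifelse(l2 >= 0, 2^l2, -(2^(-l2)))
    p <- ifelse(is_t, de_p[seq_along(genes)], stats::runif(length(genes)))
    dir <- rep("unchanged", length(genes))
    dir[fc >= 1.2 & p <= 0.05] <- "up"
    dir[fc <= -1.2 & p <= 0.05] <- "down"
    data.frame(feature = genes, fc = fc, p = p, direction = dir,
               stringsAsFactors = FALSE)
  }
  de_p4 <- mk_de(mrna_ids, gene_l2,
                 stats::runif(d$n_mrnas, 1e-4, 0.01))
  ## later stage: only a subset of targets stay differential
  keep_p30 <- target_genes[stats::runif(length(target_genes)) < d$p30_de_fraction]
  gene_l2_p30 <- gene_l2
  gene_l2_p30[!(names(gene_l2_p30) %in% keep_p30)] <- NA
  gene_l2_p30 <- gene_l2_p30[!is.na(gene_l2_p30)]
  de_p30 <- mk_de(mrna_ids, gene_l2_p30,
                  stats::runif(d$n_mrnas, 1e-4, 0.01))

  ## target map: true pairs score >= 50, decoys below
  n_true <- nrow(truth_pairs)
  n_decoy <- round(n_true * d$decoy_fraction / (1 - d$decoy_fraction))
  decoys <- data.frame(
    mirna = sample(mirna_ids, n_decoy, replace = TRUE),
    mrna = sample(mrna_ids, n_decoy, replace = TRUE),
    score = round(stats::runif(n_decoy, 0, 49.9), 1),
    stringsAsFactors = FALSE)
  target_map <- rbind(
    data.frame(mirna = truth_pairs$mirna, mrna = truth_pairs$mrna,
               score = round(stats::runif(n_true, 50, 100), 1),
               stringsAsFactors = FALSE),
    decoys)
  # a decoy can collide with a true pair; keep the true (first) entry
  target_map <- target_map[!duplicated(target_map[c("mirna", "mrna")]), ]
  row.names(target_map) <- NULL
  truth_pairs$score <- target_map$score[seq_len(n_true)]

  ## lens enrichment per stage
  mk_enrich <- function() {
    enriched <- stats::setNames(stats::runif(length(target_genes)) <
                                  d$enrichment_fraction, target_genes)
    tab <- data.frame(gene = mrna_ids, stringsAsFactors = FALSE)
    is_e <- tab$gene %in% target_genes[enriched[target_genes]]
    tab$enrichment_fc <- ifelse(is_e, stats::runif(d$n_mrnas, 1.5, 8),
                                stats::runif(d$n_mrnas, 0.2, 1))
    tab$expression <- ifelse(is_e, stats::runif(d$n_mrnas, 100, 5000),
                             stats::runif(d$n_mrnas, 0, 99))
    list(tab = tab, flags = enriched)
  }
  en_p4 <- mk_enrich(); en_p30 <- mk_enrich()
  truth_enrichment <- data.frame(
    gene = target_genes,
    enriched_p4 = unname(en_p4$flags[target_genes]),
    enriched_p30 = unname(en_p30$flags[target_genes]),
    stringsAsFactors = FALSE)

  ## perturbation datasets: direction agreement planted per target
  ref_dir <- stats::setNames(ifelse(gene_l2 >= 0, "up", "down"), target_genes)
  concordant <- stats::setNames(
    stats::runif(length(target_genes)) < d$direction_agreement, target_genes)
  ds_names <- c("hsf4_lof", "notch_lof", "klf4_lof", "e2f123_lof",
                "mafgk_lof", "brg1_lof", "foxe3_gof")
  ds_kind <- stats::setNames(ifelse(grepl("_gof$", ds_names), "gain", "loss"),
                             ds_names)
  filler <- setdiff(mrna_ids, target_genes)
  perturb <- lapply(ds_names, function(ds) {
    covered <- target_genes[stats::runif(length(target_genes)) < d$perturb_coverage]
    mis <- covered[stats::runif(length(covered)) < d$perturb_misexpression]
    quiet <- setdiff(covered, mis)
    obs_dir <- vapply(mis, function(g) {
      same <- concordant[[g]]
      dir <- if (same) ref_dir[[g]] else
        if (ref_dir[[g]] == "up") "down" else "up"
      # gain-of-function datasets print the opposite observed direction
      if (ds_kind[[ds]] == "gain") dir <- if (dir == "up") "down" else "up"
      dir
    }, "")
    fill <- sample(filler, min(1000L, length(filler)))
    tab <- rbind(
      data.frame(feature = mis,
                 fc = ifelse(obs_dir == "up", 1, -1) * stats::runif(length(mis), 1.3, 3),
                 p = stats::runif(length(mis), 1e-4, 0.04),
                 stringsAsFactors = FALSE),
      data.frame(feature = quiet,
                 fc = stats::runif(length(quiet), -1.15, 1.15),
                 p = stats::runif(length(quiet)),
                 stringsAsFactors = FALSE),
      data.frame(feature = fill,
                 fc = stats::runif(length(fill), -1.15, 1.15),
                 p = stats::runif(length(fill)),
                 stringsAsFactors = FALSE))
    tab$fc[abs(tab$fc) < 1] <- sign(tab$fc[abs(tab$fc) < 1] + 1e-9) # keep |fc|>=1 convention
    tab$direction <- "unchanged"
    tab$direction[tab$fc >= 1.2 & tab$p <= 0.05] <- "up"
    tab$direction[tab$fc <= -1.2 & tab$p <= 0.05] <- "down"
    row.names(tab) <- NULL
    tab
  })
  names(perturb) <- ds_names
  truth_concordance <- data.frame(
    target = target_genes,
    reference_direction = unname(ref_dir[target_genes]),
    concordant = unname(concordant[target_genes]),
    stringsAsFactors = FALSE)

  ## annotation: generic terms plus a few concentrated in target genes
  n_terms <- 40L
  terms <- lapply(seq_len(n_terms), function(i) {
    size <- sample(10:50, 1L)
    if (i <= 5L && length(target_genes) >= 8L) {
      k <- min(round(0.8 * size), length(target_genes))
      unique(c(sample(target_genes, k), sample(mrna_ids, size - k)))
    } else sample(mrna_ids, size)
  })
  names(terms) <- sprintf("SET:%07d", seq_len(n_terms))
  annot <- annotation_set(terms,
    stats::setNames(sprintf("synthetic gene set %d", seq_len(n_terms)),
                    names(terms)),
    universe = mrna_ids)

  ## qPCR plate for a small validation panel of planted miRNAs
  panel <- c(up_ids[seq_len(min(2L, n_up))], down_ids[seq_len(min(3L, n_down))])
  planted_ddct <- stats::setNames(
    ifelse(panel %in% up_ids, -1, 1) * log2(mir_effect[panel]), panel)
  qpcr <- build_qpcr_table(panel, planted_ddct,
                           n_bio = d$n_samples_per_group, n_tech = 3L,
                           sigma_bio_shared = 0.3, sigma_bio = 0.1,
                           sigma_tech = 0.05)

  ## write everything
  files <- c(
    mirna_matrix = "mirna_matrix.tsv", groups = "groups.tsv",
    mrna_de_p4 = "mrna_de_p4.tsv", mrna_de_p30 = "mrna_de_p30.tsv",
    target_map = "target_map.tsv",
    enrichment_p4 = "enrichment_p4.tsv", enrichment_p30 = "enrichment_p30.tsv",
    annotation = "annotation.gmt",
    perturbation_manifest = "perturbation_manifest.tsv",
    qpcr = "qpcr_ct.tsv",
    truth_mirnas = "truth_mirnas.tsv", truth_pairs = "truth_pairs.tsv",
    truth_enrichment = "truth_enrichment.tsv",
    truth_concordance = "truth_concordance.tsv",
    truth_qpcr = "truth_qpcr.tsv")
  for (ds in ds_names) files[[paste0("perturbation_", ds)]] <-
    paste0("perturbation_", ds, ".tsv")
  paths <- stats::setNames(file.path(out_dir, files), names(files))

  wt <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  write_expression_matrix(mat, paths[["mirna_matrix"]])
  wt(data.frame(sample = names(groups), group = unname(groups)),
     paths[["groups"]])
  wt(de_p4, paths[["mrna_de_p4"]]); wt(de_p30, paths[["mrna_de_p30"]])
  wt(target_map, paths[["target_map"]])
  wt(en_p4$tab, paths[["enrichment_p4"]]); wt(en_p30$tab, paths[["enrichment_p30"]])
  write_gmt(annot, paths[["annotation"]])
  wt(data.frame(dataset_id = ds_names,
                perturbation_kind = unname(ds_kind[ds_names]),
                path = paste0("perturbation_", ds_names, ".tsv")),
     paths[["perturbation_manifest"]])
  for (ds in ds_names) wt(perturb[[ds]], paths[[paste0("perturbation_", ds)]])
  wt(qpcr, paths[["qpcr"]])

  truth_mirnas <- data.frame(
    feature = c(up_ids, down_ids),
    direction = rep(c("up", "down"), c(n_up, n_down)),
    effect = c(d$up_effects, d$down_effects),
    base_intensity = c(d$up_bases, d$down_bases),
    stringsAsFactors = FALSE)
  wt(truth_mirnas, paths[["truth_mirnas"]])
  wt(truth_pairs, paths[["truth_pairs"]])
  wt(truth_enrichment, paths[["truth_enrichment"]])
  wt(truth_concordance, paths[["truth_concordance"]])
  truth_qpcr <- data.frame(assay = names(planted_ddct),
                           ddct = unname(planted_ddct),
                           stringsAsFactors = FALSE)
  wt(truth_qpcr, paths[["truth_qpcr"]])

  manifest <- file.path(out_dir, "manifest.txt")
  md5 <- tools::md5sum(unname(paths))
  writeLines(c(sprintf("seed: %d", d$seed),
               sprintf("n_mirnas: %d", d$n_mirnas),
               sprintf("n_mrnas: %d", d$n_mrnas),
               sprintf("n_samples_per_group: %d", d$n_samples_per_group),
               sprintf("%s: %s %s", names(paths), unname(files), unname(md5))),
             manifest)

  invisible(list(dir = out_dir,
                 files = c(paths, manifest = manifest),
                 groups = groups,
                 truth = list(mirnas = truth_mirnas, pairs = truth_pairs,
                              enrichment = truth_enrichment,
                              concordance = truth_concordance,
                              qpcr = truth_qpcr),
                 perturbation_kind = ds_kind))
}

# shared bio offset cancels in dCt; assay-level bio noise and technical
# noise do not
build_qpcr_table <- function(panel, planted_ddct, n_bio, n_tech,
                             sigma_bio_shared, sigma_bio, sigma_tech,
                             reference_assays = c("miR-17", "Gapdh", "Actb")) {
  assays <- c(panel, reference_assays)
  baseline <- stats::setNames(stats::runif(length(assays), 18, 30), assays)
  rows <- list()
  for (grp in c("case", "control")) for (b in seq_len(n_bio)) {
    shared <- stats::rnorm(1, 0, sigma_bio_shared)
    for (a in assays) {
      bio_dev <- stats::rnorm(1, 0, sigma_bio)
      shift <- if (grp == "case" && a %in% names(planted_ddct))
        planted_ddct[[a]] else 0
      for (tch in seq_len(n_tech)) {
        rows[[length(rows) + 1L]] <- data.frame(
          assay = a, group = grp, bio_rep = paste0("b", b),
          tech_rep = paste0("t", tch),
          ct = baseline[[a]] + shift + shared + bio_dev +
               stats::rnorm(1, 0, sigma_tech),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$ct <- round(out$ct, 4)
  out
}

#' Generate a qPCR Ct table with planted ddCt values
#'
#' Ct per well = assay baseline + group shift (the planted ddCt, applied to
#' the case group of target assays) + a biological-replicate offset shared
#' across assays (removed by reference normalization) + an assay-level
#' biological deviation + technical noise. Reference assays (`miR-17`,
#' `Gapdh`, `Actb`) carry no group shift.
#'
#' @param design a [synthetic_design()] (supplies replicate counts and seed).
#' @param planted_ddct named numeric vector: target assay -> planted ddCt
#'   (positive = fewer transcripts in the case group).
#' @param n_tech technical replicates per biological replicate.
#' @param sigma_bio_shared,sigma_bio,sigma_tech noise sds in cycles.
#' @param reference_assays normalizer assay ids included in every group.
#' @return long-format Ct data.frame (`assay`, `group`, `bio_rep`,
#'   `tech_rep`, `ct`).
#' @export
generate_qpcr <- function(design, planted_ddct, n_tech = 3L,
                          sigma_bio_shared = 0.3, sigma_bio = 0.1,
                          sigma_tech = 0.05,
                          reference_assays = c("miR-17", "Gapdh", "Actb")) {
  stopifnot(inherits(design, "synthetic_design"),
            is.numeric(planted_ddct), !is.null(names(planted_ddct)))
  if (!length(reference_assays)) stop("at least one reference assay required")
  with_rng(design$seed,
           build_qpcr_table(names(planted_ddct), planted_ddct,
                            n_bio = design$n_samples_per_group,
                            n_tech = n_tech,
                            sigma_bio_shared = sigma_bio_shared,
                            sigma_bio = sigma_bio, sigma_tech = sigma_tech,
                            reference_assays = reference_assays))
}
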