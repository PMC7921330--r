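#' Read a miRNA -> mRNA target-prediction map
#'
#' Tab-delimited with header columns `mirna`, `mrna`, `score`; scores are
#' prediction confidences in \[0, 100\].
#'
#' @param path TSV path.
#' @return data.frame with columns `mirna`, `mrna`, `score`.
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "mrna", "score")
  if (!all(need %in% names(df)))
    stop(path, ": target map needs columns ", paste(need, collapse = ", "))
  if (any(!is.finite(df$score)) || any(df$score < 0) || any(df$score > 100))
    stop(path, ": scores must lie in [0, 100]")
  df[need]
}

#' Filter target predictions by confidence score
#'
#' @param predictions data.frame with columns `mirna`, `mrna`, `score`.
#' @param min_score inclusive score floor (default 50).
#' @return the rows with `score >= min_score`.
#' @export
filter_targets <- function(predictions, min_score = 50) {
  stopifnot(all(c("mirna", "mrna", "score") %in% names(predictions)))
  predictions[predictions$score >= min_score, , drop = FALSE]
}

#' Build inverse miRNA-mRNA pairs
#'
#' Retains the pairs where a differentially expressed miRNA is matched, in
#' the filtered target map, to a target mRNA moving in the opposite
#' direction: (miRNA up, mRNA down) and (miRNA down, mRNA up). Each pair
#' additionally records the mRNA's direction in the later-stage DE table when
#' one is supplied (`missing` when the gene is absent from it).
#'
#' miRNAs that are differentially expressed but absent from the target map
#' are dropped with a warning, mirroring the situation where a prediction
#' database has no entry for a feature.
#'
#' Identifiers are matched case-insensitively after trimming, preserving the
#' spelling of the DE tables in the output.
#'
#' @param mirna_de miRNA DE table ([differential_test()] output).
#' @param mrna_de mRNA DE table for the primary stage; needs columns
#'   `feature`, `fc`, `direction`.
#' @param targets filtered target map (`mirna`, `mrna`, `score`).
#' @param mrna_de_late optional mRNA DE table for a later stage.
#' @return data.frame of class `mirna_mrna_pairs` with columns `mirna`,
#'   `mrna`, `mirna_direction`, `mrna_direction`, `mrna_direction_late`,
#'   `score`, plus attribute `group_summary`: per miRNA-direction group,
#'   pair and unique-mRNA counts.
#' @export
pair_inverse <- function(mirna_de, mrna_de, targets, mrna_de_late = NULL) {
  de_mirnas <- mirna_de[mirna_de$direction %in% c("up", "down"), ]
  key <- function(x) tolower(trimws(x))

  absent <- setdiff(key(de_mirnas$feature), unique(key(targets$mirna)))
  if (length(absent)) {
    drop <- de_mirnas$feature[key(de_mirnas$feature) %in% absent]
    warning("no target predictions for: ", paste(sort(drop), collapse = ", "),
            "; excluded from pairing", call. = FALSE)
  }

  mrna_dir <- stats::setNames(mrna_de$direction, key(mrna_de$feature))
  late_dir <- if (is.null(mrna_de_late)) NULL else
    stats::setNames(mrna_de_late$direction, key(mrna_de_late$feature))

  idx <- match(key(targets$mirna), key(de_mirnas$feature))
  hit <- !is.na(idx)
  mirna_direction <- de_mirnas$direction[idx[hit]]
  mrna_key <- key(targets$mrna[hit])
  mrna_direction <- unname(mrna_dir[mrna_key])
  mrna_direction[is.na(mrna_direction)] <- "unchanged"

  inverse <- (mirna_direction == "up" & mrna_direction == "down") |
             (mirna_direction == "down" & mrna_direction == "up")
  pairs <- data.frame(
    mirna = de_mirnas$feature[idx[hit]][inverse],
    mrna = targets$mrna[hit][inverse],
    mirna_direction = mirna_direction[inverse],
    mrna_direction = mrna_direction[inverse],
    score = targets$score[hit][inverse],
    stringsAsFactors = FALSE, row.names = NULL)
  pairs$mrna_direction_late <- if (is.null(late_dir)) "missing" else {
    d <- unname(late_dir[key(pairs$mrna)])
    d[is.na(d)] <- "missing"
    d
  }
  pairs <- pairs[order(pairs$mirna, pairs$mrna), , drop = FALSE]
  row.names(pairs) <- NULL
  attr(pairs, "group_summary") <- pair_group_summary(pairs)
  class(pairs) <- c("mirna_mrna_pairs", "data.frame")
  pairs
}

pair_group_summary <- function(pairs) {
  do.call(rbind, lapply(c("up", "down"), function(d) {
    sub <- pairs[pairs$mirna_direction == d, ]
    data.frame(mirna_direction = d,
               n_pairs = nrow(sub),
               n_unique_mrnas = length(unique(tolower(sub$mrna))),
               n_mirnas = length(unique(tolower(sub$mirna))),
               stringsAsFactors = FALSE)
  }))
}
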