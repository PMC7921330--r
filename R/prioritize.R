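#' Read a lens-enrichment table
#'
#' iSyTE-style per-stage table with columns `gene`, `enrichment_fc` (signed
#' fold change of lens expression over a body-tissue reference) and
#' `expression` (lens expression intensity).
#'
#' @param path TSV path.
#' @return data.frame with those three columns.
#' @export
read_enrichment_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "enrichment_fc", "expression")
  if (!all(need %in% names(df)))
    stop(path, ": enrichment table needs columns ", paste(need, collapse = ", "))
  if (any(!is.finite(df$expression)) || any(df$expression < 0))
    stop(path, ": expression intensities must be finite and >= 0")
  df[need]
}

#' Flag pairs whose target mRNA is lens-enriched at a stage
#'
#' A pair is flagged `enriched_<stage>` when its mRNA appears in the stage's
#' enrichment table with expression intensity at or above the floor and an
#' enrichment fold change above 1 (i.e. expressed in the lens and higher
#' there than in the reference tissue pool). Genes absent from the table are
#' not flagged.
#'
#' @param pairs pair table from [pair_inverse()].
#' @param enrichment_table table from [read_enrichment_table()].
#' @param stage label appended to the flag column, e.g. `"p4"` or `"p30"`.
#' @param expression_floor inclusive intensity floor (default 100).
#' @return `pairs` with a logical column `enriched_<stage>` added.
#' @export
enrichment_filter <- function(pairs, enrichment_table, stage,
                              expression_floor = 100) {
  key <- tolower(trimws(enrichment_table$gene))
  ok <- enrichment_table$expression >= expression_floor &
        enrichment_table$enrichment_fc > 1
  enriched_genes <- unique(key[ok])
  flag <- tolower(trimws(pairs$mrna)) %in% enriched_genes
  pairs[[paste0("enriched_", stage)]] <- flag
  pairs
}

#' Tier rule sets for candidate prioritization
#'
#' A rule set maps each tier (`top`, `high`, `promising`) to a boolean
#' expression over the evidence flags `de_p4`, `de_p30`, `enriched_p4`,
#' `enriched_p30`, applied in that order with first match winning; pairs
#' matching no rule are `unranked`. The default encodes: top-priority
#' candidates are differentially expressed at both stages and lens-enriched
#' at both stages; high-priority are differential at both stages and
#' enriched at at least one; promising are differential at the primary stage
#' and enriched at at least one.
#'
#' `tier_rules()` builds a rule set from strings in a small `AND`/`OR`
#' grammar over the flag names (parentheses allowed);
#' `read_tier_rules()` reads one rule per line in the form
#' `tier: expression`.
#'
#' @param top,high,promising rule expressions as strings.
#' @return object of class `tier_rules`: named list of parsed expressions.
#' @export
tier_rules <- function(
    top = "de_p4 AND de_p30 AND enriched_p4 AND enriched_p30",
    high = "de_p4 AND de_p30 AND (enriched_p4 OR enriched_p30)",
    promising = "de_p4 AND (enriched_p4 OR enriched_p30)") {
  rules <- list(top = top, high = high, promising = promising)
  parsed <- lapply(rules, parse_rule_expr)
  structure(parsed, class = "tier_rules")
}

#' @rdname tier_rules
#' @param path rule file path, lines of the form `tier: expression`.
#' @export
read_tier_rules <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([a-z]+)\\s*:\\s*(.+)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    stop(path, ": cannot parse rule line: ", lines[bad[1L]])
  tiers <- vapply(kv, `[[`, "", 2L)
  exprs <- vapply(kv, `[[`, "", 3L)
  unknown <- setdiff(tiers, c("top", "high", "promising"))
  if (length(unknown))
    stop(path, ": unknown tier: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(tiers))
    stop(path, ": duplicated tier definition")
  args <- stats::setNames(as.list(exprs), tiers)
  do.call(tier_rules, args)
}

parse_rule_expr <- function(text) {
  norm <- gsub("\\bAND\\b", "&", gsub("\\bOR\\b", "|", text))
  expr <- tryCatch(str2lang(norm), error = function(e)
    stop("cannot parse rule expression: ", text))
  allowed <- c("de_p4", "de_p30", "enriched_p4", "enriched_p30",
               "&", "|", "(", "!")
  used <- setdiff(all.names(expr), allowed)
  if (length(used))
    stop("unknown names in rule expression '", text, "': ",
         paste(used, collapse = ", "))
  expr
}

#' Assign priority tiers to pairs
#'
#' Evidence flags per pair are derived from its columns: `de_p4` is true for
#' every retained pair (inverse pairing requires primary-stage differential
#' expression), `de_p30` when `mrna_direction_late` matches
#' `mrna_direction`, and the `enriched_*` flags from [enrichment_filter()].
#' Rules are applied top -> high -> promising, first match wins.
#'
#' @param pairs pair table carrying `enriched_p4` and `enriched_p30` columns.
#' @param rules a [tier_rules()] object.
#' @return `pairs` with a `tier` column, plus attribute `tier_summary`: per
#'   miRNA-direction group, unique-mRNA counts per tier. A gene shared by
#'   pairs in different tiers is counted once at its highest tier.
#' @export
assign_tiers <- function(pairs, rules = tier_rules()) {
  stopifnot(inherits(rules, "tier_rules"))
  need <- c("enriched_p4", "enriched_p30", "mrna_direction", "mrna_direction_late")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("pairs lack columns: ", paste(miss, collapse = ", "),
         " (run enrichment_filter for both stages first)")
  env <- list(de_p4 = rep(TRUE, nrow(pairs)),
              de_p30 = pairs$mrna_direction_late == pairs$mrna_direction,
              enriched_p4 = pairs$enriched_p4,
              enriched_p30 = pairs$enriched_p30)
  tier <- rep("unranked", nrow(pairs))
  for (t in c("promising", "high", "top"))   # increasing precedence
    tier[eval(rules[[t]], env)] <- t
  pairs$tier <- tier
  attr(pairs, "tier_summary") <- tier_summary(pairs)
  pairs
}

tier_summary <- function(pairs) {
  lvl <- c("top", "high", "promising", "unranked")
  do.call(rbind, lapply(c("up", "down"), function(d) {
    sub <- pairs[pairs$mirna_direction == d, ]
    # unique genes at their best tier
    best <- tapply(factor(sub$tier, levels = lvl), tolower(sub$mrna),
                   function(t) lvl[min(as.integer(t))])
    counts <- table(factor(unlist(best), levels = lvl))
    data.frame(mirna_direction = d,
               top = as.integer(counts[["top"]]),
               high = as.integer(counts[["high"]]),
               promising = as.integer(counts[["promising"]]),
               unranked = as.integer(counts[["unranked"]]),
               n_unique_mrnas = length(best),
               stringsAsFactors = FALSE)
  }))
}

#' Pearson inverse-correlation of paired fold changes
#'
#' Pearson correlation between the signed log2 fold change of each pair's
#' miRNA and that of its target mRNA, over all retained pairs, with the
#' two-sided p-value from the t transform of r. Signed ratio fold changes
#' are first mapped to log2 scale (`+2 -> 1`, `-2 -> -1`) so up and down
#' magnitudes are symmetric.
#'
#' @param pairs pair table from [pair_inverse()].
#' @param mirna_de,mrna_de DE tables supplying `fc` per feature.
#' @return list of class `correlation_result`: `r`, `p`, `n_pairs`.
#' @export
inverse_correlation <- function(pairs, mirna_de, mrna_de) {
  if (nrow(pairs) < 3L) stop("need >= 3 pairs for a correlation")
  key <- function(x) tolower(trimws(x))
  mi_fc <- stats::setNames(mirna_de$fc, key(mirna_de$feature))
  mr_fc <- stats::setNames(mrna_de$fc, key(mrna_de$feature))
  x <- log2_signed(unname(mi_fc[key(pairs$mirna)]))
  y <- log2_signed(unname(mr_fc[key(pairs$mrna)]))
  if (any(is.na(x)) || any(is.na(y)))
    stop("pairs reference features absent from the DE tables")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in fold changes; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n_pairs = length(x)),
            class = "correlation_result")
}

#' Map a signed ratio fold change to log2 scale
#' @param fc signed fold changes with `abs(fc) >= 1`.
#' @return `log2(fc)` for positive values, `-log2(-fc)` for negative.
#' @export
log2_signed <- function(fc) sign(fc) * log2(abs(fc))

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (p = %.3g, n = %d pairs)\n",
              x$r, x$p, x$n_pairs))
  invisible(x)
}
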