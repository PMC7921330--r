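#' Read a long-format qPCR Ct table
#'
#' Columns: `assay` (miRNA or gene id), `group` (`case`/`control`),
#' `bio_rep`, `tech_rep`, `ct` (threshold cycles).
#'
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("assay", "group", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(df)))
    stop(path, ": qPCR table needs columns ", paste(need, collapse = ", "))
  if (!all(df$group %in% c("case", "control")))
    stop(path, ": group must be case/control")
  if (any(!is.finite(df$ct))) stop(path, ": non-finite Ct values")
  df[need]
}

# dCt per well: target Ct minus the arithmetic mean of the reference Cts in
# the same (group, bio_rep, tech_rep). Averaging Cts is equivalent to the
# geometric mean of the linear reference quantities.
delta_ct_wells <- function(table, target_assay, reference_assays) {
  tgt <- table[table$assay == target_assay, ]
  if (!nrow(tgt)) stop("target assay not in table: ", target_assay)
  if (!all(c("case", "control") %in% unique(tgt$group)))
    stop("target assay '", target_assay, "' missing from one group")
  refs <- table[table$assay %in% reference_assays, ]
  found <- unique(refs$assay)
  miss <- setdiff(reference_assays, found)
  if (length(miss))
    stop("reference assay(s) missing from table: ", paste(miss, collapse = ", "))
  ref_mean <- stats::aggregate(ct ~ group + bio_rep + tech_rep, data = refs, FUN = mean)
  names(ref_mean)[names(ref_mean) == "ct"] <- "ref_ct"
  m <- merge(tgt, ref_mean, by = c("group", "bio_rep", "tech_rep"))
  if (nrow(m) < nrow(tgt))
    stop("reference Cts missing for some wells of ", target_assay)
  m$dct <- m$ct - m$ref_ct
  m
}

#' Relative expression by the 2^-ddCt method
#'
#' Per biological replicate, dCt is the mean over technical replicates of
#' (target Ct minus mean reference Ct per well); ddCt is the mean dCt of the
#' case group minus the mean dCt of the control group; relative expression is
#' `2^-ddCt`. A value below 1 means the target is less abundant in the case
#' group (each extra cycle halves the estimated input).
#'
#' @param table Ct table (see [read_qpcr_table()]).
#' @param target_assay assay id to quantify.
#' @param reference_assays character vector of normalizer assay ids, all
#'   required in both groups.
#' @return list of class `relative_expression`: `assay`, `ddct`, `rel_expr`,
#'   `direction` (`up`/`down`/`unchanged` in the case group), and the
#'   per-biological-replicate `dct` table.
#' @export
delta_delta_ct <- function(table, target_assay, reference_assays) {
  wells <- delta_ct_wells(table, target_assay, reference_assays)
  bio <- stats::aggregate(dct ~ group + bio_rep, data = wells, FUN = mean)
  ddct <- mean(bio$dct[bio$group == "case"]) -
          mean(bio$dct[bio$group == "control"])
  rel <- 2^(-ddct)
  structure(list(assay = target_assay, ddct = ddct, rel_expr = rel,
                 direction = if (rel > 1) "up" else if (rel < 1) "down"
                             else "unchanged",
                 dct = bio),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("%s: 2^-ddCt = %.3f (ddCt = %.3f), %s in case\n",
              x$assay, x$rel_expr, x$ddct, x$direction))
  invisible(x)
}

#' Two-level nested ANOVA on dCt values
#'
#' Variance decomposition of reference-normalized Cts with technical
#' replicates nested in biological replicates:
#' `dCt ~ group + bio_rep %in% group`, with the group effect tested against
#' the biological-replicate-within-group mean square (the correct error
#' stratum for a nested design; technical replicates only stabilize the
#' biological-replicate means). Fitted via [stats::aov()].
#'
#' @param table Ct table.
#' @param target_assay assay id to test.
#' @param reference_assays normalizer assay ids.
#' @return list of class `nested_anova`: `p` (group-effect p-value), `f`,
#'   `df`, and the stratum table `ss` with sums of squares for `group`,
#'   `bio_within_group` and `residual` (technical).
#' @export
nested_anova <- function(table, target_assay, reference_assays) {
  wells <- delta_ct_wells(table, target_assay, reference_assays)
  wells$group <- factor(wells$group)
  wells$bio <- factor(paste(wells$group, wells$bio_rep, sep = ":"))
  n_bio <- tapply(wells$bio, wells$group, function(b) length(unique(b)))
  if (any(n_bio < 2L))
    stop("need >= 2 biological replicates per group (",
         paste(names(n_bio)[n_bio < 2L], collapse = ", "), " deficient)")
  n_tech <- tapply(wells$tech_rep, wells$bio, function(t) length(t))
  if (any(n_tech < 2L))
    stop("need >= 2 technical replicates per biological replicate (",
         paste(names(n_tech)[n_tech < 2L], collapse = ", "), " deficient)")
  fit <- stats::aov(dct ~ group + group:bio, data = wells)
  tab <- summary(fit)[[1L]]
  rn <- trimws(rownames(tab))
  ms_group <- tab["group" == rn, "Mean Sq"]
  df_group <- tab["group" == rn, "Df"]
  ms_bio <- tab["group:bio" == rn, "Mean Sq"]
  df_bio <- tab["group:bio" == rn, "Df"]
  f <- ms_group / ms_bio
  p <- stats::pf(f, df_group, df_bio, lower.tail = FALSE)
  ss <- data.frame(
    stratum = c("group", "bio_within_group", "residual"),
    df = c(df_group, df_bio, tab["Residuals" == rn, "Df"]),
    ss = c(tab["group" == rn, "Sum Sq"], tab["group:bio" == rn, "Sum Sq"],
           tab["Residuals" == rn, "Sum Sq"]),
    stringsAsFactors = FALSE)
  structure(list(p = p, f = f, df = c(df_group, df_bio), ss = ss),
            class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  cat(sprintf("nested ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1L], x$df[2L], x$f, x$p))
  invisible(x)
}

#' Relative expression with nested-ANOVA p-values for a panel of assays
#'
#' Convenience wrapper combining [delta_delta_ct()] and [nested_anova()]
#' over several target assays.
#'
#' @param table Ct table.
#' @param target_assays character vector of assays to quantify.
#' @param reference_assays normalizer assay ids.
#' @return data.frame with columns `assay`, `ddct`, `rel_expr`, `p`,
#'   `direction`.
#' @export
qpcr_panel <- function(table, target_assays, reference_assays) {
  rows <- lapply(target_assays, function(a) {
    est <- delta_delta_ct(table, a, reference_assays)
    an <- nested_anova(table, a, reference_assays)
    data.frame(assay = a, ddct = est$ddct, rel_expr = est$rel_expr,
               p = an$p, direction = est$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
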