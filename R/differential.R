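#' Quantile-normalize an intensity matrix across samples
#'
#' Between-array normalization: after normalization every sample's sorted
#' intensities equal the cross-sample mean of sorted intensities, while the
#' within-sample ranking of features is preserved. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x an [expression_matrix()] with at least two samples.
#' @return an `expr_matrix` of the same shape.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2L)
    stop("quantile normalization needs >= 2 samples")
  norm <- limma::normalizeQuantiles(x$values)
  dimnames(norm) <- dimnames(x$values)
  expression_matrix(norm, x$groups)
}

#' Call differentially expressed features
#'
#' For every feature: group means on the intensity scale, signed fold change
#' (see [signed_fold_change()]), a two-sided two-sample t-test on log2
#' intensities, and a direction call. A feature is `up` when
#' `fc >= fc_threshold` and `p <= alpha`, `down` when `fc <= -fc_threshold`
#' and `p <= alpha`, otherwise `unchanged`. BH-adjusted q-values are reported
#' alongside but do not enter the default call, matching common practice for
#' small intensity arrays.
#'
#' The default pools the two group variances (equal-variance t). At the two
#' or three replicates per group typical of these designs the pooled t holds
#' its nominal size exactly under log-normal noise, whereas the
#' Welch-Satterthwaite approximation is noticeably conservative;
#' `var_equal = FALSE` selects Welch for heteroscedastic data.
#'
#' Optional variance shrinkage pulls per-feature log2 variances toward the
#' across-feature mean variance with weight `shrink` in \[0, 1\] (0 = pure
#' Welch, 1 = fully pooled across features), a light-weight analogue of
#' moderated statistics.
#'
#' @param x an `expr_matrix` with two groups of >= 2 samples each.
#' @param fc_threshold minimum absolute signed fold change (default 1.2).
#' @param alpha p-value cutoff (default 0.05).
#' @param pseudo small constant added before log2 to guard zero intensities.
#' @param shrink shrinkage weight toward the global mean variance.
#' @param var_equal pool the group variances (default TRUE); FALSE gives
#'   Welch's unequal-variance test.
#' @return data.frame with columns `feature`, `mean_case`, `mean_control`,
#'   `fc`, `p`, `q`, `direction`, ordered by ascending `p`.
#' @export
differential_test <- function(x, fc_threshold = 1.2, alpha = 0.05,
                              pseudo = 1e-8, shrink = 0, var_equal = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  case <- x$groups == "case"
  ctrl <- x$groups == "control"
  n1 <- sum(case); n2 <- sum(ctrl)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 replicates")
  stopifnot(fc_threshold >= 1, alpha > 0, shrink >= 0, shrink <= 1)

  v <- x$values
  lg <- log2(v + pseudo)
  m1 <- rowMeans(v[, case, drop = FALSE])
  m2 <- rowMeans(v[, ctrl, drop = FALSE])
  lm1 <- rowMeans(lg[, case, drop = FALSE])
  lm2 <- rowMeans(lg[, ctrl, drop = FALSE])
  s1 <- apply(lg[, case, drop = FALSE], 1L, stats::var)
  s2 <- apply(lg[, ctrl, drop = FALSE], 1L, stats::var)
  if (shrink > 0) {
    s1 <- (1 - shrink) * s1 + shrink * mean(s1)
    s2 <- (1 - shrink) * s2 + shrink * mean(s2)
  }
  if (var_equal) {
    sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    se2 <- sp * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(sp))
  } else {
    se2 <- s1 / n1 + s2 / n2
    # Welch-Satterthwaite degrees of freedom
    df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  }
  tstat <- (lm1 - lm2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate: no variance anywhere -> p = 1 when means agree, 0 otherwise
  degen <- se2 == 0
  p[degen] <- ifelse(lm1[degen] == lm2[degen], 1, 0)
  fc <- signed_fold_change(pmax(m1, .Machine$double.xmin),
                           pmax(m2, .Machine$double.xmin))
  direction <- rep("unchanged", length(p))
  direction[fc >= fc_threshold & p <= alpha] <- "up"
  direction[fc <= -fc_threshold & p <= alpha] <- "down"
  out <- data.frame(feature = rownames(v),
                    mean_case = m1, mean_control = m2,
                    fc = fc, p = p,
                    q = stats::p.adjust(p, "BH"),
                    direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$feature), , drop = FALSE]
}

#' Summarize detection and the intensity distribution
#'
#' Counts features detected above an intensity floor in the control group and
#' bins their control means, the usual first-look summary for an intensity
#' array (how many features are expressed, and how the intensities spread).
#'
#' @param x an `expr_matrix`.
#' @param detect_floor control-group mean intensity above which a feature
#'   counts as detected (default 1.0).
#' @param bin_edges strictly increasing interior bin edges; bins are
#'   `(floor, e1], (e1, e2], ..., (ek, Inf)`. Default `c(5, 10, 50, 100, 500)`.
#' @return list of class `detection_summary`: `n_detected`, `intensity_min`,
#'   `intensity_max`, `bin_edges`, `bin_counts`, `bin_fractions`.
#' @export
summarize_detection <- function(x, detect_floor = 1,
                                bin_edges = c(5, 10, 50, 100, 500)) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  ctrl_mean <- rowMeans(x$values[, x$groups == "control", drop = FALSE])
  detected <- ctrl_mean[ctrl_mean > detect_floor]
  edges <- c(detect_floor, bin_edges, Inf)
  counts <- if (length(detected))
    as.vector(table(cut(detected, edges, right = TRUE)))
  else rep(0L, length(edges) - 1L)
  structure(list(n_detected = length(detected),
                 intensity_min = if (length(detected)) min(detected) else NA_real_,
                 intensity_max = if (length(detected)) max(detected) else NA_real_,
                 bin_edges = edges,
                 bin_counts = counts,
                 bin_fractions = if (length(detected)) counts / length(detected)
                                 else rep(NA_real_, length(counts))),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat(sprintf("detected: %d features, intensity range %.1f-%.1f\n",
              x$n_detected, x$intensity_min, x$intensity_max))
  for (i in seq_along(x$bin_counts))
    cat(sprintf("  (%g, %g]: %d (%.1f%%)\n", x$bin_edges[i], x$bin_edges[i + 1L],
                x$bin_counts[i], 100 * x$bin_fractions[i]))
  invisible(x)
}

#' Catalog of highly expressed features
#'
#' Features whose control-group mean intensity meets a threshold, ranked by
#' descending intensity with ties broken by feature id. This is the
#' "robustly expressed" catalog of a profiling study rather than a
#' differential call.
#'
#' @param records data.frame from [differential_test()] (or any table with
#'   `feature` and `mean_control` columns).
#' @param intensity_threshold control-mean cutoff (default 500).
#' @return data.frame with columns `feature`, `intensity`, sorted descending.
#' @export
highly_expressed <- function(records, intensity_threshold = 500) {
  stopifnot(all(c("feature", "mean_control") %in% names(records)))
  keep <- records$mean_control >= intensity_threshold
  out <- data.frame(feature = records$feature[keep],
                    intensity = records$mean_control[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$intensity, out$feature), , drop = FALSE]
}
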