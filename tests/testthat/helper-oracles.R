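# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive (enumeration, direct formulas) and separate from the
# package's own code paths.

# expression matrix with exact group means: values symmetric around the mean
make_matrix <- function(mean_case, mean_control, n = 3, jitter = 0.1,
                        ids = NULL) {
  k <- length(mean_case)
  if (is.null(ids)) ids <- sprintf("f%03d", seq_len(k))
  dev <- seq(-jitter, jitter, length.out = n)   # sums to zero
  case <- outer(mean_case, dev, `+`)
  ctrl <- outer(mean_control, dev, `+`)
  vals <- cbind(case, ctrl)
  dimnames(vals) <- list(ids, c(paste0("T", 1:n), paste0("C", 1:n)))
  expression_matrix(vals, setNames(rep(c("case", "control"), each = n),
                                   colnames(vals)))
}

# exhaustive hypergeometric upper tail: enumerate every possible query draw
hyper_enum <- function(n_universe, n_term, n_query, n_overlap) {
  draws <- utils::combn(n_universe, n_query)
  term <- seq_len(n_term)                 # wlog the first n_term elements
  hits <- apply(draws, 2L, function(d) sum(d %in% term))
  mean(hits >= n_overlap)
}

# direct textbook Pearson r (covariance formula, no cor())
pearson_formula <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force nested sums of squares from the raw decomposition
nested_ss_oracle <- function(dct, group, bio) {
  cell <- paste(group, bio)
  grand <- mean(dct)
  gm <- tapply(dct, group, mean)
  bm <- tapply(dct, cell, mean)
  n_g <- tapply(dct, group, length)
  n_b <- tapply(dct, cell, length)
  g_of_cell <- tapply(group, cell, function(g) g[1L])
  ss_group <- sum(n_g * (gm - grand)^2)
  ss_bio <- sum(n_b * (bm[names(n_b)] - gm[g_of_cell[names(n_b)]])^2)
  ss_resid <- sum((dct - bm[cell])^2)
  c(group = unname(ss_group), bio = unname(ss_bio), resid = unname(ss_resid),
    total = sum((dct - grand)^2))
}

# naive seed-site finder: string scan with chartr-based reverse complement,
# independent of the package's per-base matcher
seed_sites_naive <- function(mirna, utr) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1L]]),
                          collapse = "")
  m <- strsplit(mirna, "")[[1L]]
  core <- rc(paste(m[2:7], collapse = ""))
  u <- strsplit(utr, "")[[1L]]
  n <- nchar(utr)
  out <- NULL
  for (i in seq_len(max(0L, n - 5L))) {
    if (substr(utr, i, i + 5L) != core) next
    m8 <- i > 1L && u[i - 1L] == chartr("ACGU", "UGCA", m[8L])
    a1 <- (i + 6L) <= n && u[i + 6L] == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else
            if (a1) "7mer-A1" else "6mer"
    out <- rbind(out, data.frame(core_start = i - 1L, site_type = type,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) data.frame(core_start = integer(0),
                               site_type = character(0)) else out
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# small fully-crossed qPCR plate from explicit Ct values
qpcr_plate <- function(ct_by_cell, assay = "tgt", ref_ct = 20) {
  # ct_by_cell: list group -> bio -> numeric vector of tech Cts
  rows <- list()
  for (g in names(ct_by_cell)) for (b in names(ct_by_cell[[g]])) {
    cts <- ct_by_cell[[g]][[b]]
    for (t in seq_along(cts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        assay = c(assay, "ref"), group = g, bio_rep = b,
        tech_rep = paste0("t", t), ct = c(cts[t], ref_ct),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

extdata <- function(name) system.file("extdata", name, package = "mirlens")

default_refs <- c("miR-17", "Gapdh", "Actb")
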