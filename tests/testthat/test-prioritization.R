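mk_pairs <- function(n, mirna_dir = "up") {
  data.frame(mirna = paste0("m", seq_len(n)),
             mrna = paste0("g", seq_len(n)),
             mirna_direction = mirna_dir,
             mrna_direction = if (mirna_dir == "up") "down" else "up",
             mrna_direction_late = "missing",
             score = 80, stringsAsFactors = FALSE)
}

test_that("enrichment flags honour the inclusive expression floor", {
  pairs <- mk_pairs(3)
  tab <- data.frame(gene = c("g1", "g2"),
                    enrichment_fc = c(2.5, 3.0),
                    expression = c(100, 99.9))
  out <- enrichment_filter(pairs, tab, "p4")
  expect_identical(out$enriched_p4, c(TRUE, FALSE, FALSE))  # g3 absent
  # enrichment_fc must exceed 1
  tab2 <- data.frame(gene = "g1", enrichment_fc = 1.0, expression = 500)
  expect_false(enrichment_filter(pairs, tab2, "p4")$enriched_p4[1L])
})

test_that("generated enrichment tables flag about the designed fraction", {
  d <- synthetic_design(n_mirnas = 100, n_mrnas = 600,
                        enrichment_fraction = 0.5, seed = 31)
  dir <- withr::local_tempdir()
  g <- generate_study(d, dir)
  tr <- g$truth
  pairs <- data.frame(mirna = tr$pairs$mirna, mrna = tr$pairs$mrna,
                      mirna_direction = tr$pairs$mirna_direction,
                      mrna_direction = "down", mrna_direction_late = "missing",
                      score = tr$pairs$score, stringsAsFactors = FALSE)
  out <- enrichment_filter(pairs, read_enrichment_table(g$files[["enrichment_p4"]]),
                           "p4")
  frac <- mean(tapply(out$enriched_p4, out$mrna, any))
  expect_equal(frac, 0.5, tolerance = 0.12)
})

test_that("tier assignment follows the rule hierarchy with first match winning", {
  pairs <- mk_pairs(5)
  pairs$mrna_direction_late <- c("down", "down", "missing", "down", "missing")
  pairs$enriched_p4 <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  pairs$enriched_p30 <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  out <- assign_tiers(pairs)
  # all four kinds of evidence -> top; both DE + one enrichment -> high;
  # primary DE + one enrichment -> promising; no enrichment -> unranked
  expect_identical(out$tier, c("top", "high", "promising", "unranked", "unranked"))
  ts <- attr(out, "tier_summary")
  up <- ts[ts$mirna_direction == "up", ]
  expect_identical(up$top + up$high + up$promising + up$unranked,
                   up$n_unique_mrnas)
})

test_that("tier assignment ignores input row order and rules parse from file", {
  set.seed(55)
  pairs <- mk_pairs(20)
  pairs$mrna_direction_late <- sample(c("down", "missing"), 20, TRUE)
  pairs$enriched_p4 <- sample(c(TRUE, FALSE), 20, TRUE)
  pairs$enriched_p30 <- sample(c(TRUE, FALSE), 20, TRUE)
  out1 <- assign_tiers(pairs)
  perm <- sample(20)
  out2 <- assign_tiers(pairs[perm, ])
  expect_identical(out2$tier, out1$tier[perm])

  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("top: de_p4 AND de_p30 AND enriched_p4 AND enriched_p30",
               "high: de_p4 AND de_p30 AND (enriched_p4 OR enriched_p30)",
               "promising: de_p4 AND (enriched_p4 OR enriched_p30)"), path)
  expect_identical(assign_tiers(pairs, read_tier_rules(path))$tier, out1$tier)

  writeLines(c("top: enriched_p4", "top: enriched_p30"), path)
  expect_error(read_tier_rules(path), "duplicated")
  writeLines("top: enriched_p4 AND rm(x)", path)
  expect_error(read_tier_rules(path), "unknown names")
})

test_that("removing evidence can only demote a pair", {
  set.seed(77)
  rank_of <- c(top = 1L, high = 2L, promising = 3L, unranked = 4L)
  pairs <- mk_pairs(30)
  pairs$mrna_direction_late <- sample(c("down", "missing"), 30, TRUE)
  pairs$enriched_p4 <- sample(c(TRUE, FALSE), 30, TRUE)
  pairs$enriched_p30 <- sample(c(TRUE, FALSE), 30, TRUE)
  base <- rank_of[assign_tiers(pairs)$tier]
  for (col in c("mrna_direction_late", "enriched_p4", "enriched_p30")) {
    weaker <- pairs
    drop <- sample(30, 10)
    weaker[[col]][drop] <- if (is.logical(weaker[[col]])) FALSE else "missing"
    expect_true(all(rank_of[assign_tiers(weaker)$tier] >= base))
  }
})

test_that("inverse correlation is exactly -1 on mirrored fold changes and matches the covariance formula", {
  pairs <- mk_pairs(4)
  mirna_de <- data.frame(feature = pairs$mirna, fc = c(2, 4, 8, 16),
                         direction = "up")
  mrna_de <- data.frame(feature = pairs$mrna, fc = -c(2, 4, 8, 16),
                        direction = "down")
  res <- inverse_correlation(pairs, mirna_de, mrna_de)
  expect_equal(res$r, -1)
  expect_identical(res$n_pairs, 4L)

  # hand-checkable log2 set {(1,-1),(2,-2),(3,-3),(4,-4)}
  expect_equal(pearson_formula(1:4, -(1:4)), -1)
  expect_equal(res$r, pearson_formula(log2(c(2, 4, 8, 16)),
                                      -log2(c(2, 4, 8, 16))))

  # zero variance is an error, not a number
  mirna_flat <- data.frame(feature = pairs$mirna, fc = 2, direction = "up")
  expect_error(inverse_correlation(pairs, mirna_flat, mrna_de), "variance")
  expect_error(inverse_correlation(pairs[1:2, ], mirna_de, mrna_de), ">= 3")
})

test_that("shuffled pairings decorrelate", {
  set.seed(11)
  n <- 60
  pairs <- mk_pairs(n)
  fc <- runif(n, 1.3, 4)
  mirna_de <- data.frame(feature = pairs$mirna, fc = fc, direction = "up")
  rs <- replicate(30, {
    mrna_de <- data.frame(feature = pairs$mrna,
                          fc = -sample(fc), direction = "down")
    inverse_correlation(pairs, mirna_de, mrna_de)$r
  })
  expect_lt(abs(mean(rs)), 0.1)
  expect_true(all(abs(rs) < 0.6))
})
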