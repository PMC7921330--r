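test_that("quantile normalization fixes identical columns and matches the hand-derived 2x2 case", {
  # identical columns are a fixed point
  v <- matrix(rep(c(1, 5, 9), 4), nrow = 3,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  m <- expression_matrix(v, setNames(c("case", "case", "control", "control"),
                                     colnames(v)))
  expect_equal(quantile_normalize(m)$values, v)

  # columns (1,2) and (3,4): sorted cross-sample means are (2,3)
  v2 <- matrix(c(1, 2, 3, 4), nrow = 2,
               dimnames = list(c("f1", "f2"), c("s1", "s2")))
  m2 <- expression_matrix(v2, c(s1 = "case", s2 = "control"))
  expect_error(differential_test(quantile_normalize(m2)), "replicates")
  expect_equal(unname(quantile_normalize(m2)$values),
               matrix(c(2, 3, 2, 3), nrow = 2))

  # permuting samples permutes columns but preserves the value multiset
  set.seed(7)
  v3 <- matrix(rlnorm(60), 10, 6,
               dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  g3 <- setNames(rep(c("case", "control"), each = 3), colnames(v3))
  perm <- sample(6)
  q1 <- quantile_normalize(expression_matrix(v3, g3))
  q2 <- quantile_normalize(expression_matrix(v3[, perm], g3[perm]))
  expect_equal(sort(q2$values), sort(q1$values))
  expect_error(quantile_normalize(
    expression_matrix(v3[, 1, drop = FALSE], g3[1])), ">= 2 samples")
})

test_that("a planted two-fold shift is called with the right fold change", {
  set.seed(21)
  base <- rlnorm(50, log(50), 0.5)
  noise <- matrix(rlnorm(300, 0, 0.05), 50)
  vals <- base * noise
  vals[1, 1:3] <- base[1] * 2 * rlnorm(3, 0, 0.05)
  dimnames(vals) <- list(sprintf("f%02d", 1:50),
                         c(paste0("T", 1:3), paste0("C", 1:3)))
  m <- expression_matrix(vals, setNames(rep(c("case", "control"), each = 3),
                                        colnames(vals)))
  de <- differential_test(m)
  f1 <- de[de$feature == "f01", ]
  expect_identical(f1$direction, "up")
  expect_lt(f1$p, 0.05)
  expect_equal(f1$fc, 2, tolerance = 0.15)
})

test_that("DE calls are invariant to global rescaling before quantile normalization", {
  set.seed(33)
  vals <- matrix(rlnorm(600, log(20), 1), 100, 6,
                 dimnames = list(sprintf("f%03d", 1:100),
                                 c(paste0("T", 1:3), paste0("C", 1:3))))
  g <- setNames(rep(c("case", "control"), each = 3), colnames(vals))
  de1 <- differential_test(quantile_normalize(expression_matrix(vals, g)))
  de2 <- differential_test(quantile_normalize(expression_matrix(vals * 7.3, g)))
  expect_equal(de2$direction, de1$direction)
  expect_equal(de2$p, de1$p)
  expect_equal(de2$fc, de1$fc)
})

test_that("flat features with equal means get p = 1 by convention", {
  v <- matrix(5, 3, 4, dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  m <- expression_matrix(v, setNames(c("case", "case", "control", "control"),
                                     colnames(v)))
  expect_true(all(differential_test(m)$p == 1))
})

test_that("printed means (14.5, 20.1) give FC -1.4 after rounding", {
  m <- make_matrix(14.5, 20.1, n = 3, jitter = 0.1, ids = "mir-x")
  de <- differential_test(m)
  expect_equal(round(de$fc, 1), -1.4)
  expect_equal(de$mean_case, 14.5)
  expect_equal(de$mean_control, 20.1)
})

test_that("detection summary reproduces the 503/697 = 72.2% low-intensity fraction", {
  # 697 detected features, 503 of them at control mean <= 5
  means <- c(seq(1.2, 5.0, length.out = 503),
             seq(5.5, 15592, length.out = 194))
  m <- make_matrix(means, means, n = 2, jitter = 0.05)
  s <- summarize_detection(m, detect_floor = 1, bin_edges = c(5, 10, 50, 100, 500))
  expect_identical(s$n_detected, 697L)
  expect_equal(round(100 * s$bin_fractions[1L], 1), 72.2)
  expect_identical(sum(s$bin_counts), s$n_detected)

  # all features below the floor
  low <- make_matrix(c(0.1, 0.5), c(0.2, 0.4), n = 2)
  expect_identical(summarize_detection(low)$n_detected, 0L)

  # one feature per bin
  one <- make_matrix(rep(1, 6), c(3, 7, 20, 70, 200, 700), n = 2, jitter = 0)
  expect_true(all(summarize_detection(one)$bin_counts == 1L))
  expect_error(summarize_detection(one, bin_edges = c(5, 5)), "increasing")
})

test_that("the highly-expressed catalog filter keeps the printed 31-feature set", {
  catalog <- read.delim(extdata("lens_p4_mirna_catalog.tsv"))
  # add sub-threshold features so the filter has something to drop
  records <- rbind(catalog,
                   data.frame(feature = c("mir-low1", "mir-low2", "mir-low3"),
                              mean_control = c(499.9, 120, 4)))
  hi <- highly_expressed(records, intensity_threshold = 500)
  expect_identical(nrow(hi), 31L)
  expect_identical(hi$feature[1L], "mir-184")
  expect_equal(hi$intensity[1L], 15592.3)
  expect_true(all(diff(hi$intensity) <= 0))

  expect_identical(nrow(highly_expressed(records, 20000)), 0L)

  ties <- data.frame(feature = c("b", "a", "c"), mean_control = c(600, 600, 700))
  expect_identical(highly_expressed(ties)$feature, c("c", "a", "b"))
})
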