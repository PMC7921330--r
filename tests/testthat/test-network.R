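mk_de <- function(ids, dirs) data.frame(feature = ids,
                                        fc = ifelse(dirs == "up", 2, -2),
                                        p = 0.01, direction = dirs,
                                        stringsAsFactors = FALSE)

test_that("module edges count and sign correctly in the wild-type frame", {
  mirna_de <- mk_de(c("mElev", "mRed"), c("up", "down"))
  pairs <- data.frame(mirna = c("mElev", "mElev", "mRed"),
                      mrna = c("gA", "gB", "gC"),
                      mirna_direction = c("up", "up", "down"),
                      mrna_direction = c("down", "down", "up"),
                      stringsAsFactors = FALSE)
  e <- build_module(mirna_de, pairs)
  expect_identical(nrow(e), 5L)   # 2 regulator->miRNA + 3 miRNA->mRNA
  # elevated-in-knockout miRNA is normally repressed by the regulator
  expect_identical(e$sign[e$source == "Tdrd7" & e$target == "mElev"], "repressive")
  expect_identical(e$sign[e$source == "Tdrd7" & e$target == "mRed"], "activating")
  expect_true(all(e$sign[e$source != "Tdrd7"] == "repressive"))

  # one elevated miRNA with two targets: 3 edges
  e2 <- build_module(mk_de("mElev", "up"), pairs[pairs$mirna == "mElev", ])
  expect_identical(nrow(e2), 3L)

  # no pairs: no edges at all
  expect_identical(nrow(build_module(mirna_de, pairs[0, ])), 0L)
})

test_that("edge-sign composition predicts the knockout direction of every target", {
  d <- synthetic_design(n_mirnas = 100, n_mrnas = 400, seed = 23)
  dir <- withr::local_tempdir()
  g <- generate_study(d, dir)
  tr <- g$truth$pairs
  mirna_de <- mk_de(g$truth$mirnas$feature, g$truth$mirnas$direction)
  pairs <- data.frame(mirna = tr$mirna, mrna = tr$mrna,
                      mirna_direction = tr$mirna_direction,
                      mrna_direction = ifelse(tr$mirna_direction == "up",
                                              "down", "up"),
                      stringsAsFactors = FALSE)
  e <- build_module(mirna_de, pairs)
  expect_identical(nrow(e), length(unique(pairs$mirna)) + nrow(pairs))
  reg_sign <- setNames(e$sign[e$source == "Tdrd7"],
                       e$target[e$source == "Tdrd7"])
  mm <- e[e$source != "Tdrd7", ]
  # regulator represses miRNA (knockout elevates it) and the miRNA represses
  # its mRNA => the mRNA must be reduced in the knockout, and vice versa
  derived <- ifelse(reg_sign[mm$source] == "repressive", "down", "up")
  stated <- setNames(pairs$mrna_direction, paste(pairs$mirna, pairs$mrna))
  expect_identical(unname(derived), unname(stated[paste(mm$source, mm$target)]))
})

test_that("concordance counts same-direction calls with gain-kind inversion", {
  tables <- list(
    ds1 = data.frame(feature = c("gA", "gB"), fc = c(-1.5, 1.05),
                     p = c(0.01, 0.01)),
    ds2 = data.frame(feature = c("gA", "gC"), fc = c(1.6, -2),
                     p = c(0.2, 0.03)),
    gof = data.frame(feature = "gC", fc = 2, p = 0.01))
  refd <- c(gA = "down", gB = "down", gC = "down", gAbsent = "up")
  kind <- c(ds1 = "loss", ds2 = "loss", gof = "gain")
  rep <- concordance(c("gA", "gB", "gC", "gAbsent"), tables, refd, kind)
  pt <- rep$per_target
  # gA: misexpressed in ds1 only (ds2 p too high); down = same direction
  expect_identical(pt$n_misexpressed[pt$target == "gA"], 1L)
  expect_true(pt$concordant[pt$target == "gA"])
  # gB: present but |fc| < 1.2, never misexpressed
  expect_identical(pt$n_misexpressed[pt$target == "gB"], 0L)
  # gC: down in ds2 (same); up in the gain dataset, expectation inverted -> same
  expect_identical(pt$n_same_direction[pt$target == "gC"], 2L)
  # absent target drops out of every denominator
  expect_identical(pt$n_datasets_present[pt$target == "gAbsent"], 0L)
  expect_identical(rep$n_present, 3L)
  expect_identical(rep$n_misexpressed, 2L)
  expect_equal(rep$frac_concordant, 1)
  expect_lte(rep$n_misexpressed, rep$n_targets)
})

test_that("graph exports round-trip (SIF) and produce well-formed GraphML", {
  e <- data.frame(source = c("Tdrd7", "m1", "m1"),
                  target = c("m1", "gA", "gB"),
                  sign = c("repressive", "repressive", "activating"),
                  stringsAsFactors = FALSE)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(e, sif, "sif")
  expect_identical(length(readLines(sif)), 3L)
  back <- read_sif(sif)
  expect_identical(back$source, e$source)
  expect_identical(back$sign, e$sign)

  empty <- withr::local_tempfile(fileext = ".sif")
  export_graph(e[0, ], empty, "sif")
  expect_identical(nrow(read_sif(empty)), 0L)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(e, gml, "graphml")
  doc <- xml2::read_xml(gml)
  ns <- xml2::xml_ns(doc)
  expect_identical(length(xml2::xml_find_all(doc, "//d1:node", ns)), 4L)
  edges <- xml2::xml_find_all(doc, "//d1:edge", ns)
  expect_identical(length(edges), 3L)
  expect_setequal(xml2::xml_text(xml2::xml_find_all(doc, "//d1:data", ns)),
                  unique(e$sign))
})
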