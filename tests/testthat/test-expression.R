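test_that("cell-type aggregation takes the max over samples", {
  m <- matrix(c(10, 250, 37, 5, 8, 2), 1,
              dimnames = list("g1", paste0("s", 1:6)))
  sm <- data.frame(sample = paste0("s", 1:6),
                   cell_type = c("MC", "MC", "MC", "T", "T", "T"))
  ce <- CellExpression(m, sm, species = "mouse", platform = "microarray")
  pr <- aggregateCellTypes(ce)
  v <- SummarizedExperiment::assay(pr)
  expect_identical(v["g1", "MC"], 250)
  expect_identical(v["g1", "T"], 8)

  ## permuting sample columns changes nothing
  perm <- sample(ncol(m))
  ce2 <- CellExpression(m[, perm, drop = FALSE], sm, species = "mouse")
  expect_identical(SummarizedExperiment::assay(aggregateCellTypes(ce2)), v)

  ## one sample per cell type: profile equals the matrix up to relabeling
  m1 <- matrix(c(3, 9), 1, dimnames = list("g1", c("a", "b")))
  sm1 <- data.frame(sample = c("a", "b"), cell_type = c("MC", "T"))
  v1 <- SummarizedExperiment::assay(
    aggregateCellTypes(CellExpression(m1, sm1, species = "human")))
  expect_identical(unname(v1), unname(m1))

  ## idempotence: aggregating a profile is the identity
  expect_identical(SummarizedExperiment::assay(aggregateCellTypes(pr)), v)
})

test_that("the expressed filter is strict by default", {
  pr <- profile_of(c(MC = 150), gene = "g1")
  prof <- aggregateCellTypes(CellExpression(
    matrix(c(150, 100, 99), 3, 1,
           dimnames = list(c("g1", "g2", "g3"), "s1")),
    data.frame(sample = "s1", cell_type = "MC"), species = "mouse"))
  expect_identical(filterExpressed(prof, "MC", 100), "g1")
  expect_setequal(filterExpressed(prof, "MC", 100, strict = FALSE),
                  c("g1", "g2"))
  expect_setequal(filterExpressed(prof, "MC", 0), c("g1", "g2", "g3"))
  expect_error(filterExpressed(prof, "B", 100), "unknown cell type")
  ## anti-monotone in the threshold
  ths <- c(0, 50, 99, 100, 150, 200)
  ns <- vapply(ths, function(t) length(filterExpressed(prof, "MC", t)),
               integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("specificity equals the average fold-change formula", {
  pr <- profile_of(c(MC = 400, T = 100, B = 200, Mos = 50))
  sc <- specificity(pr, "g1")
  expect_equal(specScore(sc), (4 + 2 + 8) / 3, tolerance = 1e-12)
  expect_equal(unname(sc@foldChanges[c("T", "B", "Mos")]), c(4, 2, 8))

  ## identity: all cell types equal, epsilon 0 -> exactly 1
  pr1 <- profile_of(c(MC = 123, T = 123, B = 123, Mos = 123))
  expect_identical(specScore(specificity(pr1, "g1")), 1)

  ## zero reference with positive comparisons and epsilon 1 -> below 1
  pr0 <- profile_of(c(MC = 0, T = 10, B = 20, Mos = 5))
  sc0 <- specificity(pr0, "g1", epsilon = 1)
  expect_equal(specScore(sc0), mean(1 / (c(10, 20, 5) + 1)),
               tolerance = 1e-12)
  expect_lt(specScore(sc0), 1)

  ## zero denominator at epsilon 0 is an instructive error
  prz <- profile_of(c(MC = 10, T = 0, B = 5, Mos = 5))
  expect_error(specificity(prz, "g1"), "positive epsilon")
  expect_error(specificity(pr, "g1", comparison = c("MC", "T")),
               "reference")
})

test_that("specificity is scale invariant at epsilon 0 and converges", {
  set.seed(31)
  for (i in 1:20) {
    vals <- stats::runif(4, 1, 500)
    names(vals) <- c("MC", "T", "B", "Mos")
    s1 <- specScore(specificity(profile_of(vals), "g1"))
    k <- stats::runif(1, 0.01, 100)
    s2 <- specScore(specificity(profile_of(vals * k), "g1"))
    expect_equal(s1, s2, tolerance = 1e-12)
    ## epsilon -> 0 approaches the epsilon = 0 score
    s_eps <- vapply(c(1, 0.1, 1e-4, 1e-8), function(e)
      specScore(specificity(profile_of(vals), "g1", epsilon = e)),
      numeric(1))
    expect_lt(abs(s_eps[4] - s1), 1e-6)
    expect_true(all(diff(abs(s_eps - s1)) <= 1e-12))
  }
})

test_that("specificity is monotone in reference and comparison values", {
  base <- c(MC = 100, T = 50, B = 80, Mos = 20)
  s <- function(v) specScore(specificity(profile_of(v), "g1", epsilon = 1))
  up <- base
  up["MC"] <- 150
  expect_gt(s(up), s(base))
  dn <- base
  dn["B"] <- 120
  expect_lt(s(dn), s(base))
})

test_that("the vectorised specificity table matches the scalar score", {
  m <- matrix(stats::runif(40, 1, 300), 10, 4,
              dimnames = list(paste0("g", 1:10),
                              c("MC", "T", "B", "Mos")))
  sm <- data.frame(sample = colnames(m), cell_type = colnames(m))
  pr <- aggregateCellTypes(CellExpression(m, sm, species = "human"))
  tab <- specificityTable(pr, epsilon = 1, log2 = TRUE)
  for (g in rownames(m))
    expect_equal(tab$avg_fc[tab$gene_id == g],
                 specScore(specificity(pr, g, epsilon = 1)),
                 tolerance = 1e-12)
  expect_equal(tab$log2_avg_fc, log2(tab$avg_fc))
})

test_that("ortholog mapping splits mapped pairs from the residue", {
  map <- data.frame(human_gene = c("H1", "H2"), mouse_gene = c("M1", "M2"))
  res <- mapOrthologs(c("H1", "H2", "H3"), map)
  expect_identical(res$pairs$from, c("H1", "H2"))
  expect_identical(res$pairs$to, c("M1", "M2"))
  expect_identical(res$unmapped, "H3")

  empty <- mapOrthologs(c("H1", "H2"), map[0, ])
  expect_identical(nrow(empty$pairs), 0L)
  expect_identical(empty$unmapped, c("H1", "H2"))

  full <- mapOrthologs(c("H1", "H2"), map)
  expect_length(full$unmapped, 0L)

  dup <- rbind(map, data.frame(human_gene = "H1", mouse_gene = "M9"))
  expect_error(mapOrthologs("H1", dup), "H1")
})

test_that("expression matrices round-trip through the TSV reader", {
  m <- matrix(c(1.5, 0, 3.25, 10), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  tf <- withr::local_tempfile(fileext = ".tsv")
  sf <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene_id = rownames(m), m),
                     tf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = c("s1", "s2"),
                                cell_type = c("MC", "T")),
                     sf, sep = "\t", quote = FALSE, row.names = FALSE)
  ce <- readExpressionMatrix(tf, sf, species = "human")
  expect_identical(SummarizedExperiment::assay(ce), m)
  expect_identical(cellTypes(ce), c("MC", "T"))
  ## negative values are invalid
  m2 <- m
  m2[1, 1] <- -1
  expect_error(CellExpression(m2, data.frame(sample = c("s1", "s2"),
                                             cell_type = c("MC", "T")),
                              species = "human"), ">= 0")
})
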