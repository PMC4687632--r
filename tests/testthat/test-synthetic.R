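test_that("fixture generation is byte-deterministic in the seed", {
  spec <- synthSpec(nGenes = 25L, nTrueReceptors = 2L, failExpressed = 1L,
                    failFamily = 1L, failSignaling = 1L,
                    failMouseAbundance = 1L, seed = 7L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  t1 <- generateFixture(spec, d1)
  t2 <- generateFixture(spec, d2)
  for (k in setdiff(names(t1@files), "spec")) {
    expect_identical(readLines(t1@files[[k]]), readLines(t2@files[[k]]),
                     label = paste("file", k))
  }
  ## a different seed changes the data
  t3 <- generateFixture(synthSpec(nGenes = 25L, nTrueReceptors = 2L,
                                  failExpressed = 1L, failFamily = 1L,
                                  failSignaling = 1L,
                                  failMouseAbundance = 1L, seed = 8L),
                        withr::local_tempdir())
  expect_false(identical(readLines(t1@files[["proteins"]]),
                         readLines(t3@files[["proteins"]])))
})

test_that("infeasible specs are rejected before anything is written", {
  expect_error(synthSpec(nGenes = 5L, nTrueReceptors = 10L),
               "exceed")
})

test_that("planted features are recoverable from the emitted files", {
  td <- withr::local_tempdir()
  truth <- generateFixture(synthSpec(nGenes = 20L, nTrueReceptors = 3L,
                                     failExpressed = 2L, failFamily = 2L,
                                     failSignaling = 2L,
                                     failMouseAbundance = 2L, seed = 42L),
                           td)
  g <- truthGenes(truth)
  ps <- readProteins(truth@files[["proteins"]])
  topo <- readTopology(truth@files[["topology"]], ps)
  motifs <- defaultMotifs()
  planted <- g[!is.na(g$motif_name), ]
  expect_gt(nrow(planted), 0L)
  for (i in seq_len(nrow(planted))) {
    pid <- planted$protein_id[i]
    seq <- proteinSequence(ps, pid)
    expect_identical(substr(seq, planted$motif_start[i],
                            planted$motif_end[i]),
                     planted$motif_seq[i])
    ## the scanner finds the planted motif at its recorded span
    hits <- scanMotifs(ps[pid], topo[topo$protein_id == pid, ],
                       motifs[planted$motif_name[i]])
    expect_true(any(hits$start == planted$motif_start[i] &
                    hits$end == planted$motif_end[i]),
                label = paste("planted", planted$motif_name[i], "found in",
                              pid))
  }
  ## signaling failures carry tyrosine-free tails: no motif can match
  for (pid in g$protein_id[g$role == "fail_signaling"]) {
    hits <- scanMotifs(ps[pid], topo[topo$protein_id == pid, ], motifs)
    expect_identical(nrow(hits), 0L)
  }
})

test_that("a fixture with no planted truth yields an empty screen", {
  td <- withr::local_tempdir()
  truth <- generateFixture(
    synthSpec(nGenes = 12L, nTrueReceptors = 0L, failExpressed = 0L,
              failFamily = 0L, failSignaling = 0L,
              failMouseAbundance = 0L, seed = 2L), td)
  res <- suppressWarnings(suppressMessages(runScreen(fixtureConfig(truth))))
  expect_identical(nrow(rankedCandidates(res)), 0L)
})

test_that("perturbation knobs have their recorded effects", {
  td <- withr::local_tempdir()
  spec <- synthSpec(nGenes = 20L, nTrueReceptors = 2L, failExpressed = 1L,
                    failFamily = 1L, failSignaling = 1L,
                    failMouseAbundance = 1L, seed = 19L)
  truth <- generateFixture(spec, td)
  g <- truthGenes(truth)
  target <- g$gene_id[g$role == "true_receptor"][1L]

  low <- perturbFixture(truth, "lower_mouse_abundance",
                        withr::local_tempdir(), gene = target,
                        magnitude = 90)
  res <- suppressMessages(runScreen(fixtureConfig(low)))
  expect_false(target %in% rankedCandidates(res)$gene_id)
  row <- candidates(res)[candidates(res)$gene_id == target, ]
  expect_false(row$mouse_abundance_pass)

  dropped <- perturbFixture(truth, "drop_ortholog", withr::local_tempdir(),
                            gene = target)
  expect_message(res2 <- runScreen(fixtureConfig(dropped)),
                 "without a mouse ortholog")
  cand2 <- candidates(res2)
  expect_true(is.na(cand2$mouse_gene[cand2$gene_id == target]))
  expect_false(target %in% rankedCandidates(res2)$gene_id)

  moved <- perturbFixture(truth, "move_motif_extracellular",
                          withr::local_tempdir())
  mg <- truthGenes(moved)
  mtarget <- mg$gene_id[mg$role == "true_receptor" &
                        !mg$expect_signaling][1L]
  res3 <- suppressMessages(runScreen(fixtureConfig(moved)))
  row3 <- candidates(res3)[candidates(res3)$gene_id == mtarget, ]
  expect_false(row3$signaling_pass)
  expect_true(row3$family_pass)

  flat <- perturbFixture(truth, "shrink_mc_enrichment",
                         withr::local_tempdir(), gene = target,
                         magnitude = 1)
  ## direct evaluation of the fold-change formula on the emitted values
  hm <- utils::read.delim(flat@files[["human_expr"]], check.names = FALSE)
  hmap <- utils::read.delim(flat@files[["human_samples"]])
  m <- as.matrix(hm[, -1]); rownames(m) <- hm$gene_id
  pr <- aggregateCellTypes(CellExpression(m, hmap, species = "human"))
  expect_equal(specScore(specificity(pr, target, epsilon = 1)), 1,
               tolerance = 1e-6)
  res4 <- suppressMessages(runScreen(fixtureConfig(flat)))
  cand4 <- candidates(res4)
  expect_equal(cand4$human_specificity[cand4$gene_id == target], 1,
               tolerance = 1e-6)

  expect_error(perturbFixture(truth, "nonsense", withr::local_tempdir()),
               "unknown perturbation")
})

test_that("emitted fixtures satisfy every module's input invariants", {
  td <- withr::local_tempdir()
  truth <- generateFixture(synthSpec(nGenes = 15L, nTrueReceptors = 2L,
                                     failExpressed = 1L, failFamily = 1L,
                                     failSignaling = 1L,
                                     failMouseAbundance = 1L, seed = 77L),
                           td)
  ps <- readProteins(truth@files[["proteins"]])          # validates alphabet
  expect_length(ps, 15L)
  hits <- readDomainHits(truth@files[["domains"]], ps)   # validates coords
  expect_gt(nrow(hits), 0L)
  topo <- readTopology(truth@files[["topology"]], ps)    # validates tiling
  expect_setequal(unique(topo$protein_id), proteinIds(ps))
  he <- readExpressionMatrix(truth@files[["human_expr"]],
                             truth@files[["human_samples"]], "human")
  me <- readExpressionMatrix(truth@files[["mouse_expr"]],
                             truth@files[["mouse_samples"]], "mouse")
  expect_setequal(cellTypes(he), c("MC", "T", "B", "Mos"))
  expect_setequal(cellTypes(me),
                  c("MC", "T", "B", "Mos", "NK", "DCs", "MPs"))
  om <- readOrthologMap(truth@files[["orthologs"]])
  expect_identical(nrow(om), 15L)
})
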