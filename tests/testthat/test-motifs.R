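test_that("the motif mini-language parses and round-trips", {
  m <- parseMotif("Yxx[LI]x(6,12)Yxx[LI]", name = "ITAM")
  els <- m@elements
  expect_identical(sum(vapply(els, function(e) e$type == "class",
                              logical(1))), 8L)
  expect_identical(sum(vapply(els, function(e) e$type == "spacer",
                              logical(1))), 1L)
  expect_identical(renderMotif(m), "Yxx[IL]x(6,12)Yxx[IL]")
  expect_identical(renderMotif(parseMotif(renderMotif(m))),
                   renderMotif(m))

  itim <- parseMotif("[ILVS]xYxx[LV]")
  minlen <- sum(vapply(itim@elements, function(e)
    if (e$type == "class") 1L else e$min, integer(1)))
  expect_identical(minlen, 6L)
})

test_that("malformed patterns fail with a column position", {
  expect_error(parseMotif("Yx(3,1)M"), "0 <= min <= max")
  expect_error(parseMotif("Y[ILx"), "column 2.*unbalanced")
  expect_error(parseMotif("Y[]M"), "column 2.*empty")
  expect_error(parseMotif("Y-M"), "column 2")
  expect_error(parseMotif("YM"), "length")   # total minimum length < 3
})

test_that("direct matches are found in cytoplasmic sequence", {
  p <- cyto_protein("GGYINMGG")
  hits <- scanMotifs(p$protein, p$topology)
  expect_identical(hits$motif_name, "PI3K_binding")
  expect_identical(hits$start, 3L)
  expect_identical(hits$end, 6L)
  expect_identical(hits$matched_sequence, "YINM")

  p2 <- cyto_protein("YAALGGGGGGYAAI")
  hits2 <- scanMotifs(p2$protein, p2$topology)
  itam <- hits2[hits2$motif_name == "ITAM", ]
  expect_identical(nrow(itam), 1L)
  expect_identical(c(itam$start, itam$end), c(1L, 14L))
})

test_that("matches never leave the cytoplasmic compartment", {
  ps <- ProteinSet(c(P1 = paste0("YINM", strrep("L", 21), "GGYINMGG")),
                   gene_id = "G1", species = "human")
  topo <- data.frame(protein_id = "P1",
                     kind = c("extracellular", "transmembrane",
                              "cytoplasmic"),
                     start = c(1L, 5L, 26L), end = c(4L, 25L, 33L))
  hits <- scanMotifs(ps, topo)
  expect_true(all(hits$start >= 26L))
  ## no cytoplasmic segment -> empty result, not an error
  topo2 <- data.frame(protein_id = "P1", kind = "extracellular",
                      start = 1L, end = 33L)
  expect_identical(nrow(scanMotifs(ps, topo2)), 0L)
})

test_that("X matches only the wildcard", {
  p <- cyto_protein("GYXAMG")
  hits <- scanMotifs(p$protein, p$topology)
  expect_identical(hits$motif_name, "PI3K_binding")  # wildcards absorb X
  p2 <- cyto_protein("GYAAXG")                       # X at the M position
  expect_identical(nrow(scanMotifs(p2$protein, p2$topology)), 0L)
})

test_that("scanner equals both oracles on random sequences", {
  set.seed(123)
  motifs <- defaultMotifs()
  for (i in 1:150) {
    seq <- rand_seq(50, c(AA20, "X"),
                    prob = c(rep(1, 20), 0.4))
    p <- cyto_protein(seq)
    got <- scanMotifs(p$protein, p$topology)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    for (m in motifs) {
      mine <- sort_spans(got[got$motif_name == m@name,
                             c("start", "end")])
      loop <- sort_spans(oracle_scan_loop(chars, m))
      regex <- sort_spans(oracle_scan_regex(seq, m))
      expect_identical(mine, loop)
      expect_identical(mine, regex)
    }
  }
})

test_that("scanner equals the brute-force oracle on random grammars", {
  set.seed(321)
  for (g in 1:40) {
    m <- rand_motif()
    for (r in 1:5) {
      seq <- rand_seq(sample(30:70, 1L))
      p <- cyto_protein(seq)
      got <- sort_spans(scanMotifs(p$protein, p$topology,
                                   motifs = list(m))[, c("start", "end")])
      want <- sort_spans(oracle_scan_loop(
        strsplit(seq, "", fixed = TRUE)[[1L]], m))
      expect_identical(got, want)
    }
  }
})

test_that("hits shift with the offset when embedded in longer context", {
  set.seed(5)
  core <- "YAALGGGGGGYAAIKKYINMSSIAYAALV"
  p0 <- cyto_protein(core)
  base <- scanMotifs(p0$protein, p0$topology)
  for (off in c(5L, 17L, 40L)) {
    left <- rand_seq(off, c("G", "S", "D", "N"))
    right <- rand_seq(12, c("G", "S", "D", "N"))
    p1 <- cyto_protein(paste0(left, core, right))
    shifted <- scanMotifs(p1$protein, p1$topology)
    shifted <- shifted[shifted$start > off &
                       shifted$end <= off + nchar(core), ]
    expect_identical(shifted$start - off, base$start)
    expect_identical(shifted$end - off, base$end)
    expect_identical(shifted$motif_name, base$motif_name)
  }
})

test_that("enlarging a class or widening a spacer never removes hits", {
  set.seed(9)
  for (i in 1:20) {
    m <- rand_motif()
    seq <- rand_seq(60)
    p <- cyto_protein(seq)
    base <- scanMotifs(p$protein, p$topology, motifs = list(m))
    key <- paste(base$start, base$end)

    wider <- m
    ci <- which(vapply(wider@elements, function(e)
      e$type == "class" && !isTRUE(e$wildcard), logical(1)))
    if (length(ci)) {
      j <- ci[1L]
      wider@elements[[j]]$residues <-
        sort(unique(c(wider@elements[[j]]$residues, sample(AA20, 3L))))
      got <- scanMotifs(p$protein, p$topology, motifs = list(wider))
      expect_true(all(key %in% paste(got$start, got$end)))
    }
    si <- which(vapply(m@elements, function(e) e$type == "spacer",
                       logical(1)))
    if (length(si)) {
      w2 <- m
      w2@elements[[si[1L]]]$min <- max(0L, w2@elements[[si[1L]]]$min - 1L)
      w2@elements[[si[1L]]]$max <- w2@elements[[si[1L]]]$max + 1L
      got2 <- scanMotifs(p$protein, p$topology, motifs = list(w2))
      expect_true(all(key %in% paste(got2$start, got2$end)))
    }
  }
})

test_that("catalytic domains are detected only in the cytoplasmic tail", {
  topo <- data.frame(protein_id = "P1",
                     kind = c("extracellular", "transmembrane",
                              "cytoplasmic"),
                     start = c(1L, 101L, 122L), end = c(100L, 121L, 400L))
  hits <- data.frame(protein_id = "P1",
                     family = c("PTKc", "PTKc", "PTPc", "V-set"),
                     start = c(150L, 10L, 200L, 10L),
                     end = c(380L, 90L, 350L, 90L),
                     evalue = 1e-30)
  got <- detectCatalytic(hits, topo)
  expect_identical(got$start, c(150L, 200L))
  expect_identical(got$catalytic_class, c("kinase", "phosphatase"))
  empty <- detectCatalytic(hits[0, ], topo)
  expect_identical(nrow(empty), 0L)
})

test_that("signaling classes assemble from motif and catalytic evidence", {
  p <- cyto_protein("GGIAYAALVGG")            # one ITIM
  itim_hits <- scanMotifs(p$protein, p$topology)
  no_cat <- detectCatalytic(
    data.frame(protein_id = character(0), family = character(0),
               start = integer(0), end = integer(0), evalue = numeric(0)),
    p$topology)
  call1 <- classifySignaling(itim_hits[itim_hits$motif_name == "ITIM", ],
                             no_cat)
  expect_identical(signalingClasses(call1), "itim_inhibitory")

  ## receptor-kinase architecture: a cytoplasmic PTKc and nothing else
  topo <- data.frame(protein_id = "P9", kind = "cytoplasmic",
                     start = 1L, end = 300L)
  cat_hits <- detectCatalytic(
    data.frame(protein_id = "P9", family = "PTKc", start = 20L,
               end = 280L, evalue = 1e-50), topo)
  call2 <- classifySignaling(itim_hits[0, ], cat_hits)
  expect_identical(signalingClasses(call2), "kinase")

  call3 <- classifySignaling(itim_hits[0, ], cat_hits[0, ],
                             protein_id = "P9")
  expect_length(signalingClasses(call3), 0L)

  other <- itim_hits
  other$protein_id <- "OTHER"
  expect_error(classifySignaling(rbind(itim_hits, other), no_cat),
               "mixes protein ids")
})

test_that("motif configs are read from YAML", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c('ITSM: "TxYxx[VI]"', 'PI3K_binding: "YxxM"'), tf)
  motifs <- readMotifConfig(tf)
  expect_identical(names(motifs), c("ITSM", "PI3K_binding"))
  expect_identical(renderMotif(motifs$ITSM), "TxYxx[IV]")
  p <- cyto_protein("GGTAYKKVGG")
  hits <- scanMotifs(p$protein, p$topology, motifs = motifs)
  expect_identical(hits$motif_name, "ITSM")
})
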