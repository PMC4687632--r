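#' @include AllClasses.R
NULL

## residue pools for sequence simulation; weights keep extramembrane
## regions hydrophilic enough that only planted TM stretches cross the
## hydropathy threshold, while every residue still occurs (so spurious
## motif hits arise at a known, nonzero base rate)
.HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V")
.soluble_weights <- function(drop = character(0)) {
  w <- stats::setNames(rep(1.2, length(AA_STANDARD)), AA_STANDARD)
  w[.HYDROPHOBIC] <- 0.4
  w[drop] <- 0
  w
}
.sampleResidues <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}
.TM_RESIDUES <- c(I = 3, L = 3, V = 2, F = 1, A = 1)
.SPACER_POOL <- c("A", "G", "S", "T", "N", "Q", "D", "E")

#' Describe a synthetic screening study
#'
#' Fixes every parameter of the fixture generator; see
#' [SynthSpec-class] for slot meanings. The defaults emulate the screen's
#' study conditions: a hundred genes of which five are true MC-restricted
#' receptors with geometrically spaced MC enrichment tiers, five designated
#' failures per funnel stage, human RNA-seq-like triplicates over MC/T/B/Mos
#' and mouse microarray-like duplicates over the seven-cell-type panel,
#' lognormal sample noise.
#'
#' @param nGenes,nTrueReceptors,failExpressed,failFamily,failSignaling,failMouseAbundance gene counts
#' @param motifMix motif names cycled over planted cytoplasmic motifs
#' @param baselineRange per-gene baseline expression range
#' @param mcEnrichmentBase,mcEnrichmentStep MC enrichment tiers for true
#'   receptors (receptor i gets \code{base * step^(i-1)})
#' @param mouseBaselineHigh mouse baseline range for genes that must clear
#'   the mouse abundance stage
#' @param mouseAbundanceLow mouse MC mean for designated mouse-stage
#'   failures
#' @param samplesPerCellTypeHuman,samplesPerCellTypeMouse replicates
#' @param noiseSigma lognormal sdlog of per-sample noise
#' @param seed integer seed; fixes every byte of the fixture
#' @return a validated [SynthSpec-class]
#' @examples
#' synthSpec(nGenes = 30L, nTrueReceptors = 2L, seed = 11L)
#' @export
synthSpec <- function(nGenes = 100L, nTrueReceptors = 5L,
                      failExpressed = 5L, failFamily = 5L,
                      failSignaling = 5L, failMouseAbundance = 5L,
                      motifMix = c("ITAM", "ITIM", "ITIM_like",
                                   "PI3K_binding"),
                      baselineRange = c(20, 200), mcEnrichmentBase = 4,
                      mcEnrichmentStep = 1.8,
                      mouseBaselineHigh = c(60, 120),
                      mouseAbundanceLow = 30,
                      samplesPerCellTypeHuman = 3L,
                      samplesPerCellTypeMouse = 2L, noiseSigma = 0.25,
                      seed = 1L) {
  new("SynthSpec", nGenes = as.integer(nGenes),
      nTrueReceptors = as.integer(nTrueReceptors),
      failExpressed = as.integer(failExpressed),
      failFamily = as.integer(failFamily),
      failSignaling = as.integer(failSignaling),
      failMouseAbundance = as.integer(failMouseAbundance),
      motifMix = motifMix, baselineRange = baselineRange,
      mcEnrichmentBase = mcEnrichmentBase,
      mcEnrichmentStep = mcEnrichmentStep,
      mouseBaselineHigh = mouseBaselineHigh,
      mouseAbundanceLow = mouseAbundanceLow,
      samplesPerCellTypeHuman = as.integer(samplesPerCellTypeHuman),
      samplesPerCellTypeMouse = as.integer(samplesPerCellTypeMouse),
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

## instantiate a motif pattern as a concrete residue string; wildcards and
## spacers draw from a tyrosine-free pool so the planted string matches its
## own motif but does not smuggle in extra half-sites
.realizeMotif <- function(motif) {
  paste(vapply(motif@elements, function(el) {
    if (el$type == "spacer") {
      len <- if (el$max > el$min) sample(el$min:el$max, 1L) else el$min
      paste(sample(.SPACER_POOL, len, replace = TRUE), collapse = "")
    } else if (isTRUE(el$wildcard)) {
      sample(.SPACER_POOL, 1L)
    } else {
      sample(el$residues, 1L)
    }
  }, character(1)), collapse = "")
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

.writeExprTsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   apply(mat, 2L, function(x) sprintf("%.4f", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

## draw one gene's per-sample values: cell-type mean x lognormal noise
.sampleExpr <- function(means, nrep, sigma) {
  unlist(lapply(means, function(m) m * stats::rlnorm(nrep, 0, sigma)),
         use.names = FALSE)
}

#' Generate a self-contained synthetic screening fixture
#'
#' Writes proteins (FASTA), domain hits, topology, human and mouse
#' expression matrices with sample maps, an ortholog map and a ground-truth
#' manifest into \code{outDir}. True receptors carry an extracellular
#' Ig-like or CLECT domain, a single transmembrane helix and either a
#' planted cytoplasmic signaling motif or a cytoplasmic PTKc domain (the
#' receptor-kinase architecture, given to the receptor with the highest
#' enrichment tier); their expression is MC-enriched in both species with
#' mouse MC max above 100. Designated failure genes violate exactly their
#' named stage: mouse-stage failures get rescaled low mouse MC values,
#' signaling failures a tyrosine-free cytoplasmic tail, family failures a
#' decoy domain (or a CLECT hit placed in the tail, exercising the
#' compartment rule), expression failures a zero human MC row. All output
#' is a deterministic function of the spec and its seed; the planted
#' features are verified against the emitted files before returning.
#'
#' @param spec a [SynthSpec-class]
#' @param outDir output directory (created if needed)
#' @return a [GroundTruth-class]
#' @examples
#' td <- tempfile("fixture")
#' truth <- generateFixture(synthSpec(nGenes = 20L, nTrueReceptors = 2L,
#'                                    failExpressed = 1L, failFamily = 1L,
#'                                    failSignaling = 1L,
#'                                    failMouseAbundance = 1L, seed = 3L),
#'                          td)
#' truth
#' @export
generateFixture <- function(spec, outDir) {
  validObject(spec)
  n <- spec@nGenes
  roles <- rep("background", n)
  cursor <- 0L
  for (rr in list(c("true_receptor", spec@nTrueReceptors),
                  c("fail_expressed", spec@failExpressed),
                  c("fail_family", spec@failFamily),
                  c("fail_signaling", spec@failSignaling),
                  c("fail_mouse_abundance", spec@failMouseAbundance))) {
    k <- as.integer(rr[2L])
    if (k > 0L) roles[(cursor + 1L):(cursor + k)] <- rr[1L]
    cursor <- cursor + k
  }
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)

  set.seed(spec@seed)
  gene <- sprintf("HG%04d", seq_len(n))
  mgene <- sprintf("MG%04d", seq_len(n))
  prot <- sprintf("P%04d", seq_len(n))
  motifs <- defaultMotifs()
  fam_pool <- c("V-set", "C2-set", "IG", "I-set", "CLECT")

  true_idx <- which(roles == "true_receptor")
  enrich <- rep(NA_real_, n)
  if (length(true_idx))
    enrich[true_idx] <- spec@mcEnrichmentBase *
      spec@mcEnrichmentStep^(seq_along(true_idx) - 1L)
  ## the strongest-enriched receptor gets the receptor-kinase architecture
  kinase_idx <- if (length(true_idx)) true_idx[which.max(enrich[true_idx])]
                else integer(0)

  seqs <- character(n)
  topo <- vector("list", n)
  domains <- list()
  truth <- data.frame(gene_id = gene, mouse_gene = mgene, protein_id = prot,
                      role = roles, enrichment = enrich,
                      expect_expressed = TRUE, expect_family = TRUE,
                      expect_signaling = TRUE, expect_mouse = TRUE,
                      domain_family = NA_character_,
                      motif_name = NA_character_,
                      motif_start = NA_integer_, motif_end = NA_integer_,
                      motif_seq = NA_character_, intended_rank = NA_integer_,
                      stringsAsFactors = FALSE)
  if (length(true_idx))
    truth$intended_rank[true_idx] <- rank(-enrich[true_idx],
                                          ties.method = "first")

  for (i in seq_len(n)) {
    role <- roles[i]
    ecto_len <- sample(90:150, 1L)
    tail_len <- sample(60:100, 1L)
    tail_drop <- if (role == "fail_signaling") "Y" else character(0)
    ecto <- .sampleResidues(ecto_len, .soluble_weights())
    tm <- sample(names(.TM_RESIDUES), 21L, replace = TRUE,
                 prob = .TM_RESIDUES)
    tail <- .sampleResidues(tail_len, .soluble_weights(tail_drop))
    tm_start <- ecto_len + 1L
    tail_start <- ecto_len + 22L
    total <- ecto_len + 21L + tail_len

    plant_motif <- role %in% c("true_receptor", "fail_expressed",
                               "fail_family", "fail_mouse_abundance") &&
      !(i %in% kinase_idx)
    if (plant_motif) {
      mname <- spec@motifMix[((i - 1L) %% length(spec@motifMix)) + 1L]
      mseq <- .realizeMotif(motifs[[mname]])
      off <- sample.int(tail_len - nchar(mseq) + 1L, 1L)
      tail[off:(off + nchar(mseq) - 1L)] <-
        strsplit(mseq, "", fixed = TRUE)[[1L]]
      truth$motif_name[i] <- mname
      truth$motif_start[i] <- tail_start + off - 1L
      truth$motif_end[i] <- tail_start + off - 1L + nchar(mseq) - 1L
      truth$motif_seq[i] <- mseq
    }
    seqs[i] <- paste(c(ecto, tm, tail), collapse = "")
    topo[[i]] <- data.frame(
      protein_id = prot[i],
      kind = c("extracellular", "transmembrane", "cytoplasmic"),
      start = c(1L, tm_start, tail_start),
      end = c(ecto_len, tail_start - 1L, total))

    if (role %in% c("true_receptor", "fail_expressed", "fail_signaling",
                    "fail_mouse_abundance")) {
      fam <- sample(fam_pool, 1L)
      dlen <- sample(60:80, 1L)
      dstart <- sample.int(ecto_len - dlen, 1L)
      domains[[length(domains) + 1L]] <- data.frame(
        protein_id = prot[i], family = fam, start = dstart,
        end = dstart + dlen - 1L,
        evalue = 10^-stats::runif(1, 10, 50))
      truth$domain_family[i] <- fam
    } else if (role == "fail_family") {
      ## half decoy family in the ectodomain, half a real family label
      ## placed in the tail (rejected by the compartment rule)
      if (i %% 2L == 0L && tail_len >= 45L) {
        domains[[length(domains) + 1L]] <- data.frame(
          protein_id = prot[i], family = "CLECT", start = tail_start,
          end = tail_start + 39L, evalue = 10^-stats::runif(1, 10, 50))
      } else {
        domains[[length(domains) + 1L]] <- data.frame(
          protein_id = prot[i], family = "FN3", start = 5L,
          end = min(70L, ecto_len), evalue = 10^-stats::runif(1, 5, 20))
      }
    } else if (role == "background" && i %% 2L == 0L) {
      domains[[length(domains) + 1L]] <- data.frame(
        protein_id = prot[i], family = "FN3", start = 5L,
        end = min(70L, ecto_len), evalue = 10^-stats::runif(1, 5, 20))
    }
    if (i %in% kinase_idx) {
      domains[[length(domains) + 1L]] <- data.frame(
        protein_id = prot[i], family = "PTKc", start = tail_start + 2L,
        end = total - 2L, evalue = 10^-stats::runif(1, 30, 60))
    }
  }
  truth$expect_expressed[roles == "fail_expressed"] <- FALSE
  truth$expect_family[roles == "fail_family"] <- FALSE
  truth$expect_signaling[roles == "fail_signaling"] <- FALSE
  truth$expect_mouse[roles == "fail_mouse_abundance"] <- FALSE
  truth$expect_family[roles == "background"] <- FALSE
  truth$expect_signaling[roles == "background"] <- NA  # spurious-rate driven

  ## expression matrices ----------------------------------------------------
  h_ct <- c("MC", "T", "B", "Mos")
  m_ct <- c("MC", "T", "B", "Mos", "NK", "DCs", "MPs")
  nh <- spec@samplesPerCellTypeHuman
  nm <- spec@samplesPerCellTypeMouse
  h_samples <- paste0("h_", rep(h_ct, each = nh), "_", rep(seq_len(nh),
                                                           length(h_ct)))
  m_samples <- paste0("m_", rep(m_ct, each = nm), "_", rep(seq_len(nm),
                                                           length(m_ct)))
  hmat <- matrix(0, n, length(h_samples), dimnames = list(gene, h_samples))
  mmat <- matrix(0, n, length(m_samples), dimnames = list(mgene, m_samples))
  must_pass_mouse <- roles %in% c("true_receptor", "fail_expressed",
                                  "fail_family", "fail_signaling")

  for (i in seq_len(n)) {
    role <- roles[i]
    bh <- stats::runif(1, spec@baselineRange[1L], spec@baselineRange[2L])
    h_means <- bh * stats::runif(length(h_ct), 0.5, 1.5)
    names(h_means) <- h_ct
    if (role == "true_receptor") h_means["MC"] <- bh * enrich[i]
    if (role == "fail_expressed") h_means["MC"] <- 0
    hvals <- .sampleExpr(h_means, nh, spec@noiseSigma)
    if (role == "fail_expressed") hvals[seq_len(nh)] <- 0
    hmat[i, ] <- hvals

    bm <- if (must_pass_mouse[i])
      stats::runif(1, spec@mouseBaselineHigh[1L], spec@mouseBaselineHigh[2L])
    else stats::runif(1, spec@baselineRange[1L], spec@baselineRange[2L])
    m_means <- bm * stats::runif(length(m_ct), 0.5, 1.5)
    names(m_means) <- m_ct
    if (role == "true_receptor") m_means["MC"] <- bm * enrich[i]
    else if (must_pass_mouse[i]) m_means["MC"] <- bm * spec@mcEnrichmentBase
    else if (role == "fail_mouse_abundance")
      m_means["MC"] <- spec@mouseAbundanceLow
    mvals <- .sampleExpr(m_means, nm, spec@noiseSigma)
    ## the designated mouse-stage verdict is a generator guarantee, not a
    ## noise outcome: rescale MC samples that drift across the threshold
    mc_cols <- seq_len(nm)
    if (role == "fail_mouse_abundance" && max(mvals[mc_cols]) > 95)
      mvals[mc_cols] <- mvals[mc_cols] * 95 / max(mvals[mc_cols])
    if (must_pass_mouse[i] && max(mvals[mc_cols]) <= 105)
      mvals[mc_cols] <- mvals[mc_cols] * 105 / max(mvals[mc_cols])
    mmat[i, ] <- mvals
  }

  ## emit -------------------------------------------------------------------
  files <- c(proteins = "proteins.fasta", domains = "domains.tsv",
             topology = "topology.tsv",
             human_expr = "human_expression.tsv",
             human_samples = "human_samples.tsv",
             mouse_expr = "mouse_expression.tsv",
             mouse_samples = "mouse_samples.tsv",
             orthologs = "orthologs.tsv", truth = "truth.tsv",
             spec = "synth_spec.yaml")
  files <- stats::setNames(file.path(outDir, files), names(files))

  ps <- ProteinSet(seqs, gene_id = gene, species = "human",
                   protein_id = prot)
  writeProteins(ps, files[["proteins"]])
  dom <- if (length(domains)) do.call(rbind, domains) else
    data.frame(protein_id = character(0), family = character(0),
               start = integer(0), end = integer(0), evalue = numeric(0))
  dom$evalue <- sprintf("%.3e", dom$evalue)
  .writeTsv(dom, files[["domains"]])
  .writeTsv(do.call(rbind, topo), files[["topology"]])
  .writeExprTsv(hmat, files[["human_expr"]])
  .writeTsv(data.frame(sample = h_samples,
                       cell_type = rep(h_ct, each = nh)),
            files[["human_samples"]])
  .writeExprTsv(mmat, files[["mouse_expr"]])
  .writeTsv(data.frame(sample = m_samples,
                       cell_type = rep(m_ct, each = nm)),
            files[["mouse_samples"]])
  .writeTsv(data.frame(human_gene = gene, mouse_gene = mgene),
            files[["orthologs"]])
  .writeTsv(truth, files[["truth"]])
  spec_list <- .configList(spec)
  yaml::write_yaml(spec_list, files[["spec"]])

  out <- new("GroundTruth", spec = spec, dir = outDir,
             files = files, genes = truth, expectedEffect = character(0))
  .verifyFixture(out)
  out
}

## generation-time closure check: re-read the emitted files through the
## package's own readers and confirm the planted features
.verifyFixture <- function(truth) {
  ps <- readProteins(truth@files[["proteins"]])
  hits <- readDomainHits(truth@files[["domains"]], ps)
  topo <- readTopology(truth@files[["topology"]], ps)
  invisible(readExpressionMatrix(truth@files[["human_expr"]],
                                 truth@files[["human_samples"]], "human"))
  invisible(readExpressionMatrix(truth@files[["mouse_expr"]],
                                 truth@files[["mouse_samples"]], "mouse",
                                 platform = "microarray"))
  g <- truth@genes
  planted <- which(!is.na(g$motif_name))
  for (i in planted) {
    seq <- proteinSequence(ps, g$protein_id[i])
    got <- substr(seq, g$motif_start[i], g$motif_end[i])
    if (!identical(got, g$motif_seq[i]))
      stop("fixture self-check failed: planted motif mismatch for ",
           g$gene_id[i])
    seg <- topo[topo$protein_id == g$protein_id[i] &
                topo$kind == "cytoplasmic", , drop = FALSE]
    if (!nrow(seg) || g$motif_start[i] < seg$start[1L] ||
        g$motif_end[i] > seg$end[1L])
      stop("fixture self-check failed: planted motif outside the tail for ",
           g$gene_id[i])
  }
  if (nrow(hits)) validateDomainHits(hits, ps)
  invisible(TRUE)
}

#' Screen configuration for a generated fixture
#'
#' Convenience wrapper building a [ScreenConfig-class] whose input paths
#' point at a fixture's emitted files.
#'
#' @param truth a [GroundTruth-class]
#' @param ... overrides passed to [screenConfig()]
#' @return a [ScreenConfig-class]
#' @export
fixtureConfig <- function(truth, ...) {
  stopifnot(is(truth, "GroundTruth"))
  f <- truth@files
  screenConfig(proteinsFile = f[["proteins"]], domainsFile = f[["domains"]],
               topologyFile = f[["topology"]],
               humanExprFile = f[["human_expr"]],
               humanSampleMapFile = f[["human_samples"]],
               mouseExprFile = f[["mouse_expr"]],
               mouseSampleMapFile = f[["mouse_samples"]],
               orthologFile = f[["orthologs"]], seed = truth@spec@seed, ...)
}

#' Perturb a generated fixture in a controlled way
#'
#' Re-emits a fixture with one targeted modification whose expected effect
#' on the screen is recorded in the returned ground truth:
#' \describe{
#'   \item{\code{lower_mouse_abundance}}{set the target's mouse MC sample
#'     values to \code{magnitude} (default 90); at or below the abundance
#'     threshold this newly fails the mouse stage.}
#'   \item{\code{drop_ortholog}}{remove the target from the ortholog map;
#'     the gene becomes unmapped and fails the mouse stage.}
#'   \item{\code{move_motif_extracellular}}{relocate the target's planted
#'     motif into the extracellular region, erase cytoplasmic tyrosines and
#'     any catalytic-domain hits; signaling evidence disappears.}
#'   \item{\code{shrink_mc_enrichment}}{set the target's MC samples in both
#'     species so its average fold change at \eqn{\epsilon = 1} equals
#'     \code{magnitude} exactly (default 1, i.e. no enrichment).}
#' }
#'
#' @param truth a [GroundTruth-class] from [generateFixture()]
#' @param knob one of the four perturbation names above
#' @param outDir directory for the modified fixture
#' @param gene target human gene id (default: the first true receptor, or
#'   the first motif-bearing true receptor for the motif knob)
#' @param magnitude knob-specific magnitude (see above)
#' @return a new [GroundTruth-class] describing the perturbed fixture
#' @export
perturbFixture <- function(truth, knob, outDir, gene = NULL,
                           magnitude = NULL) {
  knobs <- c("shrink_mc_enrichment", "move_motif_extracellular",
             "drop_ortholog", "lower_mouse_abundance")
  if (!knob %in% knobs)
    stop("unknown perturbation knob '", knob, "'; expected one of: ",
         paste(knobs, collapse = ", "))
  g <- truth@genes
  if (is.null(gene)) {
    pool <- if (knob == "move_motif_extracellular")
      g$gene_id[g$role == "true_receptor" & !is.na(g$motif_name)]
    else g$gene_id[g$role == "true_receptor"]
    if (!length(pool)) stop("no eligible target gene in the fixture")
    gene <- pool[1L]
  }
  i <- match(gene, g$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene)

  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  newfiles <- stats::setNames(file.path(outDir, basename(truth@files)),
                              names(truth@files))
  for (k in names(truth@files)) file.copy(truth@files[[k]], newfiles[[k]],
                                          overwrite = TRUE)

  readExpr <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene_id
    m
  }
  effect <- ""
  if (knob == "lower_mouse_abundance") {
    if (is.null(magnitude)) magnitude <- 90
    m <- readExpr(newfiles[["mouse_expr"]])
    mc_cols <- grep("^m_MC_", colnames(m))
    m[g$mouse_gene[i], mc_cols] <- magnitude
    .writeExprTsv(m, newfiles[["mouse_expr"]])
    g$expect_mouse[i] <- magnitude > 100
    effect <- sprintf("%s mouse MC set to %g; mouse_abundance_pass -> %s",
                      gene, magnitude, g$expect_mouse[i])
  } else if (knob == "drop_ortholog") {
    om <- utils::read.delim(newfiles[["orthologs"]],
                            stringsAsFactors = FALSE)
    om <- om[om$human_gene != gene, , drop = FALSE]
    .writeTsv(om, newfiles[["orthologs"]])
    g$expect_mouse[i] <- FALSE
    effect <- sprintf("%s dropped from the ortholog map; reported unmapped",
                      gene)
  } else if (knob == "move_motif_extracellular") {
    if (is.na(g$motif_name[i]))
      stop("target gene has no planted motif to move")
    ps <- readProteins(newfiles[["proteins"]])
    topo <- readTopology(newfiles[["topology"]], ps)
    pid <- g$protein_id[i]
    seqchars <- strsplit(proteinSequence(ps, pid), "", fixed = TRUE)[[1L]]
    cyt <- topo[topo$protein_id == pid & topo$kind == "cytoplasmic", ]
    span <- cyt$start[1L]:cyt$end[1L]
    seqchars[span][seqchars[span] == "Y"] <- "F"  # erase all half-sites
    mseq <- strsplit(g$motif_seq[i], "", fixed = TRUE)[[1L]]
    ecto_at <- 5L
    seqchars[ecto_at:(ecto_at + length(mseq) - 1L)] <- mseq
    idx <- match(pid, proteinIds(ps))
    newseqs <- as.character(ps@sequences)
    newseqs[idx] <- paste(seqchars, collapse = "")
    ps2 <- ProteinSet(newseqs, gene_id = geneIds(ps),
                      species = ps@proteinData$species,
                      protein_id = proteinIds(ps))
    writeProteins(ps2, newfiles[["proteins"]])
    dom <- utils::read.delim(newfiles[["domains"]],
                             stringsAsFactors = FALSE)
    dom <- dom[!(dom$protein_id == pid &
                 dom$family %in% c(defaultPtkSet(), defaultPtpSet())), ,
               drop = FALSE]
    .writeTsv(dom, newfiles[["domains"]])
    g$expect_signaling[i] <- FALSE
    g$motif_start[i] <- ecto_at
    g$motif_end[i] <- ecto_at + length(mseq) - 1L
    effect <- sprintf("%s motif moved to the ectodomain; signaling_pass -> FALSE",
                      gene)
  } else if (knob == "shrink_mc_enrichment") {
    if (is.null(magnitude)) magnitude <- 1
    eps <- 1
    for (sp in c("human", "mouse")) {
      key <- if (sp == "human") "human_expr" else "mouse_expr"
      gid <- if (sp == "human") g$gene_id[i] else g$mouse_gene[i]
      m <- readExpr(newfiles[[key]])
      prefix <- if (sp == "human") "h_" else "m_"
      comp <- defaultComparisonSet(sp)
      acomp <- vapply(comp, function(ct)
        max(m[gid, grep(paste0("^", prefix, ct, "_"), colnames(m))]),
        numeric(1))
      ## choose the MC level whose average fold change equals `magnitude`
      v <- magnitude / mean(1 / (acomp + eps)) - eps
      m[gid, grep(paste0("^", prefix, "MC_"), colnames(m))] <- max(v, 0)
      .writeExprTsv(m, newfiles[[key]])
    }
    effect <- sprintf(
      "%s MC enrichment set so avg fold change (epsilon = 1) = %g in both species",
      gene, magnitude)
  }
  .writeTsv(g, newfiles[["truth"]])
  new("GroundTruth", spec = truth@spec, dir = outDir, files = newfiles,
      genes = g, expectedEffect = effect)
}
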