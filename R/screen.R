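#' @include AllClasses.R
NULL

#' Build a screen configuration
#'
#' Collects every input path and tunable of the candidate screen; see
#' [ScreenConfig-class] for the meaning of each field. Defaults implement
#' the published funnel: strict \code{> 0} human expressed filter, strict
#' \code{> 100} mouse abundance filter, max-over-samples aggregation,
#' average fold-change specificity against \code{T/B/Mos} (human) and
#' \code{T/B/Mos/NK/DCs/MPs} (mouse), combined by geometric mean.
#'
#' @param proteinsFile,domainsFile,humanExprFile,humanSampleMapFile paths
#' @param mouseExprFile,mouseSampleMapFile,orthologFile paths
#' @param topologyFile optional topology table (\code{""} = predict)
#' @param motifFile optional motif config (\code{""} = [defaultMotifs()])
#' @param humanExpressedThreshold default 0 (strict)
#' @param mouseAbundanceThreshold default 100 (strict)
#' @param referenceCellType default \code{"MC"}
#' @param humanComparison,mouseComparison comparison sets (defaults
#'   [defaultComparisonSet()])
#' @param igSet,clectSet,ptkSet,ptpSet family label sets
#' @param minOverlap default 0.5
#' @param epsilon fold-change pseudocount, default 1
#' @param combine \code{"geomean"} (default) or \code{"min"}
#' @param window,hydroThreshold fallback topology predictor parameters
#' @param seed integer seed recorded in reports
#' @return a validated [ScreenConfig-class]
#' @export
screenConfig <- function(proteinsFile, domainsFile, humanExprFile,
                         humanSampleMapFile, mouseExprFile,
                         mouseSampleMapFile, orthologFile,
                         topologyFile = "", motifFile = "",
                         humanExpressedThreshold = 0,
                         mouseAbundanceThreshold = 100,
                         referenceCellType = "MC",
                         humanComparison = defaultComparisonSet("human"),
                         mouseComparison = defaultComparisonSet("mouse"),
                         igSet = defaultIgSet(),
                         clectSet = defaultClectSet(),
                         ptkSet = defaultPtkSet(), ptpSet = defaultPtpSet(),
                         minOverlap = 0.5, epsilon = 1,
                         combine = c("geomean", "min"), window = 19L,
                         hydroThreshold = 1.6, seed = 1L) {
  new("ScreenConfig", proteinsFile = proteinsFile,
      domainsFile = domainsFile, topologyFile = topologyFile,
      humanExprFile = humanExprFile,
      humanSampleMapFile = humanSampleMapFile,
      mouseExprFile = mouseExprFile,
      mouseSampleMapFile = mouseSampleMapFile,
      orthologFile = orthologFile, motifFile = motifFile,
      humanExpressedThreshold = humanExpressedThreshold,
      mouseAbundanceThreshold = mouseAbundanceThreshold,
      referenceCellType = referenceCellType,
      humanComparison = humanComparison, mouseComparison = mouseComparison,
      igSet = igSet, clectSet = clectSet, ptkSet = ptkSet, ptpSet = ptpSet,
      minOverlap = minOverlap, epsilon = epsilon,
      combine = match.arg(combine), window = as.integer(window),
      hydroThreshold = hydroThreshold, seed = as.integer(seed))
}

#' Read a screen configuration from YAML
#'
#' Keys are the [screenConfig()] argument names; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file
#' @return a [ScreenConfig-class]
#' @export
readScreenConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  spec <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  pathkeys <- c("proteinsFile", "domainsFile", "topologyFile",
                "humanExprFile", "humanSampleMapFile", "mouseExprFile",
                "mouseSampleMapFile", "orthologFile", "motifFile")
  for (k in intersect(pathkeys, names(spec))) {
    p <- spec[[k]]
    if (nzchar(p) && !grepl("^(/|[A-Za-z]:)", p))
      spec[[k]] <- file.path(base, p)
  }
  do.call(screenConfig, spec)
}

.configList <- function(config) {
  nm <- slotNames(class(config))
  stats::setNames(lapply(nm, function(s) slot(config, s)), nm)
}

#' Run the candidate-receptor screen
#'
#' Executes the discovery funnel end to end. For every gene present in both
#' the human expression matrix and the protein set (one representative
#' protein per gene: the longest sequence, ties broken by protein id), four
#' stage predicates are evaluated:
#' \enumerate{
#'   \item \strong{expressed_human} — aggregated human MC expression
#'     strictly above \code{humanExpressedThreshold};
#'   \item \strong{family_pass} — an Ig-like or CLECT extracellular domain
#'     ([assignFamily()]);
#'   \item \strong{signaling_pass} — a cytoplasmic signaling motif or
#'     catalytic domain ([scanMotifs()], [detectCatalytic()],
#'     [classifySignaling()]);
#'   \item \strong{mouse_abundance_pass} — an ortholog whose mouse MC
#'     max-over-samples expression is strictly above
#'     \code{mouseAbundanceThreshold}.
#' }
#' Genes passing all four are scored for specificity in both species
#' ([specificity()]), combined (geometric mean by default) and ranked
#' (descending score, ties broken by gene id). Per-stage survivor counts
#' are reported via \code{message()}.
#'
#' @param config a [ScreenConfig-class]
#' @return a [ScreenResult-class]
#' @seealso [writeReport()]
#' @export
runScreen <- function(config) {
  validObject(config)
  paths <- c(proteins = config@proteinsFile, domains = config@domainsFile,
             human_expr = config@humanExprFile,
             human_samples = config@humanSampleMapFile,
             mouse_expr = config@mouseExprFile,
             mouse_samples = config@mouseSampleMapFile,
             orthologs = config@orthologFile)
  if (nzchar(config@topologyFile))
    paths <- c(paths, topology = config@topologyFile)
  if (nzchar(config@motifFile))
    paths <- c(paths, motifs = config@motifFile)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", missing_files, names(missing_files)),
               collapse = ", "))

  proteins <- readProteins(config@proteinsFile)
  hits <- readDomainHits(config@domainsFile, proteins)
  topo_tab <- if (nzchar(config@topologyFile))
    readTopology(config@topologyFile, proteins) else NULL
  motifs <- if (nzchar(config@motifFile)) readMotifConfig(config@motifFile)
            else defaultMotifs()
  human <- readExpressionMatrix(config@humanExprFile,
                                config@humanSampleMapFile,
                                species = "human")
  mouse <- readExpressionMatrix(config@mouseExprFile,
                                config@mouseSampleMapFile,
                                species = "mouse", platform = "microarray")
  orth <- readOrthologMap(config@orthologFile)

  ## one representative protein per gene: the longest, ties by protein_id
  pd <- as.data.frame(proteins@proteinData)
  pd$len <- BiocGenerics::width(proteins@sequences)
  pd <- pd[order(pd$gene_id, -pd$len, pd$protein_id), , drop = FALSE]
  rep_prot <- pd[!duplicated(pd$gene_id), , drop = FALSE]

  hprofile <- aggregateCellTypes(human, method = "max")
  hgenes <- rownames(SummarizedExperiment::assay(hprofile))
  universe <- intersect(hgenes, rep_prot$gene_id)
  skipped <- setdiff(rep_prot$gene_id, hgenes)
  if (length(skipped))
    message("screen: ", length(skipped),
            " gene(s) with protein but no human expression row excluded")
  message("screen: gene universe of ", length(universe), " gene(s)")
  if (!length(universe)) {
    warning("no genes shared between proteins and human expression matrix")
  }

  univ_pid <- rep_prot$protein_id[match(universe, rep_prot$gene_id)]
  univ_ps <- proteins[univ_pid]
  topo <- topologyFor(univ_ps, topology = topo_tab, window = config@window,
                      threshold = config@hydroThreshold)

  expressed <- filterExpressed(hprofile, config@referenceCellType,
                               config@humanExpressedThreshold,
                               strict = TRUE)
  mprofile <- aggregateCellTypes(mouse, method = "max")
  mvals <- SummarizedExperiment::assay(mprofile)
  morth <- mapOrthologs(universe, orth, "human_to_mouse")
  mouse_of <- stats::setNames(morth$pairs$to, morth$pairs$from)
  if (length(morth$unmapped))
    message("screen: ", length(morth$unmapped),
            " gene(s) without a mouse ortholog fail the mouse stage: ",
            paste(utils::head(morth$unmapped, 10L), collapse = ", "),
            if (length(morth$unmapped) > 10L) ", ..." else "")

  n <- length(universe)
  all_motif_hits <- scanMotifSet(univ_ps, topo, motifs)
  mh_split <- split(all_motif_hits, all_motif_hits$protein_id)
  hit_split <- split(hits, hits$protein_id)
  seg_split <- split(topo, topo$protein_id)
  no_hits <- hits[0, , drop = FALSE]
  no_mh <- all_motif_hits[0, , drop = FALSE]

  fam_cls <- character(n)
  sig_cls <- character(n)
  flags <- matrix(FALSE, n, 4L,
                  dimnames = list(universe,
                                  c("expressed_human", "family_pass",
                                    "signaling_pass",
                                    "mouse_abundance_pass")))
  for (i in seq_len(n)) {
    g <- universe[i]
    pid <- univ_pid[i]
    seg <- seg_split[[pid]]
    phits <- hit_split[[pid]]
    if (is.null(phits)) phits <- no_hits

    flags[i, "expressed_human"] <- g %in% expressed
    fam <- .familyCallCore(pid, phits, seg, config@igSet, config@clectSet,
                           config@minOverlap)
    fam_cls[i] <- familyClass(fam)
    flags[i, "family_pass"] <- familyClass(fam) != "none"
    mh <- mh_split[[pid]]
    if (is.null(mh)) mh <- no_mh
    cat_hits <- detectCatalytic(phits, seg, ptkSet = config@ptkSet,
                                ptpSet = config@ptpSet,
                                minOverlap = config@minOverlap)
    sig <- classifySignaling(mh, cat_hits, protein_id = pid)
    sig_cls[i] <- paste(sort(signalingClasses(sig)), collapse = ",")
    flags[i, "signaling_pass"] <- length(signalingClasses(sig)) > 0L
    mg <- mouse_of[g]
    flags[i, "mouse_abundance_pass"] <-
      !is.na(mg) && mg %in% rownames(mvals) &&
      mvals[mg, config@referenceCellType] > config@mouseAbundanceThreshold
  }

  cum <- c(input = n,
           expressed_human = sum(flags[, 1L]),
           family_pass = sum(flags[, 1L] & flags[, 2L]),
           signaling_pass = sum(flags[, 1L] & flags[, 2L] & flags[, 3L]),
           mouse_abundance_pass = sum(rowSums(flags) == 4L))
  for (nm in names(cum))
    message(sprintf("screen: %-22s %d", nm, cum[[nm]]))

  cand <- data.frame(gene_id = universe,
                     mouse_gene = unname(mouse_of[universe]),
                     family_class = fam_cls, signaling_classes = sig_cls,
                     as.data.frame(flags), stringsAsFactors = FALSE,
                     row.names = NULL)
  cand$human_specificity <-
    specificityTable(hprofile, genes = universe,
                     reference = config@referenceCellType,
                     comparison = config@humanComparison,
                     epsilon = config@epsilon)$avg_fc
  mg_ok <- !is.na(cand$mouse_gene) & cand$mouse_gene %in% rownames(mvals)
  cand$mouse_specificity <- NA_real_
  if (any(mg_ok))
    cand$mouse_specificity[mg_ok] <-
      specificityTable(mprofile, genes = cand$mouse_gene[mg_ok],
                       reference = config@referenceCellType,
                       comparison = config@mouseComparison,
                       epsilon = config@epsilon)$avg_fc

  final <- rowSums(flags) == 4L
  cand$combined_score <- NA_real_
  cand$rank <- NA_integer_
  if (any(final)) {
    hs <- cand$human_specificity[final]
    ms <- cand$mouse_specificity[final]
    comb <- if (config@combine == "geomean") sqrt(hs * ms) else pmin(hs, ms)
    cand$combined_score[final] <- comb
    ord <- order(-comb, cand$gene_id[final])
    rk <- integer(sum(final))
    rk[ord] <- seq_along(ord)
    cand$rank[final] <- rk
  } else {
    warning("no gene survived all funnel stages; final table is empty")
  }

  ranked <- cand[final, , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  rownames(ranked) <- NULL
  new("ScreenResult", candidates = cand, ranked = ranked,
      stageCounts = stats::setNames(as.integer(cum), names(cum)),
      config = config)
}

#' Write screen reports
#'
#' Writes three files into \code{dir}: \code{stage_flags.tsv} (the full
#' gene x stage-flag table), \code{ranked_candidates.tsv} (the final ranked
#' table) and \code{manifest.yaml} (configuration, config hash, package
#' version, per-stage survivor counts, timestamp). Rerunning with an
#' identical configuration reproduces the two tables byte for byte.
#'
#' @param result a [ScreenResult-class]
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
writeReport <- function(result, dir) {
  stopifnot(is(result, "ScreenResult"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L)
    stop("cannot write to directory: ", dir)
  fmt <- function(df) {
    for (cl in names(df))
      if (is.numeric(df[[cl]]) && !is.integer(df[[cl]]))
        df[[cl]] <- ifelse(is.na(df[[cl]]), "NA",
                           sprintf("%.6g", df[[cl]]))
    df
  }
  flags_path <- file.path(dir, "stage_flags.tsv")
  ranked_path <- file.path(dir, "ranked_candidates.tsv")
  manifest_path <- file.path(dir, "manifest.yaml")
  utils::write.table(fmt(candidates(result)), flags_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fmt(rankedCandidates(result)), ranked_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- .configList(result@config)
  cfg_yaml <- yaml::as.yaml(cfg)
  tmp <- tempfile()
  writeLines(cfg_yaml, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    package = "ReceptorScreen",
    version = as.character(utils::packageVersion("ReceptorScreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = cfg_hash,
    stage_counts = as.list(stageCounts(result)),
    config = cfg)
  yaml::write_yaml(manifest, manifest_path)
  invisible(c(stage_flags = flags_path, ranked_candidates = ranked_path,
              manifest = manifest_path))
}
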