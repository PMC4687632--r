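#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## The 20 standard residues; X marks an unknown residue and is allowed in
## sequences but never inside a residue class (only the wildcard matches it).
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA_STANDARD, "X")

TOPOLOGY_KINDS <- c("extracellular", "transmembrane", "cytoplasmic")
FAMILY_CLASSES <- c("ig_like", "clect", "none")
SIGNALING_CLASSES <- c("itam_activating", "pi3k_activating",
                       "itim_inhibitory", "kinase", "phosphatase")

#' ProteinSet: protein sequences with gene and species annotation
#'
#' A set of protein sequences (one amino-acid string per protein) together
#' with the identifier columns the screen needs: each protein belongs to
#' exactly one gene and one species. Sequences are stored as a
#' \link[Biostrings]{AAStringSet}; per-protein annotation lives in a
#' parallel \link[S4Vectors]{DataFrame} with columns \code{protein_id},
#' \code{gene_id} and \code{species}.
#'
#' @slot sequences an \code{AAStringSet}, names equal to \code{protein_id}
#' @slot proteinData a \code{DataFrame} with one row per sequence
#' @seealso [readProteins()], [ProteinSet()]
#' @exportClass ProteinSet
setClass("ProteinSet",
         representation(sequences = "AAStringSet", proteinData = "DataFrame"))

setValidity("ProteinSet", function(object) {
  seqs <- object@sequences
  pd <- object@proteinData
  msgs <- character(0)
  req <- c("protein_id", "gene_id", "species")
  if (!all(req %in% colnames(pd)))
    return(paste("proteinData must have columns", paste(req, collapse = ", ")))
  if (length(seqs) != nrow(pd))
    return("sequences and proteinData lengths differ")
  if (length(seqs) == 0L)
    return(TRUE)
  if (!identical(names(seqs), as.character(pd$protein_id)))
    msgs <- c(msgs, "names(sequences) must equal proteinData$protein_id")
  if (anyDuplicated(pd$protein_id))
    msgs <- c(msgs, "protein_id values must be unique")
  if (!all(pd$species %in% c("human", "mouse")))
    msgs <- c(msgs, "species must be 'human' or 'mouse'")
  if (any(BiocGenerics::width(seqs) < 1L))
    msgs <- c(msgs, "all sequences must have length >= 1")
  ## one gene per protein is structural (one row per protein); check the
  ## alphabet via letter frequencies over the full AA alphabet
  af <- Biostrings::alphabetFrequency(seqs)
  bad <- setdiff(colnames(af), AA_ALPHABET)
  if (sum(af[, bad, drop = FALSE]) > 0)
    msgs <- c(msgs, paste0("illegal residue characters (allowed: 20 standard",
                           " amino acids plus X)"))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' MotifDefinition: a signaling-motif pattern
#'
#' A motif is an ordered list of elements, each either a residue class (a
#' non-empty set of standard amino acids, or the wildcard which matches any
#' residue including X) or a bounded spacer \code{x(min,max)}. Motifs are
#' matched only inside the compartment named by \code{compartment}
#' (cytoplasmic for all built-in signaling motifs).
#'
#' @slot name motif label, e.g. \code{"ITAM"}
#' @slot elements list of elements; see [parseMotif()] for the mini-language
#' @slot compartment topology segment kind the match must lie in
#' @seealso [parseMotif()], [defaultMotifs()], [scanMotifs()]
#' @exportClass MotifDefinition
setClass("MotifDefinition",
         representation(name = "character", elements = "list",
                        compartment = "character"))

setValidity("MotifDefinition", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (!object@compartment %in% TOPOLOGY_KINDS)
    return("compartment must be a topology segment kind")
  els <- object@elements
  if (!length(els)) return("motif needs at least one element")
  nclass <- 0L
  minlen <- 0L
  for (el in els) {
    if (identical(el$type, "class")) {
      nclass <- nclass + 1L
      minlen <- minlen + 1L
      if (!isTRUE(el$wildcard)) {
        if (!length(el$residues) || !all(el$residues %in% AA_STANDARD))
          return("residue classes must be non-empty subsets of the 20-letter alphabet")
      }
    } else if (identical(el$type, "spacer")) {
      if (el$min < 0 || el$max < el$min)
        return("spacer requires 0 <= min <= max")
      minlen <- minlen + el$min
    } else {
      return("elements must be residue classes or spacers")
    }
  }
  if (nclass < 1L) return("motif needs at least one residue-class element")
  if (minlen < 3L) return("total minimum match length must be >= 3")
  TRUE
})

#' FamilyCall: extracellular domain-family verdict for one protein
#'
#' @slot proteinId protein identifier
#' @slot familyClass one of \code{ig_like}, \code{clect}, \code{none}
#' @slot supportingHits data.frame of the domain hits supporting the call
#'   (empty when \code{familyClass == "none"}); carries a
#'   \code{family_class} column so support for both families is retained
#'   when both are present
#' @seealso [assignFamily()]
#' @exportClass FamilyCall
setClass("FamilyCall",
         representation(proteinId = "character", familyClass = "character",
                        supportingHits = "data.frame"))

setValidity("FamilyCall", function(object) {
  if (!object@familyClass %in% FAMILY_CLASSES)
    return("familyClass must be ig_like, clect or none")
  if (object@familyClass != "none" && nrow(object@supportingHits) == 0L)
    return("a family call other than 'none' needs supporting hits")
  if (object@familyClass == "none" && nrow(object@supportingHits) > 0L)
    return("familyClass 'none' must carry no supporting hits")
  TRUE
})

#' SignalingCall: signaling capability of one protein
#'
#' @slot proteinId protein identifier
#' @slot classes subset of \code{itam_activating}, \code{pi3k_activating},
#'   \code{itim_inhibitory}, \code{kinase}, \code{phosphatase}
#' @slot motifEvidence data.frame of supporting motif hits
#' @slot catalyticEvidence data.frame of supporting catalytic-domain hits
#' @seealso [classifySignaling()]
#' @exportClass SignalingCall
setClass("SignalingCall",
         representation(proteinId = "character", classes = "character",
                        motifEvidence = "data.frame",
                        catalyticEvidence = "data.frame"))

setValidity("SignalingCall", function(object) {
  if (!all(object@classes %in% SIGNALING_CLASSES))
    return("unknown signaling class")
  nev <- nrow(object@motifEvidence) + nrow(object@catalyticEvidence)
  if ((length(object@classes) > 0L) != (nev > 0L))
    return("classes must be non-empty iff evidence is non-empty")
  TRUE
})

#' CellExpression: a genes x samples expression matrix with a sample map
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: assay
#' \code{"exprs"} holds nonnegative expression values, \code{colData} has a
#' \code{cell_type} column mapping each sample to its cell type, and
#' \code{metadata} records \code{species} and \code{platform}.
#'
#' @seealso [readExpressionMatrix()], [aggregateCellTypes()]
#' @exportClass CellExpression
setClass("CellExpression", contains = "SummarizedExperiment")

setValidity("CellExpression", function(object) {
  v <- SummarizedExperiment::assay(object)
  if (!"cell_type" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must carry a cell_type column")
  ct <- SummarizedExperiment::colData(object)$cell_type
  if (any(is.na(ct)) || any(!nzchar(as.character(ct))))
    return("every sample must have a cell-type label")
  if (any(!is.finite(v)) || any(v < 0))
    return("expression values must be finite and >= 0")
  sp <- S4Vectors::metadata(object)$species
  if (is.null(sp) || !sp %in% c("human", "mouse"))
    return("metadata$species must be 'human' or 'mouse'")
  TRUE
})

#' CellTypeProfile: a genes x cell-types matrix after aggregation
#'
#' Extends \code{SummarizedExperiment}: one column per cell type (sorted by
#' label), assay \code{"exprs"}; \code{metadata} records \code{species} and
#' the aggregation \code{method} (\code{"max"} reproduces the
#' max-over-samples rule).
#'
#' @seealso [aggregateCellTypes()], [specificity()]
#' @exportClass CellTypeProfile
setClass("CellTypeProfile", contains = "SummarizedExperiment")

setValidity("CellTypeProfile", function(object) {
  v <- SummarizedExperiment::assay(object)
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("cell-type columns must be uniquely named")
  if (is.unsorted(colnames(v)))
    return("cell-type columns must be sorted by label")
  if (any(!is.finite(v)) || any(v < 0))
    return("profile values must be finite and >= 0")
  if (is.null(S4Vectors::metadata(object)$method))
    return("metadata$method must record the aggregation method")
  TRUE
})

#' SpecificityScore: average fold change of a gene versus other cell types
#'
#' The screen's specificity statistic for one gene: the mean, over the
#' comparison cell types, of \eqn{(E_{ref} + \epsilon)/(E_c + \epsilon)}
#' where \eqn{E} are aggregated cell-type expression values.
#'
#' @slot geneId gene identifier
#' @slot species \code{"human"} or \code{"mouse"}
#' @slot reference reference cell type (the mast-cell column, \code{"MC"})
#' @slot comparison comparison cell-type labels
#' @slot epsilon pseudocount added to numerator and denominator
#' @slot foldChanges named numeric, one fold change per comparison cell type
#' @slot score the average fold change
#' @seealso [specificity()]
#' @exportClass SpecificityScore
setClass("SpecificityScore",
         representation(geneId = "character", species = "character",
                        reference = "character", comparison = "character",
                        epsilon = "numeric", foldChanges = "numeric",
                        score = "numeric"))

setValidity("SpecificityScore", function(object) {
  if (object@epsilon < 0) return("epsilon must be >= 0")
  if (length(object@comparison) == 0L)
    return("comparison set must be non-empty")
  if (object@reference %in% object@comparison)
    return("reference cell type must not be in the comparison set")
  if (!identical(sort(names(object@foldChanges)), sort(object@comparison)))
    return("foldChanges must be named by the comparison cell types")
  TRUE
})

#' ScreenConfig: all inputs and tunables of the candidate screen
#'
#' @slot proteinsFile FASTA of proteins (header \code{protein|gene|species})
#' @slot domainsFile tab-separated domain-hit table
#' @slot topologyFile tab-separated topology table; \code{""} means predict
#'   topology from hydropathy for every protein
#' @slot humanExprFile,humanSampleMapFile human expression matrix + sample map
#' @slot mouseExprFile,mouseSampleMapFile mouse expression matrix + sample map
#' @slot orthologFile two-column human/mouse ortholog table
#' @slot motifFile YAML motif config; \code{""} means [defaultMotifs()]
#' @slot humanExpressedThreshold human MC expression must exceed this (strict)
#' @slot mouseAbundanceThreshold mouse MC max must exceed this (strict;
#'   default 100)
#' @slot referenceCellType reference cell-type label (default \code{"MC"})
#' @slot humanComparison,mouseComparison comparison cell-type sets
#' @slot igSet,clectSet domain-family labels counted as Ig-like / CLECT
#' @slot ptkSet,ptpSet domain-family labels counted as PTKc / PTPc
#' @slot minOverlap fraction of a domain-hit span that must lie in the
#'   required compartment (default 0.5)
#' @slot epsilon pseudocount for fold changes (default 1)
#' @slot combine \code{"geomean"} (default) or \code{"min"} of the two
#'   species' specificity scores
#' @slot window,hydroThreshold hydropathy window and cutoff for the fallback
#'   topology predictor
#' @slot seed random seed recorded in reports
#' @seealso [screenConfig()], [runScreen()]
#' @exportClass ScreenConfig
setClass("ScreenConfig",
         representation(proteinsFile = "character", domainsFile = "character",
                        topologyFile = "character",
                        humanExprFile = "character",
                        humanSampleMapFile = "character",
                        mouseExprFile = "character",
                        mouseSampleMapFile = "character",
                        orthologFile = "character", motifFile = "character",
                        humanExpressedThreshold = "numeric",
                        mouseAbundanceThreshold = "numeric",
                        referenceCellType = "character",
                        humanComparison = "character",
                        mouseComparison = "character",
                        igSet = "character", clectSet = "character",
                        ptkSet = "character", ptpSet = "character",
                        minOverlap = "numeric", epsilon = "numeric",
                        combine = "character", window = "integer",
                        hydroThreshold = "numeric", seed = "integer"))

setValidity("ScreenConfig", function(object) {
  msgs <- character(0)
  if (object@humanExpressedThreshold < 0 || object@mouseAbundanceThreshold < 0)
    msgs <- c(msgs, "thresholds must be >= 0")
  if (object@minOverlap < 0 || object@minOverlap > 1)
    msgs <- c(msgs, "minOverlap must be in [0, 1]")
  if (object@epsilon < 0) msgs <- c(msgs, "epsilon must be >= 0")
  if (!object@combine %in% c("geomean", "min"))
    msgs <- c(msgs, "combine must be 'geomean' or 'min'")
  if (length(intersect(object@igSet, object@clectSet)))
    msgs <- c(msgs, "igSet and clectSet must be disjoint")
  if (length(intersect(object@ptkSet, object@ptpSet)))
    msgs <- c(msgs, "ptkSet and ptpSet must be disjoint")
  if (object@referenceCellType %in% object@humanComparison ||
      object@referenceCellType %in% object@mouseComparison)
    msgs <- c(msgs, "reference cell type must not be in a comparison set")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ScreenResult: the outcome of a full candidate screen
#'
#' @slot candidates data.frame with one row per screened gene: stage flags,
#'   family and signaling calls, specificity scores, combined score and rank
#'   (rank only for genes passing all four stages)
#' @slot ranked the final ranked table (all-stage survivors only)
#' @slot stageCounts named integer vector of per-stage survivor counts
#' @slot config the \code{ScreenConfig} that produced the result
#' @seealso [runScreen()], [writeReport()]
#' @exportClass ScreenResult
setClass("ScreenResult",
         representation(candidates = "data.frame", ranked = "data.frame",
                        stageCounts = "integer", config = "ScreenConfig"))

#' SynthSpec: parameters of the synthetic fixture generator
#'
#' @slot nGenes total number of genes
#' @slot nTrueReceptors genes built to pass every funnel stage
#' @slot failExpressed,failFamily,failSignaling,failMouseAbundance genes
#'   built to fail exactly that one stage
#' @slot motifMix motif names cycled over the planted cytoplasmic motifs
#' @slot baselineRange range of per-gene baseline expression levels
#' @slot mcEnrichmentBase,mcEnrichmentStep geometric tiers of the MC
#'   enrichment factor given to the true receptors (receptor i gets
#'   base * step^(i-1); the highest tier defines the intended top rank)
#' @slot mouseBaselineHigh range of mouse baselines for genes that must pass
#'   the mouse abundance stage
#' @slot mouseAbundanceLow mouse MC mean for designated mouse-stage failures
#' @slot samplesPerCellTypeHuman,samplesPerCellTypeMouse replicates per
#'   cell type
#' @slot noiseSigma sdlog of the lognormal per-sample noise
#' @slot seed random seed; fixes every byte of the output
#' @seealso [synthSpec()], [generateFixture()]
#' @exportClass SynthSpec
setClass("SynthSpec",
         representation(nGenes = "integer", nTrueReceptors = "integer",
                        failExpressed = "integer", failFamily = "integer",
                        failSignaling = "integer",
                        failMouseAbundance = "integer",
                        motifMix = "character", baselineRange = "numeric",
                        mcEnrichmentBase = "numeric",
                        mcEnrichmentStep = "numeric",
                        mouseBaselineHigh = "numeric",
                        mouseAbundanceLow = "numeric",
                        samplesPerCellTypeHuman = "integer",
                        samplesPerCellTypeMouse = "integer",
                        noiseSigma = "numeric", seed = "integer"))

setValidity("SynthSpec", function(object) {
  counts <- c(object@nTrueReceptors, object@failExpressed, object@failFamily,
              object@failSignaling, object@failMouseAbundance)
  if (object@nGenes < 0L || any(counts < 0L))
    return("all counts must be >= 0")
  if (object@nTrueReceptors + sum(counts[-1]) > object@nGenes)
    return("true receptors plus failure quotas exceed nGenes")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (length(object@baselineRange) != 2L ||
      any(object@baselineRange <= 0) || diff(object@baselineRange) < 0)
    return("baselineRange must be an increasing positive pair")
  if (object@mcEnrichmentBase <= 0 || object@mcEnrichmentStep <= 0)
    return("enrichment tiers must be positive")
  TRUE
})

#' GroundTruth: manifest of a generated synthetic fixture
#'
#' @slot spec the \code{SynthSpec} that produced the fixture
#' @slot dir directory the fixture files were written to
#' @slot files named character vector of emitted file paths
#' @slot genes data.frame with one row per gene: role, intended stage flags,
#'   planted domain/motif coordinates and planted enrichment factors
#' @slot expectedEffect free-text note set by [perturbFixture()]
#' @seealso [generateFixture()], [perturbFixture()]
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(spec = "SynthSpec", dir = "character",
                        files = "character", genes = "data.frame",
                        expectedEffect = "character"))
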