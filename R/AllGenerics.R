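#' @include AllClasses.R
NULL

#' Accessors for screen objects
#'
#' Small accessor generics: \code{proteinIds} and \code{geneIds} return the
#' identifier columns of a \code{ProteinSet}; \code{cellTypes} lists the
#' cell-type labels of an expression container; \code{familyClass},
#' \code{signalingClasses} and \code{specScore} extract the verdict from the
#' corresponding call objects; \code{candidates}, \code{rankedCandidates}
#' and \code{stageCounts} unpack a \code{ScreenResult}; \code{truthGenes}
#' returns the per-gene manifest of a \code{GroundTruth}.
#'
#' @param x the object
#' @return the extracted component (see Details above)
#' @name accessors
#' @aliases proteinIds geneIds cellTypes familyClass signalingClasses
#'   specScore candidates rankedCandidates stageCounts truthGenes
#' @examples
#' ps <- ProteinSet(c(P1 = "MKVLY"), gene_id = "G1", species = "human")
#' proteinIds(ps)
#' geneIds(ps)
NULL

#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setGeneric("familyClass", function(x) standardGeneric("familyClass"))

#' @rdname accessors
#' @export
setGeneric("signalingClasses", function(x) standardGeneric("signalingClasses"))

#' @rdname accessors
#' @export
setGeneric("specScore", function(x) standardGeneric("specScore"))

#' @rdname accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname accessors
#' @export
setGeneric("rankedCandidates", function(x) standardGeneric("rankedCandidates"))

#' @rdname accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname accessors
#' @export
setGeneric("truthGenes", function(x) standardGeneric("truthGenes"))

#' @rdname accessors
setMethod("proteinIds", "ProteinSet",
          function(x) as.character(x@proteinData$protein_id))

#' @rdname accessors
setMethod("geneIds", "ProteinSet",
          function(x) as.character(x@proteinData$gene_id))

#' @rdname accessors
setMethod("cellTypes", "CellExpression", function(x)
  sort(unique(as.character(SummarizedExperiment::colData(x)$cell_type))))

#' @rdname accessors
setMethod("cellTypes", "CellTypeProfile",
          function(x) colnames(SummarizedExperiment::assay(x)))

#' @rdname accessors
setMethod("familyClass", "FamilyCall", function(x) x@familyClass)

#' @rdname accessors
setMethod("signalingClasses", "SignalingCall", function(x) x@classes)

#' @rdname accessors
setMethod("specScore", "SpecificityScore", function(x) x@score)

#' @rdname accessors
setMethod("candidates", "ScreenResult", function(x) x@candidates)

#' @rdname accessors
setMethod("rankedCandidates", "ScreenResult", function(x) x@ranked)

#' @rdname accessors
setMethod("stageCounts", "ScreenResult", function(x) x@stageCounts)

#' @rdname accessors
setMethod("truthGenes", "GroundTruth", function(x) x@genes)

#' @describeIn ProteinSet-class number of proteins
#' @param x a \code{ProteinSet}
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @describeIn ProteinSet-class subset by index or protein id
#' @param i index, logical vector or character vector of protein ids
#' @param j,drop,... ignored
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, proteinIds(x))
  new("ProteinSet", sequences = x@sequences[i],
      proteinData = x@proteinData[i, , drop = FALSE])
})

setMethod("show", "ProteinSet", function(object) {
  cat(sprintf("ProteinSet with %d protein(s), %d gene(s)\n",
              length(object), length(unique(geneIds(object)))))
  if (length(object)) {
    sp <- table(object@proteinData$species)
    cat("  species:", paste(sprintf("%s (%d)", names(sp), sp),
                            collapse = ", "), "\n")
  }
})

setMethod("show", "MotifDefinition", function(object) {
  cat(sprintf("MotifDefinition %s: %s [%s]\n", object@name,
              renderMotif(object), object@compartment))
})

setMethod("show", "FamilyCall", function(object) {
  cat(sprintf("FamilyCall %s: %s (%d supporting hit(s))\n", object@proteinId,
              object@familyClass, nrow(object@supportingHits)))
})

setMethod("show", "SignalingCall", function(object) {
  cls <- if (length(object@classes)) paste(object@classes, collapse = ", ")
         else "(none)"
  cat(sprintf("SignalingCall %s: %s\n", object@proteinId, cls))
})

setMethod("show", "SpecificityScore", function(object) {
  cat(sprintf("SpecificityScore %s [%s]: %s vs {%s}, epsilon = %g\n",
              object@geneId, object@species, object@reference,
              paste(object@comparison, collapse = ", "), object@epsilon))
  cat(sprintf("  average fold change = %.4g\n", object@score))
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult\n  funnel survivors:\n")
  for (nm in names(object@stageCounts))
    cat(sprintf("    %-22s %d\n", nm, object@stageCounts[[nm]]))
  cat(sprintf("  ranked candidates: %d\n", nrow(object@ranked)))
  if (nrow(object@ranked))
    cat("  top candidate:", object@ranked$gene_id[1L], "\n")
})

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf(paste0("SynthSpec: %d genes (%d true receptors; failures ",
                     "%d/%d/%d/%d by stage), seed %d\n"),
              object@nGenes, object@nTrueReceptors, object@failExpressed,
              object@failFamily, object@failSignaling,
              object@failMouseAbundance, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d genes in %s\n", nrow(object@genes),
              object@dir))
  cat("  roles:", paste(sprintf("%s (%d)", names(table(object@genes$role)),
                                table(object@genes$role)), collapse = ", "),
      "\n")
  if (length(object@expectedEffect))
    cat("  perturbation:", object@expectedEffect, "\n")
})
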