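#' @include AllClasses.R
NULL

#' Parse a motif pattern from the mini-language
#'
#' Patterns are read left to right: a single uppercase residue letter is a
#' singleton class; \code{[ILV]} is a residue class; \code{x} is the
#' wildcard (matches any residue, including the unknown residue \code{X});
#' \code{x(min,max)} is a bounded spacer matching between \code{min} and
#' \code{max} arbitrary residues. Example: the ITAM consensus
#' \code{"Yxx[LI]x(6,12)Yxx[LI]"}.
#'
#' @param text pattern string
#' @param name motif label (default the pattern itself)
#' @param compartment segment kind the match must lie in (default
#'   \code{"cytoplasmic"})
#' @return a [MotifDefinition-class]
#' @examples
#' parseMotif("Yxx[LI]x(6,12)Yxx[LI]", name = "ITAM")
#' @export
parseMotif <- function(text, name = text, compartment = "cytoplasmic") {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  els <- list()
  i <- 1L
  n <- length(chars)
  perr <- function(msg, col)
    stop(sprintf("motif parse error at column %d: %s", col, msg),
         call. = FALSE)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) perr("unbalanced '['", i)
      resid <- chars[(i + 1L):(j - 1L)][chars[(i + 1L):(j - 1L)] != ""]
      if (j == i + 1L) perr("empty residue class", i)
      if (!all(resid %in% AA_STANDARD))
        perr("residue class may contain only the 20 standard residues", i)
      els[[length(els) + 1L]] <- list(type = "class",
                                      residues = sort(unique(resid)),
                                      wildcard = FALSE)
      i <- j + 1L
    } else if (ch == "x") {
      if (i < n && chars[i + 1L] == "(") {
        j <- i + 2L
        while (j <= n && chars[j] != ")") j <- j + 1L
        if (j > n) perr("unbalanced '('", i + 1L)
        body <- paste(chars[(i + 2L):(j - 1L)], collapse = "")
        parts <- strsplit(body, ",", fixed = TRUE)[[1L]]
        lo <- suppressWarnings(as.integer(parts[1L]))
        hi <- suppressWarnings(as.integer(parts[2L]))
        if (length(parts) != 2L || is.na(lo) || is.na(hi))
          perr("spacer must be x(min,max) with integer bounds", i)
        if (lo < 0L || hi < lo) perr("spacer requires 0 <= min <= max", i)
        els[[length(els) + 1L]] <- list(type = "spacer", min = lo, max = hi)
        i <- j + 1L
      } else {
        els[[length(els) + 1L]] <- list(type = "class",
                                        residues = AA_STANDARD,
                                        wildcard = TRUE)
        i <- i + 1L
      }
    } else if (ch %in% AA_STANDARD) {
      els[[length(els) + 1L]] <- list(type = "class", residues = ch,
                                      wildcard = FALSE)
      i <- i + 1L
    } else {
      perr(sprintf("unexpected character '%s'", ch), i)
    }
  }
  new("MotifDefinition", name = name, elements = els,
      compartment = compartment)
}

#' Render a motif definition back to canonical pattern text
#'
#' Canonical form: singleton classes as bare letters, wider classes as
#' \code{[...]} with residues sorted, the wildcard as \code{x}, spacers as
#' \code{x(min,max)}. \code{parseMotif(renderMotif(m))} reproduces \code{m}.
#'
#' @param motif a [MotifDefinition-class]
#' @return pattern string
#' @export
renderMotif <- function(motif) {
  paste(vapply(motif@elements, function(el) {
    if (el$type == "spacer") return(sprintf("x(%d,%d)", el$min, el$max))
    if (isTRUE(el$wildcard)) return("x")
    if (length(el$residues) == 1L) return(el$residues)
    paste0("[", paste(sort(el$residues), collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' The built-in signaling-motif set
#'
#' Consensus definitions of the four cytoplasmic signaling motifs the screen
#' looks for: ITAM (twin YxxL/I half-sites, spacer 6-12), ITIM, an ITIM-like
#' relaxation, and the PI3K-binding YxxM. Override any of them via a motif
#' config file ([readMotifConfig()]).
#'
#' @return named list of [MotifDefinition-class] objects
#' @examples
#' names(defaultMotifs())
#' @export
defaultMotifs <- function() {
  pats <- c(ITAM = "Yxx[LI]x(6,12)Yxx[LI]",
            ITIM = "[ILSV]xYxx[LV]",
            ITIM_like = "[ILSTV]xYxx[ILV]",
            PI3K_binding = "YxxM")
  lapply(stats::setNames(names(pats), names(pats)),
         function(nm) parseMotif(pats[[nm]], name = nm))
}

#' Read a motif configuration file
#'
#' YAML mapping of motif name to pattern string in the [parseMotif()]
#' mini-language, e.g. \code{ITAM: "Yxx[LI]x(6,12)Yxx[LI]"}.
#'
#' @param path YAML file
#' @return named list of [MotifDefinition-class] objects
#' @export
readMotifConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  spec <- yaml::read_yaml(path)
  if (!length(spec) || is.null(names(spec)) || any(!nzchar(names(spec))))
    stop("motif config must map motif names to pattern strings")
  lapply(stats::setNames(names(spec), names(spec)),
         function(nm) parseMotif(as.character(spec[[nm]]), name = nm))
}

## All (start, end) spans where `motif` matches the character vector
## `chars`, every feasible spacer length instantiated. Vectorised over start
## positions for one spacer-length combination at a time. Returns a list of
## integer vectors (cheaper than a data.frame in the inner loop).
.matchSpans <- function(chars, motif) {
  els <- motif@elements
  spacers <- which(vapply(els, function(e) e$type == "spacer", logical(1)))
  combos <- if (length(spacers)) {
    as.matrix(do.call(expand.grid,
                      lapply(els[spacers], function(e) e$min:e$max)))
  } else matrix(0L, 1L, 0L)
  n <- length(chars)
  base_lens <- rep(1L, length(els))
  out_s <- integer(0)
  out_e <- integer(0)
  for (ci in seq_len(nrow(combos))) {
    lens <- base_lens
    lens[spacers] <- as.integer(combos[ci, ])
    total <- sum(lens)
    if (total > n) next
    offs <- cumsum(c(0L, lens[-length(lens)]))
    starts <- seq_len(n - total + 1L)
    ok <- rep(TRUE, length(starts))
    for (k in seq_along(els)) {
      el <- els[[k]]
      if (el$type != "class" || isTRUE(el$wildcard)) next
      ok <- ok & chars[starts + offs[k]] %in% el$residues
      if (!any(ok)) break
    }
    if (any(ok)) {
      out_s <- c(out_s, starts[ok])
      out_e <- c(out_e, starts[ok] + total - 1L)
    }
  }
  keep <- !duplicated(out_s * (n + 1L) + out_e)
  list(start = out_s[keep], end = out_e[keep])
}

## scan one sequence (as a character string) against motifs, restricted to
## compartment segments given as a data.frame; shared by scanMotifs and
## scanMotifSet so the S4 surface carries no per-protein overhead
.scanOne <- function(pid, seq, seg, motifs) {
  out_s <- integer(0)
  out_e <- integer(0)
  out_m <- character(0)
  for (motif in motifs) {
    comp <- seg[seg$kind == motif@compartment, , drop = FALSE]
    for (si in seq_len(nrow(comp))) {
      sub <- substr(seq, comp$start[si], comp$end[si])
      chars <- strsplit(sub, "", fixed = TRUE)[[1L]]
      spans <- .matchSpans(chars, motif)
      if (length(spans$start)) {
        out_s <- c(out_s, spans$start + comp$start[si] - 1L)
        out_e <- c(out_e, spans$end + comp$start[si] - 1L)
        out_m <- c(out_m, rep(motif@name, length(spans$start)))
      }
    }
  }
  if (!length(out_s))
    return(data.frame(protein_id = character(0), motif_name = character(0),
                      start = integer(0), end = integer(0),
                      matched_sequence = character(0)))
  hits <- data.frame(protein_id = pid, motif_name = out_m, start = out_s,
                     end = out_e,
                     matched_sequence = substring(seq, out_s, out_e),
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$start, hits$end, hits$motif_name), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a protein's compartments for signaling motifs
#'
#' Reports every distinct (motif, start, end) span that matches inside a
#' segment of the motif's compartment (cytoplasmic for all built-in
#' motifs). Every feasible spacer length is instantiated, so overlapping
#' matches and multiple spacer widths all appear. The unknown residue
#' \code{X} matches only the wildcard.
#'
#' @param protein a length-1 [ProteinSet-class]
#' @param topology data.frame of this protein's topology segments
#' @param motifs list of [MotifDefinition-class] (default [defaultMotifs()])
#' @return data.frame with columns \code{protein_id}, \code{motif_name},
#'   \code{start}, \code{end}, \code{matched_sequence}, sorted by
#'   (start, end, motif_name); zero rows when the protein has no segment of
#'   the required compartment
#' @examples
#' ps <- ProteinSet(c(P1 = paste0(strrep("L", 21), "GGYINMGG")),
#'                  gene_id = "G1", species = "human")
#' topo <- data.frame(protein_id = "P1",
#'                    kind = c("transmembrane", "cytoplasmic"),
#'                    start = c(1L, 22L), end = c(21L, 29L))
#' scanMotifs(ps, topo)
#' @export
scanMotifs <- function(protein, topology, motifs = defaultMotifs()) {
  stopifnot(is(protein, "ProteinSet"), length(protein) == 1L)
  pid <- proteinIds(protein)
  seq <- proteinSequence(protein, pid)
  seg <- topology[topology$protein_id == pid, , drop = FALSE]
  .scanOne(pid, seq, seg, motifs)
}

#' Scan every protein of a set for signaling motifs
#'
#' Batch companion of [scanMotifs()]: identical matching semantics, one
#' combined hit table for all proteins.
#'
#' @param proteins a [ProteinSet-class]
#' @param topology data.frame of topology segments covering the proteins
#' @param motifs list of [MotifDefinition-class] (default [defaultMotifs()])
#' @return data.frame as in [scanMotifs()], proteins in set order
#' @export
scanMotifSet <- function(proteins, topology, motifs = defaultMotifs()) {
  stopifnot(is(proteins, "ProteinSet"))
  ids <- proteinIds(proteins)
  seqs <- as.character(proteins@sequences)
  seg_split <- split(topology, topology$protein_id)
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    seg <- seg_split[[ids[i]]]
    if (is.null(seg)) next
    res[[i]] <- .scanOne(ids[i], seqs[i], seg, motifs)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(protein_id = character(0), motif_name = character(0),
                      start = integer(0), end = integer(0),
                      matched_sequence = character(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write motif hits as a tab-separated table
#'
#' @param hits data.frame as from [scanMotifs()]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeMotifHits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Detect cytoplasmic catalytic domains (PTKc / PTPc)
#'
#' Returns the domain hits whose family label is in either catalytic set
#' and whose span lies at least \code{minOverlap}-inside cytoplasmic
#' segments (same overlap rule as [assignFamily()]).
#'
#' @param hits data.frame of domain hits (one protein)
#' @param topology data.frame of that protein's topology segments
#' @param ptkSet,ptpSet kinase/phosphatase family labels (defaults
#'   [defaultPtkSet()], [defaultPtpSet()]); must be disjoint
#' @param minOverlap minimum cytoplasmic overlap fraction (default 0.5)
#' @return subset of \code{hits} with an added \code{catalytic_class} column
#'   (\code{"kinase"} or \code{"phosphatase"})
#' @export
detectCatalytic <- function(hits, topology, ptkSet = defaultPtkSet(),
                            ptpSet = defaultPtpSet(), minOverlap = 0.5) {
  if (length(intersect(ptkSet, ptpSet)))
    stop("ptkSet and ptpSet must be disjoint")
  if (!nrow(hits)) {
    out <- hits
    out$catalytic_class <- character(0)
    return(out)
  }
  keep <- hits$family %in% c(ptkSet, ptpSet)
  out <- hits[keep, , drop = FALSE]
  if (nrow(out)) {
    frac <- .compartmentOverlap(out$start, out$end, topology, "cytoplasmic")
    out <- out[frac >= minOverlap, , drop = FALSE]
  }
  out$catalytic_class <- ifelse(out$family %in% ptkSet, "kinase",
                                "phosphatase")
  rownames(out) <- NULL
  out
}

#' Classify a protein's signaling capability
#'
#' Assembles signaling classes from the evidence: an ITAM hit gives
#' \code{itam_activating}, a PI3K-binding hit \code{pi3k_activating}, an
#' ITIM or ITIM-like hit \code{itim_inhibitory}, a cytoplasmic PTKc domain
#' \code{kinase} and a PTPc domain \code{phosphatase}. A protein passes the
#' screen's signaling filter iff the class set is non-empty.
#'
#' @param motifHits data.frame as from [scanMotifs()] (one protein)
#' @param catalytic data.frame as from [detectCatalytic()] (same protein)
#' @param protein_id id to use when both evidence tables are empty
#' @return a [SignalingCall-class]
#' @export
classifySignaling <- function(motifHits, catalytic,
                              protein_id = "protein") {
  ids <- unique(c(motifHits$protein_id, catalytic$protein_id))
  if (length(ids) > 1L)
    stop("evidence mixes protein ids: ", paste(ids, collapse = ", "))
  if (length(ids) == 1L) protein_id <- ids
  ## only motifs with a known class mapping count as evidence
  known <- c("ITAM", "ITIM", "ITIM_like", "PI3K_binding")
  motifHits <- motifHits[motifHits$motif_name %in% known, , drop = FALSE]
  cls <- character(0)
  if (any(motifHits$motif_name == "ITAM")) cls <- c(cls, "itam_activating")
  if (any(motifHits$motif_name == "PI3K_binding"))
    cls <- c(cls, "pi3k_activating")
  if (any(motifHits$motif_name %in% c("ITIM", "ITIM_like")))
    cls <- c(cls, "itim_inhibitory")
  if (nrow(catalytic)) cls <- unique(c(cls, catalytic$catalytic_class))
  new("SignalingCall", proteinId = protein_id, classes = cls,
      motifEvidence = motifHits, catalyticEvidence = catalytic)
}
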