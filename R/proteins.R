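#' @include AllClasses.R
NULL

#' Construct a ProteinSet from character sequences
#'
#' @param sequences named character vector (or \code{AAStringSet}) of
#'   amino-acid sequences; names are the protein ids unless
#'   \code{protein_id} is given
#' @param gene_id gene identifier per protein (recycled if length 1)
#' @param species \code{"human"} or \code{"mouse"} per protein (recycled)
#' @param protein_id protein identifiers; defaults to \code{names(sequences)}
#' @return a validated [ProteinSet-class]
#' @examples
#' ProteinSet(c(P1 = "MKVLYSTQ", P2 = "MATT"),
#'            gene_id = c("G1", "G2"), species = "human")
#' @export
ProteinSet <- function(sequences, gene_id, species, protein_id = NULL) {
  if (is.null(protein_id)) protein_id <- names(sequences)
  if (is.null(protein_id))
    stop("protein ids are required (names of 'sequences' or 'protein_id')")
  n <- length(sequences)
  gene_id <- rep_len(as.character(gene_id), n)
  species <- rep_len(as.character(species), n)
  .checkResidues(as.character(sequences), protein_id)
  seqs <- Biostrings::AAStringSet(as.character(sequences))
  names(seqs) <- protein_id
  new("ProteinSet", sequences = seqs,
      proteinData = S4Vectors::DataFrame(protein_id = as.character(protein_id),
                                         gene_id = gene_id,
                                         species = species))
}

## report the first illegal residue with its entry and 1-based position
.checkResidues <- function(seqs, ids) {
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  hit <- which(bad > 0L)
  if (length(hit)) {
    i <- hit[1L]
    stop(sprintf(
      "illegal residue '%s' in entry '%s' at position %d (allowed: %s)",
      substr(seqs[i], bad[i], bad[i]), ids[i], bad[i],
      paste(AA_ALPHABET, collapse = "")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read proteins from a FASTA file
#'
#' Headers must follow the convention \code{>protein_id|gene_id|species}
#' (species \code{human} or \code{mouse}); sequences use the 20 standard
#' residues plus \code{X}.
#'
#' @param path FASTA file
#' @return a [ProteinSet-class]; entry order is preserved
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1|G1|human", "MKVLY", ">P2|G2|human", "MATTX"), fa)
#' readProteins(fa)
#' @export
readProteins <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(ProteinSet(Biostrings::AAStringSet(), character(0), character(0),
                      protein_id = character(0)))
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- strsplit(names(seqs), "|", fixed = TRUE)
  nf <- lengths(hdr)
  if (any(nf != 3L))
    stop(sprintf("malformed FASTA header '%s': expected 'protein_id|gene_id|species'",
                 names(seqs)[which(nf != 3L)[1L]]), call. = FALSE)
  hdr <- do.call(rbind, hdr)
  bad_sp <- which(!hdr[, 3L] %in% c("human", "mouse"))
  if (length(bad_sp))
    stop(sprintf("entry '%s': species must be 'human' or 'mouse'",
                 names(seqs)[bad_sp[1L]]), call. = FALSE)
  ProteinSet(as.character(seqs), gene_id = hdr[, 2L], species = hdr[, 3L],
             protein_id = hdr[, 1L])
}

#' Write proteins to a FASTA file
#'
#' Inverse of [readProteins()]: headers are \code{protein_id|gene_id|species}.
#'
#' @param x a [ProteinSet-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeProteins <- function(x, path) {
  stopifnot(is(x, "ProteinSet"))
  seqs <- x@sequences
  names(seqs) <- paste(x@proteinData$protein_id, x@proteinData$gene_id,
                       x@proteinData$species, sep = "|")
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Extract one protein's sequence as a character string
#'
#' @param x a [ProteinSet-class]
#' @param protein_id the protein to extract
#' @return single character string
#' @export
proteinSequence <- function(x, protein_id) {
  i <- match(protein_id, proteinIds(x))
  if (is.na(i)) stop("unknown protein_id: ", protein_id)
  as.character(x@sequences[[i]])
}
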