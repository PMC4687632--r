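#' @include AllClasses.R
NULL

## Kyte-Doolittle hydropathy scale; X (unknown) is scored neutral.
KD_SCALE <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
              L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
              X =  0.0)

#' Default domain-family label sets
#'
#' Membership sets for the two extracellular receptor families the screen
#' keeps (Ig-like superfamily and C-type lectin-like), and for the
#' cytoplasmic catalytic domains (protein tyrosine kinase / phosphatase).
#' All four are conventions over CDD-style family labels and can be
#' overridden wherever they are used.
#'
#' @return character vector of family labels
#' @examples
#' defaultIgSet()
#' @export
defaultIgSet <- function()
  c("IG", "IG_like", "IGc1", "IGc2", "IGv", "V-set", "C1-set", "C2-set",
    "I-set")

#' @rdname defaultIgSet
#' @export
defaultClectSet <- function() c("CLECT", "C-type lectin-like")

#' @rdname defaultIgSet
#' @export
defaultPtkSet <- function() c("PTKc")

#' @rdname defaultIgSet
#' @export
defaultPtpSet <- function() c("PTPc")

.readTsv <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  miss <- setdiff(required, colnames(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df[required]
}

#' Read a domain-hit table
#'
#' Tab-separated with a header row and columns \code{protein_id},
#' \code{family}, \code{start}, \code{end}, \code{evalue} (CDD-style hits;
#' coordinates 1-based inclusive).
#'
#' @param path tab-separated file
#' @param proteins optional [ProteinSet-class]; when given, hits are checked
#'   against the known proteins and their sequence lengths
#' @return data.frame of hits
#' @export
readDomainHits <- function(path, proteins = NULL) {
  df <- .readTsv(path, c("protein_id", "family", "start", "end", "evalue"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$evalue <- as.numeric(df$evalue)
  validateDomainHits(df, proteins)
  df
}

#' Validate a domain-hit table
#'
#' Checks the coordinate invariant (1 <= start <= end, and end within the
#' protein when a protein set is supplied) and nonnegative e-values.
#'
#' @param hits data.frame as from [readDomainHits()]
#' @param proteins optional [ProteinSet-class]
#' @return the hits, invisibly; errors on violation
#' @export
validateDomainHits <- function(hits, proteins = NULL) {
  if (nrow(hits) == 0L) return(invisible(hits))
  bad <- which(is.na(hits$start) | is.na(hits$end) | hits$start < 1L |
               hits$start > hits$end)
  if (length(bad))
    stop(sprintf("domain hit %d (%s): requires 1 <= start <= end", bad[1L],
                 hits$protein_id[bad[1L]]), call. = FALSE)
  if (any(is.na(hits$evalue) | hits$evalue < 0))
    stop("domain-hit e-values must be >= 0", call. = FALSE)
  if (!is.null(proteins)) {
    idx <- match(hits$protein_id, proteinIds(proteins))
    if (anyNA(idx))
      stop("domain hit references unknown protein_id: ",
           hits$protein_id[which(is.na(idx))[1L]], call. = FALSE)
    len <- BiocGenerics::width(proteins@sequences)[idx]
    over <- which(hits$end > len)
    if (length(over))
      stop(sprintf("domain hit on %s ends at %d beyond sequence length %d",
                   hits$protein_id[over[1L]], hits$end[over[1L]],
                   len[over[1L]]), call. = FALSE)
  }
  invisible(hits)
}

#' Read a membrane-topology table
#'
#' Tab-separated with columns \code{protein_id}, \code{kind} (one of
#' \code{extracellular}, \code{transmembrane}, \code{cytoplasmic}),
#' \code{start}, \code{end}. Segments of one protein must tile its sequence
#' without gaps or overlaps.
#'
#' @param path tab-separated file
#' @param proteins optional [ProteinSet-class] used to verify that segments
#'   cover each annotated protein exactly
#' @return data.frame of segments
#' @export
readTopology <- function(path, proteins = NULL) {
  df <- .readTsv(path, c("protein_id", "kind", "start", "end"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nrow(df) && !all(df$kind %in% TOPOLOGY_KINDS))
    stop("topology kind must be one of ",
         paste(TOPOLOGY_KINDS, collapse = ", "), call. = FALSE)
  if (!is.null(proteins)) {
    for (pid in unique(df$protein_id)) {
      if (!pid %in% proteinIds(proteins))
        stop("topology references unknown protein_id: ", pid, call. = FALSE)
      validateTopology(df[df$protein_id == pid, , drop = FALSE],
                       nchar(proteinSequence(proteins, pid)))
    }
  }
  df
}

#' Check that topology segments partition a sequence
#'
#' @param segments data.frame of one protein's segments
#' @param seqLength the protein length
#' @return the segments sorted by start, invisibly; errors if the segments
#'   do not tile \code{[1, seqLength]} exactly
#' @export
validateTopology <- function(segments, seqLength) {
  seg <- segments[order(segments$start), , drop = FALSE]
  ok <- nrow(seg) > 0L && seg$start[1L] == 1L &&
    seg$end[nrow(seg)] == seqLength &&
    all(seg$start <= seg$end) &&
    (nrow(seg) == 1L || all(seg$start[-1L] == seg$end[-nrow(seg)] + 1L))
  if (!ok)
    stop(sprintf("topology for %s does not partition [1, %d]",
                 seg$protein_id[1L], seqLength), call. = FALSE)
  invisible(seg)
}

#' Windowed Kyte-Doolittle hydropathy
#'
#' Mean hydropathy over a sliding window, reported at window centers.
#'
#' @param sequence amino-acid string
#' @param window odd window size >= 5
#' @return numeric vector named by center position (positions
#'   \code{(window+1)/2 .. length-(window-1)/2})
#' @export
hydropathyProfile <- function(sequence, window = 19L) {
  if (window %% 2L == 0L || window < 5L) stop("window must be odd and >= 5")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  h <- unname(KD_SCALE[chars])
  if (anyNA(h)) stop("sequence contains residues outside the alphabet")
  n <- length(h)
  if (n < window)
    stop("sequence shorter than the hydropathy window; supply an explicit ",
         "topology table for this protein", call. = FALSE)
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  names(means) <- seq((window + 1L) / 2L, n - (window - 1L) / 2L)
  means
}

#' Predict single-pass membrane topology from hydropathy
#'
#' Fallback predictor used when no explicit topology table covers a protein.
#' It computes the windowed Kyte-Doolittle profile, takes maximal runs of
#' window centers above \code{threshold}, merges runs separated by at most
#' \code{mergeGap} centers, and keeps candidates whose span falls in (or is
#' trimmed into) the plausible transmembrane length band \code{tmBand}
#' (spans longer than the band are trimmed symmetrically about their
#' midpoint; shorter ones are discarded). Assuming a single-pass type-I
#' architecture, the strongest surviving candidate (highest peak window
#' mean) becomes the transmembrane segment, the N-terminal flank is labelled
#' extracellular and the C-terminal flank cytoplasmic. With no candidate the
#' whole protein is labelled extracellular.
#'
#' @param protein a [ProteinSet-class] row (length-1 set), or a character
#'   sequence together with \code{protein_id}
#' @param window odd hydropathy window (default 19)
#' @param threshold mean-hydropathy cutoff (default 1.6)
#' @param tmBand allowed transmembrane span length range (default 15..30)
#' @param mergeGap merge above-threshold runs separated by at most this many
#'   centers (default 3)
#' @param protein_id id used when \code{protein} is a bare sequence
#' @return data.frame with columns \code{protein_id}, \code{kind},
#'   \code{start}, \code{end}; segments tile the sequence
#' @examples
#' seq <- paste0(strrep("SD", 10), strrep("I", 23), strrep("SD", 10))
#' predictTopology(seq, protein_id = "P1")
#' @export
predictTopology <- function(protein, window = 19L, threshold = 1.6,
                            tmBand = c(15L, 30L), mergeGap = 3L,
                            protein_id = "protein") {
  if (is(protein, "ProteinSet")) {
    stopifnot(length(protein) == 1L)
    protein_id <- proteinIds(protein)
    protein <- as.character(protein@sequences[[1L]])
  }
  n <- nchar(protein)
  means <- hydropathyProfile(protein, window)
  centers <- as.integer(names(means))
  above <- means > threshold

  runs <- .runsOfTrue(above, mergeGap)
  cand <- list()
  for (r in runs) {
    s <- centers[r[1L]]
    e <- centers[r[2L]]
    wdt <- e - s + 1L
    if (wdt > tmBand[2L]) {        # trim symmetrically about the midpoint
      mid <- (s + e) / 2
      s <- as.integer(ceiling(mid - tmBand[2L] / 2 + 0.5))
      e <- s + tmBand[2L] - 1L
      wdt <- tmBand[2L]
    }
    if (wdt >= tmBand[1L])
      cand[[length(cand) + 1L]] <-
        list(start = s, end = e,
             peak = max(means[centers >= s & centers <= e]))
  }

  if (!length(cand)) {
    return(data.frame(protein_id = protein_id, kind = "extracellular",
                      start = 1L, end = n, stringsAsFactors = FALSE))
  }
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "peak"))]]
  seg <- data.frame(protein_id = character(0), kind = character(0),
                    start = integer(0), end = integer(0))
  if (best$start > 1L)
    seg <- rbind(seg, data.frame(protein_id = protein_id,
                                 kind = "extracellular", start = 1L,
                                 end = best$start - 1L))
  seg <- rbind(seg, data.frame(protein_id = protein_id,
                               kind = "transmembrane", start = best$start,
                               end = best$end))
  if (best$end < n)
    seg <- rbind(seg, data.frame(protein_id = protein_id,
                                 kind = "cytoplasmic", start = best$end + 1L,
                                 end = n))
  rownames(seg) <- NULL
  seg
}

## maximal TRUE runs in a logical vector, merging gaps of <= mergeGap FALSEs;
## returns list of c(first_index, last_index)
.runsOfTrue <- function(x, mergeGap) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(c, starts[r$values], ends[r$values])
  if (length(runs) < 2L) return(runs)
  merged <- list(runs[[1L]])
  for (i in 2L:length(runs)) {
    last <- merged[[length(merged)]]
    if (runs[[i]][1L] - last[2L] - 1L <= mergeGap)
      merged[[length(merged)]] <- c(last[1L], runs[[i]][2L])
    else merged[[length(merged) + 1L]] <- runs[[i]]
  }
  merged
}

#' Topology for every protein: table where available, prediction otherwise
#'
#' Explicit topology-table annotation takes precedence; proteins absent from
#' the table fall back to [predictTopology()]. All returned per-protein
#' segment sets are checked to partition the sequence.
#'
#' @param proteins a [ProteinSet-class]
#' @param topology optional data.frame as from [readTopology()]
#' @param ... passed to [predictTopology()]
#' @return data.frame of segments covering every protein
#' @export
topologyFor <- function(proteins, topology = NULL, ...) {
  if (length(proteins) == 0L)
    return(data.frame(protein_id = character(0), kind = character(0),
                      start = integer(0), end = integer(0)))
  out <- vector("list", length(proteins))
  ids <- proteinIds(proteins)
  for (i in seq_along(ids)) {
    pid <- ids[i]
    n <- nchar(proteinSequence(proteins, pid))
    if (!is.null(topology) && any(topology$protein_id == pid)) {
      seg <- topology[topology$protein_id == pid, , drop = FALSE]
      seg <- as.data.frame(validateTopology(seg, n))
    } else {
      seg <- predictTopology(proteins[i], ...)
      validateTopology(seg, n)
    }
    out[[i]] <- seg[c("protein_id", "kind", "start", "end")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## fraction of [start, end] covered by the given segments of one kind
.compartmentOverlap <- function(start, end, segments, kind) {
  seg <- segments[segments$kind == kind, , drop = FALSE]
  if (!nrow(seg)) return(rep(0, length(start)))
  q <- IRanges::IRanges(start = start, end = end)
  s <- IRanges::reduce(IRanges::IRanges(start = seg$start, end = seg$end))
  ov <- IRanges::findOverlaps(q, s)
  inter <- IRanges::pintersect(q[S4Vectors::queryHits(ov)],
                               s[S4Vectors::subjectHits(ov)])
  cov <- numeric(length(q))
  w <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
  cov[as.integer(names(w))] <- as.numeric(w)
  cov / IRanges::width(q)
}

#' Classify a protein's extracellular domain family
#'
#' A domain hit supports the Ig-like (resp. CLECT) family when its label is
#' in \code{igSet} (resp. \code{clectSet}) and at least \code{minOverlap} of
#' its span lies within extracellular segments. The call is \code{ig_like}
#' if any Ig-like support exists, else \code{clect} if any CLECT support
#' exists, else \code{none}; when both families are supported, both support
#' sets are recorded and the reported class is the family of the hit with
#' the smallest e-value (ties resolve to \code{ig_like}).
#'
#' @param protein a length-1 [ProteinSet-class]
#' @param hits data.frame of domain hits for this protein
#' @param topology data.frame of this protein's topology segments
#' @param igSet,clectSet family label sets (defaults [defaultIgSet()],
#'   [defaultClectSet()]); must be disjoint
#' @param minOverlap minimum fraction of the hit span inside extracellular
#'   segments (default 0.5)
#' @return a [FamilyCall-class]
#' @export
assignFamily <- function(protein, hits, topology, igSet = defaultIgSet(),
                         clectSet = defaultClectSet(), minOverlap = 0.5) {
  stopifnot(is(protein, "ProteinSet"), length(protein) == 1L)
  if (length(intersect(igSet, clectSet)))
    stop("igSet and clectSet must be disjoint")
  pid <- proteinIds(protein)
  if (nrow(hits) && !all(hits$protein_id == pid))
    stop("domain hits reference a different protein than ", pid)
  seg <- topology[topology$protein_id == pid, , drop = FALSE]
  .familyCallCore(pid, hits, seg, igSet, clectSet, minOverlap)
}

## family-call work-horse on plain tables; `seg` holds this protein's
## segments only
.familyCallCore <- function(pid, hits, seg, igSet, clectSet, minOverlap) {
  empty <- hits[0, , drop = FALSE]
  if (!nrow(hits))
    return(new("FamilyCall", proteinId = pid, familyClass = "none",
               supportingHits = as.data.frame(empty)))

  frac <- .compartmentOverlap(hits$start, hits$end, seg, "extracellular")
  ecto <- frac >= minOverlap
  sup_ig <- hits[ecto & hits$family %in% igSet, , drop = FALSE]
  sup_cl <- hits[ecto & hits$family %in% clectSet, , drop = FALSE]
  if (nrow(sup_ig)) sup_ig$family_class <- "ig_like"
  if (nrow(sup_cl)) sup_cl$family_class <- "clect"
  sup <- rbind(if (nrow(sup_ig)) sup_ig, if (nrow(sup_cl)) sup_cl)

  if (is.null(sup) || !nrow(sup)) {
    cls <- "none"
    sup <- as.data.frame(empty)
  } else if (nrow(sup_ig) && nrow(sup_cl)) {
    ## both families supported: report the smaller-e-value family
    cls <- if (min(sup_cl$evalue) < min(sup_ig$evalue)) "clect" else "ig_like"
  } else {
    cls <- if (nrow(sup_ig)) "ig_like" else "clect"
  }
  rownames(sup) <- NULL
  new("FamilyCall", proteinId = pid, familyClass = cls, supportingHits = sup)
}
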