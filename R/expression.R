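#' @include AllClasses.R
NULL

#' Construct a CellExpression container
#'
#' @param values genes x samples numeric matrix (rownames = gene ids,
#'   colnames = sample ids)
#' @param sampleMap data.frame with columns \code{sample}, \code{cell_type}
#'   covering every column of \code{values}
#' @param species \code{"human"} or \code{"mouse"}
#' @param platform free-text tag, e.g. \code{"rna_seq"} or
#'   \code{"microarray"}
#' @return a [CellExpression-class]
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' sm <- data.frame(sample = c("s1", "s2", "s3"),
#'                  cell_type = c("MC", "MC", "T"))
#' CellExpression(m, sm, species = "human", platform = "rna_seq")
#' @export
CellExpression <- function(values, sampleMap, species,
                           platform = "rna_seq") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  idx <- match(colnames(values), sampleMap$sample)
  if (anyNA(idx))
    stop("samples without a cell-type label: ",
         paste(colnames(values)[is.na(idx)], collapse = ", "))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(
      cell_type = as.character(sampleMap$cell_type[idx]),
      row.names = colnames(values)),
    metadata = list(species = species, platform = platform))
  new("CellExpression", se)
}

#' Read an expression matrix with its sample map
#'
#' The matrix is tab-separated, genes in rows (first column \code{gene_id}),
#' samples in the remaining columns. The sample map is a two-column
#' tab-separated table (\code{sample}, \code{cell_type}).
#'
#' @param path expression matrix file
#' @param sampleMapPath sample-map file
#' @param species \code{"human"} or \code{"mouse"}
#' @param platform free-text tag (default \code{"rna_seq"})
#' @return a [CellExpression-class]
#' @export
readExpressionMatrix <- function(path, sampleMapPath, species,
                                 platform = "rna_seq") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1L] != "gene_id")
    stop(path, ": first column must be 'gene_id'")
  if (anyDuplicated(df$gene_id))
    stop(path, ": duplicated gene_id values")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  sm <- .readTsv(sampleMapPath, c("sample", "cell_type"))
  CellExpression(m, sm, species = species, platform = platform)
}

#' Aggregate samples into per-cell-type expression
#'
#' Collapses a genes x samples matrix to genes x cell types. The default
#' aggregation is the maximum over each cell type's samples, reproducing
#' the rule defining a cell type's expression as the largest value among
#' its replicates; \code{"mean"} and \code{"median"} are available but
#' non-default. Columns of the profile are sorted by cell-type label.
#' Aggregating an already aggregated profile is the identity (each cell
#' type is its own single sample).
#'
#' @param x a [CellExpression-class] or [CellTypeProfile-class]
#' @param method \code{"max"} (default), \code{"mean"} or \code{"median"}
#' @return a [CellTypeProfile-class]
#' @examples
#' m <- matrix(c(10, 250, 37, 5, 8, 2), 1,
#'             dimnames = list("g1", paste0("s", 1:6)))
#' sm <- data.frame(sample = paste0("s", 1:6),
#'                  cell_type = c("MC", "MC", "MC", "T", "T", "T"))
#' ce <- CellExpression(m, sm, species = "mouse", platform = "microarray")
#' SummarizedExperiment::assay(aggregateCellTypes(ce))
#' @export
aggregateCellTypes <- function(x, method = c("max", "mean", "median")) {
  method <- match.arg(method)
  v <- SummarizedExperiment::assay(x)
  ct <- if (is(x, "CellTypeProfile")) colnames(v)
        else as.character(SummarizedExperiment::colData(x)$cell_type)
  labels <- sort(unique(ct))
  if (!length(labels)) stop("no cell types to aggregate")
  fun <- switch(method, max = function(m) do.call(pmax, as.data.frame(m)),
                mean = rowMeans,
                median = function(m) apply(m, 1L, stats::median))
  agg <- vapply(labels, function(lab) {
    cols <- which(ct == lab)
    if (!length(cols)) stop("cell type with zero samples: ", lab)
    fun(v[, cols, drop = FALSE])
  }, numeric(nrow(v)))
  agg <- matrix(agg, nrow = nrow(v),
                dimnames = list(rownames(v), labels))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = agg),
    metadata = list(species = S4Vectors::metadata(x)$species,
                    platform = S4Vectors::metadata(x)$platform,
                    method = method))
  new("CellTypeProfile", se)
}

#' Filter genes by expression in one cell type
#'
#' Returns the genes whose aggregated value in \code{cellType} exceeds
#' \code{threshold}. The default is a strict inequality, matching the
#' "more than" reading of the abundance rule, so a gene sitting exactly on
#' the threshold is excluded.
#'
#' @param profile a [CellTypeProfile-class]
#' @param cellType cell-type label
#' @param threshold expression cutoff
#' @param strict use \code{>} (default) rather than \code{>=}
#' @return character vector of gene ids
#' @export
filterExpressed <- function(profile, cellType, threshold, strict = TRUE) {
  v <- SummarizedExperiment::assay(profile)
  if (!cellType %in% colnames(v))
    stop("unknown cell type: ", cellType)
  vals <- v[, cellType]
  keep <- if (strict) vals > threshold else vals >= threshold
  rownames(v)[keep]
}

#' Default comparison cell-type sets
#'
#' The cell types a mast-cell profile is compared against: for human,
#' T cells, B cells and monocytes; for mouse, additionally NK cells,
#' dendritic cells and macrophages (the six non-MC panels of the
#' cross-cell-type comparison).
#'
#' @param species \code{"human"} or \code{"mouse"}
#' @return character vector of cell-type labels
#' @export
defaultComparisonSet <- function(species = c("human", "mouse")) {
  switch(match.arg(species),
         human = c("T", "B", "Mos"),
         mouse = c("T", "B", "Mos", "NK", "DCs", "MPs"))
}

#' Expression specificity of one gene: average fold change versus other
#' cell types
#'
#' The specificity of a gene for the reference cell type is the mean, over
#' the comparison cell types, of the fold change
#' \eqn{(E_{ref} + \epsilon)/(E_c + \epsilon)}, where \eqn{E} is the
#' aggregated per-cell-type expression. With \eqn{\epsilon = 0} the score
#' is scale-invariant; a positive \eqn{\epsilon} keeps it defined when a
#' comparison cell type has zero expression.
#'
#' @param profile a [CellTypeProfile-class]
#' @param gene gene id (must be a profile row)
#' @param reference reference cell type (default \code{"MC"})
#' @param comparison comparison cell types (default
#'   [defaultComparisonSet()] for the profile's species)
#' @param epsilon pseudocount, >= 0 (default 0); must be positive when any
#'   comparison value is zero
#' @return a [SpecificityScore-class]
#' @examples
#' m <- matrix(c(400, 100, 200, 50), 1,
#'             dimnames = list("g1", c("MC", "T", "B", "Mos")))
#' sm <- data.frame(sample = colnames(m), cell_type = colnames(m))
#' pr <- aggregateCellTypes(CellExpression(m, sm, species = "human"))
#' specScore(specificity(pr, "g1"))  # (4 + 2 + 8) / 3
#' @export
specificity <- function(profile, gene, reference = "MC",
                        comparison = NULL, epsilon = 0) {
  species <- S4Vectors::metadata(profile)$species
  if (is.null(comparison)) comparison <- defaultComparisonSet(species)
  v <- SummarizedExperiment::assay(profile)
  if (!gene %in% rownames(v)) stop("unknown gene: ", gene)
  missing_ct <- setdiff(c(reference, comparison), colnames(v))
  if (length(missing_ct))
    stop("cell type(s) not in profile: ", paste(missing_ct, collapse = ", "))
  if (reference %in% comparison)
    stop("reference cell type must not be in the comparison set")
  if (epsilon < 0) stop("epsilon must be >= 0")
  eref <- v[gene, reference]
  ec <- v[gene, comparison]
  if (epsilon == 0 && any(ec == 0))
    stop("zero expression in a comparison cell type; use a positive epsilon")
  fc <- (eref + epsilon) / (ec + epsilon)
  names(fc) <- comparison
  new("SpecificityScore", geneId = gene,
      species = if (is.null(species)) NA_character_ else species,
      reference = reference, comparison = comparison, epsilon = epsilon,
      foldChanges = fc, score = mean(fc))
}

#' Specificity scores for many genes at once
#'
#' Vectorised companion of [specificity()]: one row per gene with the fold
#' change against every comparison cell type (columns \code{FC_<cell>}),
#' their average (\code{avg_fc}, the specificity score) and an optional
#' \code{log2_avg_fc} companion column.
#'
#' @inheritParams specificity
#' @param genes gene ids (default all profile rows)
#' @param log2 add a log2-transformed column (default FALSE)
#' @return data.frame, one row per gene
#' @export
specificityTable <- function(profile, genes = NULL, reference = "MC",
                             comparison = NULL, epsilon = 0,
                             log2 = FALSE) {
  v <- SummarizedExperiment::assay(profile)
  if (is.null(genes)) genes <- rownames(v)
  species <- S4Vectors::metadata(profile)$species
  if (is.null(comparison)) comparison <- defaultComparisonSet(species)
  if (reference %in% comparison)
    stop("reference cell type must not be in the comparison set")
  missing_ct <- setdiff(c(reference, comparison), colnames(v))
  if (length(missing_ct))
    stop("cell type(s) not in profile: ", paste(missing_ct, collapse = ", "))
  if (epsilon == 0 && any(v[genes, comparison] == 0))
    stop("zero expression in a comparison cell type; use a positive epsilon")
  fc <- matrix(v[genes, reference] + epsilon, nrow = length(genes),
               ncol = length(comparison)) /
    (v[genes, comparison, drop = FALSE] + epsilon)
  colnames(fc) <- paste0("FC_", comparison)
  out <- data.frame(gene_id = genes, fc, avg_fc = rowMeans(fc),
                    row.names = NULL, check.names = FALSE)
  if (log2) out$log2_avg_fc <- log2(out$avg_fc)
  out
}

#' Read a human/mouse ortholog map
#'
#' Two-column tab-separated table (\code{human_gene}, \code{mouse_gene}).
#'
#' @param path file path
#' @return data.frame with the two columns
#' @export
readOrthologMap <- function(path) {
  .readTsv(path, c("human_gene", "mouse_gene"))
}

#' Map genes through an ortholog table
#'
#' @param genes gene ids in the source species
#' @param map data.frame as from [readOrthologMap()]
#' @param direction \code{"human_to_mouse"} (default) or
#'   \code{"mouse_to_human"}
#' @return list with \code{pairs} (data.frame \code{from}, \code{to}) and
#'   \code{unmapped} (character vector); errors if a queried gene has
#'   conflicting duplicate mappings
#' @export
mapOrthologs <- function(genes, map,
                         direction = c("human_to_mouse",
                                       "mouse_to_human")) {
  direction <- match.arg(direction)
  from_col <- if (direction == "human_to_mouse") "human_gene" else "mouse_gene"
  to_col <- if (direction == "human_to_mouse") "mouse_gene" else "human_gene"
  sub <- unique(map[map[[from_col]] %in% genes, c(from_col, to_col)])
  dup <- unique(sub[[from_col]][duplicated(sub[[from_col]])])
  if (length(dup))
    stop("conflicting duplicate ortholog mappings for: ",
         paste(dup, collapse = ", "))
  dup_to <- unique(sub[[to_col]][duplicated(sub[[to_col]])])
  if (length(dup_to))
    stop("ortholog map not one-to-one on the screened set; targets mapped ",
         "more than once: ", paste(dup_to, collapse = ", "))
  idx <- match(genes, sub[[from_col]])
  mapped <- !is.na(idx)
  list(pairs = data.frame(from = genes[mapped],
                          to = sub[[to_col]][idx[mapped]],
                          stringsAsFactors = FALSE),
       unmapped = genes[!mapped])
}
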