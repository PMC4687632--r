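## Independent oracles and small fixture builders used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Kyte-Doolittle values restated independently of the package source.
ORACLE_KD <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9,
               A = 1.8, G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3,
               P = -1.6, H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5,
               K = -3.9, R = -4.5, X = 0)

## windowed mean hydropathy by direct per-window averaging
oracle_hydropathy <- function(seq, window = 19L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  vals <- ORACLE_KD[chars]
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(length(vals) - half)
  out <- vapply(centers, function(c) mean(vals[(c - half):(c + half)]),
                numeric(1))
  names(out) <- centers
  out
}

## brute-force motif matcher: explicit recursion over positions and spacer
## lengths, character-by-character comparison
oracle_scan_loop <- function(chars, motif) {
  els <- motif@elements
  n <- length(chars)
  res_s <- integer(0)
  res_e <- integer(0)
  rec <- function(pos, k, start) {
    if (k > length(els)) {
      res_s <<- c(res_s, start)
      res_e <<- c(res_e, pos - 1L)
      return(invisible())
    }
    el <- els[[k]]
    if (el$type == "class") {
      if (pos <= n &&
          (isTRUE(el$wildcard) || chars[pos] %in% el$residues))
        rec(pos + 1L, k + 1L, start)
    } else {
      for (len in el$min:el$max)
        if (pos + len <= n + 1L) rec(pos + len, k + 1L, start)
    }
  }
  for (s in seq_len(n)) rec(s, 1L, s)
  unique(data.frame(start = res_s, end = res_e))
}

## exhaustive matcher on a different engine: instantiate every spacer-length
## combination as a PCRE pattern and collect all overlapping starts via a
## zero-width lookahead
oracle_scan_regex <- function(seq, motif) {
  els <- motif@elements
  spacer_i <- which(vapply(els, function(e) e$type == "spacer", logical(1)))
  combos <- if (length(spacer_i))
    do.call(expand.grid, lapply(els[spacer_i], function(e) e$min:e$max))
  else data.frame(row.names = 1L)
  res_s <- integer(0)
  res_e <- integer(0)
  for (ci in seq_len(nrow(combos))) {
    body <- ""
    total <- 0L
    si <- 0L
    for (el in els) {
      if (el$type == "spacer") {
        si <- si + 1L
        len <- as.integer(combos[ci, si])
        body <- paste0(body, sprintf(".{%d}", len))
        total <- total + len
      } else if (isTRUE(el$wildcard)) {
        body <- paste0(body, ".")
        total <- total + 1L
      } else {
        body <- paste0(body, "[", paste(el$residues, collapse = ""), "]")
        total <- total + 1L
      }
    }
    m <- gregexpr(paste0("(?=", body, ")"), seq, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      res_s <- c(res_s, as.integer(m))
      res_e <- c(res_e, as.integer(m) + total - 1L)
    }
  }
  unique(data.frame(start = res_s, end = res_e))
}

sort_spans <- function(df) {
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

rand_seq <- function(n, alphabet = AA20, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

## random motif grammar: random residue classes, wildcards and spacers,
## always valid (>= 1 class, min length >= 3)
rand_motif <- function() {
  repeat {
    k <- sample(3:7, 1L)
    els <- lapply(seq_len(k), function(j) {
      kind <- sample(c("class", "wild", "spacer"), 1L,
                     prob = c(0.5, 0.3, 0.2))
      if (kind == "spacer") {
        lo <- sample(0:3, 1L)
        list(type = "spacer", min = lo, max = lo + sample(0:3, 1L))
      } else if (kind == "wild") {
        list(type = "class", residues = AA20, wildcard = TRUE)
      } else {
        list(type = "class",
             residues = sort(sample(AA20, sample(1:4, 1L))),
             wildcard = FALSE)
      }
    })
    nclass <- sum(vapply(els, function(e) e$type == "class", logical(1)))
    minlen <- sum(vapply(els, function(e)
      if (e$type == "class") 1L else e$min, integer(1)))
    if (nclass >= 1L && minlen >= 3L)
      return(new("MotifDefinition", name = "RAND", elements = els,
                 compartment = "cytoplasmic"))
  }
}

## a one-protein set with an all-cytoplasmic topology, for scanner tests
cyto_protein <- function(seq, pid = "P1") {
  ps <- ProteinSet(stats::setNames(seq, pid), gene_id = "G1",
                   species = "human")
  topo <- data.frame(protein_id = pid, kind = "cytoplasmic", start = 1L,
                     end = nchar(seq))
  list(protein = ps, topology = topo)
}

## tiny aggregated profile from named per-cell-type values for one gene
profile_of <- function(values, gene = "g1", species = "human") {
  m <- matrix(values, 1, dimnames = list(gene, names(values)))
  sm <- data.frame(sample = names(values), cell_type = names(values))
  aggregateCellTypes(CellExpression(m, sm, species = species))
}
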