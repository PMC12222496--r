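#' Parse a DepMap-style gene column header
#'
#' DepMap matrices label gene columns as `"SYMBOL (EntrezID)"`. A bare
#' symbol without the parenthesised id is also accepted.
#'
#' @param text Character vector of headers.
#' @return A data.frame with columns `symbol` (character) and `entrez`
#'   (integer, `NA` when absent), one row per input header.
#' @examples
#' parse_gene_header(c("CDS1 (1040)", "EPCAM"))
#' @export
parse_gene_header <- function(text) {
  if (length(text) == 0L || any(is.na(text)) || any(!nzchar(trimws(text)))) {
    stop("gene headers must be non-empty strings")
  }
  text <- trimws(text)
  m <- regmatches(text, regexec("^(.*?)\\s*\\((\\d+)\\)$", text))
  symbol <- character(length(text))
  entrez <- rep(NA_integer_, length(text))
  for (i in seq_along(text)) {
    if (length(m[[i]]) == 3L) {
      symbol[i] <- m[[i]][2L]
      entrez[i] <- as.integer(m[[i]][3L])
    } else {
      symbol[i] <- text[i]
    }
  }
  if (any(!nzchar(symbol))) {
    stop("gene header with empty symbol part: ",
         paste(text[!nzchar(symbol)], collapse = ", "))
  }
  data.frame(symbol = symbol, entrez = entrez, stringsAsFactors = FALSE)
}

new_omics_matrix <- function(values, genes, kind) {
  stopifnot(is.matrix(values), nrow(genes) == ncol(values))
  colnames(values) <- genes$symbol
  structure(list(values = values, genes = genes, kind = kind),
            class = "OmicsMatrix")
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix (%s): %d cell lines x %d genes\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

#' Read a DepMap-dialect omics matrix
#'
#' Expects a CSV whose first column holds cell-line ids (e.g. ACH-000001)
#' and whose remaining headers parse via [parse_gene_header()]. Empty cells
#' are kept as missing values, never silently zeroed. Duplicate gene
#' symbols are mean-summarized into a single column (the convention used
#' for repeatedly profiled genes in methylation/proteomics matrices).
#'
#' @param path Path to the CSV file.
#' @param kind One of `"expression"`, `"effect"`, `"generic"`.
#' @return An `OmicsMatrix`: list with `values` (cell lines x genes, row
#'   names = cell-line ids), `genes` (symbol/entrez table), `kind`.
#' @export
read_omics_matrix <- function(path, kind = c("expression", "effect", "generic")) {
  kind <- match.arg(kind)
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L) stop("matrix file needs a cell-line column and at least one gene column")
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate cell-line ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  values <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  genes <- parse_gene_header(colnames(dt)[-1L])
  if (anyDuplicated(genes$symbol)) {
    dup <- unique(genes$symbol[duplicated(genes$symbol)])
    warning("duplicate gene columns mean-summarized: ", paste(dup, collapse = ", "))
    keep <- !duplicated(genes$symbol)
    merged <- vapply(genes$symbol[keep], function(s) {
      rowMeans(values[, genes$symbol == s, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(values)))
    merged[is.nan(merged)] <- NA_real_
    values <- matrix(merged, nrow = nrow(values),
                     dimnames = list(NULL, genes$symbol[keep]))
    genes <- genes[keep, , drop = FALSE]
    rownames(genes) <- NULL
  }
  rownames(values) <- ids
  new_omics_matrix(values, genes, kind)
}

#' Harmonize an expression / effect matrix pair
#'
#' Applies the standard preprocessing before any association is computed:
#' expression genes with mean below `min_mean_expression` are removed
#' (genes at exactly the threshold are retained); missing effect scores
#' are imputed as that gene's mean over non-missing cell lines; both
#' matrices are restricted to their shared cell lines, sorted
#' lexicographically by id so downstream results do not depend on input
#' file order; and effect genes are restricted to the surviving
#' expression gene set.
#'
#' @param expr,eff `OmicsMatrix` objects (expression and gene effect).
#' @param min_mean_expression Mean log2(TPM+1) below which an expression
#'   gene is dropped. Default 1.
#' @return A list with elements `expr` and `eff`, harmonized.
#' @export
preprocess_pair <- function(expr, eff, min_mean_expression = 1.0) {
  stopifnot(inherits(expr, "OmicsMatrix"), inherits(eff, "OmicsMatrix"))
  keep_expr <- colMeans(expr$values, na.rm = TRUE) >= min_mean_expression
  expr_vals <- expr$values[, keep_expr, drop = FALSE]
  expr_genes <- expr$genes[keep_expr, , drop = FALSE]

  eff_vals <- eff$values
  all_missing <- colSums(!is.na(eff_vals)) == 0L
  if (any(all_missing)) {
    warning("effect genes entirely missing dropped: ",
            paste(colnames(eff_vals)[all_missing], collapse = ", "))
    eff_vals <- eff_vals[, !all_missing, drop = FALSE]
    eff$genes <- eff$genes[!all_missing, , drop = FALSE]
  }
  if (anyNA(eff_vals)) {
    gm <- colMeans(eff_vals, na.rm = TRUE)
    idx <- which(is.na(eff_vals), arr.ind = TRUE)
    eff_vals[idx] <- gm[idx[, 2L]]
  }

  shared <- sort(intersect(rownames(expr_vals), rownames(eff_vals)))
  if (length(shared) == 0L) stop("no shared cell lines between expression and effect matrices")
  expr_vals <- expr_vals[shared, , drop = FALSE]
  eff_vals <- eff_vals[shared, , drop = FALSE]

  keep_eff <- colnames(eff_vals) %in% colnames(expr_vals)
  eff_vals <- eff_vals[, keep_eff, drop = FALSE]
  eff_genes <- eff$genes[keep_eff, , drop = FALSE]
  rownames(expr_genes) <- rownames(eff_genes) <- NULL

  list(expr = new_omics_matrix(expr_vals, expr_genes, expr$kind),
       eff = new_omics_matrix(eff_vals, eff_genes, eff$kind))
}

#' Read a gene annotation table
#'
#' TSV with columns `gene`, `chromosome`, `arm`, `start`, `end`
#' (1-based inclusive coordinates). The genomic position of a gene is
#' approximated as the midpoint of start and end. Records with
#' non-numeric or inverted coordinates are rejected with a warning;
#' a missing arm becomes `"unknown"`.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns gene, chromosome, arm, start_bp,
#'   end_bp, midpoint_bp.
#' @export
read_gene_annotation <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                          colClasses = "character")
  need <- c("gene", "chromosome", "arm", "start", "end")
  if (!all(need %in% colnames(dt))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  start <- suppressWarnings(as.numeric(dt$start))
  end <- suppressWarnings(as.numeric(dt$end))
  bad <- is.na(start) | is.na(end) | start > end | start <= 0
  if (any(bad)) {
    warning(sum(bad), " annotation record(s) rejected (non-numeric or inverted coordinates)")
  }
  arm <- dt$arm
  arm[is.na(arm) | !nzchar(arm)] <- "unknown"
  out <- data.frame(gene = dt$gene, chromosome = dt$chromosome, arm = arm,
                    start_bp = start, end_bp = end,
                    midpoint_bp = (start + end) / 2,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonicalize unordered gene pairs
#'
#' @param a,b Character vectors of gene symbols.
#' @return Character vector of `"min|max"` keys.
#' @keywords internal
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Read a reference gene-pair set
#'
#' TSV with columns `gene_a`, `gene_b` and optionally `identity`
#' (fractional sequence identity). Pairs are stored unordered in
#' canonical lexicographic order, once each. When an identity column is
#' present, pairs below `min_identity` are excluded (the convention for
#' paralog lists, where a 20% floor is standard). Self-pairs are dropped
#' with a warning.
#'
#' @param path Path to the TSV.
#' @param source_label Label recorded with the set.
#' @param min_identity Minimum sequence identity in `[0,1]`; applied only
#'   when the file carries an identity column. Default 0.2.
#' @return A `PairSet`: data.frame with columns gene_a, gene_b (canonical
#'   order), attribute `source_label`.
#' @export
read_pair_set <- function(path, source_label, min_identity = 0.2) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  if (!all(c("gene_a", "gene_b") %in% colnames(dt))) {
    stop("pair set must have columns gene_a, gene_b")
  }
  if ("identity" %in% colnames(dt)) {
    dt <- dt[!is.na(dt$identity) & dt$identity >= min_identity, , drop = FALSE]
  }
  make_pair_set(dt$gene_a, dt$gene_b, source_label)
}

#' Build a pair set from two symbol vectors
#' @param gene_a,gene_b Character vectors.
#' @param source_label Label recorded with the set.
#' @param allow_self Keep self-pairs instead of dropping them.
#' @return A `PairSet` data.frame.
#' @export
make_pair_set <- function(gene_a, gene_b, source_label = "custom", allow_self = FALSE) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  self <- gene_a == gene_b
  if (any(self) && !allow_self) {
    warning(sum(self), " self-pair(s) dropped from ", source_label)
    gene_a <- gene_a[!self]; gene_b <- gene_b[!self]
  }
  a <- pmin(gene_a, gene_b); b <- pmax(gene_a, gene_b)
  keep <- !duplicated(paste(a, b, sep = "|"))
  out <- data.frame(gene_a = a[keep], gene_b = b[keep], stringsAsFactors = FALSE)
  attr(out, "source_label") <- source_label
  class(out) <- c("PairSet", "data.frame")
  out
}

#' Write ranked buffering predictions to TSV
#'
#' Columns: rank, buffering_gene, buffered_gene, score, original_pcc,
#' z_pcc, flags (semicolon-joined tokens), label. Round-trips losslessly
#' through [read_predictions()].
#'
#' @param path Output path.
#' @param preds A `RankedPredictions` data.frame.
#' @export
write_predictions <- function(path, preds) {
  out <- data.frame(rank = preds$rank,
                    buffering_gene = preds$buffering_gene,
                    buffered_gene = preds$buffered_gene,
                    score = preds$score,
                    original_pcc = preds$original_r,
                    z_pcc = preds$z,
                    flags = preds$flags,
                    label = preds$label,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ranked buffering predictions written by [write_predictions()]
#' @param path Path to the TSV.
#' @return A `RankedPredictions` data.frame.
#' @export
read_predictions <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                          colClasses = list(character = c("buffering_gene", "buffered_gene",
                                                          "flags", "label")))
  if (nrow(dt) == 0L) {
    return(new_ranked_predictions(
      data.frame(rank = integer(), buffering_gene = character(),
                 buffered_gene = character(), score = numeric(),
                 original_r = numeric(), z = numeric(),
                 flags = character(), label = character(),
                 stringsAsFactors = FALSE)))
  }
  flags <- dt$flags; flags[is.na(flags)] <- ""
  new_ranked_predictions(
    data.frame(rank = as.integer(dt$rank),
               buffering_gene = dt$buffering_gene,
               buffered_gene = dt$buffered_gene,
               score = dt$score, original_r = dt$original_pcc,
               z = dt$z_pcc, flags = flags, label = dt$label,
               stringsAsFactors = FALSE))
}

new_ranked_predictions <- function(df) {
  class(df) <- c("RankedPredictions", "data.frame")
  df
}

#' Persist an association matrix as text with gene-list sidecars
#'
#' Writes `<path>` (TSV numeric matrix), `<path>.rows` and `<path>.cols`
#' (gene lists). [read_association()] restores the object.
#' @param A An `AssociationMatrix`.
#' @param path Base output path.
#' @export
write_association <- function(A, path) {
  utils::write.table(unclass_assoc(A), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  writeLines(rownames(A), paste0(path, ".rows"))
  writeLines(colnames(A), paste0(path, ".cols"))
  writeLines(attr(A, "method"), paste0(path, ".method"))
  invisible(path)
}

#' @rdname write_association
#' @export
read_association <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  rn <- readLines(paste0(path, ".rows"))
  cn <- readLines(paste0(path, ".cols"))
  dimnames(vals) <- list(rn, cn)
  new_association_matrix(vals, readLines(paste0(path, ".method")))
}

unclass_assoc <- function(A) {
  a <- A; attributes(a) <- list(dim = dim(A), dimnames = dimnames(A)); a
}
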