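# Build an OmicsMatrix from a plain matrix (dimnames = cell lines / genes)
omat <- function(values, kind = "generic") {
  genes <- data.frame(symbol = colnames(values), entrez = NA_integer_,
                      stringsAsFactors = FALSE)
  baconet:::new_omics_matrix(values, genes, kind)
}

# A tiny harmonized expression/effect pair with known structure
tiny_pair <- function(n_cells = 30, seed = 11) {
  baconet:::with_seed(seed, {
    cells <- sprintf("SYN-%03d", seq_len(n_cells))
    expr <- matrix(rnorm(n_cells * 4, mean = 5), n_cells, 4,
                   dimnames = list(cells, paste0("G", 1:4)))
    eff <- matrix(rnorm(n_cells * 3, mean = -0.3, sd = 0.3), n_cells, 3,
                  dimnames = list(cells, paste0("G", 1:3)))
    eff[, 1] <- 2 - 0.5 * expr[, 2] + rnorm(n_cells, sd = 0.05)  # G2 buffers G1
    list(expr = omat(expr, "expression"), eff = omat(eff, "effect"))
  })
}

write_depmap_csv <- function(values, path, entrez = seq_len(ncol(values))) {
  hdr <- sprintf("%s (%d)", colnames(values), entrez)
  lines <- c(paste(c("", hdr), collapse = ","),
             vapply(seq_len(nrow(values)), function(i) {
               paste(c(rownames(values)[i],
                       ifelse(is.na(values[i, ]), "", format(values[i, ], digits = 10))),
                     collapse = ",")
             }, ""))
  writeLines(lines, path)
  path
}

ranked_preds <- function(buffering, buffered, score = NULL,
                         original_r = NULL, z = NULL, label = "unlabeled") {
  n <- length(buffering)
  baconet:::new_ranked_predictions(data.frame(
    rank = seq_len(n), buffering_gene = buffering, buffered_gene = buffered,
    score = score %||% rev(seq_len(n)) / n,
    original_r = original_r %||% rev(seq_len(n)) / n,
    z = z %||% rep(4, n), flags = character(n), label = rep_len(label, n),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_assoc <- function(n, m, seed) {
  baconet:::with_seed(seed, {
    matrix(runif(n * m, -1, 1), n, m,
           dimnames = list(paste0("r", seq_len(n)), paste0("c", seq_len(m))))
  })
}
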