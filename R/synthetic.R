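#' Default planted buffering pairs
#'
#' Twenty pairs, distinct buffering and buffered genes, random loss cells
#' (30% of the panel) and a Chronos drop of 1.0 — the magnitude of a
#' clear buffering relationship on DepMap scales.
#' @param n Number of pairs.
#' @return data.frame with columns buffering, buffered, loss_fraction,
#'   effect_size, lineage (NA = random loss cells).
#' @export
default_planted_pairs <- function(n = 20) {
  data.frame(buffering = sprintf("G%04d", 100 + seq_len(n)),
             buffered = sprintf("G%04d", seq_len(n)),
             loss_fraction = rep(0.3, n), effect_size = rep(1.0, n),
             lineage = rep(NA_character_, n), stringsAsFactors = FALSE)
}

#' Configuration for the synthetic expression/effect test bed
#'
#' Emulates the structure of paired DepMap-style matrices at desk scale:
#' cell lines with lineage labels, log2(TPM+1)-scale expression with
#' Gaussian noise truncated at zero, Chronos-scale fitness effects,
#' planted buffering pairs (expression loss in a subset of cells drives
#' the buffered gene's effect more negative there), optional lineage
#' co-expression confounder modules, and a small genome for uniform gene
#' placement.
#'
#' A planted pair may be tied to a lineage: its buffering gene is then
#' expressed only in that lineage (loss cells = all other cells, and the
#' gene's baseline mean is raised to keep it above the expression
#' filter), which is what lets a lineage co-expression module mimic the
#' pair's signal — the tissue-driven false-positive mechanism.
#'
#' @param n_cells Number of cell lines. Default 500.
#' @param lineages data.frame with columns label, proportion (sums to 1).
#' @param n_expr_genes,n_eff_genes Gene universe sizes; effect genes are
#'   the first `n_eff_genes` expression gene symbols (effect genes are a
#'   subset of expression genes, as after real preprocessing).
#' @param planted_pairs data.frame as from [default_planted_pairs()].
#' @param confounder_modules List of confounder modules; see
#'   [confounder_module()].
#' @param noise_sd_expr,noise_sd_eff Gaussian noise SDs. Defaults 1.0
#'   (log2 TPM units) and 0.2 (Chronos units).
#' @param expr_mean_range Range of per-gene baseline expression means.
#' @param eff_mean_center,eff_mean_sd Distribution of per-gene baseline
#'   Chronos means.
#' @param loss_residual Multiplicative residual expression in loss cells
#'   (near-zero rather than exactly 0 so correlations stay defined).
#' @param genome data.frame with columns chromosome, length_bp.
#' @param proximity_pairs Optional data.frame (gene_a, gene_b,
#'   distance_bp) of pairs to place deliberately close on one arm.
#' @return A validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_cells = 500,
                             lineages = data.frame(
                               label = paste0("lineage_", LETTERS[1:4]),
                               proportion = 0.25),
                             n_expr_genes = 300, n_eff_genes = 300,
                             planted_pairs = default_planted_pairs(),
                             confounder_modules = list(),
                             noise_sd_expr = 1.0, noise_sd_eff = 0.2,
                             expr_mean_range = c(2, 8),
                             eff_mean_center = -0.2, eff_mean_sd = 0.3,
                             loss_residual = 0.05,
                             genome = data.frame(
                               chromosome = paste0("chr", 1:5),
                               length_bp = 2e8),
                             proximity_pairs = NULL) {
  if (abs(sum(lineages$proportion) - 1) > 1e-8) stop("lineage proportions must sum to 1")
  if (n_eff_genes > n_expr_genes) stop("effect genes are a subset of expression genes")
  genes <- sprintf("G%04d", seq_len(n_expr_genes))
  eff_genes <- genes[seq_len(n_eff_genes)]
  if (nrow(planted_pairs) > 0) {
    if (!all(planted_pairs$buffering %in% genes)) stop("planted buffering gene outside expression universe")
    if (!all(planted_pairs$buffered %in% eff_genes)) stop("planted buffered gene outside effect universe")
    if (any(planted_pairs$loss_fraction <= 0 | planted_pairs$loss_fraction >= 1)) {
      stop("loss_fraction must lie strictly between 0 and 1")
    }
    if (any(planted_pairs$effect_size <= 0)) stop("effect_size must be positive")
    bad_lin <- !is.na(planted_pairs$lineage) &
      !(planted_pairs$lineage %in% lineages$label)
    if (any(bad_lin)) stop("planted pair tied to unknown lineage")
  }
  for (mod in confounder_modules) {
    if (!mod$lineage %in% lineages$label) stop("confounder module tied to unknown lineage")
  }
  structure(list(n_cells = n_cells, lineages = lineages,
                 n_expr_genes = n_expr_genes, n_eff_genes = n_eff_genes,
                 genes = genes, eff_genes = eff_genes,
                 planted_pairs = planted_pairs,
                 confounder_modules = confounder_modules,
                 noise_sd_expr = noise_sd_expr, noise_sd_eff = noise_sd_eff,
                 expr_mean_range = expr_mean_range,
                 eff_mean_center = eff_mean_center, eff_mean_sd = eff_mean_sd,
                 loss_residual = loss_residual, genome = genome,
                 proximity_pairs = proximity_pairs),
            class = "SyntheticConfig")
}

#' A lineage co-expression confounder module
#'
#' A block of genes whose expression is shifted upward in one lineage
#' (creating tissue-driven co-expression) together with a block of
#' effect genes whose Chronos scores shift in that lineage
#' (lineage-specific essentialities). When tied via `linked_pairs` to
#' planted pairs that are themselves lineage-restricted, the module
#' genes correlate with those pairs' buffered genes without any
#' buffering relation — the canonical false-positive structure.
#'
#' @param genes Module expression gene symbols.
#' @param lineage Lineage label driving the module.
#' @param expr_shift Expression shift (log2 TPM units) in that lineage.
#' @param eff_genes Effect genes with lineage-specific essentiality.
#' @param eff_shift Chronos shift for `eff_genes` in that lineage.
#' @param linked_pairs Integer indices of planted pairs restricted to
#'   this module's lineage.
#' @return A module list for [synthetic_config()].
#' @export
confounder_module <- function(genes, lineage, expr_shift = 3,
                              eff_genes = character(), eff_shift = -0.5,
                              linked_pairs = integer()) {
  list(genes = genes, lineage = lineage, expr_shift = expr_shift,
       eff_genes = eff_genes, eff_shift = eff_shift,
       linked_pairs = as.integer(linked_pairs))
}

#' The confounded study configuration
#'
#' The default configuration plus one 30-gene co-expression module in
#' lineage A (+3 log2 TPM), 30 lineage-responsive effect genes (-0.5
#' Chronos in lineage A), with the first planted pair restricted to
#' lineage A so the module mimics its buffering signal.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `SyntheticConfig`.
#' @export
confounded_synthetic_config <- function(...) {
  planted <- default_planted_pairs()
  planted$lineage[1L] <- "lineage_A"
  mod <- confounder_module(genes = sprintf("G%04d", 230 + 1:30),
                           lineage = "lineage_A", expr_shift = 3,
                           eff_genes = sprintf("G%04d", 30 + 1:30),
                           eff_shift = -0.5, linked_pairs = 1L)
  synthetic_config(planted_pairs = planted, confounder_modules = list(mod), ...)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a paired synthetic expression/effect dataset
#'
#' Draws the full test bed described by a [synthetic_config()] from a
#' seeded generator: identical seeds give bit-identical outputs.
#'
#' @param cfg A `SyntheticConfig`.
#' @param seed Integer seed for all randomness.
#' @return List with elements `expr`, `eff` (`OmicsMatrix`), `meta`
#'   (cell-line metadata), `ann` (gene annotation), and `truth`
#'   (list: `planted` pairs, `confounder_fp` pairs, `annotation`).
#' @export
generate_dataset <- function(cfg, seed) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  with_seed(seed, {
    n <- cfg$n_cells
    cells <- sprintf("SYN-%06d", seq_len(n))
    counts <- floor(cfg$lineages$proportion * n)
    counts[length(counts)] <- n - sum(counts[-length(counts)])
    lineage <- rep(cfg$lineages$label, times = counts)
    growth <- sample(c("adherent", "suspension"), n, replace = TRUE,
                     prob = c(0.7, 0.3))
    meta <- data.frame(cell_line_id = cells, lineage = lineage,
                       growth_pattern = growth, stringsAsFactors = FALSE)

    genes <- cfg$genes
    ann <- place_genes(genes, cfg$genome, cfg$proximity_pairs)

    mu <- stats::runif(length(genes), cfg$expr_mean_range[1], cfg$expr_mean_range[2])
    names(mu) <- genes
    # lineage-restricted buffering genes need enough baseline expression
    # to survive the mean-expression filter despite loss in most cells
    linked <- cfg$planted_pairs$buffering[!is.na(cfg$planted_pairs$lineage)]
    mu[linked] <- pmax(mu[linked], 6)

    expr_vals <- matrix(stats::rnorm(n * length(genes), mean = rep(mu, each = n),
                                     sd = cfg$noise_sd_expr),
                        nrow = n, dimnames = list(cells, genes))
    nu <- stats::rnorm(cfg$n_eff_genes, cfg$eff_mean_center, cfg$eff_mean_sd)
    eff_vals <- matrix(stats::rnorm(n * cfg$n_eff_genes,
                                    mean = rep(nu, each = n),
                                    sd = cfg$noise_sd_eff),
                       nrow = n, dimnames = list(cells, cfg$eff_genes))

    for (mod in cfg$confounder_modules) {
      in_lin <- lineage == mod$lineage
      expr_vals[in_lin, mod$genes] <- expr_vals[in_lin, mod$genes] + mod$expr_shift
      eg <- intersect(mod$eff_genes, colnames(eff_vals))
      if (length(eg) > 0) {
        eff_vals[in_lin, eg] <- eff_vals[in_lin, eg] + mod$eff_shift
      }
    }

    pp <- cfg$planted_pairs
    for (i in seq_len(nrow(pp))) {
      if (is.na(pp$lineage[i])) {
        loss <- sample(n, round(pp$loss_fraction[i] * n))
      } else {
        loss <- which(lineage != pp$lineage[i])
      }
      expr_vals[loss, pp$buffering[i]] <- cfg$loss_residual *
        expr_vals[loss, pp$buffering[i]]
      eff_vals[loss, pp$buffered[i]] <- eff_vals[loss, pp$buffered[i]] -
        pp$effect_size[i]
    }
    expr_vals <- pmax(expr_vals, 0)

    gene_tab <- function(g) data.frame(symbol = g,
                                       entrez = 10000L + match(g, genes),
                                       stringsAsFactors = FALSE)
    truth_fp <- do.call(rbind, c(list(
      data.frame(gene_a = character(), gene_b = character(),
                 stringsAsFactors = FALSE)),
      lapply(cfg$confounder_modules, function(mod) {
        buffered <- pp$buffered[mod$linked_pairs]
        buffered <- buffered[pp$lineage[mod$linked_pairs] == mod$lineage]
        if (length(buffered) == 0) return(NULL)
        expand.grid(gene_a = mod$genes, gene_b = buffered,
                    stringsAsFactors = FALSE)
      })))
    list(expr = new_omics_matrix(expr_vals, gene_tab(genes), "expression"),
         eff = new_omics_matrix(eff_vals, gene_tab(cfg$eff_genes), "effect"),
         meta = meta, ann = ann,
         truth = list(planted = pp, confounder_fp = truth_fp, annotation = ann))
  })
}

place_genes <- function(genes, genome, proximity_pairs) {
  chrom <- sample(genome$chromosome, length(genes), replace = TRUE,
                  prob = genome$length_bp / sum(genome$length_bp))
  len <- genome$length_bp[match(chrom, genome$chromosome)]
  width <- 2e4
  start <- floor(stats::runif(length(genes), 1, len - width))
  ann <- data.frame(gene = genes, chromosome = chrom, arm = "p",
                    start_bp = start, end_bp = start + width,
                    stringsAsFactors = FALSE)
  ann$midpoint_bp <- (ann$start_bp + ann$end_bp) / 2
  ann$arm <- ifelse(ann$midpoint_bp < len / 2, "p", "q")
  if (!is.null(proximity_pairs)) {
    for (i in seq_len(nrow(proximity_pairs))) {
      a <- match(proximity_pairs$gene_a[i], ann$gene)
      b <- match(proximity_pairs$gene_b[i], ann$gene)
      if (is.na(a) || is.na(b)) stop("proximity pair gene not in universe")
      ann$chromosome[b] <- ann$chromosome[a]
      ann$start_bp[b] <- ann$start_bp[a] + proximity_pairs$distance_bp[i]
      ann$end_bp[b] <- ann$start_bp[b] + width
      ann$midpoint_bp[b] <- (ann$start_bp[b] + ann$end_bp[b]) / 2
      lenb <- genome$length_bp[match(ann$chromosome[b], genome$chromosome)]
      ann$arm[b] <- ifelse(ann$midpoint_bp[b] < lenb / 2, "p", "q")
    }
  }
  ann
}

#' Write a synthetic dataset to disk in the standard file dialects
#'
#' Emits `expression.csv` and `effect.csv` (DepMap dialect, headers
#' `"SYMBOL (entrez)"`), `model.csv` (cell-line metadata),
#' `annotation.tsv`, and `truth_planted.tsv` / `truth_confounder_fp.tsv`,
#' so generated data round-trips through the package's readers.
#'
#' @param ds A dataset from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics <- function(M, path) {
    hdr <- sprintf("%s (%d)", M$genes$symbol, M$genes$entrez)
    df <- data.frame(rownames(M$values), M$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("", hdr)
    data.table::fwrite(df, path)
  }
  write_omics(ds$expr, file.path(dir, "expression.csv"))
  write_omics(ds$eff, file.path(dir, "effect.csv"))
  data.table::fwrite(ds$meta, file.path(dir, "model.csv"))
  ann <- ds$ann[, c("gene", "chromosome", "arm", "start_bp", "end_bp")]
  colnames(ann) <- c("gene", "chromosome", "arm", "start", "end")
  data.table::fwrite(ann, file.path(dir, "annotation.tsv"), sep = "\t")
  data.table::fwrite(ds$truth$planted, file.path(dir, "truth_planted.tsv"), sep = "\t")
  data.table::fwrite(ds$truth$confounder_fp,
                     file.path(dir, "truth_confounder_fp.tsv"), sep = "\t")
  invisible(dir)
}

#' Count recovered planted pairs among predictions
#'
#' Matches on the ordered (buffering, buffered) key — a planted pair is
#' directional, so the reversed orientation does not count.
#'
#' @param preds A `RankedPredictions` data.frame.
#' @param planted The `truth$planted` table of a generated dataset.
#' @return Integer count of planted pairs present in `preds`.
#' @export
planted_recovery <- function(preds, planted) {
  pk <- paste(planted$buffering, planted$buffered, sep = "|")
  sum(paste(preds$buffering_gene, preds$buffered_gene, sep = "|") %in% pk)
}
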