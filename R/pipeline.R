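#' Named method configuration
#'
#' Describes one end-to-end prediction route: an optional a priori
#' normalization applied to both matrices independently, an association
#' index, and the optional post hoc balancing step.
#'
#' Balancing on top of linear-regression scores is permitted but marked
#' experimental: the balancing margin is calibrated for correlation
#' coefficients, not -log10 p scales.
#'
#' @param association `"pearson"`, `"spearman"` or `"linreg"`.
#' @param covariate Covariate for `"linreg"`: `"none"`, `"lineage"` or
#'   `"growth_pattern"`.
#' @param prenorm `"none"`, `"combat"` or `"whiten"`.
#' @param batch ComBat batch variable: `"lineage"` or `"growth_pattern"`
#'   (cell-line axis), `"chromosome"` or `"arm"` (gene axis; needs a gene
#'   annotation at run time).
#' @param whiten A [whiten_spec()] when `prenorm = "whiten"`.
#' @param bacon Apply the balancing transform. Default TRUE.
#' @param k Balancing margin. Default 0.05.
#' @return A `MethodConfig` list.
#' @export
method_config <- function(association = c("pearson", "spearman", "linreg"),
                          covariate = c("none", "lineage", "growth_pattern"),
                          prenorm = c("none", "combat", "whiten"),
                          batch = c("lineage", "growth_pattern", "chromosome", "arm"),
                          whiten = whiten_spec("cholesky"),
                          bacon = TRUE, k = 0.05) {
  association <- match.arg(association)
  covariate <- match.arg(covariate)
  prenorm <- match.arg(prenorm)
  batch <- match.arg(batch)
  if (association == "linreg" && bacon) {
    message("note: balancing on top of linreg scores is experimental")
  }
  cfg <- structure(list(association = association, covariate = covariate,
                        prenorm = prenorm, batch = batch, whiten = whiten,
                        bacon = bacon, k = k), class = "MethodConfig")
  cfg
}

#' @export
format.MethodConfig <- function(x, ...) {
  pre <- switch(x$prenorm, none = NULL,
                combat = paste0("combat(", x$batch, ")"),
                whiten = paste0("whiten(", x$whiten$method, ")"))
  assoc <- if (x$association == "linreg" && x$covariate != "none") {
    paste0("linreg(", x$covariate, ")")
  } else x$association
  paste(c(pre, assoc, if (x$bacon) "bacon"), collapse = "+")
}

#' @export
print.MethodConfig <- function(x, ...) {
  cat("MethodConfig:", format(x), "\n"); invisible(x)
}

apply_prenorm <- function(M, cfg, meta, ann) {
  switch(cfg$prenorm,
    none = M,
    whiten = whiten_cells(M, cfg$whiten),
    combat = {
      if (cfg$batch %in% c("lineage", "growth_pattern")) {
        b <- stats::setNames(meta[[cfg$batch]], meta$cell_line_id)
        combat_adjust(M, b, axis = "cell_lines")
      } else {
        if (is.null(ann)) stop("gene-axis ComBat needs a gene annotation")
        key <- if (cfg$batch == "chromosome") ann$chromosome else
          paste(ann$chromosome, ann$arm)
        b <- stats::setNames(key, ann$gene)
        combat_adjust(M, b, axis = "genes")
      }
    })
}

#' Run one method configuration end to end
#'
#' Applies the configured a priori normalization to each matrix
#' independently, computes the association matrix, balances it when
#' configured, and extracts ranked predictions. The original
#' (un-prenormalized) Pearson matrix is always computed alongside so
#' every prediction carries its original coefficient and global z —
#' the reference point for transformation-strength metrics.
#'
#' @param expr,eff Harmonized `OmicsMatrix` pair.
#' @param meta Cell-line metadata (needed for lineage/growth covariates
#'   and batches).
#' @param cfg A [method_config()].
#' @param top_n Number of ranked predictions to extract. Default 100.
#' @param ann Optional gene annotation (gene-axis ComBat only).
#' @return List with `predictions` (`RankedPredictions`), `original`
#'   (Pearson `AssociationMatrix`), and `scored` (the ranked matrix).
#' @export
run_config <- function(expr, eff, meta = NULL, cfg = method_config(),
                       top_n = 100, ann = NULL) {
  stopifnot(inherits(cfg, "MethodConfig"))
  check_harmonized(expr, eff)
  original <- cross_correlation(expr, eff, "pearson")
  e1 <- apply_prenorm(expr, cfg, meta, ann)
  e2 <- apply_prenorm(eff, cfg, meta, ann)
  A <- switch(cfg$association,
    pearson = cross_correlation(e1, e2, "pearson"),
    spearman = cross_correlation(e1, e2, "spearman"),
    linreg = linreg_scores(e1, e2, meta, cfg$covariate))
  scored <- if (cfg$bacon) bacon_balance(A, balance_config(cfg$k)) else A
  list(predictions = top_pairs(scored, original, top_n),
       original = original, scored = scored)
}

ref_universe_count <- function(ref, row_genes, col_genes) {
  a_in <- (ref$gene_a %in% row_genes & ref$gene_b %in% col_genes) |
          (ref$gene_b %in% row_genes & ref$gene_a %in% col_genes)
  sum(a_in)
}

#' Evaluate method configurations with the full metric stack
#'
#' For every configuration and every prediction-set size N, computes:
#' counts and fold-change enrichments of each reference pair set,
#' diversity index, self-addiction / proximal / co-expression-FP counts,
#' low-z transformation-strength counts, and the empirical FDR at rank N.
#'
#' @inheritParams run_config
#' @param configs Named list of [method_config()] objects.
#' @param refs Named list of reference `PairSet` objects (treated as TP
#'   sets for the FDR).
#' @param ann Gene annotation for proximity flagging (optional).
#' @param N_list Prediction-set sizes. Default `c(100, 1000)`.
#' @param coexpr Co-expression matrix; computed from `expr` when NULL.
#' @return A `MetricReport` data.frame, one row per config x N.
#' @export
evaluate_methods <- function(expr, eff, meta = NULL, configs, refs,
                             ann = NULL, N_list = c(100, 1000),
                             coexpr = NULL) {
  if (is.null(names(configs))) names(configs) <- vapply(configs, format, "")
  if (is.null(coexpr)) coexpr <- self_correlation(expr)
  universe <- ncol(expr$values) * ncol(eff$values)
  rows <- list()
  for (cn in names(configs)) {
    run <- run_config(expr, eff, meta, configs[[cn]], top_n = max(N_list),
                      ann = ann)
    for (N in N_list) {
      preds <- run$predictions[run$predictions$rank <= N, , drop = FALSE]
      preds <- label_tp_fp(preds, refs, ann = ann, coexpr = coexpr)
      row <- data.frame(config = cn, N = N, stringsAsFactors = FALSE)
      for (rn in names(refs)) {
        uref <- ref_universe_count(refs[[rn]], rownames(run$original),
                                   colnames(run$original))
        if (uref > 0) {
          enr <- set_enrichment(preds, refs[[rn]], universe, uref)
          row[[paste0(rn, "_count")]] <- enr$count
          row[[paste0(rn, "_fc")]] <- enr$fold_change
        } else {
          row[[paste0(rn, "_count")]] <- 0L
          row[[paste0(rn, "_fc")]] <- NA_real_
        }
      }
      row$diversity <- diversity_index(preds)
      row$self_addictions <- sum(has_flag(preds$flags, "self_addiction"))
      row$proximal <- sum(has_flag(preds$flags, "proximal"))
      row$coexpression_fp <- sum(has_flag(preds$flags, "coexpression_fp"))
      lz <- low_z_counts(preds)
      for (nm in names(lz)) row[[nm]] <- lz[[nm]]
      row$fdr_at_N <- utils::tail(cumulative_fdr(preds), 1L)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("MetricReport", "data.frame")
  out
}

#' High-confidence set specification
#' @param fdr_threshold Cumulative-FDR cutoff for nomination. Default 0.5.
#' @param remove Flags whose carriers are filtered from the nominated
#'   set.
#' @param nomination `"last"` (all ranks up to the last one satisfying
#'   the threshold, reading the threshold as a cutoff on the cumulative
#'   curve) or `"first"` (stop at the first crossing).
#' @return A `HighConfidenceSpec` list.
#' @export
high_confidence_spec <- function(fdr_threshold = 0.5,
                                 remove = c("self_addiction", "proximal",
                                            "coexpression_fp"),
                                 nomination = c("last", "first")) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
  structure(list(fdr_threshold = fdr_threshold, remove = remove,
                 nomination = match.arg(nomination)),
            class = "HighConfidenceSpec")
}

#' Nominate a high-confidence buffering pair set
#'
#' Runs the best-performing route (Cholesky whitening + Pearson +
#' balancing), walks the ranked predictions accumulating the empirical
#' FDR, nominates all pairs up to the deepest rank still at or under the
#' FDR threshold, and then removes self-addictions, proximal pairs and
#' co-expression-driven pairs (configurable) from the nominated set.
#'
#' @inheritParams evaluate_methods
#' @param spec A [high_confidence_spec()].
#' @param search_depth How many ranked predictions to walk. Default 5000.
#' @param cfg Method route; defaults to whiten(cholesky)+pearson+bacon.
#' @return The filtered `RankedPredictions` (the high-confidence set),
#'   with attributes `n_nominated` (before flag removal) and
#'   `fdr_threshold`.
#' @export
high_confidence_set <- function(expr, eff, meta = NULL, refs, ann,
                                spec = high_confidence_spec(),
                                search_depth = 5000, coexpr = NULL,
                                cfg = method_config("pearson",
                                                    prenorm = "whiten",
                                                    whiten = whiten_spec("cholesky"),
                                                    bacon = TRUE)) {
  stopifnot(inherits(spec, "HighConfidenceSpec"))
  if (is.null(coexpr)) coexpr <- self_correlation(expr)
  run <- run_config(expr, eff, meta, cfg, top_n = search_depth, ann = ann)
  preds <- label_tp_fp(run$predictions, refs, ann = ann, coexpr = coexpr)
  fdr <- cumulative_fdr(preds)
  ok <- which(fdr <= spec$fdr_threshold)
  if (length(ok) == 0L) {
    warning("no rank satisfies the FDR threshold; empty set returned")
    cut <- 0L
  } else {
    cut <- if (spec$nomination == "last") max(ok) else {
      bad <- which(fdr > spec$fdr_threshold)
      if (length(bad) == 0L) max(ok) else min(bad) - 1L
    }
  }
  nominated <- preds[seq_len(cut), , drop = FALSE]
  drop <- Reduce(`|`, lapply(spec$remove, function(tok) has_flag(nominated$flags, tok)),
                 logical(nrow(nominated)))
  out <- nominated[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_nominated") <- cut
  attr(out, "fdr_threshold") <- spec$fdr_threshold
  out
}

#' Cell-line subsampling experiment
#'
#' Repeatedly subsamples cell lines without replacement (the gene
#' universe, and so the number of tested pairs, is held constant), runs
#' each configuration on the subsample, and reports per-reference-set
#' counts among the top predictions and the diversity index, aggregated
#' as mean and SD per size.
#'
#' Per-replicate seeds derive from the master seed by a fixed counter
#' scheme and are recorded in the result.
#'
#' @inheritParams evaluate_methods
#' @param sizes Subsample sizes (cell lines). Default `c(100, 200, 500)`.
#' @param reps Replicates per size. Default 10.
#' @param seed Master seed.
#' @param top_n Prediction-set size examined. Default 100.
#' @return data.frame with one row per size x config x reference set,
#'   columns mean_count / sd_count (plus diversity columns); replicate
#'   detail in `attr(, "replicates")`.
#' @export
subsample_experiment <- function(expr, eff, meta = NULL, refs,
                                 sizes = c(100, 200, 500), reps = 10,
                                 seed = 1, configs = list(pcc = method_config(bacon = FALSE)),
                                 top_n = 100) {
  n_avail <- nrow(expr$values)
  if (any(sizes > n_avail)) stop("subsample size exceeds available cell lines")
  if (is.null(names(configs))) names(configs) <- vapply(configs, format, "")
  detail <- list()
  counter <- 0L
  for (size in sizes) {
    for (r in seq_len(reps)) {
      counter <- counter + 1L
      rep_seed <- (seed + 7919L * counter) %% .Machine$integer.max
      idx <- with_seed(rep_seed, sort(sample(n_avail, size)))
      se <- new_omics_matrix(expr$values[idx, , drop = FALSE], expr$genes, expr$kind)
      sf <- new_omics_matrix(eff$values[idx, , drop = FALSE], eff$genes, eff$kind)
      sm <- if (is.null(meta)) NULL else meta[meta$cell_line_id %in% rownames(se$values), ]
      for (cn in names(configs)) {
        run <- run_config(se, sf, sm, configs[[cn]], top_n = top_n)
        counts <- vapply(refs, function(ref) {
          keys <- pair_key(run$predictions$buffering_gene,
                           run$predictions$buffered_gene)
          sum(keys %in% pair_key(ref$gene_a, ref$gene_b))
        }, numeric(1))
        detail[[length(detail) + 1L]] <- data.frame(
          size = size, rep = r, seed = rep_seed, config = cn,
          ref = names(refs), count = as.numeric(counts),
          diversity = diversity_index(run$predictions),
          stringsAsFactors = FALSE)
      }
    }
  }
  detail <- do.call(rbind, detail)
  agg <- do.call(rbind, lapply(split(detail, detail[, c("size", "config", "ref")], drop = TRUE),
    function(d) data.frame(size = d$size[1], config = d$config[1], ref = d$ref[1],
                           mean_count = mean(d$count), sd_count = stats::sd(d$count),
                           mean_diversity = mean(d$diversity),
                           sd_diversity = stats::sd(d$diversity),
                           stringsAsFactors = FALSE)))
  agg <- agg[order(agg$config, agg$ref, agg$size), ]
  rownames(agg) <- NULL
  attr(agg, "replicates") <- detail
  agg
}

#' Dynamic gene-space grid
#'
#' Crosses expression-signal thresholds (keep genes with log2(TPM+1) of
#' at least `expr_level` in at least T_e cell lines) with essentiality
#' thresholds (keep genes with a Chronos score at or below T_c in at
#' least `min_ess_lines` cell lines), and reports per grid cell the
#' universe size (product of surviving gene counts), each reference
#' set's universe density, and top-N counts and fold changes per method.
#'
#' @inheritParams evaluate_methods
#' @param expr_thresholds Minimum numbers of expressing cell lines.
#' @param effect_thresholds Chronos cutoffs (e.g. -0.3: gene must reach
#'   -0.3 or lower in `min_ess_lines` lines).
#' @param expr_level Expression level defining "expressed". Default 3.
#' @param min_ess_lines Cell lines that must reach the Chronos cutoff.
#'   Default 30.
#' @param top_n Prediction-set size. Default 100.
#' @return Long data.frame, one row per grid cell x config x reference.
#' @export
gene_space_grid <- function(expr, eff, expr_thresholds, effect_thresholds,
                            refs, meta = NULL,
                            configs = list(pcc = method_config(bacon = FALSE),
                                           pcc_bacon = method_config()),
                            expr_level = 3, min_ess_lines = 30, top_n = 100) {
  stopifnot(length(expr_thresholds) > 0, length(effect_thresholds) > 0)
  if (is.null(names(configs))) names(configs) <- vapply(configs, format, "")
  n_expressing <- colSums(expr$values >= expr_level)
  rows <- list()
  for (te in expr_thresholds) {
    keep_e <- n_expressing >= te
    for (tc in effect_thresholds) {
      keep_c <- colSums(eff$values <= tc) >= min_ess_lines
      if (!any(keep_e) || !any(keep_c)) {
        rows[[length(rows) + 1L]] <- data.frame(
          expr_threshold = te, effect_threshold = tc,
          n_expr_genes = sum(keep_e), n_eff_genes = sum(keep_c),
          universe = sum(keep_e) * sum(keep_c), config = NA_character_,
          ref = NA_character_, ref_density = NA_real_,
          count = NA_real_, fold_change = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      se <- new_omics_matrix(expr$values[, keep_e, drop = FALSE],
                             expr$genes[keep_e, , drop = FALSE], expr$kind)
      sf <- new_omics_matrix(eff$values[, keep_c, drop = FALSE],
                             eff$genes[keep_c, , drop = FALSE], eff$kind)
      universe <- sum(keep_e) * sum(keep_c)
      for (cn in names(configs)) {
        run <- run_config(se, sf, meta, configs[[cn]],
                          top_n = min(top_n, universe))
        for (rn in names(refs)) {
          uref <- ref_universe_count(refs[[rn]], colnames(se$values),
                                     colnames(sf$values))
          enr <- if (uref > 0) {
            set_enrichment(run$predictions, refs[[rn]], universe, uref)
          } else list(count = 0L, fold_change = NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            expr_threshold = te, effect_threshold = tc,
            n_expr_genes = sum(keep_e), n_eff_genes = sum(keep_c),
            universe = universe, config = cn, ref = rn,
            ref_density = uref / universe,
            count = enr$count, fold_change = enr$fold_change,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
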