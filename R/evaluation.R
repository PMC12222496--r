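#' Extract the top-N ranked buffering predictions
#'
#' Takes the N highest-scoring entries of a (balanced or raw) association
#' matrix and attaches the original pre-normalization Pearson coefficient
#' and its global z score. Ties in score are broken by higher original
#' coefficient, then lexicographically by (buffering, buffered) gene, so
#' rankings are fully deterministic.
#'
#' @param B Scored matrix (a `BalancedMatrix` or `AssociationMatrix`).
#' @param A_orig The original (un-prenormalized) Pearson
#'   `AssociationMatrix` sharing `B`'s labels.
#' @param N Number of pairs to return.
#' @return A `RankedPredictions` data.frame with columns rank,
#'   buffering_gene, buffered_gene, score, original_r, z, flags, label.
#' @export
top_pairs <- function(B, A_orig, N) {
  if (!identical(dimnames(B), dimnames(A_orig))) {
    stop("scored and original matrices must share labels")
  }
  total <- length(B)
  if (N > total) {
    warning("N exceeds the number of pairs; returning all ", total)
    N <- total
  }
  if (N == 0L) {
    return(new_ranked_predictions(data.frame(
      rank = integer(), buffering_gene = character(), buffered_gene = character(),
      score = numeric(), original_r = numeric(), z = numeric(),
      flags = character(), label = character(), stringsAsFactors = FALSE)))
  }
  score <- as.vector(B)
  orig <- as.vector(unclass_assoc(A_orig))
  z <- if (stats::sd(orig) == 0) rep(0, length(orig)) else
    as.vector(zscore_global(A_orig))
  buffering <- rep(rownames(B), times = ncol(B))
  buffered <- rep(colnames(B), each = nrow(B))
  # restrict to entries at or above the N-th score (keeps all tied
  # candidates) before the full tie-broken ordering
  thr <- sort(score, decreasing = TRUE)[N]
  cand <- which(score >= thr)
  o <- cand[order(-score[cand], -orig[cand], buffering[cand], buffered[cand])][seq_len(N)]
  new_ranked_predictions(data.frame(
    rank = seq_len(N),
    buffering_gene = buffering[o], buffered_gene = buffered[o],
    score = score[o], original_r = orig[o], z = z[o],
    flags = "", label = "unlabeled", stringsAsFactors = FALSE))
}

#' Diversity index of a prediction set
#'
#' The minimal number of genes accounting for half of the gene slots in
#' the set, normalized by the maximum possible (N genes for N pairs).
#' An index of 1 means no gene repeats (maximally diverse); hub-dominated
#' sets, the signature of co-expression-driven false positives, score
#' near 0.
#'
#' @param preds A `RankedPredictions` data.frame (or any data.frame with
#'   buffering_gene / buffered_gene columns).
#' @return A number in (0, 1].
#' @export
diversity_index <- function(preds) {
  N <- nrow(preds)
  if (N < 1L) stop("need at least one pair")
  counts <- sort(table(c(preds$buffering_gene, preds$buffered_gene)),
                 decreasing = TRUE)
  used <- which(cumsum(counts) >= N)[1L]
  as.numeric(used) / N
}

#' Flag genomically proximal pairs
#'
#' Pairs whose genes lie on the same chromosome arm (or chromosome, per
#' `scope`) with midpoints strictly less than `max_dist_bp` apart are
#' flagged `proximal`; such pairs are treated as likely false positives
#' reflecting residual proximity bias in CRISPR screens. Genes missing
#' from the annotation leave their pairs unflagged, with a warning.
#'
#' @param preds A `RankedPredictions` data.frame.
#' @param ann Gene annotation from [read_gene_annotation()].
#' @param max_dist_bp Distance cutoff in base pairs (strict). Default 10 Mbp.
#' @param scope `"arm"` or `"chromosome"`: the unit both genes must share.
#' @return `preds` with the `proximal` token added to `flags` where due.
#' @export
flag_proximal <- function(preds, ann, max_dist_bp = 1e7,
                          scope = c("arm", "chromosome")) {
  scope <- match.arg(scope)
  ia <- match(preds$buffering_gene, ann$gene)
  ib <- match(preds$buffered_gene, ann$gene)
  uncov <- is.na(ia) | is.na(ib)
  if (any(uncov)) {
    warning(sum(uncov), " pair(s) with unannotated gene(s) left unflagged")
  }
  same_unit <- ann$chromosome[ia] == ann$chromosome[ib]
  if (scope == "arm") same_unit <- same_unit & ann$arm[ia] == ann$arm[ib]
  near <- abs(ann$midpoint_bp[ia] - ann$midpoint_bp[ib]) < max_dist_bp
  hit <- !uncov & same_unit & near
  hit[is.na(hit)] <- FALSE
  preds$flags <- add_flag(preds$flags, "proximal", hit)
  preds
}

add_flag <- function(flags, token, hit) {
  add <- hit & !vapply(strsplit(flags, ";", fixed = TRUE),
                       function(x) token %in% x, logical(1))
  flags[add] <- ifelse(nzchar(flags[add]), paste0(flags[add], ";", token), token)
  flags
}

has_flag <- function(flags, token) {
  vapply(strsplit(flags, ";", fixed = TRUE), function(x) token %in% x, logical(1))
}

#' Flag co-expression-driven false-positive predictions
#'
#' Within the partners predicted to buffer the same gene, a lower-ranked
#' partner whose co-expression with any better-ranked partner exceeds
#' `z_threshold` (on z-standardized co-expression coefficients) is
#' flagged `coexpression_fp`: its association is better explained by
#' tissue-driven co-expression with the stronger partner than by
#' buffering.
#'
#' By default z standardization uses the off-diagonal co-expression
#' coefficients among the distinct buffering genes of the evaluated
#' prediction set; `standardize = "full_matrix"` standardizes over the
#' whole co-expression matrix instead.
#'
#' @param preds A `RankedPredictions` data.frame.
#' @param coexpr Symmetric co-expression correlation matrix covering the
#'   buffering genes in `preds`.
#' @param z_threshold Flagging threshold on the z scale. Default 3.
#' @param standardize `"pred_genes"` (default) or `"full_matrix"`.
#' @return `preds` with `coexpression_fp` tokens added.
#' @export
coexpression_fp_flags <- function(preds, coexpr, z_threshold = 3,
                                  standardize = c("pred_genes", "full_matrix")) {
  standardize <- match.arg(standardize)
  genes <- unique(preds$buffering_gene)
  missing <- setdiff(genes, rownames(coexpr))
  if (length(missing) > 0L) {
    stop("co-expression matrix does not cover buffering gene(s): ",
         paste(missing, collapse = ", "))
  }
  if (standardize == "pred_genes") {
    sub <- coexpr[genes, genes, drop = FALSE]
    vals <- sub[upper.tri(sub)]
  } else {
    vals <- coexpr[upper.tri(coexpr)]
  }
  if (length(vals) < 2L || stats::sd(vals) == 0) {
    mu <- 0; sdv <- 1   # degenerate population: raw coefficients used as-is
  } else {
    mu <- mean(vals); sdv <- stats::sd(vals)
  }
  hit <- logical(nrow(preds))
  for (g in unique(preds$buffered_gene)) {
    idx <- which(preds$buffered_gene == g)
    if (length(idx) < 2L) next
    idx <- idx[order(preds$rank[idx])]
    partners <- preds$buffering_gene[idx]
    zsub <- (coexpr[partners, partners, drop = FALSE] - mu) / sdv
    for (p in 2:length(idx)) {
      better <- seq_len(p - 1L)
      better <- better[partners[better] != partners[p]]
      if (length(better) > 0L && any(zsub[p, better] > z_threshold)) {
        hit[idx[p]] <- TRUE
      }
    }
  }
  preds$flags <- add_flag(preds$flags, "coexpression_fp", hit)
  preds
}

#' Label predictions as TP / FP / unlabeled for the empirical FDR
#'
#' A pair is a true positive (TP) when it occurs (unordered) in any
#' reference pair set or is a self-addiction (buffering gene equals
#' buffered gene). A non-TP pair is a false positive (FP) when it is
#' flagged proximal or co-expression-driven; remaining pairs stay
#' unlabeled. Self-addictions additionally receive the `self_addiction`
#' flag.
#'
#' @param preds A `RankedPredictions` data.frame; [flag_proximal()] and
#'   [coexpression_fp_flags()] are applied here when `ann` / `coexpr`
#'   are supplied (pass `NULL` to reuse existing flags).
#' @param tp_sets List of `PairSet` objects treated as true positives.
#' @param ann Optional gene annotation for proximity flagging.
#' @param coexpr Optional co-expression matrix for FP flagging.
#' @param ... Passed on to the flagging helpers.
#' @return `preds` with `label` filled in.
#' @export
label_tp_fp <- function(preds, tp_sets, ann = NULL, coexpr = NULL, ...) {
  if (!is.null(ann)) preds <- flag_proximal(preds, ann, ...)
  if (!is.null(coexpr)) preds <- coexpression_fp_flags(preds, coexpr)
  self <- preds$buffering_gene == preds$buffered_gene
  preds$flags <- add_flag(preds$flags, "self_addiction", self)
  keys <- pair_key(preds$buffering_gene, preds$buffered_gene)
  tp_keys <- unique(unlist(lapply(tp_sets, function(s) pair_key(s$gene_a, s$gene_b))))
  is_tp <- self | keys %in% tp_keys
  is_fp <- !is_tp & (has_flag(preds$flags, "proximal") |
                     has_flag(preds$flags, "coexpression_fp"))
  preds$label <- ifelse(is_tp, "TP", ifelse(is_fp, "FP", "unlabeled"))
  preds
}

#' Cumulative empirical false discovery rate along a ranking
#'
#' At each rank r, `FDR(r) = #FP(<= r) / (#FP(<= r) + #TP(<= r))`,
#' with unlabeled pairs counted in neither term and 0/0 defined as 0.
#'
#' @param preds A labeled `RankedPredictions` data.frame.
#' @return Numeric vector of FDR values, one per rank.
#' @export
cumulative_fdr <- function(preds) {
  fp <- cumsum(preds$label == "FP")
  tp <- cumsum(preds$label == "TP")
  ifelse(fp + tp == 0L, 0, fp / (fp + tp))
}

#' Count predictions lacking a strong original correlation
#'
#' For each threshold t, the number of predicted pairs whose global z
#' score of the original correlation is below t — a measure of how
#' strongly a normalization promoted pairs outside the original data's
#' high-correlation support (transformation strength).
#'
#' @param preds A `RankedPredictions` data.frame with `z` attached.
#' @param thresholds Numeric thresholds. Default `c(0, 1, 2, 3)`.
#' @return Named integer vector of counts.
#' @export
low_z_counts <- function(preds, thresholds = c(0, 1, 2, 3)) {
  vapply(thresholds, function(t) sum(preds$z < t), integer(1)) |>
    stats::setNames(sprintf("z_lt_%g", thresholds))
}

#' Enrichment of a reference pair set among predictions
#'
#' Counts reference hits among the predictions and compares the observed
#' density with the universe density: fold change
#' `(count/N) / (universe_ref_pairs/universe_pairs)` and an upper-tail
#' hypergeometric p value for >= count hits when drawing N pairs from
#' the universe.
#'
#' @param preds A `RankedPredictions` data.frame (N pairs drawn).
#' @param ref A `PairSet` of reference pairs.
#' @param universe_pairs Total number of testable pairs.
#' @param universe_ref_pairs Number of reference pairs in the universe.
#' @return List with `count`, `fold_change`, `p_value`.
#' @export
set_enrichment <- function(preds, ref, universe_pairs, universe_ref_pairs) {
  stopifnot(universe_ref_pairs <= universe_pairs)
  if (universe_ref_pairs == 0L) stop("zero reference density in the universe: fold change undefined")
  N <- nrow(preds)
  keys <- pair_key(preds$buffering_gene, preds$buffered_gene)
  count <- sum(keys %in% pair_key(ref$gene_a, ref$gene_b))
  fc <- (count / N) / (universe_ref_pairs / universe_pairs)
  p <- stats::phyper(count - 1, universe_ref_pairs,
                     universe_pairs - universe_ref_pairs, N, lower.tail = FALSE)
  list(count = count, fold_change = fc, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment; thin wrapper with
#' input validation.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Chromosome-pair density of buffering predictions
#'
#' Tabulates predicted pairs by (buffering chromosome, buffered
#' chromosome), with the expected count under independence of the two
#' chromosome margins, an upper-tail hypergeometric p value per cell and
#' BH-adjusted q values. Pairs with unannotated genes are dropped.
#'
#' @param preds A `RankedPredictions` data.frame.
#' @param ann Gene annotation.
#' @return data.frame with columns buffering_chrom, buffered_chrom,
#'   observed, expected, p_value, q_value.
#' @export
chromosome_pair_density <- function(preds, ann) {
  ca <- ann$chromosome[match(preds$buffering_gene, ann$gene)]
  cb <- ann$chromosome[match(preds$buffered_gene, ann$gene)]
  keep <- !is.na(ca) & !is.na(cb)
  ca <- ca[keep]; cb <- cb[keep]
  total <- length(ca)
  tab <- as.data.frame(table(buffering_chrom = ca, buffered_chrom = cb),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "observed"
  marg_a <- table(ca); marg_b <- table(cb)
  tab$expected <- as.numeric(marg_a[tab$buffering_chrom]) *
    as.numeric(marg_b[tab$buffered_chrom]) / total
  tab$p_value <- stats::phyper(tab$observed - 1,
                               as.numeric(marg_b[tab$buffered_chrom]),
                               total - as.numeric(marg_b[tab$buffered_chrom]),
                               as.numeric(marg_a[tab$buffering_chrom]),
                               lower.tail = FALSE)
  tab$q_value <- bh_adjust(tab$p_value)
  tab
}

#' Genetic interaction strength from knockout log fold changes
#'
#' `dLFC = double-knockout LFC - (single A LFC + single B LFC)`; a pair
#' is called a synthetic-lethal hit when dLFC falls strictly below the
#' hit threshold (default -1, a strong negative fitness phenotype).
#'
#' @param double_lfc,single_a,single_b Log2 fold changes (vectorized).
#' @param hit_threshold Strict hit cutoff. Default -1.
#' @return data.frame with columns `dlfc`, `is_hit`.
#' @export
delta_lfc <- function(double_lfc, single_a, single_b, hit_threshold = -1) {
  stopifnot(all(is.finite(double_lfc)), all(is.finite(single_a)),
            all(is.finite(single_b)))
  d <- double_lfc - (single_a + single_b)
  data.frame(dlfc = d, is_hit = d < hit_threshold)
}
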