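new_association_matrix <- function(values, method) {
  structure(values, method = method, class = c("AssociationMatrix", "matrix"))
}

#' @export
print.AssociationMatrix <- function(x, ...) {
  cat(sprintf("AssociationMatrix (%s): %d expression genes x %d effect genes\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}

check_harmonized <- function(expr, eff) {
  if (!identical(rownames(expr$values), rownames(eff$values))) {
    stop("matrices are not harmonized: cell lines differ or are ordered differently; run preprocess_pair() first")
  }
  if (nrow(expr$values) < 3L) stop("need at least 3 shared cell lines")
}

zero_constant_cols <- function(M, label) {
  const <- apply(M, 2L, function(x) stats::sd(x) == 0 || !is.finite(stats::sd(x)))
  if (any(const)) {
    warning("constant ", label, " column(s) yield correlation 0: ",
            paste(colnames(M)[const], collapse = ", "))
  }
  const
}

#' Cross-dataset correlation of expression with fitness effect
#'
#' Entry (A, B) is the correlation of gene A's expression with gene B's
#' knockout fitness effect (Chronos score) across cell lines. A positive
#' coefficient suggests that B is more essential where A is lowly
#' expressed, the expected signature of A buffering B. The matrix is not
#' symmetric and its row/column dimensions define the universe sizes used
#' by the balancing denominator downstream.
#'
#' Constant columns (correlation undefined) produce 0 with a warning so
#' the matrix keeps its full size without ever promoting such pairs.
#'
#' @param expr,eff Harmonized `OmicsMatrix` objects (same cell lines,
#'   same order).
#' @param method `"pearson"` or `"spearman"` (Pearson on average ranks).
#' @param block_size Number of effect columns correlated per block;
#'   blockwise evaluation keeps memory bounded on genome-scale matrices
#'   and is numerically identical to the one-shot computation.
#' @return An `AssociationMatrix` (expression genes x effect genes).
#' @export
cross_correlation <- function(expr, eff, method = c("pearson", "spearman"),
                              block_size = Inf) {
  method <- match.arg(method)
  check_harmonized(expr, eff)
  X <- expr$values
  Y <- eff$values
  if (method == "spearman") {
    X <- apply(X, 2L, rank)
    Y <- apply(Y, 2L, rank)
    dimnames(X) <- dimnames(expr$values); dimnames(Y) <- dimnames(eff$values)
  }
  cx <- zero_constant_cols(X, "expression")
  cy <- zero_constant_cols(Y, "effect")
  m <- ncol(Y)
  if (!is.finite(block_size) || block_size >= m) {
    R <- suppressWarnings(stats::cor(X, Y))
  } else {
    R <- matrix(NA_real_, ncol(X), m, dimnames = list(colnames(X), colnames(Y)))
    starts <- seq(1L, m, by = block_size)
    for (s in starts) {
      j <- s:min(s + block_size - 1L, m)
      R[, j] <- suppressWarnings(stats::cor(X, Y[, j, drop = FALSE]))
    }
  }
  R[cx, ] <- 0
  R[, cy] <- 0
  R[is.na(R)] <- 0
  new_association_matrix(R, method)
}

#' Within-matrix correlation (co-expression / co-essentiality)
#'
#' Symmetric gene-gene correlation of one omics matrix with itself, e.g.
#' co-expression of log2(TPM+1) profiles. Unit diagonal for non-constant
#' genes; constant genes give 0 off-diagonal with a warning.
#'
#' @inheritParams cross_correlation
#' @param M An `OmicsMatrix`.
#' @return Symmetric correlation matrix with gene symbols as dimnames.
#' @export
self_correlation <- function(M, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(M$values) < 3L) stop("need at least 3 cell lines")
  X <- M$values
  if (method == "spearman") {
    X <- apply(X, 2L, rank)
    dimnames(X) <- dimnames(M$values)
  }
  const <- zero_constant_cols(X, "input")
  R <- suppressWarnings(stats::cor(X))
  R[const, ] <- 0; R[, const] <- 0
  diag(R)[const] <- 1
  R[is.na(R)] <- 0
  R
}

#' Signed -log10 p association scores from multiple linear regression
#'
#' For each gene pair, fits ordinary least squares of the buffered gene's
#' fitness effect on the buffering gene's expression plus an optional
#' categorical covariate (cell-line lineage or growth pattern, dummy
#' coded). The association index is `-log10(p)` of the expression
#' coefficient's two-sided t test; because the p value does not carry the
#' slope's direction, the index is negated for pairs with a negative
#' slope. p values are floored at 1e-300 (score cap ~300).
#'
#' Implemented by residualizing both datasets on the covariate design
#' (Frisch-Waugh), which reproduces the per-pair OLS t statistic exactly
#' while remaining a matrix operation.
#'
#' @inheritParams cross_correlation
#' @param meta Cell-line metadata data.frame with columns `cell_line_id`,
#'   `lineage`, `growth_pattern`; required unless `covariate = "none"`.
#' @param covariate `"none"`, `"lineage"` or `"growth_pattern"`.
#' @return An `AssociationMatrix` with `method = "linreg"`.
#' @export
linreg_scores <- function(expr, eff, meta = NULL,
                          covariate = c("none", "lineage", "growth_pattern")) {
  covariate <- match.arg(covariate)
  check_harmonized(expr, eff)
  X <- expr$values
  Y <- eff$values
  k <- nrow(X)
  if (covariate == "none") {
    Z <- matrix(1, k, 1L)
  } else {
    if (is.null(meta)) stop("meta required for covariate = ", covariate)
    lev <- meta[[covariate]][match(rownames(X), meta$cell_line_id)]
    if (anyNA(lev)) stop("metadata missing for cell lines: ",
                         paste(rownames(X)[is.na(lev)], collapse = ", "))
    Z <- stats::model.matrix(~ factor(lev))
  }
  p_par <- qr(Z)$rank
  df <- k - p_par - 1L
  if (df < 1L) stop("need at least p + 2 cell lines for the regression")
  # residualize on intercept + covariate dummies
  Q <- qr.Q(qr(Z))
  Xr <- X - Q %*% crossprod(Q, X)
  Yr <- Y - Q %*% crossprod(Q, Y)
  sx <- sqrt(colSums(Xr^2))
  sy <- sqrt(colSums(Yr^2))
  degener_x <- sx < 1e-12
  if (any(degener_x)) {
    warning("expression gene(s) collinear with the covariate design scored 0: ",
            paste(colnames(X)[degener_x], collapse = ", "))
    sx[degener_x] <- 1
  }
  degener_y <- sy < 1e-12
  sy[degener_y] <- 1
  Rp <- crossprod(sweep(Xr, 2L, sx, "/"), sweep(Yr, 2L, sy, "/"))
  Rp <- pmin(pmax(Rp, -1), 1)
  tt <- Rp * sqrt(df / pmax(1 - Rp^2, .Machine$double.eps))
  p <- pmax(2 * stats::pt(-abs(tt), df), 1e-300)
  S <- sign(Rp) * (-log10(p))
  S[degener_x, ] <- 0
  S[, degener_y] <- 0
  dimnames(S) <- list(colnames(X), colnames(Y))
  new_association_matrix(S, "linreg")
}

#' Globally z-standardize an association matrix
#'
#' Standardizes over all n x m entries using the grand mean and the
#' sample standard deviation. Used to judge how strongly a normalization
#' moved a pair away from its original correlation support (pairs with a
#' low z in the original data lacked a strong correlation there).
#'
#' @param A An `AssociationMatrix` or plain numeric matrix.
#' @return Matrix of z scores with the same shape and labels.
#' @export
zscore_global <- function(A) {
  v <- as.vector(A)
  if (length(v) < 2L) stop("need at least 2 entries")
  s <- stats::sd(v)
  if (s == 0) stop("zero variance: z scores undefined")
  (unclass_assoc(A) - mean(v)) / s
}
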