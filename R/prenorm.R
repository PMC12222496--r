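#' Empirical-Bayes batch adjustment (ComBat) of one omics matrix
#'
#' Adjusts location/scale batch effects within a single matrix before
#' association, delegating to [sva::ComBat()]. Batches can run along the
#' cell-line axis (lineage or growth pattern as batch) or along the gene
#' axis (chromosome or chromosome-arm as batch). Expression and effect
#' matrices are always adjusted separately and independently.
#'
#' @param M An `OmicsMatrix`.
#' @param batches Named character vector or mapping from id (cell-line id
#'   or gene symbol, depending on `axis`) to batch label.
#' @param axis `"cell_lines"` or `"genes"`.
#' @param single_batch `"error"` (default) or `"passthrough"`: behaviour
#'   when only one batch level is present.
#' @return An `OmicsMatrix` with identical shape and labels.
#' @export
combat_adjust <- function(M, batches, axis = c("cell_lines", "genes"),
                          single_batch = c("error", "passthrough")) {
  axis <- match.arg(axis)
  single_batch <- match.arg(single_batch)
  ids <- if (axis == "cell_lines") rownames(M$values) else colnames(M$values)
  b <- batches[ids]
  if (anyNA(b)) stop("batch label missing for: ", paste(ids[is.na(b)], collapse = ", "))
  b <- factor(as.character(b))
  if (nlevels(b) < 2L) {
    if (single_batch == "error") stop("need at least 2 batches (got ", nlevels(b), ")")
    warning("single batch: matrix passed through unadjusted")
    return(M)
  }
  if (any(table(b) < 2L)) {
    stop("every batch needs at least 2 members; singleton batch(es): ",
         paste(names(which(table(b) < 2L)), collapse = ", "))
  }
  # ComBat wants features x samples; samples are the batched axis
  dat <- if (axis == "cell_lines") t(M$values) else M$values
  # features with zero variance within a batch break the EB fit; jitter-free
  # guard: drop-in mean adjustment is not attempted, sva handles the rest
  adj <- suppressMessages(sva::ComBat(dat = dat, batch = b))
  vals <- if (axis == "cell_lines") t(adj) else adj
  dimnames(vals) <- dimnames(M$values)
  new_omics_matrix(vals, M$genes, M$kind)
}

#' Whitening specification
#'
#' @param method `"cholesky"`, `"pca"` or `"zca"`.
#' @param ridge Non-negative value added to the covariance diagonal to
#'   regularize near-singular cases. Default 0.
#' @return A `WhitenSpec` list.
#' @export
whiten_spec <- function(method = c("cholesky", "pca", "zca"), ridge = 0) {
  method <- match.arg(method)
  stopifnot(is.numeric(ridge), length(ridge) == 1L, ridge >= 0)
  structure(list(method = method, ridge = ridge), class = "WhitenSpec")
}

#' Whiten an omics matrix across cell lines
#'
#' Decorrelates the cell lines (not the genes): cell lines are treated as
#' variables and genes as observations, the k x k cell-line covariance
#' is estimated over genes (sample covariance), and a whitening transform
#' W with W Sigma W' = I is applied so the whitened cell-line variables
#' have identity sample covariance. Conceptually the matrix is transposed
#' before whitening and re-transposed afterwards; labels are preserved.
#'
#' Three standard transforms are available:
#' \describe{
#'   \item{cholesky}{W = L' where Sigma^-1 = L L' with L lower
#'     triangular; depends on the cell-line ordering, which is fixed
#'     lexicographically by [preprocess_pair()], so results are
#'     deterministic.}
#'   \item{pca}{W = Lambda^-1/2 U' from the eigendecomposition
#'     Sigma = U Lambda U'; each eigenvector's largest-magnitude
#'     component is made positive for a deterministic sign.}
#'   \item{zca}{W = Sigma^-1/2, the symmetric inverse square root.}
#' }
#'
#' @param M An `OmicsMatrix` with more genes than cell lines (otherwise
#'   the covariance is singular and a positive `ridge` is required).
#' @param spec A [whiten_spec()].
#' @return A whitened `OmicsMatrix`, cell lines x genes.
#' @export
whiten_cells <- function(M, spec = whiten_spec()) {
  stopifnot(inherits(spec, "WhitenSpec"))
  D <- t(M$values)                      # genes (observations) x cell lines (variables)
  n_obs <- nrow(D)
  if (n_obs < 2L) stop("need at least 2 genes to estimate the cell-line covariance")
  mu <- colMeans(D)
  Dc <- sweep(D, 2L, mu)
  Sigma <- crossprod(Dc) / (n_obs - 1)
  if (spec$ridge > 0) Sigma <- Sigma + diag(spec$ridge, nrow(Sigma))
  W <- switch(spec$method,
    cholesky = {
      ch <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(ch)) stop("cell-line covariance is not positive definite; set a positive ridge in whiten_spec()")
      # convention: Sigma^-1 = L L' with L lower triangular, W = L'
      chol(chol2inv(ch))
    },
    pca = pca_whitener(Sigma, zca = FALSE),
    zca = pca_whitener(Sigma, zca = TRUE))
  Dw <- Dc %*% t(W)
  vals <- t(Dw)
  dimnames(vals) <- dimnames(M$values)
  new_omics_matrix(vals, M$genes, M$kind)
}

pca_whitener <- function(Sigma, zca) {
  e <- eigen(Sigma, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values)) {
    stop("cell-line covariance is (near) singular; set a positive ridge in whiten_spec()")
  }
  U <- e$vectors
  # deterministic eigenvector signs: largest-|.| component positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  W <- diag(1 / sqrt(e$values), length(e$values)) %*% t(U)
  if (zca) W <- U %*% W
  W
}
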