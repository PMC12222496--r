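test_that("cross correlation recovers exact linear relationships", {
  p <- tiny_pair()
  expr <- p$expr
  eff <- p$eff
  eff$values[, 1] <- 2 * expr$values[, 1] + 3        # positive affine map
  eff$values[, 2] <- -expr$values[, 2]
  A <- cross_correlation(expr, eff)
  expect_equal(A["G1", "G1"], 1)
  expect_equal(A["G2", "G2"], -1)
  expect_true(all(abs(A) <= 1 + 1e-12))
})

test_that("constant columns correlate as zero with a warning", {
  p <- tiny_pair()
  p$expr$values[, 3] <- 7
  expect_warning(A <- cross_correlation(p$expr, p$eff), "constant")
  expect_true(all(A["G3", ] == 0))
})

test_that("unharmonized or tiny inputs are rejected", {
  p <- tiny_pair()
  shuffled <- p$eff
  shuffled$values <- shuffled$values[rev(seq_len(nrow(shuffled$values))), ]
  expect_error(cross_correlation(p$expr, shuffled), "not harmonized")
  small <- tiny_pair(n_cells = 2)
  expect_error(cross_correlation(small$expr, small$eff), "at least 3")
})

test_that("blockwise cross correlation equals the one-shot computation", {
  p <- tiny_pair(n_cells = 40, seed = 3)
  full <- cross_correlation(p$expr, p$eff)
  blocked <- cross_correlation(p$expr, p$eff, block_size = 2)
  expect_equal(unclass(blocked), unclass(full), tolerance = 1e-10)
})

test_that("spearman is invariant under strictly monotone transforms", {
  p <- tiny_pair(n_cells = 25, seed = 9)
  base <- cross_correlation(p$expr, p$eff, "spearman")
  warped <- p$expr
  warped$values[, 1] <- exp(warped$values[, 1])
  warped$values[, 2] <- warped$values[, 2]^3
  again <- cross_correlation(warped, p$eff, "spearman")
  expect_equal(unclass(again), unclass(base), tolerance = 1e-12)
})

test_that("self correlation is symmetric with unit diagonal", {
  p <- tiny_pair(n_cells = 20, seed = 2)
  co <- self_correlation(p$expr)
  expect_equal(co, t(co))
  expect_equal(unname(diag(co)), rep(1, ncol(co)))
  dup <- p$expr
  dup$values[, 2] <- 2 * dup$values[, 1] + 1
  co2 <- self_correlation(dup)
  expect_equal(co2["G1", "G2"], 1)
})

test_that("linreg scores match per-pair lm() with a lineage covariate", {
  set.seed(21)
  n <- 40
  cells <- sprintf("c%02d", 1:n)
  lin <- rep(c("lung", "skin", "cns"), length.out = n)
  expr <- omat(matrix(rnorm(n * 2, 5), n, 2, dimnames = list(cells, c("G1", "G2"))))
  eff <- omat(matrix(rnorm(n * 2), n, 2, dimnames = list(cells, c("E1", "E2"))))
  eff$values[, 1] <- 0.8 * expr$values[, 1] - 0.3 * (lin == "skin") + rnorm(n, sd = 0.4)
  meta <- data.frame(cell_line_id = cells, lineage = lin,
                     growth_pattern = "adherent", stringsAsFactors = FALSE)
  S <- linreg_scores(expr, eff, meta, covariate = "lineage")
  for (i in 1:2) for (j in 1:2) {
    fit <- summary(lm(eff$values[, j] ~ expr$values[, i] + factor(lin)))
    coefr <- fit$coefficients[2, ]
    expected <- sign(coefr["Estimate"]) * -log10(coefr["Pr(>|t|)"])
    expect_equal(unname(S[i, j]), unname(expected), tolerance = 1e-8)
  }
  expect_gt(S["G1", "E1"], 5)
})

test_that("linreg direction follows the slope sign", {
  set.seed(5)
  n <- 60
  cells <- sprintf("c%02d", 1:n)
  expr <- omat(matrix(rnorm(n, 5), n, 1, dimnames = list(cells, "G1")))
  eff <- omat(matrix(0, n, 2, dimnames = list(cells, c("POS", "NEG"))))
  eff$values[, "POS"] <- 2 * expr$values[, 1] + rnorm(n, sd = 0.1)
  eff$values[, "NEG"] <- -2 * expr$values[, 1] + rnorm(n, sd = 0.1)
  S <- linreg_scores(expr, eff, covariate = "none")
  expect_gt(S["G1", "POS"], 10)
  expect_lt(S["G1", "NEG"], -10)
})

test_that("null linreg scores stay small, matching p-value uniformity", {
  # 1000 independent null pairs at n = 100: |score| > 2 means p < 0.01,
  # so about 1% of pairs may exceed it
  set.seed(77)
  n <- 100
  cells <- sprintf("c%03d", 1:n)
  expr <- omat(matrix(rnorm(n * 40), n, 40,
                      dimnames = list(cells, sprintf("G%02d", 1:40))))
  eff <- omat(matrix(rnorm(n * 25), n, 25,
                     dimnames = list(cells, sprintf("E%02d", 1:25))))
  S <- linreg_scores(expr, eff, covariate = "none")
  expect_gte(mean(abs(S) < 2), 0.97)
  expect_lte(mean(abs(S) < 2), 1.0)
})

test_that("linreg with no covariate ranks like |r| and flags collinearity", {
  p <- tiny_pair(n_cells = 35, seed = 13)
  S <- linreg_scores(p$expr, p$eff, covariate = "none")
  A <- cross_correlation(p$expr, p$eff)
  expect_equal(order(abs(as.vector(S))), order(abs(as.vector(unclass(A)))))
  expect_equal(sign(as.vector(S)), sign(as.vector(unclass(A))))

  const <- p$expr
  const$values[, 1] <- 4
  expect_warning(S2 <- linreg_scores(const, p$eff, covariate = "none"), "collinear")
  expect_true(all(S2["G1", ] == 0))
})

test_that("global z-standardization has the documented exact behaviour", {
  A <- matrix(c(-1, 1), 1, 2)
  z <- zscore_global(A)
  expect_equal(as.vector(z), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  B <- rand_assoc(6, 5, seed = 8)
  zb <- zscore_global(B)
  expect_lt(abs(mean(zb)), 1e-12)
  expect_equal(sd(as.vector(zb)), 1, tolerance = 1e-12)
  expect_equal(zscore_global(3 * B + 2), zb, tolerance = 1e-12)
  expect_error(zscore_global(matrix(0.4, 3, 3)), "zero variance")
  expect_error(zscore_global(matrix(1, 1, 1)), "at least 2")
})
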