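test_that("top pairs rank by score with original-coefficient tie-breaks", {
  B <- matrix(c(0.9, 0.5, 0.5, 0.1), 2, 2,
              dimnames = list(c("A", "B"), c("X", "Y")))
  A0 <- matrix(c(0.9, 0.3, 0.8, 0.1), 2, 2, dimnames = dimnames(B))
  preds <- top_pairs(B, A0, 3)
  expect_equal(preds$rank, 1:3)
  expect_equal(preds$buffering_gene[1], "A")
  # score tie at 0.5: original_r 0.8 (A,Y) beats 0.3 (B,X)
  expect_equal(preds$buffering_gene[2], "A")
  expect_equal(preds$buffered_gene[2], "Y")
  expect_equal(preds$buffering_gene[3], "B")
  expect_equal(preds$score, c(0.9, 0.5, 0.5))

  expect_equal(nrow(top_pairs(B, A0, 0)), 0L)
  expect_warning(all4 <- top_pairs(B, A0, 10), "exceeds")
  expect_equal(nrow(all4), 4L)
  # with B = A0, ranking is by the coefficient itself
  ident <- top_pairs(A0, A0, 4)
  expect_equal(ident$score, ident$original_r)
  expect_equal(ident$score, sort(as.vector(A0), decreasing = TRUE))
})

test_that("full score ties resolve lexicographically and deterministically", {
  B <- matrix(0.5, 2, 2, dimnames = list(c("B", "A"), c("Y", "X")))
  preds <- top_pairs(B, B, 4)
  expect_equal(preds$buffering_gene, c("A", "A", "B", "B"))
  expect_equal(preds$buffered_gene, c("X", "Y", "X", "Y"))
})

test_that("diversity index matches its defining hand examples", {
  many <- ranked_preds(sprintf("A%03d", 1:100), sprintf("B%03d", 1:100))
  expect_equal(diversity_index(many), 1)

  hub <- ranked_preds(rep("HUB", 100), sprintf("B%03d", 1:100))
  expect_equal(diversity_index(hub), 0.01)

  mixed <- ranked_preds(c("A", "A", "A", "E"), c("B", "C", "D", "F"))
  expect_equal(diversity_index(mixed), 0.5)
  expect_error(diversity_index(ranked_preds(character(), character())))
})

test_that("proximity flags follow arm scope and the strict distance boundary", {
  ann <- data.frame(gene = c("P1", "P2", "P3", "P4", "P5"),
                    chromosome = c("chr1", "chr1", "chr2", "chr1", "chr1"),
                    arm = c("p", "p", "p", "p", "q"),
                    start_bp = 1, end_bp = 1,
                    midpoint_bp = c(5e6, 14e6, 14e6, 15e6, 6e6),
                    stringsAsFactors = FALSE)
  preds <- ranked_preds(c("P1", "P1", "P1", "P1"), c("P2", "P3", "P4", "P5"))
  out <- flag_proximal(preds, ann)
  expect_equal(baconet:::has_flag(out$flags, "proximal"),
               c(TRUE,   # 9 Mbp apart, same arm
                 FALSE,  # other chromosome
                 FALSE,  # exactly 10 Mbp: strict boundary
                 FALSE)) # same chromosome, different arm
  # chromosome scope ignores the arm split
  out2 <- flag_proximal(preds, ann, scope = "chromosome")
  expect_true(baconet:::has_flag(out2$flags, "proximal")[4])
  # flagging is symmetric in the two genes
  sw <- flag_proximal(ranked_preds("P2", "P1"), ann)
  expect_true(baconet:::has_flag(sw$flags, "proximal"))
  expect_warning(flag_proximal(ranked_preds("P1", "NOPE"), ann), "unannotated")
})

test_that("co-expression FP flags respect rank order and the z threshold", {
  genes <- c("P1", "P2", "P3")
  co <- diag(3)
  dimnames(co) <- list(genes, genes)
  co["P1", "P2"] <- co["P2", "P1"] <- 0.95
  co["P1", "P3"] <- co["P3", "P1"] <- 0.05
  co["P2", "P3"] <- co["P3", "P2"] <- -0.1
  preds <- ranked_preds(c("P1", "P3", "P2"), c("G", "G", "G"))
  # standardization population: off-diagonal coefficients {0.95, 0.05, -0.1}
  vals <- c(0.95, 0.05, -0.1)
  z_p1p2 <- (0.95 - mean(vals)) / sd(vals)
  expect_gt(z_p1p2, 1)  # the only high co-expression in the population
  out <- coexpression_fp_flags(preds, co, z_threshold = 1)
  expect_equal(baconet:::has_flag(out$flags, "coexpression_fp"),
               c(FALSE, FALSE, TRUE))  # P2 co-expressed with higher-ranked P1
  out2 <- coexpression_fp_flags(preds, co, z_threshold = 10)
  expect_false(any(baconet:::has_flag(out2$flags, "coexpression_fp")))
  single <- coexpression_fp_flags(ranked_preds("P1", "H"), co)
  expect_false(any(baconet:::has_flag(single$flags, "coexpression_fp")))
  expect_error(coexpression_fp_flags(ranked_preds("ZZ", "G"), co), "cover")
})

test_that("TP/FP labeling combines reference sets, self-addictions and flags", {
  ann <- data.frame(gene = c("A", "B", "C", "D"), chromosome = "chr1",
                    arm = "p", start_bp = 1, end_bp = 1,
                    midpoint_bp = c(1e6, 5e6, 80e6, 95e6),
                    stringsAsFactors = FALSE)
  preds <- ranked_preds(c("G", "A", "C"), c("G", "B", "D"))
  tp <- list(make_pair_set("Q", "R", "ref"))
  out <- suppressWarnings(label_tp_fp(preds, tp, ann = ann))  # G unannotated
  expect_equal(out$label, c("TP",        # self-addiction
                            "FP",        # proximal 4 Mbp, not in any TP set
                            "unlabeled")) # 15 Mbp apart, no flags
  # membership in a TP set overrides the proximity flag
  tp2 <- list(make_pair_set("A", "B", "ref"))
  out2 <- suppressWarnings(label_tp_fp(preds, tp2, ann = ann))
  expect_equal(out2$label[2], "TP")
  expect_true(baconet:::has_flag(out2$flags[2], "proximal"))
})

test_that("cumulative FDR follows FP/(FP+TP) with unlabeled pairs excluded", {
  preds <- ranked_preds(letters[1:5], LETTERS[1:5],
                        label = c("TP", "FP", "TP", "unlabeled", "FP"))
  expect_equal(cumulative_fdr(preds), c(0, 1/2, 1/3, 1/3, 2/4))
  allt <- ranked_preds(letters[1:3], LETTERS[1:3], label = "TP")
  expect_equal(cumulative_fdr(allt), c(0, 0, 0))
  none <- ranked_preds("a", "A", label = "unlabeled")
  expect_equal(cumulative_fdr(none), 0)
  # appending an FP never decreases the FDR, values stay in [0, 1]
  mix <- ranked_preds(letters[1:6], LETTERS[1:6],
                      label = c("FP", "TP", "unlabeled", "FP", "TP", "FP"))
  f <- cumulative_fdr(mix)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(f[mix$label == "FP"] >=
                  c(0, f[which(mix$label == "FP")[-1] - 1])))
})

test_that("low-z counts census the transformation strength thresholds", {
  preds <- ranked_preds(letters[1:4], LETTERS[1:4],
                        z = c(4, 3.5, -0.5, 2.2))
  expect_equal(low_z_counts(preds),
               c(z_lt_0 = 1L, z_lt_1 = 1L, z_lt_2 = 1L, z_lt_3 = 2L))
  high <- ranked_preds(letters[1:2], LETTERS[1:2], z = c(5, 4))
  expect_equal(unname(low_z_counts(high)), rep(0L, 4))
  expect_length(low_z_counts(preds, numeric()), 0)
})

test_that("set enrichment matches hypergeometric closed forms", {
  ref <- make_pair_set(paste0("a", 1:5), paste0("b", 1:5), "ref")
  hit5 <- ranked_preds(paste0("a", 1:5), paste0("b", 1:5))
  enr <- set_enrichment(hit5, ref, universe_pairs = 10, universe_ref_pairs = 5)
  expect_equal(enr$count, 5L)
  expect_equal(enr$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(enr$fold_change, 2)

  miss <- ranked_preds(paste0("x", 1:5), paste0("y", 1:5))
  enr0 <- set_enrichment(miss, ref, 10, 5)
  expect_equal(enr0$count, 0L)
  expect_equal(enr0$fold_change, 0)
  expect_equal(enr0$p_value, 1)

  # density equal in draw and universe -> fold change 1
  one <- ranked_preds(c("a1", "x1"), c("b1", "y1"))
  expect_equal(set_enrichment(one, ref, 10, 5)$fold_change, 1)
  expect_error(set_enrichment(one, ref, 10, 0), "undefined")

  # exact enumeration oracle on a small universe
  exact_upper <- function(count, K, Nu, n) {
    sum(vapply(count:min(K, n), function(k)
      choose(K, k) * choose(Nu - K, n - k), numeric(1))) / choose(Nu, n)
  }
  expect_equal(set_enrichment(hit5[1:3, ], ref, 12, 5)$p_value,
               exact_upper(3, 5, 12, 3), tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.5, 4)), rep(0.5, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("chromosome pair density conserves counts and flags concentration", {
  ann <- data.frame(gene = c(paste0("A", 1:4), paste0("B", 1:4)),
                    chromosome = rep(c("chr1", "chr2"), each = 4),
                    arm = "p", start_bp = 1, end_bp = 1, midpoint_bp = 1,
                    stringsAsFactors = FALSE)
  preds <- ranked_preds(paste0("A", 1:4), paste0("B", 1:4))
  tab <- chromosome_pair_density(preds, ann)
  expect_equal(sum(tab$observed), 4L)
  cell <- tab[tab$buffering_chrom == "chr1" & tab$buffered_chrom == "chr2", ]
  expect_equal(cell$observed, 4L)
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))
})

test_that("uniform chromosome placement rarely yields significant density cells", {
  hits <- 0L
  for (s in 1:20) {
    ab <- baconet:::with_seed(600 + s, {
      list(a = sample(paste0("chr", 1:4), 40, replace = TRUE),
           b = sample(paste0("chr", 1:4), 40, replace = TRUE))
    })
    genes_a <- sprintf("A%02d", 1:40); genes_b <- sprintf("B%02d", 1:40)
    ann <- data.frame(gene = c(genes_a, genes_b),
                      chromosome = c(ab$a, ab$b), arm = "p",
                      start_bp = 1, end_bp = 1, midpoint_bp = 1,
                      stringsAsFactors = FALSE)
    tab <- chromosome_pair_density(ranked_preds(genes_a, genes_b), ann)
    if (any(tab$q_value < 0.05)) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("delta LFC arithmetic and the strict hit boundary", {
  out <- delta_lfc(c(-3, -1, -2.5), c(-1, -0.5, -1), c(-0.5, -0.5, -0.5))
  expect_equal(out$dlfc, c(-1.5, 0, -1))
  expect_equal(out$is_hit, c(TRUE, FALSE, FALSE))
  expect_error(delta_lfc(NA, 0, 0))
})
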