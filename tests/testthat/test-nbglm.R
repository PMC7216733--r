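# two-group toy shared by several oracle comparisons
two_group_toy <- function() {
  y <- c(12L, 18L, 15L, 40L, 35L, 52L)
  X <- cbind(Intercept = 1, group = rep(c(0, 1), each = 3))
  list(y = y, X = X, offsets = rep(0, 6), group = rep(c("a", "b"), each = 3))
}

test_that("a saturated Poisson fit reproduces the data with zero deviance", {
  y <- c(3L, 9L, 27L, 5L)
  X <- diag(4)
  f <- fit_gene_glm(y, X, offsets = rep(0, 4), phi = 0)
  expect_equal(f$mu, as.numeric(y), tolerance = 1e-6)
  expect_equal(f$deviance, 0, tolerance = 1e-8)
})

test_that("at dispersion zero the IRLS fit matches a Poisson GLM oracle", {
  tg <- two_group_toy()
  f <- fit_gene_glm(tg$y, tg$X, tg$offsets, phi = 0)
  oracle <- glm(tg$y ~ tg$X[, 2], family = poisson())
  expect_equal(unname(f$beta), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(oracle)), tolerance = 1e-6)

  # with nonzero offsets too
  off <- log(c(1, 2, 1, 3, 1, 2))
  f2 <- fit_gene_glm(tg$y, tg$X, off, phi = 0)
  oracle2 <- glm(tg$y ~ tg$X[, 2] + offset(off), family = poisson())
  expect_equal(unname(f2$beta), unname(coef(oracle2)), tolerance = 1e-6)
})

test_that("the intercept-only fit is the sample mean under equal offsets", {
  y <- c(4L, 8L, 6L, 10L)
  f <- fit_gene_glm(y, matrix(1, 4, 1), offsets = rep(0, 4), phi = 0.2)
  expect_equal(unique(round(f$mu, 8)), mean(y), tolerance = 1e-6)
})

test_that("all-zero genes get a floored fit without crashing", {
  f <- fit_gene_glm(rep(0L, 4), cbind(1, c(0, 0, 1, 1)), rep(0, 4), phi = 0.1)
  expect_false(f$converged)
  expect_true(all(f$mu < 1e-6))
})

test_that("the contrast LRT matches the closed-form Poisson oracle at phi = 0", {
  tg <- two_group_toy()
  counts <- rbind(g1 = tg$y, g2 = c(5L, 9L, 7L, 6L, 8L, 7L))
  res <- lrt_contrast(counts, tg$X, tg$offsets, dispersions = 0,
                      contrast = c(0, 1))
  for (g in 1:2) {
    lr_oracle <- oracle_poisson_lrt(counts[g, ], tg$group)
    expect_equal(res$LR[g], lr_oracle, tolerance = 1e-6)
  }
  # log2FC is the group log-ratio
  expect_equal(res$log2FC[1], log2(mean(tg$y[4:6]) / mean(tg$y[1:3])),
               tolerance = 1e-6)
})

test_that("the LRT is invariant to contrast rescaling and basis reordering", {
  set.seed(21)
  d <- table1_design()
  gd <- build_design_matrix(d)
  X <- gd$design_matrix
  counts <- random_counts(d$sample_ids, 12, mu = 300, seed = 22)
  off <- rep(log(1e4), 12)
  cs <- generate_contrasts(gd)
  cvec <- cs[["[NoSi-Si]"]]$vector

  r1 <- lrt_contrast(counts, X, off, 0.1, cvec)
  r2 <- lrt_contrast(counts, X, off, 0.1, 3.7 * cvec)
  expect_equal(r1$LR, r2$LR, tolerance = 1e-6)

  # permute the coefficient basis: same test through a different completion
  perm <- c(3, 1, 6, 2, 5, 4)
  r3 <- lrt_contrast(counts, X[, perm], off, 0.1, cvec[perm])
  expect_equal(r1$LR, r3$LR, tolerance = 1e-6)
  expect_equal(r1$log2FC, r3$log2FC, tolerance = 1e-6)

  # gene order permutation gives permuted, identical results
  gperm <- sample(nrow(counts))
  r4 <- lrt_contrast(counts[gperm, ], X, off, 0.1, cvec)
  expect_equal(r4$LR, r1$LR[gperm], tolerance = 1e-10)

  expect_error(lrt_contrast(counts, X, off, 0.1, numeric(6)), "zero")
})

test_that("a symmetric gene shows no fold-change and p near 1", {
  d <- factorial_design(2, 2, r = 3L)
  gd <- build_design_matrix(d)
  counts <- matrix(50L, 2, 12,
                   dimnames = list(c("flat1", "flat2"), d$sample_ids))
  cs <- generate_contrasts(gd)
  res <- lrt_contrast(counts, gd$design_matrix, rep(0, 12), 0.05,
                      cs[[1]])
  expect_equal(res$log2FC, c(0, 0), tolerance = 1e-6)
  expect_true(all(res$pvalue > 0.99))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(0.07, 5)), rep(0.07, 5))
  # mapped back to input order
  p <- c(0.9, 0.001, 0.04, 0.5)
  expect_equal(adjust_bh(p), p.adjust(p, "BH"))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("p-value histogram tail diagnostics flag non-uniform tails", {
  set.seed(31)
  u <- runif(2000)
  h <- pvalue_histogram(u)
  expect_identical(sum(h$counts), 2000L)
  expect_true(h$uniform_tail)

  # a 5x spike in the last bin trips the flag
  spiked <- c(runif(2000), rep(0.99, 400))
  expect_message(hs <- pvalue_histogram(spiked), "stringent")
  expect_false(hs$uniform_tail)

  # all p = 0: single spike in the first bin, empty tail is out of tolerance
  h0 <- suppressMessages(pvalue_histogram(rep(0, 500)))
  expect_identical(h0$counts[1], 500L)
  expect_false(h0$uniform_tail)
})

test_that("top DEG ordering uses p, then |log2FC|, then gene id", {
  res <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                    log2FC = c(1, -3, 2, 0.5, 2),
                    LR = 1:5, pvalue = c(0.01, 0.001, 0.001, 0.2, 0.01),
                    adj_pvalue = c(0.02, 0.004, 0.004, 0.25, 0.02),
                    deg = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  class(res) <- c("fex_contrast_test", "data.frame")
  top <- top_degs(res, k = 10)
  expect_identical(top$genes, c("g2", "g3", "g5", "g1"))
  expect_identical(top_degs(res, k = 2)$genes, c("g2", "g3"))
})
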