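unit_norm <- function(counts) {
  # a fex_norm with factors 1 for toy matrices
  structure(list(method = "TMM",
                 factors = setNames(rep(1, ncol(counts)), colnames(counts)),
                 library_sizes = colSums(counts),
                 effective_sizes = setNames(rep(1e6, ncol(counts)), colnames(counts))),
            class = "fex_norm")
}

test_that("expression profiles row-normalize and route low genes to cluster 0", {
  counts <- rbind(spike = c(0L, 900L, 0L),
                  even = c(300L, 300L, 300L),
                  low = c(1L, 2L, 0L),
                  zero = c(0L, 0L, 0L))
  colnames(counts) <- paste0("s", 1:3)
  pr <- expression_profiles(counts, unit_norm(counts), mean_filter_cutoff = 50)
  expect_identical(sort(pr$cluster0), c("low", "zero"))
  expect_equal(unname(pr$profiles["spike", ]), c(0, 1, 0))
  expect_equal(rowSums(pr$profiles), setNames(c(1, 1), c("spike", "even")),
               tolerance = 1e-10)

  # unequal factors enter the profile: hand computation
  n2 <- unit_norm(counts)
  n2$effective_sizes <- setNames(c(1e6, 2e6, 1e6), paste0("s", 1:3))
  n2$factors <- n2$effective_sizes / exp(mean(log(n2$effective_sizes)))
  pr2 <- expression_profiles(counts, n2, 50)
  s <- c(1e6, 2e6, 1e6) / mean(c(1e6, 2e6, 1e6))
  hand <- (counts["even", ] / s) / sum(counts["even", ] / s)
  expect_equal(pr2$profiles["even", ], hand, tolerance = 1e-12)

  expect_error(expression_profiles(counts[3:4, ], unit_norm(counts), 50),
               "lower the cutoff")
})

test_that("arcsine transform hits its endpoints and inverts", {
  expect_equal(arcsine_transform(matrix(c(0, 1, 0.5), 1)),
               matrix(c(0, pi / 2, pi / 4), 1))
  withr::with_seed(13, {
    p <- matrix(runif(60), 10)
    p <- p / rowSums(p)
  })
  v <- arcsine_transform(p)
  expect_equal(sin(v)^2, p, tolerance = 1e-12)
  expect_error(arcsine_transform(matrix(1.01, 1)), "\\[0, 1\\]")
})

test_that("K = 1 has the closed-form fit and ICL equals BIC", {
  withr::with_seed(17, X <- matrix(rnorm(200), 50, 4))
  m <- fit_gmm(X, K = 1, n_inits = 3, seed = 5)
  expect_equal(drop(m$means), colMeans(X), tolerance = 1e-8)
  expect_equal(m$covariances[[1]], cov(X) * 49 / 50, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(unname(m$posteriors[, 1]), rep(1, 50))
  expect_equal(m$entropy, 0)
  expect_equal(m$icl, m$bic)
  expect_equal(icl(m), m$bic, tolerance = 1e-10)
  expect_equal(m$n_params, 0 + 4 + 10)
})

test_that("EM log-likelihood is monotone and deterministic under a seed", {
  withr::with_seed(19, {
    X <- rbind(matrix(rnorm(400, 0), 100, 4),
               matrix(rnorm(400, 6), 100, 4))
  })
  m1 <- fit_gmm(X, K = 2, n_inits = 4, seed = 9)
  m2 <- fit_gmm(X, K = 2, n_inits = 4, seed = 9)
  expect_identical(m1$loglik, m2$loglik)
  expect_identical(m1$posteriors, m2$posteriors)
  expect_true(all(diff(m1$loglik_trace) > -1e-6 * (abs(m1$loglik) + 1)))

  # two 6-sigma-separated Gaussians are recovered exactly
  truth <- rep(1:2, each = 100)
  hard <- max.col(m1$posteriors)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(hard, truth), 1)
  # and our EM reaches at least mclust's VVV log-likelihood (small slack)
  withr::local_package("mclust")
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_gte(m1$loglik, mc$loglik - 1e-3 * abs(mc$loglik))
})

test_that("fit_gmm validates its inputs", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_gmm(X, K = 0), ">= 1")
  expect_error(fit_gmm(X, K = 10), "smaller than")
})

test_that("ICL equals the hand-evaluated formula and BIC for hard posteriors", {
  withr::with_seed(23, X <- rbind(matrix(rnorm(80, 0, 0.1), 20, 4),
                                  matrix(rnorm(80, 5, 0.1), 20, 4)))
  m <- fit_gmm(X, K = 2, n_inits = 3, seed = 2)
  ent_hand <- -sum(ifelse(m$posteriors > 0, m$posteriors * log(m$posteriors), 0))
  icl_hand <- -2 * m$loglik + m$n_params * log(40) + 2 * ent_hand
  expect_equal(icl(m), icl_hand, tolerance = 1e-10)
  # posteriors are essentially hard here, so ICL ~ BIC
  expect_equal(m$icl, m$bic, tolerance = 1e-4)
})

test_that("planted single-cluster data selects the smallest K with a convex curve", {
  sc <- simulate_coexpression(1, sizes = 300, n_samples = 8, seed = 51)
  norm <- tmm_factors(sc$counts)
  X <- arcsine_transform(expression_profiles(sc$counts, norm, 50)$profiles)
  sel <- suppressWarnings(select_model(X, grid = c(2L, 4L, 6L), seed = 31))
  expect_identical(sel$K, 2L)
  icl2 <- sel$icl_curve$icl[sel$icl_curve$loop == 2]
  expect_true(all(diff(icl2) > 0))
  expect_true(sel$convex)

  # bit-identical reproduction under the same seed
  sel2 <- suppressWarnings(select_model(X, grid = c(2L, 4L, 6L), seed = 31))
  expect_identical(sel$assignments, sel2$assignments)
  expect_identical(sel$icl_curve, sel2$icl_curve)
})

test_that("cluster relabeling is by decreasing size with index tie-break", {
  expect_identical(relabel_by_size(c(2L, 2L, 2L, 1L, 3L, 3L), 3L),
                   c(1L, 1L, 1L, 3L, 2L, 2L))
  # tie: clusters 1 and 2 both size 2 -> original order preserved
  expect_identical(relabel_by_size(c(1L, 1L, 2L, 2L, 3L, 3L, 3L), 3L),
                   c(2L, 2L, 3L, 3L, 1L, 1L, 1L))
})

test_that("checkpointing resumes an interrupted selection identically", {
  withr::with_seed(37, X <- rbind(matrix(rnorm(240, 0, 0.2), 30, 8),
                                  matrix(rnorm(240, 3, 0.2), 30, 8)))
  rownames(X) <- sprintf("g%03d", 1:60)
  ck <- tempfile("ckpt")
  sel1 <- suppressWarnings(select_model(X, grid = c(2L, 3L), loop1_inits = 2L,
                                        loop2_inits = 3L, seed = 41,
                                        checkpoint_dir = ck))
  # second run reuses every checkpoint file and reproduces the selection
  n_files <- length(list.files(ck))
  sel2 <- suppressWarnings(select_model(X, grid = c(2L, 3L), loop1_inits = 2L,
                                        loop2_inits = 3L, seed = 41,
                                        checkpoint_dir = ck))
  expect_identical(length(list.files(ck)), n_files)
  expect_identical(sel1$assignments, sel2$assignments)
})

test_that("the coexpression wrapper labels every gene exactly once", {
  sc <- simulate_coexpression(3, sizes = 40, n_samples = 6, seed = 43)
  counts <- rbind(sc$counts,
                  lowg = rep(1L, 6))
  norm <- unit_norm(counts)
  norm$effective_sizes <- setNames(rep(1, 6), colnames(counts))
  cx <- suppressWarnings(coexpression(counts, norm, mean_filter_cutoff = 50,
                                      grid = c(2L, 3L, 4L), loop1_inits = 2L,
                                      loop2_inits = 4L, seed = 47))
  expect_identical(sort(names(cx$assignments)), sort(rownames(counts)))
  expect_identical(unname(cx$assignments["lowg"]), 0L)
  expect_identical(sum(cx$assignments == 0), length(cx$cluster0))
  expect_true(all(cx$assignments %in% 0:cx$selection$K))
})
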