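# Negative-binomial GLM machinery: per-gene IRLS fits, Cox-Reid adjusted
# profile likelihood for dispersion, and likelihood-ratio contrast tests.
# Variance parameterization throughout: Var(y) = mu + phi * mu^2.

nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-12)
  if (phi < 1e-10) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-12)
  if (phi < 1e-10) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  } else {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) -
              (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  }
}

#' Fit the NB GLM for one gene
#'
#' Iteratively reweighted least squares for a negative-binomial GLM with
#' log link and fixed dispersion. Weights are the Fisher weights
#' `mu/(1 + phi*mu)`. Convergence when the relative deviance change drops
#' below `tol` (default 1e-8) or after `max_iter` iterations, with
#' step-halving on any deviance increase, a 1e-10 ridge on the normal
#' equations and coefficients clipped to `|beta| <= 50`. All-zero genes get
#' the intercept at the clip floor with `converged = FALSE`.
#'
#' @param y Integer counts, one per sample.
#' @param X Design matrix (samples x coefficients).
#' @param offsets Per-sample log effective library sizes.
#' @param phi Dispersion (>= 0).
#' @param beta_init Optional warm start.
#' @param tol,max_iter Convergence controls.
#' @return List: `beta`, `mu`, `deviance`, `loglik`, `converged`, `iter`.
#' @export
fit_gene_glm <- function(y, X, offsets, phi, beta_init = NULL,
                         tol = 1e-8, max_iter = 100L) {
  if (any(!is.finite(X))) stop_fex("non-finite design entries")
  if (any(!is.finite(offsets))) stop_fex("offsets must be finite")
  if (phi < 0) stop_fex("dispersion must be >= 0")
  p <- ncol(X)
  if (all(y == 0)) {
    beta <- c(-50, numeric(p - 1L))
    mu <- exp(offsets + drop(X %*% beta))
    return(list(beta = beta, mu = mu, deviance = nb_deviance(y, mu, phi),
                loglik = nb_loglik(y, mu, phi), converged = FALSE, iter = 0L))
  }
  ridge <- diag(1e-10, p)
  if (is.null(beta_init)) {
    mu <- pmax((y + mean(y)) / 2, 1e-4)
    eta <- log(mu) - offsets
  } else {
    beta <- pmin(pmax(beta_init, -50), 50)
    eta <- drop(X %*% beta)
    mu <- exp(eta + offsets)
  }
  beta <- beta_init
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- eta + (y - mu) / mu
    XtW <- t(X * w)
    beta_new <- tryCatch(drop(solve(XtW %*% X + ridge, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- pmin(pmax(beta_new, -50), 50)
    # step-halving if the deviance went up
    step <- 1
    repeat {
      cand <- if (is.null(beta)) beta_new else beta + step * (beta_new - beta)
      cand <- pmin(pmax(cand, -50), 50)
      eta_c <- drop(X %*% cand)
      mu_c <- pmax(exp(eta_c + offsets), 1e-12)
      dev_c <- nb_deviance(y, mu_c, phi)
      if (is.finite(dev_c) && (dev_c <= dev + 1e-12 || step < 1e-4 || is.null(beta))) break
      step <- step / 2
    }
    beta <- cand; eta <- eta_c; mu <- mu_c
    if (is.finite(dev) && abs(dev - dev_c) < tol * (abs(dev_c) + 0.1)) {
      dev <- dev_c; converged <- TRUE; break
    }
    dev <- dev_c
  }
  list(beta = beta, mu = mu, deviance = dev,
       loglik = nb_loglik(y, mu, phi), converged = converged, iter = it)
}

# fit every gene; phis recycled; returns matrices
fit_all_genes <- function(counts, X, offsets, phis, beta_init = NULL) {
  G <- nrow(counts)
  phis <- rep_len(phis, G)
  p <- ncol(X)
  beta <- matrix(NA_real_, G, p, dimnames = list(rownames(counts), colnames(X)))
  mu <- matrix(NA_real_, G, ncol(X) * 0 + length(offsets))
  ll <- dev <- numeric(G)
  conv <- logical(G)
  for (g in seq_len(G)) {
    f <- fit_gene_glm(counts[g, ], X, offsets, phis[g],
                      beta_init = if (is.null(beta_init)) NULL else beta_init[g, ])
    beta[g, ] <- f$beta; mu[g, ] <- f$mu
    ll[g] <- f$loglik; dev[g] <- f$deviance; conv[g] <- f$converged
  }
  list(beta = beta, mu = mu, loglik = ll, deviance = dev, converged = conv)
}

# Cox-Reid adjusted profile log-likelihood of phi for one gene, at the
# IRLS fit: ll(beta_hat, phi) - 0.5 * logdet(X' W X)
gene_apl <- function(y, X, offsets, phi, beta_init = NULL) {
  f <- fit_gene_glm(y, X, offsets, phi, beta_init = beta_init)
  w <- f$mu / (1 + phi * f$mu)
  info <- crossprod(X * sqrt(w)) + diag(1e-10, ncol(X))
  ld <- determinant(info, logarithm = TRUE)$modulus
  f$loglik - 0.5 * as.numeric(ld)
}

apl_default_grid <- function(n = 19L) exp(seq(log(1e-4), log(10), length.out = n))

# genes x grid matrix of APL values
apl_grid_matrix <- function(counts, X, offsets, grid) {
  G <- nrow(counts)
  out <- matrix(NA_real_, G, length(grid))
  for (g in seq_len(G)) {
    init <- NULL
    for (i in seq_along(grid)) {
      f <- fit_gene_glm(counts[g, ], X, offsets, grid[i], beta_init = init)
      init <- f$beta
      w <- f$mu / (1 + grid[i] * f$mu)
      info <- crossprod(X * sqrt(w)) + diag(1e-10, ncol(X))
      out[g, i] <- f$loglik -
        0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
    }
  }
  out
}

#' Estimate the common NB dispersion
#'
#' Maximizes the sum over genes of the Cox-Reid adjusted profile
#' log-likelihood over a log-spaced grid on `[1e-4, 10]`, refined by
#' golden-section search around the best grid point. Deterministic.
#'
#' @param counts Genes x samples count matrix.
#' @param X Design matrix.
#' @param offsets Log effective library sizes.
#' @param grid Dispersion grid (log-spaced by default).
#' @return List: `phi` (the estimate), `grid`, `apl` (genes x grid APL
#'   matrix, reusable by [estimate_tagwise_dispersions()]).
#' @export
estimate_common_dispersion <- function(counts, X, offsets,
                                       grid = apl_default_grid()) {
  if (nrow(X) - ncol(X) < 1L)
    stop_fex("no residual degrees of freedom; use a simpler model")
  aplmat <- apl_grid_matrix(counts, X, offsets, grid)
  total <- colSums(aplmat)
  i <- which.max(total)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  obj <- function(lphi) {
    phi <- exp(lphi)
    sum(vapply(seq_len(nrow(counts)), function(g)
      gene_apl(counts[g, ], X, offsets, phi), numeric(1)))
  }
  op <- stats::optimize(obj, lower = log(lo), upper = log(hi), maximum = TRUE,
                        tol = 1e-4)
  phi <- exp(op$maximum)
  if (op$objective < total[i]) phi <- grid[i]
  list(phi = phi, grid = grid, apl = aplmat)
}

#' Estimate shrunken per-gene dispersions
#'
#' Empirical-Bayes shrinkage of gene-wise dispersions toward the common
#' value: each gene maximizes its own Cox-Reid adjusted profile
#' log-likelihood plus `prior_df / df_residual` times the across-gene
#' average APL (whose maximizer is the common dispersion). `prior_df = 0`
#' gives the unshrunken per-gene maximizer; `prior_df = Inf` returns the
#' common dispersion for every gene.
#'
#' @param counts,X,offsets As in [estimate_common_dispersion()].
#' @param common Result of [estimate_common_dispersion()] (reused grid), or
#'   `NULL` to compute it.
#' @param prior_df Prior degrees of freedom (default 10).
#' @return Numeric vector of per-gene dispersions.
#' @export
estimate_tagwise_dispersions <- function(counts, X, offsets, common = NULL,
                                         prior_df = 10) {
  if (prior_df < 0) stop_fex("prior_df must be >= 0")
  if (is.null(common)) common <- estimate_common_dispersion(counts, X, offsets)
  G <- nrow(counts)
  if (is.infinite(prior_df)) return(rep(common$phi, G))
  grid <- common$grid
  df_res <- nrow(X) - ncol(X)
  wshrink <- prior_df / df_res
  avg <- colMeans(common$apl)
  avg_fun <- stats::splinefun(log(grid), avg, method = "natural")
  phis <- numeric(G)
  for (g in seq_len(G)) {
    score <- common$apl[g, ] + wshrink * avg
    i <- which.max(score)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    obj <- function(lphi)
      gene_apl(counts[g, ], X, offsets, exp(lphi)) + wshrink * avg_fun(lphi)
    op <- stats::optimize(obj, lower = log(lo), upper = log(hi), maximum = TRUE,
                          tol = 1e-4)
    phis[g] <- if (op$objective >= score[i]) exp(op$maximum) else grid[i]
  }
  stats::setNames(phis, rownames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()] after domain
#' checks).
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
adjust_bh <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop_fex("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# orthonormal completion of a contrast vector: columns span its orthogonal
# complement, so X %*% B is the null design under c' beta = 0
null_space_completion <- function(cvec) {
  if (all(cvec == 0)) stop_fex("contrast vector is zero")
  Q <- qr.Q(qr(matrix(cvec, ncol = 1L)), complete = TRUE)
  Q[, -1L, drop = FALSE]
}

#' Likelihood-ratio test of one contrast across all genes
#'
#' The design is reparametrized so the contrast is a single coefficient
#' (orthonormal completion of the contrast vector); the full and the
#' contrast-constrained null model are fitted by IRLS with the per-gene
#' dispersions held fixed, and twice the log-likelihood difference is
#' referred to a chi-square with 1 degree of freedom. BH adjustment is
#' applied across genes within the contrast.
#'
#' @param counts Genes x samples count matrix.
#' @param X Design matrix.
#' @param offsets Log effective library sizes.
#' @param dispersions Scalar or per-gene dispersions (held fixed).
#' @param contrast A `fex_contrast` or a bare coefficient vector.
#' @param alpha DEG-calling level on the adjusted p-value (default 0.05).
#' @param full_fit Optional precomputed result of the full-model fits.
#' @return A `fex_contrast_test` data frame: `gene`, `log2FC`, `LR`,
#'   `pvalue`, `adj_pvalue`, `deg`.
#' @export
lrt_contrast <- function(counts, X, offsets, dispersions, contrast,
                         alpha = 0.05, full_fit = NULL) {
  cvec <- if (inherits(contrast, "fex_contrast")) contrast$vector else contrast
  if (length(cvec) != ncol(X)) stop_fex("contrast length does not match design")
  if (all(cvec == 0)) stop_fex("contrast vector is zero")
  # estimability: c must lie in the row space of X
  P <- qr(t(X))
  resid_c <- cvec - qr.fitted(P, cvec)
  if (sqrt(sum(resid_c^2)) > 1e-8 * max(1, sqrt(sum(cvec^2))))
    stop_fex("contrast is not estimable under this design")
  G <- nrow(counts)
  phis <- rep_len(dispersions, G)
  if (is.null(full_fit)) full_fit <- fit_all_genes(counts, X, offsets, phis)
  B <- null_space_completion(cvec)
  X0 <- X %*% B
  ll0 <- numeric(G)
  for (g in seq_len(G)) {
    f0 <- fit_gene_glm(counts[g, ], X0, offsets, phis[g],
                       beta_init = drop(crossprod(B, full_fit$beta[g, ])))
    ll0[g] <- f0$loglik
  }
  lr <- 2 * (full_fit$loglik - ll0)
  lr <- pmax(lr, 0)                    # clip tiny negative numerical slack
  pv <- stats::pchisq(lr, df = 1L, lower.tail = FALSE)
  adj <- adjust_bh(pv)
  res <- data.frame(gene = rownames(counts),
                    log2FC = drop(full_fit$beta %*% cvec) / log(2),
                    LR = lr, pvalue = pv, adj_pvalue = adj,
                    deg = adj <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("fex_contrast_test", "data.frame")
  attr(res, "alpha") <- alpha
  res
}

#' Raw p-value histogram diagnostic
#'
#' Fixed-width right-closed bins on `[0, 1]`. The `uniform_tail` flag is
#' true iff each of the last four bins is within `3 * sqrt(m / n_bins)` of
#' the uniform expectation `m / n_bins`; a false flag is the standard sign
#' of insufficient low-count filtering and triggers advice to refilter with
#' a more stringent CPM cutoff.
#'
#' @param pvals Raw p-values.
#' @param n_bins Number of bins (default 20).
#' @return A `fex_pdiag` list: `counts`, `breaks`, `uniform_tail`.
#' @export
pvalue_histogram <- function(pvals, n_bins = 20L) {
  if (!length(pvals)) stop_fex("no p-values supplied")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- graphics::hist(pvals, breaks = breaks, plot = FALSE, right = TRUE,
                      include.lowest = TRUE)
  m <- length(pvals)
  expect <- m / n_bins
  tail_bins <- h$counts[(n_bins - 3L):n_bins]
  flag <- all(abs(tail_bins - expect) <= 3 * sqrt(expect))
  if (!flag)
    message("p-value histogram tail departs from uniform; consider repeating ",
            "the analysis with a more stringent filtering cut-off")
  structure(list(counts = h$counts, breaks = breaks, uniform_tail = flag),
            class = "fex_pdiag")
}

#' Top differentially expressed genes
#'
#' Orders a contrast result by raw p-value (ties broken by decreasing
#' absolute log2 fold-change, then gene id) and returns the top `k` DEGs
#' together with the normalized log2-expression submatrix used for the
#' Ward/Euclidean heat map.
#'
#' @param result A `fex_contrast_test`.
#' @param k Number of genes (default 50).
#' @param norm_log_expr Optional genes x samples matrix of
#'   `log2(normalized count + 1)` to subset for clustering input.
#' @param degs_only Restrict to flagged DEGs (default TRUE).
#' @return List: `genes` (ordered ids) and `matrix` (possibly `NULL`).
#' @export
top_degs <- function(result, k = 50L, norm_log_expr = NULL, degs_only = TRUE) {
  if (k < 1L) stop_fex("k must be >= 1")
  r <- if (degs_only) result[result$deg, , drop = FALSE] else result
  ord <- order(r$pvalue, -abs(r$log2FC), r$gene)
  genes <- utils::head(r$gene[ord], k)
  mat <- if (!is.null(norm_log_expr) && length(genes))
    norm_log_expr[genes, , drop = FALSE] else NULL
  list(genes = genes, matrix = mat)
}
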