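# Gaussian-mixture co-expression on arcsine-transformed normalized
# expression profiles, with a two-loop small-EM strategy and ICL model
# selection. Full (unequal-proportion, general-covariance) components.

#' Normalized expression profiles
#'
#' Scales counts by the per-sample effective-size factor (rescaled to mean
#' 1, so normalized counts keep the count scale), sends genes whose mean
#' normalized count falls below `mean_filter_cutoff` to Cluster 0, and
#' row-normalizes the remaining genes so each profile sums to 1. Genes with
#' all-zero counts always go to Cluster 0.
#'
#' @param counts Genes x samples count matrix (already subset to the gene
#'   list of interest, e.g. a union of DEG lists).
#' @param norm A `fex_norm` for the same samples.
#' @param mean_filter_cutoff Minimum mean normalized count (default 50).
#' @return List: `profiles` (rows sum to 1), `cluster0` (filtered gene
#'   ids), `mean_normalized` (per-gene means).
#' @export
expression_profiles <- function(counts, norm, mean_filter_cutoff = 50) {
  if (!nrow(counts)) stop_fex("empty gene list")
  if (!identical(colnames(counts), names(norm$factors)))
    stop_fex("normalization result does not match the count columns")
  s <- norm$effective_sizes / mean(norm$effective_sizes)
  normed <- sweep(counts, 2L, s, "/")
  mean_norm <- rowMeans(normed)
  low <- mean_norm < mean_filter_cutoff | rowSums(counts) == 0
  if (all(low))
    stop_fex("all %d genes fall below the mean normalized count cutoff (%g); lower the cutoff",
             nrow(counts), mean_filter_cutoff)
  kept <- normed[!low, , drop = FALSE]
  profiles <- kept / rowSums(kept)
  list(profiles = profiles, cluster0 = rownames(counts)[low],
       mean_normalized = mean_norm)
}

#' Arcsine square-root transform of profiles
#'
#' `v = arcsin(sqrt(p))`, mapping `[0, 1]` to `[0, pi/2]`; the variance-
#' stabilizing transform for proportions. Entries outside `[0, 1]` by more
#' than 1e-12 are an error; smaller excursions are clipped.
#'
#' @param profiles Matrix with entries in `[0, 1]`.
#' @return Transformed matrix of the same shape.
#' @export
arcsine_transform <- function(profiles) {
  if (any(profiles < -1e-12 | profiles > 1 + 1e-12))
    stop_fex("profile entries must lie in [0, 1]")
  asin(sqrt(pmin(pmax(profiles, 0), 1)))
}

# log densities: n x K matrix of log(pi_k N(x | mu_k, Sigma_k))
gmm_log_component_dens <- function(X, model) {
  n <- nrow(X); d <- ncol(X); K <- length(model$proportions)
  out <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    U <- model$chol[[k]]
    z <- backsolve(U, t(X) - model$means[k, ], transpose = TRUE)
    out[, k] <- log(model$proportions[k]) -
      0.5 * (d * log(2 * pi) + 2 * sum(log(diag(U))) + colSums(z^2))
  }
  out
}

# regularize a covariance until Cholesky succeeds; per the module contract
# the diagonal is inflated by 1e-6 * trace / d (escalating tenfold)
safe_chol <- function(S) {
  d <- ncol(S)
  U <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(U)) return(list(U = U, S = S))
  bump <- 1e-6 * sum(diag(S)) / d
  if (bump <= 0 || !is.finite(bump)) bump <- 1e-8
  for (i in 0:12) {
    Sr <- S + diag(bump * 10^i, d)
    U <- tryCatch(chol(Sr), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, S = Sr))
  }
  stop_fex("covariance regularization failed")
}

gmm_mstep <- function(X, tau) {
  n <- nrow(X); d <- ncol(X); K <- ncol(tau)
  nk <- colSums(tau)
  nk <- pmax(nk, 1e-10)
  proportions <- nk / sum(nk)
  means <- matrix(NA_real_, K, d)
  covs <- chols <- vector("list", K)
  for (k in seq_len(K)) {
    means[k, ] <- colSums(X * tau[, k]) / nk[k]
    Xc <- sweep(X, 2L, means[k, ])
    S <- crossprod(Xc * sqrt(tau[, k])) / nk[k]
    sc <- safe_chol(S)
    covs[[k]] <- sc$S; chols[[k]] <- sc$U
  }
  list(proportions = proportions, means = means, covariances = covs, chol = chols)
}

gmm_estep <- function(X, model) {
  ld <- gmm_log_component_dens(X, model)
  m <- apply(ld, 1L, max)
  lse <- m + log(rowSums(exp(ld - m)))
  tau <- exp(ld - lse)
  list(tau = tau, loglik = sum(lse))
}

# k-means++ seeding of hard responsibilities (uses the current RNG stream)
gmm_seed_responsibilities <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1L], ])^2)
  if (K > 1L) for (k in 2:K) {
    prob <- d2 / sum(d2)
    if (all(d2 == 0)) prob <- rep(1 / n, n)
    centers[k] <- sample.int(n, 1L, prob = prob)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[k], ])^2))
  }
  cmat <- X[centers, , drop = FALSE]
  dist2 <- vapply(seq_len(K), function(k)
    rowSums(sweep(X, 2L, cmat[k, ])^2), numeric(n))
  dist2 <- matrix(dist2, nrow = n)
  assign <- max.col(-dist2, ties.method = "first")
  tau <- matrix(1e-6, n, K)
  tau[cbind(seq_len(n), assign)] <- 1
  tau / rowSums(tau)
}

gmm_em_run <- function(X, tau, max_iter, tol) {
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    model <- gmm_mstep(X, tau)
    e <- gmm_estep(X, model)
    tau <- e$tau
    trace <- c(trace, e$loglik)
    if (is.finite(ll_old) &&
        abs(e$loglik - ll_old) < tol * (abs(e$loglik) + 1)) break
    ll_old <- e$loglik
  }
  list(model = model, tau = tau, loglik = e$loglik, trace = trace, iter = it)
}

#' Fit a K-component Gaussian mixture with the small-EM strategy
#'
#' Runs `n_inits` initializations (k-means++ seeding of responsibilities,
#' then 10 short EM iterations each), keeps the best short run by
#' log-likelihood, and continues it to convergence (relative log-likelihood
#' change below 1e-8, at most 1000 iterations). Covariances are full and
#' regularized on the diagonal when Cholesky factorization fails.
#' Deterministic given `seed`.
#'
#' @param data Genes x samples matrix (arcsine-transformed profiles).
#' @param K Number of components (>= 1, < number of genes).
#' @param n_inits Number of short-EM initializations.
#' @param seed Integer seed for the initializations.
#' @param short_iters Iterations per short run (default 10).
#' @param max_iter,tol Full-run convergence controls.
#' @return A `fex_gmm`: `K`, `proportions`, `means`, `covariances`,
#'   `posteriors`, `loglik`, `loglik_trace`, `n_params`, `icl`, `bic`,
#'   `entropy`.
#' @export
fit_gmm <- function(data, K, n_inits = 5L, seed = 1L, short_iters = 10L,
                    max_iter = 1000L, tol = 1e-8) {
  X <- as.matrix(data)
  n <- nrow(X); d <- ncol(X)
  if (K < 1L) stop_fex("K must be >= 1")
  if (K >= n) stop_fex("K (%d) must be smaller than the number of genes (%d)", K, n)
  if (d > n) warning("more dimensions than genes; covariances will be heavily regularized")

  best <- NULL
  for (i in seq_len(n_inits)) {
    old <- .Random.seed_save()
    set.seed(derive_seed(seed, "init", K, i))
    tau0 <- if (K == 1L) matrix(1, n, 1L) else gmm_seed_responsibilities(X, K)
    .Random.seed_restore(old)
    run <- gmm_em_run(X, tau0, max_iter = short_iters, tol = 0)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  run <- gmm_em_run(X, best$tau, max_iter = max_iter, tol = tol)
  trace <- c(best$trace, run$trace)

  tau <- run$tau
  ent <- -sum(ifelse(tau > 0, tau * log(tau), 0))
  nu <- (K - 1) + K * d + K * d * (d + 1) / 2
  bic <- -2 * run$loglik + nu * log(n)
  structure(list(K = K,
                 proportions = run$model$proportions,
                 means = run$model$means,
                 covariances = run$model$covariances,
                 posteriors = tau,
                 loglik = run$loglik,
                 loglik_trace = trace,
                 n_params = nu,
                 entropy = ent,
                 bic = bic,
                 icl = bic + 2 * ent,
                 seed = seed, n_inits = n_inits),
            class = "fex_gmm")
}

# save/restore the global RNG state so seeded sub-draws do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv()))
    rm(".Random.seed", envir = globalenv())
}

#' @export
print.fex_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d, logL = %.2f, ICL = %.2f, entropy = %.2f\n",
              x$K, x$loglik, x$icl, x$entropy))
  invisible(x)
}

#' Integrated completed likelihood
#'
#' `ICL = -2 logL + nu_K log(n) + 2 Ent` with the soft posterior entropy
#' `Ent = -sum_g sum_k tau_gk log tau_gk`; equals BIC when posteriors are
#' hard (in particular at K = 1).
#'
#' @param model A `fex_gmm`.
#' @param n Number of genes (defaults to the fitted number).
#' @return The ICL value.
#' @export
icl <- function(model, n = nrow(model$posteriors)) {
  -2 * model$loglik + model$n_params * log(n) + 2 * model$entropy
}

#' Two-loop ICL model selection
#'
#' Loop 1 fits mixtures at each grid value of K (default 5, 10, 15, 20,
#' 25, 30) with `loop1_inits` small-EM initializations each and locates
#' the ICL-minimizing grid point `K*`. Loop 2 re-estimates every K in
#' `[K*-4, K*+4]` (clipped to `[2, max(grid)]`) with `loop2_inits`
#' initializations. The selected model is the global ICL minimizer; genes
#' are assigned to their maximum-posterior component and clusters are
#' relabeled by decreasing size (ties by lowest original index). The
#' convexity flag records whether the loop-2 ICL curve has a single local
#' minimum. Per-K fits can be checkpointed so an interrupted run resumes.
#'
#' @param data Genes x samples matrix (arcsine-transformed profiles).
#' @param grid Loop-1 values of K.
#' @param loop1_inits,loop2_inits Initializations per K in each loop.
#' @param seed Run seed (per-K, per-init sub-seeds are derived from it).
#' @param checkpoint_dir Optional directory for per-K resumable fits.
#' @return A `fex_selection`: `best` (a `fex_gmm`), `K`, `assignments`
#'   (named cluster labels, 1..K by decreasing size), `icl_curve` (data
#'   frame over both loops), `convex`, `interval`.
#' @export
select_model <- function(data, grid = c(5L, 10L, 15L, 20L, 25L, 30L),
                         loop1_inits = 5L, loop2_inits = 40L, seed = 1L,
                         checkpoint_dir = NULL) {
  X <- as.matrix(data)
  n <- nrow(X)
  if (n <= max(grid)) {
    grid <- grid[grid < n]
    warning(sprintf("grid truncated to K < %d genes", n))
    if (!length(grid)) stop_fex("too few genes for any grid value of K")
  }
  fit_ck <- function(K, inits, tag) {
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      f <- file.path(checkpoint_dir, sprintf("%s_K%02d_seed%d_inits%d.rds",
                                             tag, K, seed, inits))
      if (file.exists(f)) return(readRDS(f))
      m <- fit_gmm(X, K, n_inits = inits, seed = derive_seed(seed, tag, K))
      saveRDS(m, f)
      return(m)
    }
    fit_gmm(X, K, n_inits = inits, seed = derive_seed(seed, tag, K))
  }
  loop1 <- lapply(grid, fit_ck, inits = loop1_inits, tag = "loop1")
  icl1 <- vapply(loop1, icl, numeric(1))
  k_star <- grid[which.min(icl1)]
  interval <- max(2L, k_star - 4L):min(max(grid), k_star + 4L)
  interval <- interval[interval < n]
  loop2 <- lapply(interval, fit_ck, inits = loop2_inits, tag = "loop2")
  icl2 <- vapply(loop2, icl, numeric(1))

  all_models <- c(loop1, loop2)
  all_icl <- c(icl1, icl2)
  best <- all_models[[which.min(all_icl)]]

  # single local minimum on the loop-2 curve?
  d2 <- diff(icl2)
  sign_changes <- sum(diff(sign(d2[d2 != 0])) != 0)
  convex <- length(icl2) < 3L || sign_changes <= 1L

  assignments <- relabel_by_size(max.col(best$posteriors, ties.method = "first"),
                                 best$K)
  names(assignments) <- rownames(X)
  curve <- data.frame(loop = c(rep(1L, length(grid)), rep(2L, length(interval))),
                      K = c(grid, interval), icl = c(icl1, icl2))
  structure(list(best = best, K = best$K, assignments = assignments,
                 icl_curve = curve, convex = convex, interval = interval,
                 seed = seed),
            class = "fex_selection")
}

# relabel cluster indices by decreasing size; ties keep lowest original index
relabel_by_size <- function(labels, K) {
  sizes <- tabulate(labels, nbins = K)
  ord <- order(-sizes, seq_len(K))
  map <- integer(K); map[ord] <- seq_len(K)
  map[labels]
}

#' @export
print.fex_selection <- function(x, ...) {
  cat(sprintf("ICL model selection: K = %d (interval %d..%d), ICL = %.2f, %s\n",
              x$K, min(x$interval), max(x$interval), icl(x$best),
              if (x$convex) "convex ICL curve" else "NON-convex ICL curve"))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Co-expression clustering of a gene list
#'
#' End-to-end wrapper: computes normalized expression profiles, sends
#' low-mean genes to Cluster 0, arcsine-transforms the remaining profiles
#' and runs the two-loop ICL selection.
#'
#' @param counts Genes x samples counts restricted to the gene list (e.g.
#'   a union of DEG lists).
#' @param norm A `fex_norm` for the same samples.
#' @param mean_filter_cutoff Cluster-0 cutoff (default 50).
#' @param ... Passed to [select_model()] (`grid`, `loop1_inits`,
#'   `loop2_inits`, `seed`, `checkpoint_dir`).
#' @return A `fex_coexp`: `selection`, `assignments` (every input gene,
#'   labels 0..K with 0 = low-mean filtered), `profiles`, `cluster0`.
#' @export
coexpression <- function(counts, norm, mean_filter_cutoff = 50, ...) {
  pr <- expression_profiles(counts, norm, mean_filter_cutoff)
  V <- arcsine_transform(pr$profiles)
  sel <- select_model(V, ...)
  assignments <- c(sel$assignments,
                   stats::setNames(rep(0L, length(pr$cluster0)), pr$cluster0))
  assignments <- assignments[rownames(counts)]
  names(assignments) <- rownames(counts)
  structure(list(selection = sel, assignments = assignments,
                 profiles = pr$profiles, cluster0 = pr$cluster0),
            class = "fex_coexp")
}

#' @export
print.fex_coexp <- function(x, ...) {
  cat(sprintf("Co-expression: %d genes, %d in Cluster 0 (low mean), K = %d\n",
              length(x$assignments), length(x$cluster0), x$selection$K))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' @export
summary.fex_coexp <- function(object, ...) {
  k <- object$selection$K
  sizes <- table(factor(object$assignments, levels = 0:k))
  data.frame(cluster = as.integer(names(sizes)), size = as.integer(sizes))
}

#' Plot mean cluster profiles
#' @param x A `fex_coexp`.
#' @param ... Unused.
#' @export
plot.fex_coexp <- function(x, ...) {
  k <- x$selection$K
  prof <- x$profiles
  graphics::matplot(t(vapply(seq_len(k), function(cl) {
    g <- names(x$assignments)[x$assignments == cl]
    colMeans(prof[g, , drop = FALSE])
  }, numeric(ncol(prof)))), type = "l", lty = 1,
  xlab = "sample", ylab = "mean profile", main = "Cluster mean profiles")
  invisible(x)
}

#' Per-cluster mean profiles
#' @param coexp A `fex_coexp`.
#' @return Clusters x samples matrix of mean profiles (clusters 1..K).
#' @export
cluster_profiles <- function(coexp) {
  k <- coexp$selection$K
  out <- t(vapply(seq_len(k), function(cl) {
    g <- names(coexp$assignments)[coexp$assignments == cl]
    colMeans(coexp$profiles[g, , drop = FALSE])
  }, numeric(ncol(coexp$profiles))))
  rownames(out) <- paste0("cluster", seq_len(k))
  out
}
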