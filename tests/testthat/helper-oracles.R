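# independent oracles, coded from the published recipes rather than from
# the package's implementation paths

# step-by-step weighted trimmed mean of M-values for one sample vs a
# reference: exclude zero genes, trim 30% by M and 5% by A, weight by the
# inverse asymptotic binomial variance
oracle_tmm_pair <- function(obs, ref, No, Nr) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / No) / (ref / Nr))
  A <- 0.5 * log2((obs / No) * (ref / Nr))
  w <- (No - obs) / (No * obs) + (Nr - ref) / (Nr * ref)
  n <- length(M)
  loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
  loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

oracle_tmm <- function(counts) {
  N <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x, 0.75)) / N
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(counts)), function(j)
    if (j == ref) 1 else oracle_tmm_pair(counts[, j], counts[, ref], N[j], N[ref]))
  f / exp(mean(log(f)))
}

# NB log-likelihood maximized directly by optim (no IRLS), for dispersion
# and fit oracles
oracle_nb_fit <- function(y, X, offsets, phi) {
  nll <- function(beta) {
    mu <- exp(offsets + drop(X %*% beta))
    if (phi < 1e-10) -sum(dpois(y, mu, log = TRUE))
    else -sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
  start <- qr.solve(X, log(pmax(y, 0.5)) - offsets)
  op <- optim(start, nll, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  list(beta = op$par, loglik = -op$value)
}

# brute-force fine-grid maximizer of the Cox-Reid adjusted profile
# log-likelihood for a single gene
oracle_apl_argmax <- function(y, X, offsets, grid = exp(seq(log(1e-4), log(10), length.out = 400))) {
  apl <- vapply(grid, function(phi) {
    f <- oracle_nb_fit(y, X, offsets, phi)
    mu <- exp(offsets + drop(X %*% f$beta))
    w <- mu / (1 + phi * mu)
    f$loglik - 0.5 * determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
  }, numeric(1))
  grid[which.max(apl)]
}

# closed-form Poisson likelihood-ratio test for a two-group comparison
# with equal offsets: group means vs pooled mean
oracle_poisson_lrt <- function(y, group) {
  ll <- function(y, mu) sum(dpois(y, mu, log = TRUE))
  full <- sum(vapply(unique(group), function(g)
    ll(y[group == g], mean(y[group == g])), numeric(1)))
  null <- ll(y, mean(y))
  2 * (full - null)
}
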