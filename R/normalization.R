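#' Counts per million
#'
#' @param counts Genes x samples matrix.
#' @param effective_sizes Per-sample positive scaling totals (raw library
#'   sizes for pre-normalization CPM, `N_j * f_j` after normalization).
#' @return Real matrix: `counts[g, j] * 1e6 / effective_sizes[j]`.
#' @export
compute_cpm <- function(counts, effective_sizes) {
  if (any(!is.finite(effective_sizes) | effective_sizes <= 0))
    stop_fex("effective sizes must be positive and finite")
  if (length(effective_sizes) != ncol(counts))
    stop_fex("one effective size per sample required")
  sweep(counts, 2L, effective_sizes, "/") * 1e6
}

#' Filter weakly expressed genes
#'
#' CPM is computed on raw library sizes (filtering precedes normalization).
#' Under `"NbConditions"` a gene is kept iff its mean CPM within at least
#' one biological condition reaches `cpm_cutoff`. Under `"NbReplicates"` a
#' gene is kept iff its CPM reaches the cutoff in at least `r` samples,
#' where `r` is the minimum number of replicates over conditions.
#'
#' @param project A `fex_project`.
#' @param strategy `"NbConditions"` (default) or `"NbReplicates"`.
#' @param cpm_cutoff Non-negative CPM threshold (default 1).
#' @return List with `project` (filtered) and `report` (a `fex_filter`
#'   with `strategy`, `cpm_cutoff`, `kept_genes`, `removed_genes`).
#' @export
filter_low_expressed <- function(project, strategy = c("NbConditions", "NbReplicates"),
                                 cpm_cutoff = 1) {
  strategy <- match.arg(strategy)
  if (cpm_cutoff < 0) stop_fex("cpm_cutoff must be >= 0")
  counts <- project$counts
  cond <- condition_labels(project$design)
  cpm <- compute_cpm(counts, colSums(counts))
  if (strategy == "NbConditions") {
    cond_means <- vapply(unique(cond), function(cc)
      rowMeans(cpm[, cond == cc, drop = FALSE]), numeric(nrow(cpm)))
    cond_means <- matrix(cond_means, nrow = nrow(cpm))
    keep <- rowSums(cond_means >= cpm_cutoff) > 0
  } else {
    r_min <- min(table(cond))
    keep <- rowSums(cpm >= cpm_cutoff) >= r_min
  }
  report <- structure(list(strategy = strategy, cpm_cutoff = cpm_cutoff,
                           kept_genes = rownames(counts)[keep],
                           removed_genes = rownames(counts)[!keep]),
                      class = "fex_filter")
  filtered <- project
  filtered$counts <- counts[keep, , drop = FALSE]
  list(project = filtered, report = report)
}

#' @export
print.fex_filter <- function(x, ...) {
  cat(sprintf("Low-count filter (%s, CPM cutoff %g): kept %d, removed %d genes\n",
              x$strategy, x$cpm_cutoff, length(x$kept_genes), length(x$removed_genes)))
  invisible(x)
}

new_norm_result <- function(method, factors, lib_sizes, samples) {
  factors <- factors / geo_mean(factors)
  structure(list(method = method,
                 factors = stats::setNames(factors, samples),
                 library_sizes = stats::setNames(lib_sizes, samples),
                 effective_sizes = stats::setNames(lib_sizes * factors, samples)),
            class = "fex_norm")
}

#' @export
print.fex_norm <- function(x, ...) {
  cat(sprintf("%s normalization factors (geometric mean 1):\n", x$method))
  print(round(x$factors, 4))
  invisible(x)
}

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values against a reference sample (the sample
#' whose upper-quartile/total ratio is closest to the mean of that ratio).
#' For each sample, genes with a zero count in either the sample or the
#' reference are excluded, 30% of genes are trimmed by extreme log-ratio M
#' and 5% by extreme mean abundance A, and the remaining M-values are
#' averaged with inverse asymptotic binomial-variance weights. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Genes x samples count matrix.
#' @return A `fex_norm` result.
#' @export
tmm_factors <- function(counts) {
  check_norm_input(counts)
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  new_norm_result("TMM", f, colSums(counts), colnames(counts))
}

#' RLE normalization factors
#'
#' Relative log expression: for each sample the size factor is the median,
#' over genes expressed in every sample, of the ratio of the count to the
#' gene's geometric mean across samples. Size factors are converted to
#' factors `f_j` with geometric mean 1 such that `N_j * f_j` is
#' proportional to the size factor.
#'
#' @param counts Genes x samples count matrix.
#' @return A `fex_norm` result.
#' @export
rle_factors <- function(counts) {
  check_norm_input(counts)
  allpos <- rowSums(counts == 0) == 0L
  if (!any(allpos)) stop_fex("RLE requires >= 1 gene with nonzero counts in all samples")
  ref <- exp(rowMeans(log(counts[allpos, , drop = FALSE])))
  s <- apply(counts[allpos, , drop = FALSE] / ref, 2L, stats::median)
  lib <- colSums(counts)
  # effective size proportional to s_j  =>  f_j proportional to s_j / N_j
  new_norm_result("RLE", s / lib, lib, colnames(counts))
}

check_norm_input <- function(counts) {
  if (ncol(counts) < 2L) stop_fex("normalization requires >= 2 samples")
  if (any(colSums(counts) == 0)) {
    stop_fex("sample '%s' has zero total counts",
             colnames(counts)[colSums(counts) == 0][1L])
  }
  invisible(TRUE)
}

#' Normalize a project
#'
#' @param project A `fex_project` (usually after [filter_low_expressed()]).
#' @param method `"TMM"` (default) or `"RLE"`.
#' @return A `fex_norm` result for the project's samples.
#' @export
normalize_project <- function(project, method = c("TMM", "RLE")) {
  method <- match.arg(method)
  switch(method, TMM = tmm_factors(project$counts), RLE = rle_factors(project$counts))
}
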