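#' Hypergeometric tail probabilities
#'
#' Exact over- and under-representation tails for drawing `n` genes from a
#' universe of `N` of which `K` carry the term and observing `k` carriers:
#' `p_over = P(X >= k)`, `p_under = P(X <= k)`. Both tails include `X = k`,
#' so `p_over + p_under >= 1`. Computed via [stats::phyper()], which
#' evaluates the tail sums in log space.
#'
#' @param k Observed carriers in the list.
#' @param K Carriers in the universe.
#' @param n List size.
#' @param N Universe size.
#' @return Named numeric: `p_over`, `p_under`.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(n, K))
    stop_fex("inconsistent hypergeometric counts (k=%d, K=%d, n=%d, N=%d)", k, K, n, N)
  c(p_over = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
    p_under = stats::phyper(k, K, N - K, n, lower.tail = TRUE))
}

#' Term enrichment of a gene list
#'
#' Hypergeometric over/under-representation of every annotation term
#' against a reference universe (by default the filtered, expressed gene
#' set). Genes outside the universe are dropped from the list with a
#' warning. BH adjustment is applied separately to the over and under
#' p-value families; rows are sorted by `p_over`.
#'
#' @param gene_list Character vector of gene ids.
#' @param annotation A `fex_annotation` (gene/term pairs).
#' @param universe Character vector of reference gene ids.
#' @param alpha Significance level for the flags (default 0.05).
#' @return A `fex_enrichment` data frame: `term`, `N`, `K`, `n`, `k`,
#'   `p_over`, `p_under`, `adj_p_over`, `adj_p_under`, `over_represented`,
#'   `under_represented`.
#' @export
enrich <- function(gene_list, annotation, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_fex("empty universe")
  ann <- unique(annotation[annotation$gene %in% universe, , drop = FALSE])
  if (!nrow(ann)) stop_fex("annotation has no gene in the universe")
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning(sprintf("%d gene(s) outside the universe dropped from the list",
                    length(outside)))
    gene_list <- intersect(gene_list, universe)
  }
  N <- length(universe); n <- length(gene_list)
  terms <- sort(unique(ann$term))
  Ks <- table(factor(ann$term, levels = terms))
  in_list <- ann[ann$gene %in% gene_list, , drop = FALSE]
  ks <- table(factor(in_list$term, levels = terms))
  pv <- t(mapply(hypergeom_tail, k = as.integer(ks), K = as.integer(Ks),
                 MoreArgs = list(n = n, N = N)))
  res <- data.frame(term = terms, N = N, K = as.integer(Ks), n = n,
                    k = as.integer(ks),
                    p_over = pv[, "p_over"], p_under = pv[, "p_under"],
                    stringsAsFactors = FALSE, row.names = NULL)
  res$adj_p_over <- adjust_bh(res$p_over)
  res$adj_p_under <- adjust_bh(res$p_under)
  res$over_represented <- res$adj_p_over <= alpha
  res$under_represented <- res$adj_p_under <= alpha
  res <- res[order(res$p_over, res$term), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("fex_enrichment", "data.frame")
  res
}
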