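#' Quality-control summaries
#'
#' Computes the machine-readable content of the standard pre-analysis QC
#' panels: per-sample library sizes, quartiles of `log2(normalized count +
#' 1)` per sample (raw and normalized), a Ward dendrogram on Euclidean
#' distances between samples in the transformed space, and a centered
#' (unscaled) PCA of the samples.
#'
#' @param project A `fex_project`.
#' @param norm A `fex_norm` for the same samples.
#' @return A `fex_qc` list: `library_sizes`, `boxplot_stats` (data frame of
#'   quartiles per sample, raw and normalized), `dendrogram` (an `hclust`),
#'   `pca` (list with `coordinates` and `percent_variance`).
#' @export
qc_summaries <- function(project, norm) {
  counts <- project$counts
  if (!identical(colnames(counts), names(norm$factors)))
    stop_fex("normalization result does not match the project's samples")
  lib <- colSums(counts)
  norm_counts <- compute_cpm(counts, norm$effective_sizes) *
    mean(norm$effective_sizes) / 1e6
  qfun <- function(m, kind) {
    qs <- apply(log2(m + 1), 2L, stats::quantile, probs = c(0, .25, .5, .75, 1))
    data.frame(sample = colnames(m), kind = kind, t(qs),
               check.names = FALSE, row.names = NULL)
  }
  box <- rbind(qfun(counts, "raw"), qfun(norm_counts, "normalized"))
  lt <- t(log2(norm_counts + 1))          # samples x genes
  hc <- stats::hclust(stats::dist(lt), method = "ward.D2")
  pc <- stats::prcomp(lt, center = TRUE, scale. = FALSE)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(library_sizes = lib,
                 boxplot_stats = box,
                 dendrogram = hc,
                 pca = list(coordinates = pc$x, percent_variance = pv)),
            class = "fex_qc")
}

#' @export
print.fex_qc <- function(x, ...) {
  cat(sprintf("QC for %d samples; library sizes %s..%s\n",
              length(x$library_sizes),
              format(min(x$library_sizes), big.mark = ","),
              format(max(x$library_sizes), big.mark = ",")))
  cat(sprintf("PC1/PC2 variance: %.1f%% / %.1f%%\n",
              x$pca$percent_variance[1L],
              if (length(x$pca$percent_variance) > 1L) x$pca$percent_variance[2L] else 0))
  invisible(x)
}

#' Plot QC panels
#'
#' Renders library-size barplot, normalized-count boxplots, the sample
#' dendrogram and the PCA scatter on the current graphics device.
#' @param x A `fex_qc`.
#' @param ... Unused.
#' @export
plot.fex_qc <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$library_sizes, las = 2, main = "Library sizes",
                    col = "steelblue")
  nb <- x$boxplot_stats[x$boxplot_stats$kind == "normalized", ]
  graphics::boxplot(t(as.matrix(nb[, -(1:2)])), names = nb$sample, las = 2,
                    main = "log2(norm count + 1)")
  plot(x$dendrogram, main = "Ward / Euclidean", xlab = "", sub = "")
  plot(x$pca$coordinates[, 1:2],
       xlab = sprintf("PC1 (%.1f%%)", x$pca$percent_variance[1]),
       ylab = sprintf("PC2 (%.1f%%)", x$pca$percent_variance[2]),
       main = "PCA", pch = 19)
  graphics::text(x$pca$coordinates[, 1:2], labels = rownames(x$pca$coordinates),
                 pos = 3, cex = 0.7)
  invisible(x)
}
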