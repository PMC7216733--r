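#' Differential expression analysis over automatically generated contrasts
#'
#' Fits the negative-binomial GLM defined by the project's factorial design
#' to every gene (offsets = log effective library sizes from the chosen
#' normalization), estimates a common dispersion by Cox-Reid adjusted
#' profile likelihood and shrinks per-gene dispersions toward it, then
#' tests each requested contrast by a 1-df likelihood-ratio test with BH
#' adjustment within the contrast.
#'
#' @param project A `fex_project` (typically already low-count filtered).
#' @param norm A `fex_norm` for the same samples.
#' @param with_interaction Include the biological-factor interaction.
#' @param contrasts Character vector of contrast names to test, or `"all"`.
#' @param alpha DEG-calling level on adjusted p-values.
#' @param dispersion `"tagwise"` (common + shrinkage, default), `"common"`,
#'   or a fixed numeric value (scalar or per gene).
#' @param prior_df Shrinkage prior degrees of freedom (default 10).
#' @return A `fex_diff` object with elements `glm_design`, `contrasts`,
#'   `tests` (named list of `fex_contrast_test`), `dispersion_common`,
#'   `dispersions`, `fit`, `diagnostics` (per-contrast p-value histograms),
#'   `norm`, `alpha`.
#' @export
diff_analysis <- function(project, norm, with_interaction = TRUE,
                          contrasts = "all", alpha = 0.05,
                          dispersion = "tagwise", prior_df = 10) {
  counts <- project$counts
  if (!identical(colnames(counts), names(norm$factors)))
    stop_fex("normalization result does not match the project's samples")
  glm_design <- build_design_matrix(project$design, with_interaction)
  X <- glm_design$design_matrix
  offsets <- log(norm$effective_sizes)
  all_contrasts <- generate_contrasts(glm_design)
  sel <- if (identical(contrasts, "all")) names(all_contrasts) else contrasts
  missing <- setdiff(sel, names(all_contrasts))
  if (length(missing)) stop_fex("unknown contrast '%s'", missing[1L])
  use_contrasts <- all_contrasts[sel]

  common <- NULL
  if (is.numeric(dispersion)) {
    phis <- rep_len(dispersion, nrow(counts))
    phi_common <- mean(phis)
  } else if (identical(dispersion, "common")) {
    common <- estimate_common_dispersion(counts, X, offsets)
    phi_common <- common$phi
    phis <- rep(phi_common, nrow(counts))
  } else if (identical(dispersion, "tagwise")) {
    common <- estimate_common_dispersion(counts, X, offsets)
    phi_common <- common$phi
    phis <- estimate_tagwise_dispersions(counts, X, offsets, common, prior_df)
  } else stop_fex("dispersion must be 'tagwise', 'common' or numeric")

  full_fit <- fit_all_genes(counts, X, offsets, phis)
  tests <- diagnostics <- list()
  for (nm in names(use_contrasts)) {
    tests[[nm]] <- lrt_contrast(counts, X, offsets, phis, use_contrasts[[nm]],
                                alpha = alpha, full_fit = full_fit)
    diagnostics[[nm]] <- suppressMessages(pvalue_histogram(tests[[nm]]$pvalue))
  }
  structure(list(glm_design = glm_design, contrasts = use_contrasts,
                 tests = tests, dispersion_common = phi_common,
                 dispersions = phis, fit = full_fit,
                 diagnostics = diagnostics, norm = norm, alpha = alpha,
                 project_name = project$name),
            class = "fex_diff")
}

#' @export
print.fex_diff <- function(x, ...) {
  cat(sprintf("NB-GLM differential analysis: %d genes, %d contrasts (alpha = %g)\n",
              nrow(x$fit$beta), length(x$tests), x$alpha))
  cat(sprintf("common dispersion %.4g\n", x$dispersion_common))
  print(summary(x))
  invisible(x)
}

#' @export
summary.fex_diff <- function(object, ...) {
  rows <- lapply(names(object$tests), function(nm) {
    tt <- object$tests[[nm]]
    data.frame(contrast = nm,
               degs = sum(tt$deg),
               up = sum(tt$deg & tt$log2FC > 0),
               down = sum(tt$deg & tt$log2FC < 0),
               uniform_tail = object$diagnostics[[nm]]$uniform_tail,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Log2 fold-change matrix
#' @param object A `fex_diff`.
#' @param ... Unused.
#' @return Genes x contrasts matrix of log2 fold-changes.
#' @export
coef.fex_diff <- function(object, ...) {
  sapply(object$tests, function(tt) stats::setNames(tt$log2FC, tt$gene))
}

#' Plot raw p-value histograms per contrast
#' @param x A `fex_diff`.
#' @param ... Unused.
#' @export
plot.fex_diff <- function(x, ...) {
  n <- length(x$diagnostics)
  nc <- ceiling(sqrt(n))
  op <- graphics::par(mfrow = c(ceiling(n / nc), nc), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(x$diagnostics)) {
    d <- x$diagnostics[[nm]]
    graphics::barplot(d$counts, space = 0, main = nm, cex.main = 0.7,
                      col = if (d$uniform_tail) "grey70" else "indianred")
  }
  invisible(x)
}

#' Extract DEG lists from a differential analysis
#'
#' @param diff A `fex_diff`.
#' @param contrasts Contrast names (default all tested).
#' @return Named list of gene-id vectors (one per contrast).
#' @export
deg_lists <- function(diff, contrasts = names(diff$tests)) {
  out <- lapply(diff$tests[contrasts], function(tt) sort(tt$gene[tt$deg]))
  names(out) <- contrasts
  out
}
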