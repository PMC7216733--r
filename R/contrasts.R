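#' Build the GLM design basis for a factorial experiment
#'
#' Treatment (reference-level) coding with the first-appearing modality of
#' each factor as reference. Coefficient order: intercept, replicate
#' deviations, first-factor deviations, second-factor deviations,
#' interaction deviations. Also returns the condition map: for every
#' combination of biological-factor modalities, the coefficient combination
#' giving that condition's mean at the reference replicate.
#'
#' @param design A `fex_design`.
#' @param with_interaction Include the interaction between the two
#'   biological factors (ignored for one-factor designs).
#' @return A `fex_glm_design`: list with `coefficient_names`,
#'   `design_matrix` (samples x coefficients), `condition_map` (conditions
#'   x coefficients), `factor_levels`, `with_interaction`,
#'   `replicate_cols` (indices of replicate coefficients).
#' @export
build_design_matrix <- function(design, with_interaction = TRUE) {
  check_complete(design)
  facs <- design$biological_factors
  two_factor <- length(facs) == 2L
  df <- data.frame(row.names = design$sample_ids)
  if (!is.null(design$replicate_factor)) df$.rep <- design$replicate_factor
  df$.A <- facs[[1L]]
  if (two_factor) df$.B <- facs[[2L]]

  terms <- c(if (!is.null(design$replicate_factor)) ".rep", ".A",
             if (two_factor) ".B",
             if (two_factor && with_interaction) ".A:.B")
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, df)

  # readable coefficient names
  nm <- colnames(X)
  nm <- sub("^\\(Intercept\\)$", "Intercept", nm)
  rename <- function(nm, tag, fac_name, levels) {
    for (lv in levels[order(-nchar(levels))])
      nm <- gsub(paste0(tag, lv), paste0(fac_name, ":", lv), nm, fixed = TRUE)
    nm
  }
  if (!is.null(design$replicate_factor))
    nm <- rename(nm, ".rep", design$replicate_name, levels(design$replicate_factor))
  nm <- rename(nm, ".A", names(facs)[1L], levels(facs[[1L]]))
  if (two_factor) nm <- rename(nm, ".B", names(facs)[2L], levels(facs[[2L]]))
  colnames(X) <- nm

  if (qr(X)$rank < ncol(X))
    stop_fex("design matrix is rank deficient (%d < %d)", qr(X)$rank, ncol(X))
  if (nrow(X) < 2L * ncol(X))
    warning(sprintf(paste("only %d samples for %d coefficients; at least twice as many",
                          "observations as parameters are advised (consider dropping",
                          "the interaction)"), nrow(X), ncol(X)))

  # condition map: one pseudo-sample per condition at the reference replicate
  grid <- expand.grid(A = levels(facs[[1L]]),
                      B = if (two_factor) levels(facs[[2L]]) else NA,
                      stringsAsFactors = FALSE)
  gd <- data.frame(.A = factor(grid$A, levels = levels(facs[[1L]])))
  if (!is.null(design$replicate_factor))
    gd$.rep <- factor(levels(design$replicate_factor)[1L],
                      levels = levels(design$replicate_factor))
  if (two_factor) gd$.B <- factor(grid$B, levels = levels(facs[[2L]]))
  cmap <- stats::model.matrix(fml, gd)
  colnames(cmap) <- nm
  rownames(cmap) <- if (two_factor) paste(grid$A, grid$B, sep = ".") else grid$A

  structure(list(coefficient_names = nm,
                 design_matrix = X,
                 condition_map = cmap,
                 factor_names = names(facs),
                 factor_levels = lapply(facs, levels),
                 replicate_cols = grep(paste0("^", (design$replicate_name %||% "\r"), ":"), nm),
                 with_interaction = two_factor && with_interaction),
            class = "fex_glm_design")
}

#' @export
print.fex_glm_design <- function(x, ...) {
  cat(sprintf("GLM design: %d samples x %d coefficients%s\n",
              nrow(x$design_matrix), ncol(x$design_matrix),
              if (x$with_interaction) " (with interaction)" else ""))
  cat("  coefficients:", paste(x$coefficient_names, collapse = ", "), "\n")
  invisible(x)
}

new_contrast <- function(name, kind, weights, glm_design, degenerate = FALSE) {
  structure(list(name = name, kind = kind,
                 weights_on_conditions = weights,
                 vector = contrast_to_vector(weights, glm_design),
                 degenerate = degenerate),
            class = "fex_contrast")
}

#' @export
print.fex_contrast <- function(x, ...) {
  cat(sprintf("%s contrast %s\n", x$kind, x$name))
  w <- x$weights_on_conditions
  cat("  condition weights:", paste(sprintf("%s=%+g", names(w), w), collapse = " "), "\n")
  invisible(x)
}

#' Realize condition weights on the GLM coefficient basis
#'
#' Expands a zero-sum weighting of condition means into the equivalent
#' vector over the GLM coefficients (replicate coefficients receive weight
#' 0 since every condition mean is taken at the reference replicate and the
#' weights sum to zero).
#'
#' @param weights Named numeric over the rownames of
#'   `glm_design$condition_map`, summing to zero.
#' @param glm_design A `fex_glm_design`.
#' @return Numeric vector over `glm_design$coefficient_names`.
#' @export
contrast_to_vector <- function(weights, glm_design) {
  unknown <- setdiff(names(weights), rownames(glm_design$condition_map))
  if (length(unknown)) stop_fex("unknown condition '%s' in contrast weights", unknown[1L])
  if (abs(sum(weights)) > 1e-10) stop_fex("contrast weights must sum to zero")
  v <- drop(crossprod(glm_design$condition_map[names(weights), , drop = FALSE], weights))
  stats::setNames(v, glm_design$coefficient_names)
}

#' Automatically generate the full contrast list
#'
#' For a two-factor design with factor A (modalities `a_1..a_I`) and factor
#' B (`b_1..b_J`), generates, in order: for every unordered pair of A
#' modalities the averaged contrast `[a-a']` (unweighted mean over B); the
#' per-modality contrasts `[b_a-b_a']` for each B modality; symmetrically
#' the B-averaged and B-per-modality contrasts; and for every pair of pairs
#' the interaction contrast `[a_b-a_b']-[a'_b-a'_b']`. Pair orientation is
#' first-appearing minus later-appearing modality. One-factor designs get
#' all pairwise contrasts. Total for two factors:
#' `C(I,2)(J+1) + C(J,2)(I+1) + C(I,2)C(J,2)`.
#'
#' Under an additive model (no interaction coefficient) interaction
#' contrasts are identically zero; they are flagged degenerate and excluded
#' unless `include_degenerate = TRUE`.
#'
#' @param glm_design A `fex_glm_design`.
#' @param include_degenerate Keep degenerate interaction contrasts.
#' @return List of `fex_contrast`, named by contrast name.
#' @export
generate_contrasts <- function(glm_design, include_degenerate = FALSE) {
  lv <- glm_design$factor_levels
  conds <- rownames(glm_design$condition_map)
  out <- list()
  add <- function(cl) out[[cl$name]] <<- cl

  if (length(lv) == 1L) {
    A <- lv[[1L]]
    for (p in level_pairs(A)) {
      w <- stats::setNames(numeric(length(conds)), conds)
      w[p[1L]] <- 1; w[p[2L]] <- -1
      add(new_contrast(sprintf("[%s-%s]", p[1L], p[2L]), "averaged", w, glm_design))
    }
    return(out)
  }

  A <- lv[[1L]]; B <- lv[[2L]]
  cond <- function(a, b) paste(a, b, sep = ".")
  zero <- stats::setNames(numeric(length(conds)), conds)
  pairsA <- level_pairs(A); pairsB <- level_pairs(B)

  for (p in pairsA) {                      # A averaged over B
    w <- zero
    for (b in B) { w[cond(p[1], b)] <- 1 / length(B); w[cond(p[2], b)] <- -1 / length(B) }
    add(new_contrast(sprintf("[%s-%s]", p[1], p[2]), "averaged", w, glm_design))
  }
  for (p in pairsA) for (b in B) {         # A within each B modality
    w <- zero; w[cond(p[1], b)] <- 1; w[cond(p[2], b)] <- -1
    add(new_contrast(sprintf("[%s_%s-%s_%s]", b, p[1], b, p[2]),
                     "per_modality", w, glm_design))
  }
  for (p in pairsB) {                      # B averaged over A
    w <- zero
    for (a in A) { w[cond(a, p[1])] <- 1 / length(A); w[cond(a, p[2])] <- -1 / length(A) }
    add(new_contrast(sprintf("[%s-%s]", p[1], p[2]), "averaged", w, glm_design))
  }
  for (p in pairsB) for (a in A) {         # B within each A modality
    w <- zero; w[cond(a, p[1])] <- 1; w[cond(a, p[2])] <- -1
    add(new_contrast(sprintf("[%s_%s-%s_%s]", a, p[1], a, p[2]),
                     "per_modality", w, glm_design))
  }
  for (pa in pairsA) for (pb in pairsB) {  # differences of differences
    w <- zero
    w[cond(pa[1], pb[1])] <- 1;  w[cond(pa[1], pb[2])] <- -1
    w[cond(pa[2], pb[1])] <- -1; w[cond(pa[2], pb[2])] <- 1
    nm <- sprintf("[%s_%s-%s_%s]-[%s_%s-%s_%s]",
                  pa[1], pb[1], pa[1], pb[2], pa[2], pb[1], pa[2], pb[2])
    add(new_contrast(nm, "interaction", w, glm_design,
                     degenerate = !glm_design$with_interaction))
  }
  if (!include_degenerate)
    out <- Filter(function(cl) !cl$degenerate, out)
  out
}

level_pairs <- function(levels) {
  if (length(levels) < 2L) return(list())
  idx <- utils::combn(length(levels), 2L, simplify = FALSE)
  lapply(idx, function(i) levels[i])
}

#' Parse a contrast name back into kind and modalities
#'
#' Inverts the naming grammar of [generate_contrasts()] using the factor
#' levels for disambiguation (modalities containing `-` or `_` that collide
#' with other level names are not supported by the grammar).
#'
#' @param name Contrast name string.
#' @param glm_design A `fex_glm_design` giving the level sets.
#' @return List with `kind` and `modalities` (character vector).
#' @export
parse_contrast_name <- function(name, glm_design) {
  lv <- glm_design$factor_levels
  if (grepl("]-[", name, fixed = TRUE)) {
    inner <- regmatches(name, gregexpr("\\[[^][]*\\]", name))[[1L]]
    parts <- unlist(lapply(inner, function(s) parse_bracket(s, lv)))
    return(list(kind = "interaction", modalities = unique(parts)))
  }
  parts <- parse_bracket(name, lv)
  kind <- if (length(parts) == 2L) "averaged" else "per_modality"
  list(kind = kind, modalities = unique(parts))
}

parse_bracket <- function(s, lv) {
  body <- sub("^\\[", "", sub("\\]$", "", s))
  halves <- strsplit(body, "-", fixed = TRUE)[[1L]]
  if (length(halves) != 2L) stop_fex("cannot parse contrast name '%s'", s)
  all_levels <- unlist(lv, use.names = FALSE)
  split_term <- function(term) {
    if (term %in% all_levels) return(term)
    for (l1 in all_levels) for (l2 in all_levels) {
      if (identical(term, paste(l1, l2, sep = "_"))) return(c(l1, l2))
    }
    stop_fex("cannot resolve modalities in contrast term '%s'", term)
  }
  unlist(lapply(halves, split_term))
}
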