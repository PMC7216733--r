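# Seeded generators of factorial NB count data with planted differential
# expression, planted co-expression clusters and planted enriched terms,
# together with the ground truth needed by recovery tests.

#' Specification of a synthetic factorial experiment
#'
#' @param factor_names Names of the 1-2 biological factors.
#' @param modalities List of modality vectors, one per factor.
#' @param replicates Replicates per condition: a scalar, or a vector/matrix
#'   over conditions for unbalanced designs.
#' @param n_genes Number of genes.
#' @param baseline_log2_range Range of the uniform baseline log2 mean
#'   (default `c(3, 12)`).
#' @param lib_sdlog Log-normal sd of the library-size multipliers
#'   (default 0.1, mean log 0).
#' @param phi NB dispersion (scalar or per gene); variance `mu + phi mu^2`.
#' @param de_fraction Fractions of genes carrying a planted main-A, main-B
#'   and interaction effect (named or positional vector of length 3; the
#'   second/third entries are ignored for one-factor designs).
#' @param effect_log2 Absolute planted effect size on the log2 scale
#'   (default 2, i.e. 4-fold); signs are randomized per gene.
#' @param seed Integer seed.
#' @return A `fex_sim_spec` list.
#' @export
simulation_spec <- function(factor_names = c("Tissue", "Treatment"),
                            modalities = list(c("MatureLeaf", "Root"), c("NoSi", "Si")),
                            replicates = 3L,
                            n_genes = 2000L,
                            baseline_log2_range = c(3, 12),
                            lib_sdlog = 0.1,
                            phi = 0.1,
                            de_fraction = c(A = 0.1, B = 0.1, AB = 0.05),
                            effect_log2 = 2,
                            seed = 1L) {
  if (length(factor_names) != length(modalities))
    stop_fex("one modality vector per factor required")
  if (any(de_fraction < 0 | de_fraction > 1)) stop_fex("de_fraction must lie in [0, 1]")
  if (n_genes < 1L) stop_fex("n_genes must be >= 1")
  structure(list(factor_names = factor_names, modalities = modalities,
                 replicates = replicates, n_genes = as.integer(n_genes),
                 baseline_log2_range = baseline_log2_range,
                 lib_sdlog = lib_sdlog, phi = phi,
                 de_fraction = rep_len(de_fraction, 3L),
                 effect_log2 = effect_log2, seed = as.integer(seed)),
            class = "fex_sim_spec")
}

sim_condition_grid <- function(spec) {
  mods <- spec$modalities
  if (length(mods) == 1L) {
    data.frame(A = mods[[1L]], stringsAsFactors = FALSE)
  } else {
    # A varies slowest, matching the condition_map ordering downstream
    expand.grid(B = mods[[2L]], A = mods[[1L]],
                stringsAsFactors = FALSE)[, c("A", "B")]
  }
}

#' Simulate a factorial NB count dataset with planted effects
#'
#' Per-gene condition log2 means are built additively: a uniform baseline,
#' plus planted main effects for a seeded fraction of genes and (for
#' two-factor designs) planted interaction effects. Counts are drawn as
#' `NB(mean = mu_gj * l_j, var = mu + phi mu^2)` with log-normal library
#' multipliers `l_j`. Ground truth per contrast is the set of genes whose
#' planted condition log2 means give a non-zero value of that contrast.
#'
#' @param spec A `fex_sim_spec` from [simulation_spec()].
#' @return List: `project` (a validated `fex_project`), `truth` (list with
#'   `condition_log2_means`, `de_genes` per generated contrast name,
#'   `effects`, `lib_multipliers`, `phi`, `spec`).
#' @export
simulate_counts <- function(spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, "counts"))
  grid <- sim_condition_grid(spec)
  two <- ncol(grid) == 2L
  n_cond <- nrow(grid)
  reps <- rep_len(as.integer(spec$replicates), n_cond)
  G <- spec$n_genes

  # sample layout and target table
  cond_lab <- if (two) paste(grid$A, grid$B, sep = "_") else grid$A
  sample_ids <- unlist(lapply(seq_len(n_cond), function(i)
    paste0(cond_lab[i], "_R", seq_len(reps[i]))))
  cols <- data.frame(matrix(nrow = length(sample_ids), ncol = 0))
  cols[[spec$factor_names[1L]]] <- rep(grid$A, reps)
  if (two) cols[[spec$factor_names[2L]]] <- rep(grid$B, reps)
  cols$Replicate <- unlist(lapply(reps, function(r) paste0("R", seq_len(r))))
  design <- design_table(sample_ids, cols, spec$factor_names, "Replicate")

  # planted effects
  base <- stats::runif(G, spec$baseline_log2_range[1], spec$baseline_log2_range[2])
  pick <- function(frac) sort(sample.int(G, round(frac * G)))
  sgn <- function(idx) sample(c(-1, 1), length(idx), replace = TRUE)
  effects <- list()
  lm2 <- matrix(base, G, n_cond)            # condition log2 means
  colnames(lm2) <- if (two) paste(grid$A, grid$B, sep = ".") else grid$A
  rownames(lm2) <- sprintf("gene%05d", seq_len(G))

  a_lv <- spec$modalities[[1L]]
  idxA <- pick(spec$de_fraction[1L])
  effects$A <- stats::setNames(sgn(idxA) * spec$effect_log2, rownames(lm2)[idxA])
  for (g in seq_along(idxA)) {
    shift <- effects$A[g]
    on <- grid$A != a_lv[1L]                # non-reference A modalities shifted
    lm2[idxA[g], on] <- lm2[idxA[g], on] + shift
  }
  if (two) {
    b_lv <- spec$modalities[[2L]]
    idxB <- pick(spec$de_fraction[2L])
    effects$B <- stats::setNames(sgn(idxB) * spec$effect_log2, rownames(lm2)[idxB])
    for (g in seq_along(idxB)) {
      on <- grid$B != b_lv[1L]
      lm2[idxB[g], on] <- lm2[idxB[g], on] + effects$B[g]
    }
    idxI <- pick(spec$de_fraction[3L])
    effects$AB <- stats::setNames(sgn(idxI) * spec$effect_log2, rownames(lm2)[idxI])
    for (g in seq_along(idxI)) {
      on <- grid$A != a_lv[1L] & grid$B != b_lv[1L]
      lm2[idxI[g], on] <- lm2[idxI[g], on] + effects$AB[g]
    }
  }

  # counts
  lmult <- stats::rlnorm(length(sample_ids), 0, spec$lib_sdlog)
  phis <- rep_len(spec$phi, G)
  cond_of_sample <- rep(seq_len(n_cond), reps)
  counts <- matrix(0L, G, length(sample_ids),
                   dimnames = list(rownames(lm2), sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- 2^lm2[, cond_of_sample[j]] * lmult[j]
    pois <- phis < 1e-12
    y <- integer(G)
    if (any(pois)) y[pois] <- as.integer(stats::rpois(sum(pois), mu[pois]))
    if (any(!pois)) y[!pois] <- as.integer(stats::rnbinom(sum(!pois), mu = mu[!pois],
                                                          size = 1 / phis[!pois]))
    counts[, j] <- y
  }

  project <- align_and_validate(counts, design, "synthetic")
  glm_design <- build_design_matrix(design, with_interaction = two)
  contrasts <- generate_contrasts(glm_design)
  de_genes <- lapply(contrasts, function(cl) {
    vals <- lm2[, names(cl$weights_on_conditions), drop = FALSE] %*%
      cl$weights_on_conditions
    rownames(lm2)[abs(vals) > 1e-9]
  })
  list(project = project,
       truth = list(condition_log2_means = lm2, de_genes = de_genes,
                    effects = effects,
                    lib_multipliers = stats::setNames(lmult, sample_ids),
                    phi = phis, spec = spec))
}

#' Simulate counts with planted co-expression clusters
#'
#' Genes within a cluster share a condition profile (a spiky Dirichlet-like
#' draw over the samples); per-gene totals vary, and NB noise with
#' dispersion `phi` is added. Labels are returned for recovery tests.
#'
#' @param n_clusters Number of planted clusters (>= 1).
#' @param sizes Genes per cluster (scalar or vector).
#' @param n_samples Number of samples (columns).
#' @param phi NB dispersion of the noise (default 0.02).
#' @param total_range Range of per-gene mean normalized totals
#'   (default `c(500, 5000)`).
#' @param concentration Dirichlet concentration of the cluster profiles
#'   (smaller = spikier, better separated; default 0.7).
#' @param seed Integer seed.
#' @return List: `counts` (gene x sample integer matrix), `labels` (planted
#'   cluster per gene), `profiles` (planted cluster profiles).
#' @export
simulate_coexpression <- function(n_clusters, sizes = 120L, n_samples = 12L,
                                  phi = 0.02, total_range = c(500, 5000),
                                  concentration = 0.7, seed = 1L) {
  if (n_clusters < 1L) stop_fex("need >= 1 cluster")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "coexpr"))
  sizes <- rep_len(as.integer(sizes), n_clusters)
  G <- sum(sizes)
  # Dirichlet draws via gamma
  profiles <- t(vapply(seq_len(n_clusters), function(k) {
    g <- stats::rgamma(n_samples, shape = concentration)
    g / sum(g)
  }, numeric(n_samples)))
  labels <- rep(seq_len(n_clusters), sizes)
  totals <- stats::runif(G, total_range[1], total_range[2])
  mu <- profiles[labels, , drop = FALSE] * totals * n_samples
  counts <- if (phi < 1e-12) {
    matrix(as.integer(stats::rpois(length(mu), mu)), G, n_samples)
  } else {
    matrix(as.integer(stats::rnbinom(length(mu), mu = mu, size = 1 / phi)),
           G, n_samples)
  }
  dimnames(counts) <- list(sprintf("cxg%05d", seq_len(G)),
                           sprintf("S%02d", seq_len(n_samples)))
  list(counts = counts,
       labels = stats::setNames(labels, rownames(counts)),
       profiles = profiles)
}

#' Simulate a gene annotation with planted enriched terms
#'
#' @param genes Universe of gene ids.
#' @param n_terms Number of background terms.
#' @param planted Named list: term name -> character vector of genes
#'   carrying it (attached deterministically).
#' @param background_rate Probability that any (gene, background term)
#'   pair exists (default 0.01).
#' @param seed Integer seed.
#' @return A `fex_annotation`.
#' @export
simulate_annotation <- function(genes, n_terms = 20L, planted = list(),
                                background_rate = 0.01, seed = 1L) {
  if (background_rate < 0 || background_rate > 1)
    stop_fex("background_rate must lie in [0, 1]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "annot"))
  gs <- ts <- character(0)
  if (n_terms > 0L && background_rate > 0) {
    terms <- sprintf("TERM%03d", seq_len(n_terms))
    hit <- which(matrix(stats::runif(length(genes) * n_terms), length(genes)) <
                   background_rate, arr.ind = TRUE)
    gs <- genes[hit[, 1L]]; ts <- terms[hit[, 2L]]
  }
  for (nm in names(planted)) {
    gs <- c(gs, planted[[nm]]); ts <- c(ts, rep(nm, length(planted[[nm]])))
  }
  annotation_pairs(gs, ts)
}

#' Write a synthetic project to disk in the standard project layout
#'
#' Emits `Data/<name>/<name>_COUNTS.csv` and `<name>_TARGET.csv` in the
#' dialect [read_counts()]/[read_target()] accept, plus `truth.json`.
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Workspace root (contains `Data/`).
#' @param name Project name.
#' @return The project data directory, invisibly.
#' @export
write_simulation <- function(sim, dir, name = "synthetic") {
  pdir <- file.path(dir, "Data", name)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$project$counts, file.path(pdir, paste0(name, "_COUNTS.csv")))
  design <- sim$project$design
  tgt <- data.frame(Sample = design$sample_ids, check.names = FALSE)
  for (nm in names(design$biological_factors))
    tgt[[nm]] <- as.character(design$biological_factors[[nm]])
  if (!is.null(design$replicate_factor))
    tgt[[design$replicate_name]] <- as.character(design$replicate_factor)
  utils::write.table(tgt, file.path(pdir, paste0(name, "_TARGET.csv")),
                     sep = ",", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$spec <- unclass(truth$spec)
  truth$condition_log2_means <- NULL        # large; regenerate from the spec
  jsonlite::write_json(truth, file.path(pdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(pdir)
}
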