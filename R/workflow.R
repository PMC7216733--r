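# Orchestration of the full workflow over the Data/<project> ->
# Results/<project> directory layout, driven by a declarative config.

#' Default workflow configuration
#'
#' Returns the full configuration list with defaults; fields supplied in
#' `...` (or read from a YAML file via [read_config()]) override them.
#'
#' @param project Project name (`Data/<project>/<project>_COUNTS.csv`).
#' @param factors Names of the biological-factor columns in the target.
#' @param ... Overrides, see the vignette for the field list.
#' @return A named list.
#' @export
workflow_config <- function(project, factors, ...) {
  cfg <- list(
    project = project,
    factors = factors,
    replicate = "Replicate",
    sample_filters = list(),
    filter_strategy = "NbConditions",
    cpm_cutoff = 1,
    normalization = "TMM",
    interaction = TRUE,
    alpha = 0.05,
    dispersion = "tagwise",
    prior_df = 10,
    contrasts = "all",
    venn = NULL,                 # character vector of contrast names
    coexpression = list(enabled = TRUE, input = "union",
                        contrasts = NULL,   # default: all tested contrasts
                        mean_filter_cutoff = 50,
                        grid = c(5L, 10L, 15L, 20L, 25L, 30L),
                        loop1_inits = 5L, loop2_inits = 40L),
    annotation = NULL,           # path to a gene/term file
    enrichment_alpha = 0.05,
    qc = TRUE,
    qc_only = FALSE,             # stop after filtering/normalization/QC
    seed = 1L)
  utils::modifyList(cfg, list(...))
}

#' Read a YAML workflow configuration
#' @param path YAML file with the fields of [workflow_config()].
#' @return Config list with defaults filled in.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$project) || is.null(raw$factors))
    stop_fex("config must declare 'project' and 'factors'")
  do.call(workflow_config,
          c(list(project = raw$project, factors = raw$factors),
            raw[setdiff(names(raw), c("project", "factors"))]))
}

write_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sanitize_name <- function(x) gsub("[^][A-Za-z0-9._-]", "_", x)

#' Run the complete workflow for a project
#'
#' Executes load -> QC -> contrasts -> differential analysis -> set
#' operations -> co-expression -> enrichment against the standard
#' directory layout (`Data/<project>/` inputs, `Results/<project>/`
#' outputs). Every stage logs its parameters to `run.log`; co-expression
#' fits are checkpointed so an interrupted run resumes. Identical config
#' and seed reproduce identical outputs.
#'
#' @param config A config list from [workflow_config()] or [read_config()].
#' @param dir Workspace root containing `Data/` (default `"."`).
#' @param results_dir Output root (default `file.path(dir, "Results")`).
#' @return Invisibly, a list with the stage results (`project`, `filter`,
#'   `norm`, `qc`, `diff`, `venn`, `coexp`, `enrichment`).
#' @export
run_project <- function(config, dir = ".", results_dir = file.path(dir, "Results")) {
  out <- file.path(results_dir, config$project)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  log_line <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                        sprintf(...)), file = logf, append = TRUE)
  cat(sprintf("# workflow run, config echo\n%s", yaml::as.yaml(config)), file = logf)
  stage <- function(name, expr) {
    log_line("stage %s: start", name)
    r <- tryCatch(expr, error = function(e) {
      log_line("stage %s: ERROR %s", name, conditionMessage(e))
      stop_fex("stage '%s' failed: %s", name, conditionMessage(e))
    })
    log_line("stage %s: done", name)
    r
  }

  # --- load ------------------------------------------------------------
  ddir <- file.path(dir, "Data", config$project)
  project <- stage("load", {
    counts <- read_counts(file.path(ddir, paste0(config$project, "_COUNTS.csv")))
    design <- read_target(file.path(ddir, paste0(config$project, "_TARGET.csv")),
                          config$factors, config$replicate)
    p <- align_and_validate(counts, design, config$project)
    filter_samples(p, config$sample_filters)
  })
  annotation <- NULL
  if (!is.null(config$annotation))
    annotation <- stage("annotation", read_annotation(config$annotation))

  # --- filter + normalize + qc ----------------------------------------
  fl <- stage("filter", filter_low_expressed(project, config$filter_strategy,
                                             config$cpm_cutoff))
  write_csv(data.frame(gene = c(fl$report$kept_genes, fl$report$removed_genes),
                       kept = rep(c(TRUE, FALSE),
                                  c(length(fl$report$kept_genes),
                                    length(fl$report$removed_genes)))),
            file.path(out, "filtered_genes.csv"))
  fproj <- fl$project
  norm <- stage("normalize", normalize_project(fproj, config$normalization))
  qc <- NULL
  if (isTRUE(config$qc)) {
    qc <- stage("qc", qc_summaries(fproj, norm))
    write_csv(data.frame(sample = names(qc$library_sizes),
                         library_size = as.integer(qc$library_sizes)),
              file.path(out, "library_sizes.csv"))
    write_csv(qc$boxplot_stats, file.path(out, "boxplot_stats.csv"))
    write_csv(data.frame(sample = rownames(qc$pca$coordinates),
                         qc$pca$coordinates[, seq_len(min(4, ncol(qc$pca$coordinates))),
                                            drop = FALSE],
                         check.names = FALSE),
              file.path(out, "pca_coordinates.csv"))
    jsonlite::write_json(list(merge = qc$dendrogram$merge,
                              height = qc$dendrogram$height,
                              labels = qc$dendrogram$labels),
                         file.path(out, "dendrogram.json"), digits = NA)
  }

  if (isTRUE(config$qc_only)) {
    log_line("workflow complete (qc only)")
    return(invisible(list(project = fproj, filter = fl$report, norm = norm,
                          qc = qc, results_dir = out)))
  }

  # --- contrasts + differential analysis ------------------------------
  diff <- stage("diff", diff_analysis(fproj, norm,
                                      with_interaction = config$interaction,
                                      contrasts = config$contrasts,
                                      alpha = config$alpha,
                                      dispersion = config$dispersion,
                                      prior_df = config$prior_df))
  ctab <- data.frame(name = names(diff$contrasts),
                     kind = vapply(diff$contrasts, `[[`, "", "kind"),
                     t(vapply(diff$contrasts, `[[`, numeric(ncol(diff$glm_design$design_matrix)),
                              "vector")), check.names = FALSE)
  write_csv(ctab, file.path(out, "Contrasts.csv"))

  eff <- norm$effective_sizes
  norm_counts <- compute_cpm(fproj$counts, eff) * mean(eff) / 1e6
  cond <- condition_labels(fproj$design)
  cond_means <- vapply(unique(cond), function(cc)
    rowMeans(norm_counts[, cond == cc, drop = FALSE]), numeric(nrow(norm_counts)))
  cond_means <- matrix(cond_means, nrow = nrow(norm_counts),
                       dimnames = list(rownames(norm_counts),
                                       paste0("mean_", unique(cond))))
  log_expr <- log2(norm_counts + 1)
  diffdir <- file.path(out, "DiffAnalysis")
  for (nm in names(diff$tests)) {
    cdir <- file.path(diffdir, sanitize_name(nm))
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    tt <- diff$tests[[nm]]
    tab <- cbind(tt, cond_means[tt$gene, , drop = FALSE])
    if (!is.null(annotation)) {
      terms <- vapply(tab$gene, function(g)
        paste(annotation$term[annotation$gene == g], collapse = ";"), "")
      tab$annotation <- terms
    }
    write_csv(tab, file.path(cdir, "all_genes.csv"))
    write_csv(tab[tab$deg, , drop = FALSE], file.path(cdir, "DEG.csv"))
    d <- diff$diagnostics[[nm]]
    write_csv(data.frame(bin_upper = d$breaks[-1L], count = d$counts),
              file.path(cdir, "pvalue_histogram.csv"))
    top <- top_degs(tt, 50L, log_expr)
    if (length(top$genes))
      write_csv(data.frame(gene = top$genes, top$matrix, check.names = FALSE),
                file.path(cdir, "top50_heatmap_data.csv"))
  }
  write_csv(summary(diff), file.path(diffdir, "deg_summary.csv"))

  # --- set operations --------------------------------------------------
  degs <- deg_lists(diff)
  venn <- NULL
  venn_names <- config$venn %||% names(degs)
  if (length(venn_names) >= 2L) {
    venn <- stage("venn", venn_regions(degs[venn_names]))
    write_csv(data.frame(signature = names(venn),
                         size = lengths(venn),
                         ids = vapply(venn, paste, "", collapse = ";")),
              file.path(out, "venn_regions.csv"))
  }

  # --- co-expression ---------------------------------------------------
  coexp <- NULL
  cx <- config$coexpression
  if (isTRUE(cx$enabled)) {
    cx_contrasts <- cx$contrasts %||% names(degs)
    gene_list <- combine_lists(degs[cx_contrasts], cx$input %||% "union")
    writeLines(gene_list, file.path(out, "combined_list.txt"))
    if (length(gene_list) > 2L) {
      cxdir <- file.path(out, "Coexpression")
      dir.create(cxdir, showWarnings = FALSE)
      coexp <- stage("coexpression",
                     coexpression(fproj$counts[gene_list, , drop = FALSE], norm,
                                  mean_filter_cutoff = cx$mean_filter_cutoff %||% 50,
                                  grid = cx$grid %||% c(5L, 10L, 15L, 20L, 25L, 30L),
                                  loop1_inits = cx$loop1_inits %||% 5L,
                                  loop2_inits = cx$loop2_inits %||% 40L,
                                  seed = derive_seed(config$seed, "coexpression"),
                                  checkpoint_dir = file.path(cxdir, "checkpoints")))
      maxpost <- apply(coexp$selection$best$posteriors, 1L, max)
      write_csv(data.frame(gene = names(coexp$assignments),
                           cluster = as.integer(coexp$assignments),
                           max_posterior = ifelse(coexp$assignments == 0, NA,
                                                  maxpost[match(names(coexp$assignments),
                                                                rownames(coexp$profiles))])),
                file.path(cxdir, "cluster_assignments.csv"))
      write_csv(coexp$selection$icl_curve, file.path(cxdir, "icl_curve.csv"))
      cp <- cluster_profiles(coexp)
      write_csv(data.frame(cluster = rownames(cp), cp, check.names = FALSE),
                file.path(cxdir, "cluster_profiles.csv"))
      write_csv(summary(coexp), file.path(cxdir, "cluster_sizes.csv"))
    } else log_line("coexpression skipped: fewer than 3 genes in the combined list")
  }

  # --- enrichment ------------------------------------------------------
  enr <- NULL
  if (!is.null(annotation)) {
    edir <- file.path(out, "Enrichment")
    dir.create(edir, showWarnings = FALSE)
    universe <- fl$report$kept_genes
    enr <- stage("enrichment", {
      lists <- degs
      if (!is.null(coexp)) {
        for (cl in seq_len(coexp$selection$K)) {
          lists[[sprintf("cluster%d", cl)]] <-
            names(coexp$assignments)[coexp$assignments == cl]
        }
      }
      lists <- Filter(length, lists)
      res <- lapply(lists, function(l)
        tryCatch(suppressWarnings(enrich(l, annotation, universe,
                                         config$enrichment_alpha)),
                 error = function(e) NULL))
      for (nm in names(res)) if (!is.null(res[[nm]]))
        write_csv(res[[nm]], file.path(edir, sprintf("enrichment_%s.csv",
                                                     sanitize_name(nm))))
      res
    })
  }
  log_line("workflow complete")
  invisible(list(project = fproj, filter = fl$report, norm = norm, qc = qc,
                 diff = diff, venn = venn, coexp = coexp, enrichment = enr,
                 results_dir = out))
}
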