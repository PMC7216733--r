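#' Read a count table
#'
#' Reads a genes-by-samples table of raw counts. The first column holds gene
#' identifiers; every remaining column is one sample. The field separator is
#' auto-detected among comma, semicolon and tab from the header line.
#' Numeric values that are integral (e.g. `"12.0"`) are accepted and coerced
#' to integer counts.
#'
#' @param path Path to the counts file (`<project>_COUNTS.csv`).
#' @param sep Field separator; `NULL` (default) auto-detects.
#' @return An integer matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_counts <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_fex("counts file not found: %s", path)
  sep <- sep %||% detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 3L) stop_fex("counts file needs >= 2 sample columns, got %d", ncol(df) - 1L)
  genes <- as.character(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop_fex("duplicate gene id in counts file: %s", dup[1L])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(mat)))
    stop_fex("duplicate sample id in counts file: %s",
             colnames(mat)[duplicated(colnames(mat))][1L])
  suppressWarnings(storage <- apply(mat, 2L, as.numeric))
  bad <- which(!is.finite(storage) | storage < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_fex("invalid count (negative, missing or non-numeric) at gene '%s', sample '%s'",
             genes[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]])
  }
  if (any(abs(storage - round(storage)) > 1e-8)) {
    bad <- which(abs(storage - round(storage)) > 1e-8, arr.ind = TRUE)
    stop_fex("non-integer count at gene '%s', sample '%s'",
             genes[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]])
  }
  counts <- matrix(as.integer(round(storage)), nrow = nrow(mat),
                   dimnames = list(genes, colnames(mat)))
  counts
}

#' Write a count table
#'
#' Inverse of [read_counts()]; comma-separated, header `Gene_ID,<samples>`.
#' @param counts Integer matrix, genes x samples.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(Gene_ID = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c(",", ";", "\t"), function(s)
    lengths(regmatches(header, gregexpr(s, header, fixed = TRUE))), integer(1))
  if (all(counts == 0L)) stop_fex("cannot detect separator in %s", path)
  c(",", ";", "\t")[which.max(counts)]
}

#' Read a target (design) table
#'
#' The target table describes the experimental design: one row per sample,
#' the first column holding sample ids and one column per factor. Up to two
#' biological factors plus an optional replicate factor are supported.
#' Modality order is the order of first appearance in the file; the first
#' modality of each factor becomes the reference level of the GLM coding.
#'
#' @param path Path to the target file (`<project>_TARGET.csv`).
#' @param factor_names Character vector (length 1 or 2) naming the
#'   biological-factor columns.
#' @param replicate_name Name of the replicate column, or `NULL` if the
#'   design has no replicate factor.
#' @param sep Field separator; `NULL` auto-detects.
#' @return A `fex_design` object: list with `sample_ids`,
#'   `biological_factors` (named list of factors) and `replicate_factor`.
#' @export
read_target <- function(path, factor_names, replicate_name = NULL, sep = NULL) {
  if (!file.exists(path)) stop_fex("target file not found: %s", path)
  sep <- sep %||% detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  samples <- as.character(df[[1L]])
  design_table(samples, df[, -1L, drop = FALSE], factor_names, replicate_name)
}

#' Build a design table from in-memory columns
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param columns Data frame of factor columns (one per declared factor).
#' @param factor_names Names of the 1-2 biological factors.
#' @param replicate_name Name of the replicate factor or `NULL`.
#' @return A `fex_design` object.
#' @export
design_table <- function(sample_ids, columns, factor_names, replicate_name = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop_fex("duplicate sample id: %s", sample_ids[duplicated(sample_ids)][1L])
  if (length(factor_names) < 1L || length(factor_names) > 2L)
    stop_fex("1 or 2 biological factors required, got %d", length(factor_names))
  for (nm in c(factor_names, replicate_name)) {
    if (!nm %in% colnames(columns)) stop_fex("declared factor column '%s' is missing", nm)
    vals <- as.character(columns[[nm]])
    if (any(is.na(vals) | vals == ""))
      stop_fex("sample '%s' has no modality for factor '%s'",
               sample_ids[which(is.na(vals) | vals == "")[1L]], nm)
  }
  as_first_appearance <- function(v) {
    v <- as.character(v)
    factor(v, levels = unique(v))
  }
  bio <- lapply(columns[factor_names], as_first_appearance)
  names(bio) <- factor_names
  for (nm in factor_names) {
    if (nlevels(bio[[nm]]) < 2L)
      stop_fex("biological factor '%s' needs >= 2 modalities", nm)
  }
  rep_fac <- if (!is.null(replicate_name)) as_first_appearance(columns[[replicate_name]]) else NULL
  d <- structure(list(sample_ids = sample_ids,
                      biological_factors = bio,
                      replicate_factor = rep_fac,
                      replicate_name = replicate_name),
                 class = "fex_design")
  d
}

#' @export
print.fex_design <- function(x, ...) {
  cat(sprintf("Design: %d samples\n", length(x$sample_ids)))
  for (nm in names(x$biological_factors))
    cat(sprintf("  factor %s: %s\n", nm,
                paste(levels(x$biological_factors[[nm]]), collapse = ", ")))
  if (!is.null(x$replicate_factor))
    cat(sprintf("  replicate %s: %s\n", x$replicate_name,
                paste(levels(x$replicate_factor), collapse = ", ")))
  invisible(x)
}

# every combination of biological-factor modalities must occur >= 1 time
check_complete <- function(design) {
  tab <- condition_table(design)
  missing <- which(tab == 0L)
  if (length(missing)) {
    lab <- if (length(dim(tab)) == 2L) {
      idx <- arrayInd(missing, dim(tab))
      paste(rownames(tab)[idx[, 1L]], colnames(tab)[idx[, 2L]], sep = " x ")
    } else names(tab)[missing]
    stop_fex("incomplete design: no sample for condition(s) %s",
             paste(lab, collapse = ", "))
  }
  invisible(TRUE)
}

condition_table <- function(design) {
  facs <- design$biological_factors
  if (length(facs) == 1L) table(facs[[1L]]) else table(facs[[1L]], facs[[2L]])
}

#' Align counts with a design table and validate the project
#'
#' Reorders the count columns to the sample order of the target table,
#' checks the sample-id sets match exactly, and enforces the
#' complete-design constraint (every combination of biological-factor
#' modalities observed in at least one sample).
#'
#' @param counts Integer matrix from [read_counts()].
#' @param design `fex_design` from [read_target()].
#' @param name Project name.
#' @return A `fex_project` object.
#' @export
align_and_validate <- function(counts, design, name = "project") {
  cs <- colnames(counts); ds <- design$sample_ids
  if (!setequal(cs, ds)) {
    stop_fex("sample ids differ between counts and target (only in counts: %s; only in target: %s)",
             paste(setdiff(cs, ds), collapse = ",") %e% "-",
             paste(setdiff(ds, cs), collapse = ",") %e% "-")
  }
  counts <- counts[, ds, drop = FALSE]
  if (ncol(counts) < 2L) stop_fex("at least 2 samples required")
  check_complete(design)
  structure(list(counts = counts, design = design, name = name),
            class = "fex_project")
}

`%e%` <- function(a, b) if (nzchar(a)) a else b

#' @export
print.fex_project <- function(x, ...) {
  cat(sprintf("Project '%s': %d genes x %d samples\n",
              x$name, nrow(x$counts), ncol(x$counts)))
  print(x$design)
  invisible(x)
}

#' Keep or drop samples by factor modality
#'
#' Applies a list of filtering rules to a project. Each rule is a list
#' `list(factor=, modality=, action="keep"|"drop")`. Keep rules retain only
#' samples matching at least one keep rule on that factor; drop rules remove
#' matching samples. Factors left with a single modality are removed from
#' the design (the analysis becomes lower-dimensional); a replicate factor
#' left with one modality is dropped. The filtered design is re-validated
#' for completeness.
#'
#' @param project A `fex_project`.
#' @param rules List of rules as above; an empty list returns the project
#'   unchanged.
#' @return The filtered `fex_project`.
#' @export
filter_samples <- function(project, rules = list()) {
  if (!length(rules)) return(project)
  design <- project$design
  all_factors <- c(design$biological_factors,
                   stats::setNames(list(design$replicate_factor),
                                   design$replicate_name %||% "..none.."))
  all_factors <- Filter(Negate(is.null), all_factors)
  keep <- rep(TRUE, length(design$sample_ids))
  keep_rules <- list()
  for (r in rules) {
    if (!r$factor %in% names(all_factors))
      stop_fex("rule names unknown factor '%s'", r$factor)
    fac <- all_factors[[r$factor]]
    if (!r$modality %in% levels(fac))
      stop_fex("factor '%s' has no modality '%s'", r$factor, r$modality)
    if (identical(r$action, "drop")) {
      keep <- keep & fac != r$modality
    } else if (identical(r$action, "keep")) {
      keep_rules[[r$factor]] <- c(keep_rules[[r$factor]], r$modality)
    } else stop_fex("rule action must be 'keep' or 'drop'")
  }
  for (nm in names(keep_rules))
    keep <- keep & (as.character(all_factors[[nm]]) %in% keep_rules[[nm]])
  if (sum(keep) < 2L) stop_fex("filtering leaves %d sample(s); >= 2 required", sum(keep))

  samples <- design$sample_ids[keep]
  drop_single <- function(fac_list) {
    Filter(function(f) nlevels(f) >= 2L, lapply(fac_list, droplevels))
  }
  bio <- drop_single(lapply(design$biological_factors, function(f) f[keep]))
  if (!length(bio))
    stop_fex("filtering removed all biological variation; nothing to model")
  rep_fac <- design$replicate_factor
  rep_name <- design$replicate_name
  if (!is.null(rep_fac)) {
    rep_fac <- droplevels(rep_fac[keep])
    if (nlevels(rep_fac) < 2L) { rep_fac <- NULL; rep_name <- NULL }
  }
  new_design <- structure(list(sample_ids = samples, biological_factors = bio,
                               replicate_factor = rep_fac, replicate_name = rep_name),
                          class = "fex_design")
  align_and_validate(project$counts[, keep, drop = FALSE], new_design, project$name)
}

#' Read a gene-to-term annotation file
#'
#' Two columns (gene id, term id), no header required; extra columns are
#' ignored. Duplicated pairs are removed. Pairs for genes absent from the
#' count table are retained: the universe restriction happens at test time
#' in [enrich()].
#'
#' @param path Path to the annotation file.
#' @param sep Separator; `NULL` auto-detects.
#' @return A `fex_annotation`: data frame with columns `gene` and `term`.
#' @export
read_annotation <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_fex("annotation file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("annotation file is empty")
    return(annotation_pairs(character(0), character(0)))
  }
  sep <- sep %||% detect_sep(path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop_fex("malformed annotation row at line %d", bad[1L])
  first <- vapply(parts, `[`, "", 1L)
  second <- vapply(parts, `[`, "", 2L)
  # tolerate an optional header row
  if (tolower(first[1L]) %in% c("gene", "gene_id", "geneid")) {
    first <- first[-1L]; second <- second[-1L]
  }
  annotation_pairs(trimws(first), trimws(second))
}

#' Build an annotation from gene/term vectors
#' @param genes,terms Parallel character vectors of gene-term pairs.
#' @return A `fex_annotation` data frame (deduplicated).
#' @export
annotation_pairs <- function(genes, terms) {
  df <- unique(data.frame(gene = as.character(genes), term = as.character(terms),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("fex_annotation", "data.frame")
  df
}
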