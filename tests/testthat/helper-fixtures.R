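# fixtures built in code; no files needed beyond tempdir()

# the canonical 2 tissues x 2 treatments x 3 replicates target layout
table1_target <- function() {
  tissues <- c("MatureLeaf", "Root")
  treatments <- c("NoSi", "Si")
  reps <- c("R1", "R2", "R3")
  grid <- expand.grid(Replicate = reps, Treatment = treatments,
                      Tissue = tissues, stringsAsFactors = FALSE)
  grid <- grid[, c("Tissue", "Treatment", "Replicate")]
  grid$Sample <- with(grid, paste(Tissue, Treatment, Replicate, sep = "_"))
  grid[, c("Sample", "Tissue", "Treatment", "Replicate")]
}

table1_design <- function() {
  tgt <- table1_target()
  design_table(tgt$Sample, tgt[, -1L], c("Tissue", "Treatment"), "Replicate")
}

# random NB counts over an arbitrary design data frame
random_counts <- function(samples, n_genes, mu = 200, size = 5, seed = 1) {
  withr::with_seed(seed, {
    matrix(rnbinom(n_genes * length(samples), mu = mu, size = size),
           nrow = n_genes,
           dimnames = list(sprintf("g%04d", seq_len(n_genes)), samples))
  })
}

table1_project <- function(n_genes = 50, seed = 1) {
  d <- table1_design()
  align_and_validate(random_counts(d$sample_ids, n_genes, seed = seed), d)
}

# a complete I x J design with r replicates, single samples when r = 1
factorial_design <- function(I, J, r = 1L) {
  a <- paste0("a", seq_len(I)); b <- paste0("b", seq_len(J))
  grid <- expand.grid(rep = seq_len(r), B = b, A = a, stringsAsFactors = FALSE)
  samples <- with(grid, paste(A, B, rep, sep = "_"))
  cols <- data.frame(A = grid$A, B = grid$B)
  if (r > 1L) {
    cols$Rep <- paste0("r", grid$rep)
    design_table(samples, cols, c("A", "B"), "Rep")
  } else design_table(samples, cols, c("A", "B"))
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
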