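test_that("count tables round-trip through write/read and reject bad input", {
  counts <- matrix(c(0L, 5L, 12L, 3L, 7L, 100L), 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  f <- tempfile(fileext = ".csv")
  write_counts(counts, f)
  expect_identical(read_counts(f), counts)

  dup <- write_temp_csv(c("Gene_ID,s1,s2", "g1,1,2", "g1,3,4"))
  expect_error(read_counts(dup), "duplicate gene.*g1")

  neg <- write_temp_csv(c("Gene_ID,s1,s2", "g1,1,2", "g2,-1,4"))
  expect_error(read_counts(neg), "g2.*s1")

  frac <- write_temp_csv(c("Gene_ID,s1,s2", "g1,1.5,2", "g2,3,4"))
  expect_error(read_counts(frac), "non-integer")

  # integral-valued decimals are coerced
  dec <- write_temp_csv(c("Gene_ID;s1;s2", "g1;12.0;2", "g2;3;4"))
  expect_identical(read_counts(dec)["g1", "s1"], 12L)
})

test_that("the canonical two-factor target parses with first-appearance levels", {
  tgt <- table1_target()
  f <- write_temp_csv(c("Sample,Tissue,Treatment,Replicate",
                        apply(tgt, 1, paste, collapse = ",")))
  d <- read_target(f, c("Tissue", "Treatment"), "Replicate")
  expect_length(d$biological_factors, 2L)
  expect_identical(levels(d$biological_factors$Tissue), c("MatureLeaf", "Root"))
  expect_identical(levels(d$biological_factors$Treatment), c("NoSi", "Si"))
  expect_identical(levels(d$replicate_factor), c("R1", "R2", "R3"))
  expect_length(d$sample_ids, 12L)

  # single-factor, 3-replicate table is valid
  f1 <- write_temp_csv(c("Sample,Geno,Rep",
                         paste0("s", 1:6, ",", rep(c("wt", "mut"), each = 3),
                                ",", rep(c("r1", "r2", "r3"), 2))))
  d1 <- read_target(f1, "Geno", "Rep")
  expect_identical(levels(d1$biological_factors$Geno), c("wt", "mut"))

  # a missing modality value is fatal
  fbad <- write_temp_csv(c("Sample,Tissue,Treatment,Replicate",
                           "s1,Root,,R1", "s2,Root,Si,R2"))
  expect_error(read_target(fbad, c("Tissue", "Treatment"), "Replicate"),
               "no modality.*Treatment")
})

test_that("align_and_validate reorders columns, is idempotent, enforces completeness", {
  d <- table1_design()
  counts <- random_counts(d$sample_ids, 20)
  shuffled <- counts[, rev(colnames(counts))]
  p <- align_and_validate(shuffled, d)
  expect_identical(colnames(p$counts), d$sample_ids)
  expect_identical(p$counts, counts)

  p2 <- align_and_validate(p$counts, p$design)
  expect_identical(p2$counts, p$counts)

  # removing an entire condition breaks completeness
  keep <- !(d$sample_ids %in% grep("Root_Si", d$sample_ids, value = TRUE))
  dsub <- design_table(d$sample_ids[keep],
                       data.frame(Tissue = as.character(d$biological_factors$Tissue)[keep],
                                  Treatment = as.character(d$biological_factors$Treatment)[keep],
                                  Replicate = as.character(d$replicate_factor)[keep]),
                       c("Tissue", "Treatment"), "Replicate")
  # force both factors to keep both modalities so only the cell is empty
  expect_error(align_and_validate(counts[, keep], dsub), "incomplete design")

  expect_error(align_and_validate(counts[, -1], d), "sample ids differ")
})

test_that("filter_samples drops/keeps samples and re-derives the factor structure", {
  p <- table1_project()
  # dropping one tissue removes the Tissue factor entirely
  root <- filter_samples(p, list(list(factor = "Tissue", modality = "MatureLeaf",
                                      action = "drop")))
  expect_identical(ncol(root$counts), 6L)
  expect_named(root$design$biological_factors, "Treatment")

  # empty rules are the identity
  expect_identical(filter_samples(p, list())$counts, p$counts)

  # keeping one replicate leaves a valid replicate-free project
  r1 <- filter_samples(p, list(list(factor = "Replicate", modality = "R1",
                                    action = "keep")))
  expect_identical(sort(colnames(r1$counts)),
                   sort(grep("_R1$", colnames(p$counts), value = TRUE)))
  expect_null(r1$design$replicate_factor)

  # every remaining condition is non-empty (completeness preserved)
  expect_true(all(condition_labels(r1$design) %in%
                    c("MatureLeaf.NoSi", "MatureLeaf.Si", "Root.NoSi", "Root.Si")))
  expect_error(filter_samples(p, list(list(factor = "Tissue", modality = "Stem",
                                           action = "drop"))), "no modality")
})

test_that("annotation files deduplicate, warn on empty, keep out-of-universe genes", {
  f <- write_temp_csv(c("g1,T1", "g1,T2", "g2,T1", "g2,T1", "g3,T3"))
  ann <- read_annotation(f)
  expect_identical(nrow(ann), 4L)

  fe <- tempfile(); writeLines(character(0), fe)
  expect_warning(ann0 <- read_annotation(fe), "empty")
  expect_identical(nrow(ann0), 0L)

  # genes absent from any count table are retained until test time
  expect_true("g3" %in% ann$gene)
  fbad <- write_temp_csv(c("g1,T1", "justonefield"))
  expect_error(read_annotation(fbad), "line 2")
})
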