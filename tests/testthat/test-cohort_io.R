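test_that("read_cohort parses the example table and enforces the schema", {
  path <- system.file("extdata", "example_cohort.tsv", package = "gliomaCNS5")
  coh <- read_cohort(path)
  expect_s3_class(coh, "glioma_cohort")
  expect_equal(nrow(coh), 14)
  expect_equal(sum(coh$histology == "unknown"), 1)
  expect_true(all(coh$os_time >= 0, na.rm = TRUE))

  # missing required column is a schema error naming the column
  broken <- tempfile(fileext = ".tsv")
  df <- utils::read.delim(path)
  utils::write.table(df[, setdiff(names(df), "idh_status")], broken,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(broken), "idh_status")

  # duplicate case_id is an error
  dup <- rbind(df, df[1, ])
  utils::write.table(dup, broken, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(broken), "duplicate")

  # empty file with valid header yields an empty cohort
  utils::write.table(df[0, ], broken, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(nrow(read_cohort(broken)), 0)

  # unmapped level token maps to unknown with a warning
  df2 <- df
  df2$idh_status[1] <- "IDH1_R132H"
  utils::write.table(df2, broken, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_warning(coh2 <- read_cohort(broken), "idh_status")
  expect_equal(coh2$idh_status[1], "unknown")
})

test_that("cohort TSV round trip is byte-identical for canonical input", {
  sim <- simulate_cohort(small_sim_config(), seed = 42)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_cohort(sim$annotations, f1)
  write_cohort(read_cohort(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("IDH status extraction applies the codon and substitution filters", {
  maf <- maf_df(
    list("S1", "IDH1", "Missense_Mutation", "p.R132H"),
    list("S2", "TP53", "Missense_Mutation", "p.R273H"),
    list("S3", "IDH1", "Missense_Mutation", "p.V71I"),   # wrong codon
    list("S4", "IDH2", "Missense_Mutation", "p.R172K"),
    list("S5", "IDH1", "Silent",            "p.R132R"),  # not missense
    list("S6", "IDH1", "Missense_Mutation", "p.Arg132His"))  # 3-letter form
  expect_equal(extract_idh_status(maf, "S1"), "mutant")
  expect_equal(extract_idh_status(maf, "S2"), "wildtype")
  expect_equal(extract_idh_status(maf, "S3"), "wildtype")
  expect_equal(extract_idh_status(maf, "S4"), "mutant")
  expect_equal(extract_idh_status(maf, "S5"), "wildtype")
  expect_equal(extract_idh_status(maf, "S6"), "mutant")
})

test_that("H3 status extraction accepts both numbering conventions", {
  maf <- maf_df(
    list("S1", "H3F3A",    "Missense_Mutation", "p.G35R"),
    list("S2", "HIST1H3B", "Missense_Mutation", "p.K28M"),
    list("S3", "H3-3A",    "Missense_Mutation", "p.K27M"),
    list("S4", "H3F3A",    "Missense_Mutation", "p.K28R"),  # wrong alt
    list("S5", "HIST1H3B", "Missense_Mutation", "p.G35R"),  # G34 only in H3-3A
    list("S6", "H3F3A",    "Missense_Mutation", "p.K28M"),
    list("S6", "H3F3A",    "Missense_Mutation", "p.G35R"))
  expect_equal(extract_h3_status(maf, "S1"), "G34_mut")
  expect_equal(extract_h3_status(maf, "S2"), "K27M")
  expect_equal(extract_h3_status(maf, "S3"), "K27M")
  expect_equal(extract_h3_status(maf, "S4"), "wildtype")
  expect_equal(extract_h3_status(maf, "S5"), "wildtype")
  # both hotspots: K27M wins with a conflict warning
  expect_warning(st <- extract_h3_status(maf, "S6"), "both")
  expect_equal(st, "K27M")
})

test_that("extraction is order-independent and skips unparseable records", {
  maf <- maf_df(
    list("S1", "IDH1", "Missense_Mutation", "garbage"),
    list("S1", "IDH1", "Missense_Mutation", "p.R132H"))
  expect_warning(st <- extract_idh_status(maf, "S1"), "unparseable")
  expect_equal(st, "mutant")
  shuffled <- maf[rev(seq_len(nrow(maf))), ]
  st2 <- suppressWarnings(extract_idh_status(shuffled, "S1"))
  expect_equal(st2, st)   # set semantics: row order irrelevant
})

test_that("read_maf reads the example MAF and extraction matches annotations", {
  maf <- read_maf(system.file("extdata", "example_mutations.maf",
                              package = "gliomaCNS5"))
  expect_equal(extract_idh_status(maf, "TCGA-EX-0004-01A"), "mutant")
  expect_equal(extract_idh_status(maf, "TCGA-EX-0009-01A"), "wildtype")
  expect_equal(extract_h3_status(maf, "TCGA-EX-0012-01A"), "K27M")
})

test_that("apply_maf_statuses distinguishes no-data from confirmed wildtype", {
  coh <- as_glioma_cohort(rbind(
    case_row("A", idh_status = "unknown"),
    case_row("B", idh_status = "unknown"),
    case_row("C", idh_status = "mutant")))
  maf <- maf_df(list("A-01A", "TP53", "Missense_Mutation", "p.R273H"))
  out <- apply_maf_statuses(coh, maf)
  expect_equal(out$idh_status, c("wildtype", "unknown", "mutant"))
  expect_equal(attr(out, "maf_resolved")[["idh"]], 1L)
})

test_that("methylation aggregation averages probes excluding missing values", {
  betas <- matrix(c(0.2, 0.4, 0.9,
                    0.1, NA,  0.8), nrow = 3,
                  dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- c(p1 = "G1", p2 = "G1", p3 = "G2")
  agg <- aggregate_methylation(betas, map)
  expect_equal(agg["G1", "s1"], 0.3)
  expect_equal(agg["G1", "s2"], 0.1)    # mean of remaining after NA
  expect_equal(agg["G2", "s1"], 0.9)    # single-probe passthrough
  expect_true(all(agg >= 0 & agg <= 1, na.rm = TRUE))
  expect_identical(colnames(agg), colnames(betas))

  # unmapped probe dropped with a message; median mode
  map2 <- c(p1 = "G1", p2 = "G1", p3 = "")
  expect_message(agg2 <- aggregate_methylation(betas, map2, fun = "median"),
                 "dropped")
  expect_equal(rownames(agg2), "G1")

  expect_error(aggregate_methylation(betas * 2, map), "0, 1")
})

test_that("aggregation preserves range and sample set on simulated data", {
  cfg <- small_sim_config()
  sim <- simulate_cohort(cfg, seed = 9)
  met <- simulate_methylation(sim$truth, cfg, seed = 10)
  agg <- aggregate_methylation(met$betas, met$probe_to_gene)
  expect_identical(colnames(agg), colnames(met$betas))
  expect_true(all(agg >= 0 & agg <= 1))
  expect_equal(nrow(agg), length(unique(met$probe_to_gene)))
})

test_that("matrix TSV and MTX readers agree", {
  m <- matrix(rpois(12, 20), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  m1 <- read_matrix_tsv(tsv)
  expect_equal(m1, m, ignore_attr = FALSE)

  mtx <- tempfile(fileext = ".mtx")
  gf <- tempfile(); sf <- tempfile()
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
  writeLines(rownames(m), gf); writeLines(colnames(m), sf)
  m2 <- read_matrix_mtx(mtx, gf, sf)
  expect_equal(m2, m)
})
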