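test_that("classify_case follows the decision tree on canonical cases", {
  d <- classify_case(case_row(histology = "oligoastrocytoma",
                              hist_grade = "III", idh_status = "mutant",
                              codel_1p19q = "yes"))
  expect_equal(d$category, "OLIGO_IDH_MUT_CODEL")
  expect_equal(d$grade, 3L)

  d <- classify_case(case_row(histology = "glioblastoma", hist_grade = "IV",
                              idh_status = "unknown"))
  expect_equal(d$category, "NA")
  expect_equal(d$na_reason, "idh_unknown")

  # "molecular glioblastoma": lower-grade histology with a GBM marker
  d <- classify_case(case_row(histology = "astrocytoma", hist_grade = "II",
                              idh_status = "wildtype", atrx = "wildtype",
                              tertp = "mutant"))
  expect_equal(d$category, "GBM_IDH_WT")
  expect_equal(d$grade, 4L)

  # CDKN2A/B homozygous deletion elevates an IDH-mutant astrocytoma to 4
  d <- classify_case(case_row(histology = "astrocytoma", hist_grade = "II",
                              idh_status = "mutant", codel_1p19q = "no",
                              cdkn2ab_hd = "yes"))
  expect_equal(d$category, "ASTRO_IDH_MUT")
  expect_equal(d$grade, 4L)

  # H3 K27M takes the pediatric-type exit whatever the histology
  for (h in c("astrocytoma", "glioblastoma", "oligodendroglioma")) {
    d <- classify_case(case_row(histology = h, hist_grade = "IV",
                                idh_status = "wildtype",
                                h3_status = "K27M"))
    expect_equal(d$category, "PEDIATRIC_H3_K27")
    expect_true(is.na(d$grade))
  }

  # first matching rule: all-unknown molecular fields on known histology
  d <- classify_case(list(case_id = "X", histology = "astrocytoma"))
  expect_equal(d$category, "NA")
  expect_equal(d$na_reason, "idh_unknown")
})

test_that("ATRX shortcut applies only when codeletion is unknown", {
  base <- case_row(idh_status = "mutant", atrx = "mutant")
  base$codel_1p19q <- "unknown"
  expect_equal(classify_case(base)$category, "ASTRO_IDH_MUT")
  base$codel_1p19q <- "yes"   # measured codeletion wins over the shortcut
  expect_equal(classify_case(base)$category, "OLIGO_IDH_MUT_CODEL")
  base$atrx <- "wildtype"; base$codel_1p19q <- "unknown"
  d <- classify_case(base)
  expect_equal(d$category, "NA")
  expect_equal(d$na_reason, "codel_unresolvable")
})

test_that("rule engine is total, deterministic and respects invariants on the full grid", {
  grid <- feature_grid()
  fit <- classify_cohort(grid)
  d <- fit$diagnoses
  expect_equal(nrow(d), nrow(grid))

  # exactly one diagnosis each, category always valid
  valid <- c("OLIGO_IDH_MUT_CODEL", "ASTRO_IDH_MUT", "GBM_IDH_WT",
             "PEDIATRIC_H3_K27", "PEDIATRIC_H3_G34", "NA",
             "EXCLUDED_UNKNOWN_HISTOLOGY")
  expect_true(all(d$category %in% valid))

  # determinism: a second run is identical
  expect_identical(d, classify_cohort(grid)$diagnoses)

  # grade bounds per category
  expect_true(all(d$grade[d$category == "OLIGO_IDH_MUT_CODEL"] %in% 2:3))
  expect_true(all(d$grade[d$category == "GBM_IDH_WT"] == 4L))
  expect_true(all(d$grade[d$category == "ASTRO_IDH_MUT"] %in% 2:4))
  expect_true(all(is.na(d$grade[d$category %in%
    c("NA", "EXCLUDED_UNKNOWN_HISTOLOGY", "PEDIATRIC_H3_K27",
      "PEDIATRIC_H3_G34")])))

  # dominance: unknown IDH always NA (known histology); mutant+codel always OLIGO
  known_hist <- grid$histology != "unknown"
  expect_true(all(d$category[known_hist & grid$idh_status == "unknown"] == "NA"))
  expect_true(all(d$category[known_hist & grid$idh_status == "mutant" &
                             grid$codel_1p19q == "yes"] ==
                  "OLIGO_IDH_MUT_CODEL"))

  # every NA carries a reason, non-NA categories carry none
  expect_true(all(d$na_reason[d$category == "NA"] != "none"))
  expect_true(all(d$na_reason[d$category != "NA"] == "none"))

  # rule traces non-empty everywhere
  expect_true(all(nzchar(d$rule_trace)))
})

test_that("monotone information: filling an unknown field never produces EXCLUDED", {
  set.seed(21)
  grid <- feature_grid()
  na_rows <- grid[sample(which(classify_cohort(grid)$diagnoses$category == "NA"),
                         200), ]
  fills <- list(idh_status = "mutant", codel_1p19q = "no", atrx = "mutant",
                h3_status = "wildtype", tertp = "mutant")
  for (i in seq_len(nrow(na_rows))) {
    row <- na_rows[i, ]
    for (f in names(fills)) {
      if (row[[f]] != "unknown") next
      row2 <- row
      row2[[f]] <- fills[[f]]
      expect_false(classify_case(row2)$category ==
                   "EXCLUDED_UNKNOWN_HISTOLOGY")
    }
  }
})

test_that("classify_cohort cross-table margins match legacy composition", {
  sim <- simulate_cohort(sim_config(), seed = 5)
  fit <- classify_cohort(sim$annotations)
  expect_equal(fit$n_excluded, 75)
  expect_equal(fit$n_analyzed, 1047)
  expect_equal(sum(fit$reclass_table), 1047)
  rs <- rowSums(fit$reclass_table)
  expect_equal(unname(rs[grep("^oligodendroglioma", names(rs))] |> sum()), 174)
  expect_equal(unname(rs[grep("^oligoastrocytoma", names(rs))] |> sum()), 114)
  expect_equal(unname(rs[grep("^astrocytoma", names(rs))] |> sum()), 169)
  expect_equal(unname(rs[grep("^glioblastoma", names(rs))] |> sum()), 590)

  # every oligoastrocytoma with a definite diagnosis counts as changed
  oa <- fit$diagnoses$changed[sim$annotations$histology == "oligoastrocytoma"]
  expect_true(all(oa[!is.na(oa)]))

  # empty cohort
  empty <- classify_cohort(sim$annotations[0, ])
  expect_equal(empty$n_analyzed, 0)
})

test_that("an all-unknown-IDH cohort is entirely NA", {
  coh <- rbind(case_row("a", idh_status = "unknown"),
               case_row("b", histology = "glioblastoma", hist_grade = "IV",
                        idh_status = "unknown"))
  fit <- classify_cohort(coh)
  expect_true(all(fit$diagnoses$category == "NA"))
  expect_true(all(fit$diagnoses$na_reason == "idh_unknown"))
  expect_true(all(is.na(fit$diagnoses$changed)))
})

test_that("rule coverage report accounts for every case and is additive", {
  grid <- feature_grid()
  fit <- classify_cohort(grid)
  rep <- rule_coverage_report(fit)
  expect_setequal(rep$rule, c("R0", "R1", "R2", "R2a", "R2b", "R2c",
                              "R3", "R3a", "R3b", "R3c", "R3d", "R3e"))
  expect_equal(sum(rep$hits), nrow(grid))
  expect_true(all(rep$trace_hits >= 1))   # exhaustive grid exercises all rules

  one <- classify_cohort(case_row())
  r1 <- rule_coverage_report(one)
  expect_equal(sum(r1$hits), 1)
  two <- classify_cohort(rbind(case_row("a"), case_row("b")))
  r2 <- rule_coverage_report(two)
  expect_equal(r2$trace_hits, 2L * r1$trace_hits)
})

test_that("legacy grade IV codeleted oligodendroglioma is capped at grade 3", {
  d <- classify_case(case_row(histology = "glioblastoma", hist_grade = "IV",
                              idh_status = "mutant", codel_1p19q = "yes"))
  expect_equal(d$category, "OLIGO_IDH_MUT_CODEL")
  expect_equal(d$grade, 3L)
  expect_true(d$oligo_grade4_capped)
})
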