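## WHO CNS5 rule engine for adult-type diffuse gliomas.
##
## The decision order is deliberate and total: every combination of feature
## levels maps to exactly one diagnosis. Rule identifiers (R0..R3e) are
## stable strings so decision traces can be regression-tested.

.cns5_categories <- c("OLIGO_IDH_MUT_CODEL", "ASTRO_IDH_MUT", "GBM_IDH_WT",
                      "PEDIATRIC_H3_K27", "PEDIATRIC_H3_G34", "NA",
                      "EXCLUDED_UNKNOWN_HISTOLOGY")
.na_reasons <- c("idh_unknown", "h3_unknown", "codel_unresolvable",
                 "nec_no_gbm_markers", "none")

.rule_descriptions <- c(
  R0  = "histology unknown: excluded from reclassification",
  R1  = "IDH status unknown: diagnosis NA",
  R2  = "IDH-mutant branch entered",
  R2a = "IDH-mutant + 1p/19q codeleted: oligodendroglioma, grade 2-3",
  R2b = "IDH-mutant, not codeleted (or ATRX-mutant shortcut): astrocytoma, grade 2-4",
  R2c = "IDH-mutant, codeletion unresolved and no ATRX shortcut: NA",
  R3  = "IDH-wildtype branch entered",
  R3a = "H3 K27-altered: pediatric-type diffuse midline glioma",
  R3b = "H3 G34-mutant: pediatric-type diffuse hemispheric glioma",
  R3c = "IDH-wildtype, H3 status unknown: NA",
  R3d = "IDH-wildtype with GBM feature (grade IV histology, TERTp, EGFR amp, +7/-10): glioblastoma grade 4",
  R3e = "IDH-wildtype lower-grade glioma without molecular GBM features: NA (NEC)")

## Vectorized classifier core. `cohort` must already be canonicalized
## (as by read_cohort / as_glioma_cohort).
.classify_vec <- function(cohort) {
  n <- nrow(cohort)
  category <- character(n)
  grade <- rep(NA_integer_, n)
  na_reason <- rep("none", n)
  trace <- character(n)
  oligo_g4_capped <- logical(n)

  hist <- cohort$histology
  hg   <- cohort$hist_grade
  idh  <- cohort$idh_status
  codel <- cohort$codel_1p19q
  atrx <- cohort$atrx
  tertp <- cohort$tertp
  egfr <- cohort$egfr_amp
  g7l10 <- cohort$gain7_loss10
  cdkn <- cohort$cdkn2ab_hd
  h3   <- cohort$h3_status

  ## grade 2/3 from legacy histological grade; an unresolved legacy grade
  ## defaults to 2 (the conservative lower grade)
  low_grade <- ifelse(hg == "III", 3L, 2L)

  r0 <- hist == "unknown"
  category[r0] <- "EXCLUDED_UNKNOWN_HISTOLOGY"
  trace[r0] <- "R0"

  r1 <- !r0 & idh == "unknown"
  category[r1] <- "NA"
  na_reason[r1] <- "idh_unknown"
  trace[r1] <- "R1"

  mut <- !r0 & !r1 & idh == "mutant"
  r2a <- mut & codel == "yes"
  category[r2a] <- "OLIGO_IDH_MUT_CODEL"
  ## WHO CNS5 oligodendroglioma has no grade 4: a legacy grade IV histology
  ## is capped at grade 3 and flagged
  grade[r2a] <- ifelse(hg[r2a] == "IV", 3L, low_grade[r2a])
  oligo_g4_capped[r2a] <- hg[r2a] == "IV"
  trace[r2a] <- "R2>R2a"

  ## ATRX shortcut applies only when codeletion is unknown; a measured
  ## codeletion always takes precedence
  r2b <- mut & (codel == "no" | (codel == "unknown" & atrx == "mutant"))
  category[r2b] <- "ASTRO_IDH_MUT"
  grade[r2b] <- ifelse(cdkn[r2b] == "yes" | hg[r2b] == "IV", 4L, low_grade[r2b])
  trace[r2b] <- "R2>R2b"

  r2c <- mut & !r2a & !r2b
  category[r2c] <- "NA"
  na_reason[r2c] <- "codel_unresolvable"
  trace[r2c] <- "R2>R2c"

  wt <- !r0 & !r1 & idh == "wildtype"
  r3a <- wt & h3 == "K27M"
  category[r3a] <- "PEDIATRIC_H3_K27"
  trace[r3a] <- "R3>R3a"

  r3b <- wt & h3 == "G34_mut"
  category[r3b] <- "PEDIATRIC_H3_G34"
  trace[r3b] <- "R3>R3b"

  r3c <- wt & h3 == "unknown"
  category[r3c] <- "NA"
  na_reason[r3c] <- "h3_unknown"
  trace[r3c] <- "R3>R3c"

  gbm_feature <- hg == "IV" | tertp == "mutant" | egfr == "yes" | g7l10 == "yes"
  r3d <- wt & h3 == "wildtype" & gbm_feature
  category[r3d] <- "GBM_IDH_WT"
  grade[r3d] <- 4L
  trace[r3d] <- "R3>R3d"

  r3e <- wt & h3 == "wildtype" & !gbm_feature
  category[r3e] <- "NA"
  na_reason[r3e] <- "nec_no_gbm_markers"
  trace[r3e] <- "R3>R3e"

  data.frame(case_id = cohort$case_id, category = category, grade = grade,
             na_reason = na_reason, rule_trace = trace,
             oligo_grade4_capped = oligo_g4_capped,
             stringsAsFactors = FALSE)
}

#' Classify one glioma case under WHO CNS5 rules
#'
#' Maps a single case annotation to its integrated molecular diagnosis. The
#' decision path, in order: unknown histology is excluded (R0); unknown IDH
#' status yields NA (R1); IDH-mutant tumors split on 1p/19q codeletion into
#' oligodendroglioma (R2a) or astrocytoma (R2b, with the ATRX-mutation
#' shortcut standing in for an unknown codeletion, and grade 4 when CDKN2A/B
#' is homozygously deleted or the legacy grade was IV), else NA (R2c);
#' IDH-wildtype tumors exit to the pediatric-type H3-altered entities (R3a,
#' R3b), NA when H3 is unknown (R3c), glioblastoma grade 4 on any molecular
#' or histological GBM feature (R3d), and otherwise NA, absorbing the
#' not-elsewhere-classified lower-grade IDH-wildtype bucket (R3e).
#'
#' @param case a one-row `glioma_cohort` data frame, or a list / named
#'   vector with the cohort schema fields.
#' @return a one-row data frame with `category`, `grade` (integer or `NA`
#'   for entities without an adult grade), `na_reason`, `rule_trace` and the
#'   `oligo_grade4_capped` flag.
#' @export
classify_case <- function(case) {
  if (!is.data.frame(case)) case <- as.data.frame(case, stringsAsFactors = FALSE)
  if (!"case_id" %in% names(case)) case$case_id <- "case"
  for (col in setdiff(.cohort_columns, names(case)))
    case[[col]] <- if (col %in% c("age_at_diagnosis", "os_time", "os_event"))
      NA_real_ else "unknown"
  cohort <- suppressWarnings(as_glioma_cohort(case))
  .classify_vec(cohort)
}

## Documented mapping from legacy histology+grade to the CNS5 label space,
## used only for the "changed diagnosis" flag. Oligoastrocytoma has no CNS5
## counterpart, so it always counts as changed.
.legacy_equivalent <- function(histology, hist_grade) {
  cat <- rep(NA_character_, length(histology))
  cat[histology == "oligodendroglioma"] <- "OLIGO_IDH_MUT_CODEL"
  cat[histology == "astrocytoma"] <- "ASTRO_IDH_MUT"
  cat[histology == "glioblastoma"] <- "GBM_IDH_WT"
  grade <- rep(NA_integer_, length(histology))
  grade[hist_grade == "II"] <- 2L
  grade[hist_grade == "III"] <- 3L
  grade[hist_grade == "IV"] <- 4L
  list(category = cat, grade = grade)
}

#' Classify a whole cohort and cross-tabulate old versus new diagnoses
#'
#' Applies [classify_case()] to every case, flags cases whose diagnosis
#' changed (legacy type+grade differs from the CNS5 category+grade under the
#' documented label mapping; oligoastrocytomas always change since WHO CNS5
#' abolished the mixed entity), and builds the reclassification cross-table
#' over the non-excluded cases.
#'
#' @param cohort a `glioma_cohort` data frame.
#' @return an object of class `cns5_classification`: a list with
#'   `diagnoses` (per-case data frame), `reclass_table` (legacy x CNS5
#'   count matrix over non-excluded cases), `n_excluded`, `n_analyzed`,
#'   `n_changed`.
#' @export
classify_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (!inherits(cohort, "glioma_cohort")) cohort <- as_glioma_cohort(cohort)
  if (anyDuplicated(cohort$case_id)) stop("duplicate case_id in cohort")
  diag <- .classify_vec(cohort)

  eq <- .legacy_equivalent(cohort$histology, cohort$hist_grade)
  definite <- !diag$category %in% c("NA", "EXCLUDED_UNKNOWN_HISTOLOGY")
  changed <- rep(NA, nrow(diag))
  changed[definite] <-
    is.na(eq$category[definite]) |
    eq$category[definite] != diag$category[definite] |
    is.na(eq$grade[definite]) |
    eq$grade[definite] != diag$grade[definite]
  diag$changed <- changed

  keep <- diag$category != "EXCLUDED_UNKNOWN_HISTOLOGY"
  legacy_lab <- factor(
    paste(cohort$histology, cohort$hist_grade, sep = "_")[keep],
    levels = unique(paste(rep(.histology_levels[1:4], each = 4),
                          .grade_levels, sep = "_")))
  new_grade <- ifelse(is.na(diag$grade), "none", diag$grade)
  new_lab <- factor(paste(diag$category, new_grade, sep = "_")[keep])
  reclass <- table(legacy = legacy_lab, cns5 = new_lab)
  reclass <- reclass[rowSums(reclass) > 0, , drop = FALSE]

  out <- list(diagnoses = diag,
              reclass_table = unclass(reclass),
              n_excluded = sum(!keep),
              n_analyzed = sum(keep),
              n_changed = sum(changed, na.rm = TRUE),
              cohort = cohort)
  class(out) <- "cns5_classification"
  out
}

#' @export
print.cns5_classification <- function(x, ...) {
  cat("WHO CNS5 reclassification\n")
  cat(sprintf("  cases: %d analyzed, %d excluded (unknown histology)\n",
              x$n_analyzed, x$n_excluded))
  cat(sprintf("  changed diagnosis (definite categories): %d\n", x$n_changed))
  tab <- table(factor(x$diagnoses$category, levels = .cns5_categories))
  cat("  categories:\n")
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("    %-28s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' @export
summary.cns5_classification <- function(object, ...) {
  print(object)
  cat("\nReclassification table (legacy rows x CNS5 columns):\n")
  print(object$reclass_table)
  na_cases <- object$diagnoses[object$diagnoses$category == "NA", ]
  if (nrow(na_cases)) {
    cat("\nNA reasons:\n")
    print(table(na_cases$na_reason))
  }
  invisible(object)
}

#' Grade-stratified survival group labels from a classification
#'
#' Collapses CNS5 diagnoses to the grade-stratified group keys used in
#' survival comparisons (`OLIGO_2`, `OLIGO_3`, `ASTRO_2`, `ASTRO_3`,
#' `ASTRO_4`, `GBM_4`). NA, excluded and pediatric-type cases get
#' `NA_character_` — they do not form adult survival groups.
#'
#' @param x a `cns5_classification` object.
#' @return a character vector named by `case_id`.
#' @export
diagnosis_groups <- function(x) {
  stopifnot(inherits(x, "cns5_classification"))
  d <- x$diagnoses
  key <- rep(NA_character_, nrow(d))
  key[d$category == "OLIGO_IDH_MUT_CODEL"] <-
    paste0("OLIGO_", d$grade[d$category == "OLIGO_IDH_MUT_CODEL"])
  key[d$category == "ASTRO_IDH_MUT"] <-
    paste0("ASTRO_", d$grade[d$category == "ASTRO_IDH_MUT"])
  key[d$category == "GBM_IDH_WT"] <- "GBM_4"
  stats::setNames(key, d$case_id)
}

#' Rule coverage report for a classified cohort
#'
#' Tabulates rule usage over a classified cohort: `hits` counts cases whose
#' decision path *terminated* at the rule (these sum to the cohort size),
#' while `trace_hits` counts every appearance of the rule on a decision
#' trace, so the branch-entry rules R2/R3 accumulate their whole subtree.
#'
#' @param x a `cns5_classification` object.
#' @return a data frame with columns `rule`, `description`, `hits`,
#'   `trace_hits`.
#' @export
rule_coverage_report <- function(x) {
  stopifnot(inherits(x, "cns5_classification"))
  steps <- strsplit(x$diagnoses$rule_trace, ">", fixed = TRUE)
  terminal <- vapply(steps, function(s) s[length(s)], character(1))
  hits <- table(factor(terminal, levels = names(.rule_descriptions)))
  trace_hits <- table(factor(unlist(steps), levels = names(.rule_descriptions)))
  data.frame(rule = names(.rule_descriptions),
             description = unname(.rule_descriptions),
             hits = as.integer(hits),
             trace_hits = as.integer(trace_hits),
             stringsAsFactors = FALSE)
}
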