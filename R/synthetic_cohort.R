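## Synthetic TCGA-like glioma cohorts with planted ground truth.
##
## Generation is truth-first: each case's latent WHO CNS5 class is drawn
## before its observable features, and the molecular fields are then filled
## in so that the rule engine recovers the latent class exactly whenever no
## field is masked. Missingness is applied afterwards. This gives every
## pipeline stage a gold standard that the real cohort lacks.

#' Build a simulation configuration
#'
#' Defaults emulate the scale and structure of the combined TCGA-LGG /
#' TCGA-GBM glioma cohort: legacy type composition 174 oligodendrogliomas,
#' 114 oligoastrocytomas, 169 astrocytomas, 590 glioblastomas and 75 cases
#' of unknown histology; class-conditional molecular profiles; per-class
#' exponential survival with medians mirroring the reported per-group
#' medians (the grade-2 oligodendroglioma median, unreached in the source
#' cohort, is set to a finite 140 months); and field-wise missingness rates
#' reflecting the reported unknown-status counts (about 10% unknown IDH,
#' 15% unknown H3 among IDH-wildtype).
#'
#' @param n_legacy named integer vector of cases per legacy histology.
#' @param grade2_frac named fractions of grade II among grade II-III cases
#'   per lower-grade legacy type.
#' @param class_probs list (per legacy type) of probabilities over latent
#'   CNS5 classes `OLIGO`, `ASTRO`, `GBM`, `PED_K27`, `PED_G34`.
#' @param cdkn_hd_rate probability that a lower-grade IDH-mutant
#'   astrocytoma carries a CDKN2A/B homozygous deletion (making it grade 4).
#' @param atrx_mut_rate ATRX mutation rate among IDH-mutant astrocytomas.
#' @param missingness named per-field masking probabilities.
#' @param survival_medians named per-class median OS in months.
#' @param censoring_rate probability that a case is censored.
#' @param expression parameters of the expression generator: `n_genes`
#'   (background genes), `block_size` (class-specific block), `effect_size`
#'   (mean shift in SD units), `subtype_effect_size` (shift of the latent
#'   subtype's signature block within glioblastoma samples; defaults to
#'   `effect_size`, set 0 for a cohort whose only planted structure is the
#'   three class blocks), `sigma` (per-gene log2 SD), `n_aliquot_cases`
#'   (cases given a second aliquot), `aliquot_sd` (within-case noise).
#' @param methylation parameters of the methylation generator: `n_genes`,
#'   `probes_per_gene`, `block_size`, `effect_size`, `sigma`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(
    n_legacy = c(oligodendroglioma = 174L, oligoastrocytoma = 114L,
                 astrocytoma = 169L, glioblastoma = 590L, unknown = 75L),
    grade2_frac = c(oligodendroglioma = 0.58, oligoastrocytoma = 0.54,
                    astrocytoma = 0.32),
    class_probs = list(
      oligodendroglioma = c(OLIGO = 0.85, ASTRO = 0.10, GBM = 0.05,
                            PED_K27 = 0, PED_G34 = 0),
      oligoastrocytoma  = c(OLIGO = 0.35, ASTRO = 0.45, GBM = 0.20,
                            PED_K27 = 0, PED_G34 = 0),
      astrocytoma       = c(OLIGO = 0.01, ASTRO = 0.60, GBM = 0.38,
                            PED_K27 = 0.005, PED_G34 = 0.005),
      glioblastoma      = c(OLIGO = 0, ASTRO = 0.095, GBM = 0.90,
                            PED_K27 = 0.0025, PED_G34 = 0.0025)),
    cdkn_hd_rate = 0.05,
    atrx_mut_rate = 0.8,
    missingness = c(idh = 0.10, h3 = 0.15, codel = 0.05, atrx = 0.05,
                    tertp = 0.05, egfr = 0.05, gain7 = 0.05, cdkn = 0.05),
    survival_medians = c(OLIGO_2 = 140, OLIGO_3 = 90.5, ASTRO_2 = 105.1,
                         ASTRO_3 = 67.4, ASTRO_4 = 38.7, GBM_4 = 14.0,
                         PED = 15, EXCLUDED = 30),
    censoring_rate = 0.4,
    expression = list(n_genes = 1000L, block_size = 40L, effect_size = 2,
                      sigma = 1, n_aliquot_cases = 18L, aliquot_sd = 0.3),
    methylation = list(n_genes = 300L, probes_per_gene = 3L,
                       block_size = 30L, effect_size = 1.5, sigma = 0.5)) {
  stopifnot(all(n_legacy >= 0), all(missingness >= 0 & missingness <= 1),
            all(survival_medians > 0),
            censoring_rate >= 0, censoring_rate <= 1)
  for (p in class_probs)
    if (abs(sum(p) - 1) > 1e-8) stop("class_probs rows must sum to 1")
  structure(list(n_legacy = n_legacy, grade2_frac = grade2_frac,
                 class_probs = class_probs, cdkn_hd_rate = cdkn_hd_rate,
                 atrx_mut_rate = atrx_mut_rate, missingness = missingness,
                 survival_medians = survival_medians,
                 censoring_rate = censoring_rate,
                 expression = expression, methylation = methylation),
            class = "sim_config")
}

## Class key ("OLIGO_2", ..., "GBM_4", "PED_K27", "PED_G34", "EXCLUDED")
## used to index survival medians and expression blocks.
.class_key <- function(category, grade) {
  ifelse(category == "EXCLUDED_UNKNOWN_HISTOLOGY", "EXCLUDED",
  ifelse(category == "PEDIATRIC_H3_K27", "PED_K27",
  ifelse(category == "PEDIATRIC_H3_G34", "PED_G34",
  ifelse(category == "OLIGO_IDH_MUT_CODEL", paste0("OLIGO_", grade),
  ifelse(category == "ASTRO_IDH_MUT", paste0("ASTRO_", grade), "GBM_4")))))
}

#' Simulate a glioma cohort annotation table with latent truth
#'
#' Draws each case's latent CNS5 class conditionally on its legacy
#' histology, fills in molecular features consistently with the rule
#' engine's logic (so classification recovers the latent class when nothing
#' is masked), then applies field-wise missingness and attaches exponential
#' per-class survival.
#'
#' @param cfg a [sim_config()] object.
#' @param seed integer seed.
#' @return list with `annotations` (a `glioma_cohort`, masked), `features`
#'   (the same table before masking) and `truth` (data frame with
#'   `case_id`, `truth_category`, `truth_grade`, `class_key`).
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  rows <- list(); truths <- list()
  counter <- 0L
  for (htype in names(cfg$n_legacy)) {
    n <- cfg$n_legacy[[htype]]
    if (n == 0) next
    for (i in seq_len(n)) {
      counter <- counter + 1L
      case_id <- sprintf("SIM-%04d", counter)
      if (htype == "unknown") {
        hist_grade <- "unknown"
        truth_cat <- "EXCLUDED_UNKNOWN_HISTOLOGY"; truth_grade <- NA_integer_
        feat <- list(idh = "unknown", codel = "unknown", atrx = "unknown",
                     tertp = "unknown", egfr = "unknown", gain7 = "unknown",
                     cdkn = "unknown", h3 = "unknown")
        age <- round(stats::rnorm(1, 55, 14))
      } else {
        hist_grade <- if (htype == "glioblastoma") "IV" else
          if (stats::runif(1) < cfg$grade2_frac[[htype]]) "II" else "III"
        cls <- sample(names(cfg$class_probs[[htype]]), 1,
                      prob = cfg$class_probs[[htype]])
        low <- if (hist_grade == "III") 3L else 2L
        if (cls == "OLIGO") {
          truth_cat <- "OLIGO_IDH_MUT_CODEL"
          truth_grade <- if (hist_grade == "IV") 3L else low
          feat <- list(idh = "mutant", codel = "yes", atrx = "wildtype",
                       tertp = if (stats::runif(1) < 0.8) "mutant" else "wildtype",
                       egfr = "no", gain7 = "no", cdkn = "no",
                       h3 = "wildtype")
          age <- round(stats::rnorm(1, 44, 10))
        } else if (cls == "ASTRO") {
          truth_cat <- "ASTRO_IDH_MUT"
          cdkn_hd <- hist_grade != "IV" && stats::runif(1) < cfg$cdkn_hd_rate
          truth_grade <- if (hist_grade == "IV" || cdkn_hd) 4L else low
          feat <- list(idh = "mutant", codel = "no",
                       atrx = if (stats::runif(1) < cfg$atrx_mut_rate)
                         "mutant" else "wildtype",
                       tertp = "wildtype", egfr = "no", gain7 = "no",
                       cdkn = if (cdkn_hd ||
                                  (hist_grade == "IV" && stats::runif(1) < 0.3))
                         "yes" else "no",
                       h3 = "wildtype")
          age <- round(stats::rnorm(1, 38, 11))
        } else if (cls == "GBM") {
          truth_cat <- "GBM_IDH_WT"; truth_grade <- 4L
          tertp <- stats::runif(1) < 0.7
          egfr <- stats::runif(1) < 0.4
          gain7 <- stats::runif(1) < 0.5
          ## a histologically lower-grade "molecular glioblastoma" must carry
          ## at least one molecular GBM feature
          if (hist_grade != "IV" && !tertp && !egfr && !gain7) tertp <- TRUE
          feat <- list(idh = "wildtype", codel = "no", atrx = "wildtype",
                       tertp = if (tertp) "mutant" else "wildtype",
                       egfr = if (egfr) "yes" else "no",
                       gain7 = if (gain7) "yes" else "no",
                       cdkn = if (stats::runif(1) < 0.4) "yes" else "no",
                       h3 = "wildtype")
          age <- round(stats::rnorm(1, 60, 12))
        } else {  # pediatric-type H3-altered
          truth_cat <- if (cls == "PED_K27") "PEDIATRIC_H3_K27"
                       else "PEDIATRIC_H3_G34"
          truth_grade <- NA_integer_
          feat <- list(idh = "wildtype", codel = "no", atrx = "wildtype",
                       tertp = "wildtype", egfr = "no", gain7 = "no",
                       cdkn = "no",
                       h3 = if (cls == "PED_K27") "K27M" else "G34_mut")
          age <- round(stats::rnorm(1, 26, 5))
        }
      }
      rows[[counter]] <- data.frame(
        case_id = case_id, histology = htype, hist_grade = hist_grade,
        idh_status = feat$idh, codel_1p19q = feat$codel, atrx = feat$atrx,
        tertp = feat$tertp, egfr_amp = feat$egfr,
        gain7_loss10 = feat$gain7, cdkn2ab_hd = feat$cdkn,
        h3_status = feat$h3, age_at_diagnosis = max(age, 18),
        os_time = NA_real_, os_event = NA_integer_,
        stringsAsFactors = FALSE)
      truths[[counter]] <- data.frame(
        case_id = case_id, truth_category = truth_cat,
        truth_grade = truth_grade, stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  truth$class_key <- .class_key(truth$truth_category, truth$truth_grade)

  surv <- simulate_survival(truth, cfg, seed = seed + 1000L)
  features$os_time <- surv$os_time
  features$os_event <- surv$os_event

  annotations <- features
  mask_field <- c(idh = "idh_status", h3 = "h3_status", codel = "codel_1p19q",
                  atrx = "atrx", tertp = "tertp", egfr = "egfr_amp",
                  gain7 = "gain7_loss10", cdkn = "cdkn2ab_hd")
  for (m in names(mask_field)) {
    rate <- cfg$missingness[[m]]
    if (is.null(rate) || rate == 0) next
    hit <- stats::runif(nrow(annotations)) < rate
    annotations[[mask_field[[m]]]][hit] <- "unknown"
  }
  list(annotations = as_glioma_cohort(annotations),
       features = as_glioma_cohort(features),
       truth = truth)
}

#' Simulate per-class exponential survival
#'
#' Event times are exponential with rate `log(2) / median` for the case's
#' latent class; censoring is applied independently per case at the
#' configured rate, with the censoring time drawn uniformly on the event
#' time (so censored follow-up is always shorter than the unobserved
#' event).
#'
#' @param truth truth table from [simulate_cohort()] (needs `class_key`).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return data frame with `case_id`, `os_time`, `os_event`.
#' @export
simulate_survival <- function(truth, cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  med <- cfg$survival_medians
  key <- truth$class_key
  key[!key %in% names(med) & startsWith(key, "PED")] <- "PED"
  if (any(!key %in% names(med)))
    stop("no survival median configured for class(es): ",
         paste(setdiff(key, names(med)), collapse = ", "))
  t_event <- stats::rexp(nrow(truth), rate = log(2) / med[key])
  censored <- stats::runif(nrow(truth)) < cfg$censoring_rate
  os_time <- ifelse(censored, stats::runif(nrow(truth)) * t_event, t_event)
  data.frame(case_id = truth$case_id,
             os_time = round(os_time, 2),
             os_event = as.integer(!censored),
             stringsAsFactors = FALSE)
}

#' Simulate a class-structured expression matrix
#'
#' Log-normal baseline expression with planted structure: one block of
#' genes per major latent class shifted by `effect_size` standard
#' deviations in samples of that class; marker-gene analogues (`CRNDE` up
#' in IDH-mutant classes, `FREM2` and `SPRY1` up in glioblastoma); three
#' disjoint subtype signature blocks (Proneural / Classical / Mesenchymal)
#' shifted in glioblastoma samples according to a uniformly drawn latent
#' subtype; and activator / repressor pathway gene blocks moving up / down
#' with glioblastoma, from which three nested pathway variants of
#' increasing depth are built. A configurable number of cases receives a
#' second aliquot column with within-case noise.
#'
#' @param truth truth table from [simulate_cohort()].
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `expr` (gene-by-aliquot matrix of positive
#'   normalized-count-scale values), `aliquot_to_case` (named vector),
#'   `signatures` (list of three 50-gene sets), `pathways` (list of three
#'   nested `pathway_definition`s), `subtype_truth` (named latent subtype
#'   per glioblastoma case).
#' @export
simulate_expression <- function(truth, cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  ex <- cfg$expression
  classes <- c("OLIGO", "ASTRO", "GBM")
  major <- sub("_.*", "", truth$class_key)

  block_genes <- lapply(classes, function(cl)
    sprintf("BLK_%s_%03d", cl, seq_len(ex$block_size)))
  names(block_genes) <- classes
  signatures <- list(
    Proneural   = sprintf("SIG_PN_%02d", 1:50),
    Classical   = sprintf("SIG_CL_%02d", 1:50),
    Mesenchymal = sprintf("SIG_MES_%02d", 1:50))
  pw_act <- sprintf("PWY_ACT_%03d", 1:30)
  pw_rep <- sprintf("PWY_REP_%03d", 1:10)
  markers <- c("CRNDE", "FREM2", "SPRY1")
  background <- sprintf("GENE_%05d", seq_len(ex$n_genes))
  genes <- c(markers, unlist(block_genes), unlist(signatures),
             pw_act, pw_rep, background)

  ## latent glioblastoma subtype, one per GBM case
  gbm_cases <- truth$case_id[major == "GBM"]
  subtype_truth <- stats::setNames(
    sample(names(signatures), length(gbm_cases), replace = TRUE), gbm_cases)

  base_mu <- stats::setNames(stats::runif(length(genes), 3, 8), genes)
  n <- nrow(truth)
  shift <- matrix(0, length(genes), n, dimnames = list(genes, truth$case_id))
  es <- ex$effect_size * ex$sigma
  for (cl in classes) {
    in_cl <- major == cl
    shift[block_genes[[cl]], in_cl] <- shift[block_genes[[cl]], in_cl] + es
  }
  is_idh_mut <- major %in% c("OLIGO", "ASTRO")
  is_gbm <- major == "GBM"
  shift["CRNDE", is_idh_mut] <- shift["CRNDE", is_idh_mut] + es
  shift["FREM2", is_gbm] <- shift["FREM2", is_gbm] + es
  shift["SPRY1", is_gbm] <- shift["SPRY1", is_gbm] + es
  shift[pw_act, is_gbm] <- shift[pw_act, is_gbm] + es
  shift[pw_rep, is_gbm] <- shift[pw_rep, is_gbm] - es
  ses <- if (is.null(ex$subtype_effect_size)) es
         else ex$subtype_effect_size * ex$sigma
  for (cid in gbm_cases) {
    sg <- signatures[[subtype_truth[[cid]]]]
    shift[sg, cid] <- shift[sg, cid] + ses
  }

  log2_expr <- base_mu + shift +
    matrix(stats::rnorm(length(genes) * n, sd = ex$sigma), length(genes), n)
  aliquots <- paste0(truth$case_id, "-01A")
  colnames(log2_expr) <- aliquots
  aliquot_to_case <- stats::setNames(truth$case_id, aliquots)

  if (ex$n_aliquot_cases > 0) {
    extra_cases <- sample(truth$case_id, min(ex$n_aliquot_cases, n))
    extra_cols <- log2_expr[, paste0(extra_cases, "-01A"), drop = FALSE] +
      matrix(stats::rnorm(length(genes) * length(extra_cases),
                          sd = ex$aliquot_sd),
             length(genes), length(extra_cases))
    colnames(extra_cols) <- paste0(extra_cases, "-01B")
    log2_expr <- cbind(log2_expr, extra_cols)
    aliquot_to_case <- c(aliquot_to_case,
                         stats::setNames(extra_cases, colnames(extra_cols)))
  }

  depth1 <- pathway_definition("FREM2_like_depth1",
                               c(pw_act[1:8], pw_rep[1:2]),
                               c(rep(1, 8), rep(-1, 2)))
  depth2 <- pathway_definition("FREM2_like_depth2",
                               c(pw_act[1:16], pw_rep[1:4]),
                               c(rep(1, 12), rep(0.5, 4), rep(-1, 4)))
  depth3 <- pathway_definition("FREM2_like_depth3",
                               c(pw_act, pw_rep),
                               c(rep(1, 20), rep(0.5, 10), rep(-1, 6),
                                 rep(-0.5, 4)))

  list(expr = 2^log2_expr, aliquot_to_case = aliquot_to_case,
       signatures = signatures,
       pathways = list(depth1 = depth1, depth2 = depth2, depth3 = depth3),
       subtype_truth = subtype_truth)
}

#' Simulate a probe-level methylation matrix
#'
#' Gene-level methylation states are drawn on the logit scale with a
#' class-specific shift on one gene block per major class (emulating the
#' G-CIMP-like hypermethylation contrast between IDH-mutant and
#' IDH-wildtype tumors); each gene is observed through several probes with
#' independent probe noise, and betas are the logistic transform, so all
#' values lie in (0, 1).
#'
#' @inheritParams simulate_expression
#' @return list with `betas` (probe-by-sample matrix), `probe_to_gene`
#'   (named vector), `sample_to_case`.
#' @export
simulate_methylation <- function(truth, cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  me <- cfg$methylation
  classes <- c("OLIGO", "ASTRO", "GBM")
  major <- sub("_.*", "", truth$class_key)
  block <- lapply(classes, function(cl)
    sprintf("MGENE_%s_%03d", cl, seq_len(me$block_size)))
  names(block) <- classes
  genes <- c(unlist(block), sprintf("MGENE_BG_%04d", seq_len(me$n_genes)))
  n <- nrow(truth)
  mu <- stats::setNames(stats::rnorm(length(genes), 0, 1.2), genes)
  logit <- matrix(mu, length(genes), n, dimnames = list(genes, NULL))
  for (cl in classes)
    logit[block[[cl]], major == cl] <- logit[block[[cl]], major == cl] +
      me$effect_size
  logit <- logit + matrix(stats::rnorm(length(genes) * n, sd = me$sigma),
                          length(genes), n)
  probes <- as.vector(vapply(seq_len(me$probes_per_gene),
                             function(k) paste0("cg_", genes, "_", k),
                             character(length(genes))))
  probe_logit <- logit[rep(seq_len(length(genes)), me$probes_per_gene), ] +
    matrix(stats::rnorm(length(probes) * n, sd = 0.3), length(probes), n)
  samples <- paste0(truth$case_id, "-01D")
  betas <- stats::plogis(probe_logit)
  dimnames(betas) <- list(probes, samples)
  probe_to_gene <- stats::setNames(rep(genes, me$probes_per_gene), probes)
  list(betas = betas, probe_to_gene = probe_to_gene,
       sample_to_case = stats::setNames(truth$case_id, samples))
}

#' Simulate MAF mutation records consistent with the cohort
#'
#' Emits one record table in the minimal MAF schema. A case belongs to the
#' MAF sample universe when its annotated IDH status survived masking, or
#' (with probability `rescue_fraction`) when it was masked but genomic data
#' nevertheless exist — emulating cohort cases whose clinical annotation
#' lacks mutation calls that sequencing can still resolve. Records are
#' always consistent with the *true* (pre-mask) features: IDH-mutant cases
#' get an IDH1 p.R132H (or occasionally IDH2 p.R172K) missense row,
#' H3-altered cases the corresponding H3F3A hotspot row (initiator-Met
#' numbering, as annotation pipelines emit), and every sample in the
#' universe carries a TP53 passenger row so that wildtype status is
#' confirmable by presence.
#'
#' @param sim output of [simulate_cohort()].
#' @param rescue_fraction probability that a masked-IDH case still has
#'   genomic data (default 0.12).
#' @param seed integer seed.
#' @return a MAF-schema data frame as returned by [read_maf()].
#' @export
simulate_maf <- function(sim, rescue_fraction = 0.12, seed = 1L) {
  set.seed(seed)
  ann <- sim$annotations; feat <- sim$features
  masked <- ann$idh_status == "unknown" & feat$idh_status != "unknown"
  in_maf <- feat$idh_status != "unknown" &
    (!masked | stats::runif(nrow(ann)) < rescue_fraction)
  rows <- list()
  for (i in which(in_maf)) {
    sid <- paste0(ann$case_id[i], "-01A")
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, hugo_symbol = "TP53",
      variant_classification = "Missense_Mutation",
      protein_change = "p.R273H", stringsAsFactors = FALSE)
    if (feat$idh_status[i] == "mutant") {
      if (stats::runif(1) < 0.9) {
        gene <- "IDH1"; pc <- "p.R132H"
      } else {
        gene <- "IDH2"; pc <- "p.R172K"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, hugo_symbol = gene,
        variant_classification = "Missense_Mutation",
        protein_change = pc, stringsAsFactors = FALSE)
    }
    if (feat$h3_status[i] == "K27M")
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, hugo_symbol = "H3F3A",
        variant_classification = "Missense_Mutation",
        protein_change = "p.K28M", stringsAsFactors = FALSE)
    if (feat$h3_status[i] == "G34_mut")
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, hugo_symbol = "H3F3A",
        variant_classification = "Missense_Mutation",
        protein_change = "p.G35R", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
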