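# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

maf_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], hugo_symbol = r[[2]],
               variant_classification = r[[3]], protein_change = r[[4]],
               stringsAsFactors = FALSE)))
}

# One fully-specified case row; override any field by name.
case_row <- function(case_id = "C1", histology = "astrocytoma",
                     hist_grade = "II", idh_status = "mutant",
                     codel_1p19q = "no", atrx = "mutant",
                     tertp = "wildtype", egfr_amp = "no",
                     gain7_loss10 = "no", cdkn2ab_hd = "no",
                     h3_status = "wildtype", age_at_diagnosis = 40,
                     os_time = 24, os_event = 1) {
  data.frame(case_id = case_id, histology = histology,
             hist_grade = hist_grade, idh_status = idh_status,
             codel_1p19q = codel_1p19q, atrx = atrx, tertp = tertp,
             egfr_amp = egfr_amp, gain7_loss10 = gain7_loss10,
             cdkn2ab_hd = cdkn2ab_hd, h3_status = h3_status,
             age_at_diagnosis = age_at_diagnosis, os_time = os_time,
             os_event = os_event, stringsAsFactors = FALSE)
}

# Full Cartesian product of every feature level, for totality checks.
feature_grid <- function() {
  g <- expand.grid(
    histology = c("astrocytoma", "oligoastrocytoma", "oligodendroglioma",
                  "glioblastoma", "unknown"),
    hist_grade = c("II", "III", "IV", "unknown"),
    idh_status = c("mutant", "wildtype", "unknown"),
    codel_1p19q = c("yes", "no", "unknown"),
    atrx = c("mutant", "wildtype", "unknown"),
    tertp = c("mutant", "wildtype", "unknown"),
    egfr_amp = c("yes", "no", "unknown"),
    gain7_loss10 = c("yes", "no", "unknown"),
    cdkn2ab_hd = c("yes", "no", "unknown"),
    h3_status = c("K27M", "G34_mut", "wildtype", "unknown"),
    stringsAsFactors = FALSE)
  g$case_id <- sprintf("G%06d", seq_len(nrow(g)))
  g$age_at_diagnosis <- 50
  g$os_time <- 12
  g$os_event <- 1L
  g
}

# Direct-evaluation PAL oracle: plain loop over pathway members.
pal_oracle <- function(pathway, cnr, sample) {
  num <- 0; den <- 0
  for (g in pathway$genes) {
    if (!g %in% rownames(cnr)) next
    a <- pathway$arr[[g]]
    num <- num + a * log10(cnr[g, sample]) * 100
    den <- den + abs(a)
  }
  num / den
}

# Brute-force AUC: count of (positive > negative) pairs, ties half.
auc_bruteforce <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Minimal pairwise_logrank-shaped object from a vector of p-values, for
# testing the significant-fraction arithmetic in isolation.
pw_from_pvalues <- function(p, alpha = 0.05) {
  n <- length(p)
  pairs <- data.frame(group1 = sprintf("g%d", seq_len(n)),
                      group2 = sprintf("h%d", seq_len(n)),
                      hr = rep(1, n), lower = rep(1, n), upper = rep(1, n),
                      p = p, stringsAsFactors = FALSE)
  structure(list(pairs = pairs, alpha = alpha, adjust = "none",
                 groups = unique(c(pairs$group1, pairs$group2))),
            class = "pairwise_logrank")
}

small_sim_config <- function(...) {
  args <- list(
    n_legacy = c(oligodendroglioma = 25L, oligoastrocytoma = 15L,
                 astrocytoma = 25L, glioblastoma = 50L, unknown = 5L),
    expression = list(n_genes = 150L, block_size = 30L, effect_size = 2,
                      sigma = 1, n_aliquot_cases = 5L, aliquot_sd = 0.3),
    methylation = list(n_genes = 60L, probes_per_gene = 3L,
                       block_size = 20L, effect_size = 1.5, sigma = 0.5))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# Strip names and attributes from a PAL result for scalar comparison.
pal_num <- function(x) as.numeric(x)
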