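## ROC-AUC evaluation of single-gene and pathway-activation biomarkers as
## pairwise discriminators between diagnosis groups. AUC is computed from
## the rank statistic (Mann-Whitney U / (n1*n2), ties counted half), which
## equals the probability that a random "positive" sample scores above a
## random "negative" one; significance from the two-sided rank-sum test.

## Rank-based AUC with the first argument as the positive class.
.auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Pairwise ROC AUC of a biomarker between groups
#'
#' For every requested (or every unordered) pair of groups, computes the
#' AUC with the first-listed group as the positive class, so
#' `AUC(A vs B) = 1 - AUC(B vs A)` exactly, including ties. The p-value
#' comes from the two-sided Wilcoxon rank-sum test (normal approximation
#' with tie correction). When the biomarker is constant in both groups the
#' AUC is 0.5 with p = 1 and a degenerate flag.
#'
#' @param values numeric biomarker value per sample.
#' @param groups group label per sample.
#' @param pairs optional 2-column matrix or data frame of group pairs
#'   (first column = positive group); default: all unordered pairs in
#'   sorted label order.
#' @param useful_auc threshold above which an AUC is marked useful in the
#'   output (default 0.7, the conventional bar for a workable diagnostic
#'   discriminator).
#' @return data frame with one row per pair: `positive`, `negative`,
#'   `auc`, `p`, `stars`, `n_pos`, `n_neg`, `useful`, `degenerate`.
#' @export
pairwise_auc <- function(values, groups, pairs = NULL, useful_auc = 0.7) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups) & is.finite(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lv <- sort(unique(groups))
  explicit <- !is.null(pairs)
  if (is.null(pairs)) {
    if (length(lv) < 2)
      return(data.frame(positive = character(0), negative = character(0),
                        auc = numeric(0), p = numeric(0),
                        stars = character(0), n_pos = integer(0),
                        n_neg = integer(0), useful = logical(0),
                        degenerate = logical(0)))
    pairs <- t(utils::combn(lv, 2))
  }
  pairs <- as.matrix(pairs)
  rows <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    gp <- pairs[r, 1]; gn <- pairs[r, 2]
    pos <- values[groups == gp]; neg <- values[groups == gn]
    if (length(pos) < 2 || length(neg) < 2) {
      if (explicit)
        stop("pair (", gp, ", ", gn, ") needs >= 2 samples per group")
      warning("pair (", gp, ", ", gn,
              ") skipped: fewer than 2 samples in a group", call. = FALSE)
      next
    }
    degenerate <- length(unique(c(pos, neg))) == 1
    if (degenerate) {
      auc <- 0.5; p <- 1
    } else {
      auc <- .auc_rank(pos, neg)
      p <- suppressWarnings(
        stats::wilcox.test(pos, neg, exact = FALSE)$p.value)
    }
    rows[[r]] <- data.frame(positive = gp, negative = gn, auc = auc, p = p,
                            stars = .p_stars(p), n_pos = length(pos),
                            n_neg = length(neg),
                            useful = auc > useful_auc, degenerate = degenerate,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(positive = character(0), negative = character(0),
                      auc = numeric(0), p = numeric(0), stars = character(0),
                      n_pos = integer(0), n_neg = integer(0),
                      useful = logical(0), degenerate = logical(0))
  out
}

#' Evaluate a panel of biomarkers across all group pairs
#'
#' Builds the long-format grid of AUC results for a set of single-gene
#' expression biomarkers and (optionally) pathway activation levels, one
#' row per (biomarker, group pair). Biomarkers absent from their matrix are
#' skipped with a warning.
#'
#' @param expr gene-by-sample expression matrix.
#' @param groups named group label per sample (names matching matrix
#'   columns), or an unnamed vector aligned with the columns.
#' @param genes character vector of gene biomarkers to evaluate.
#' @param pal_matrix optional pathway-by-sample PAL matrix from
#'   [batch_pal()]; every row is evaluated as a biomarker.
#' @inheritParams pairwise_auc
#' @return data frame with columns `biomarker`, `type` (gene/pathway) and
#'   the [pairwise_auc()] columns.
#' @export
biomarker_panel <- function(expr, groups, genes = character(0),
                            pal_matrix = NULL, useful_auc = 0.7) {
  stopifnot(is.matrix(expr))
  if (!is.null(names(groups))) {
    groups <- groups[colnames(expr)]
  } else stopifnot(length(groups) == ncol(expr))
  out <- list()
  for (g in genes) {
    if (!g %in% rownames(expr)) {
      warning("biomarker gene absent from matrix: ", g)
      next
    }
    res <- pairwise_auc(expr[g, ], groups, useful_auc = useful_auc)
    if (nrow(res)) out[[length(out) + 1L]] <-
      cbind(biomarker = g, type = "gene", res, stringsAsFactors = FALSE)
  }
  if (!is.null(pal_matrix)) {
    pg <- if (!is.null(names(groups))) groups[colnames(pal_matrix)] else groups
    for (p in rownames(pal_matrix)) {
      res <- pairwise_auc(pal_matrix[p, ], pg, useful_auc = useful_auc)
      if (nrow(res)) out[[length(out) + 1L]] <-
        cbind(biomarker = p, type = "pathway", res, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(biomarker = character(0), type = character(0),
                      positive = character(0), negative = character(0),
                      auc = numeric(0), p = numeric(0), stars = character(0),
                      n_pos = integer(0), n_neg = integer(0),
                      useful = logical(0), degenerate = logical(0)))
  do.call(rbind, out)
}
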