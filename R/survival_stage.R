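## Survival analytics over diagnosis groups: Kaplan-Meier medians, Cox
## hazard ratios against a reference group, pairwise log-rank comparisons
## with a significant-fraction summary, and the 4-gene risk-score split.

#' Kaplan-Meier median survival with confidence interval
#'
#' Product-limit estimate of the survival curve; the median is the first
#' time the estimate drops to 0.5 or below, and is reported `NA` when the
#' curve never reaches 0.5 (heavily censored groups). The confidence
#' interval uses the log-log (exponential Greenwood) transform.
#'
#' @param times non-negative follow-up times (months).
#' @param events event indicators, 1 = death observed, 0 = censored.
#' @param conf.level confidence level (default 0.95).
#' @return list with `median`, `lower`, `upper` (each possibly `NA`), `n`,
#'   `events`.
#' @export
km_median <- function(times, events, conf.level = 0.95) {
  stopifnot(length(times) == length(events), length(times) >= 1)
  if (any(times < 0, na.rm = TRUE)) stop("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf.level)
  tab <- summary(fit)$table
  list(median = unname(tab["median"]),
       lower = unname(tab[grep("LCL", names(tab))]),
       upper = unname(tab[grep("UCL", names(tab))]),
       n = unname(tab["records"]),
       events = unname(tab["events"]))
}

#' Kaplan-Meier medians per group
#'
#' @param times,events as in [km_median()].
#' @param groups group label per observation.
#' @return data frame with one row per group: `group`, `n`, `events`,
#'   `median`, `lower`, `upper`.
#' @export
km_median_by_group <- function(times, events, groups) {
  groups <- as.character(groups)
  res <- lapply(unique(groups), function(g) {
    i <- groups == g
    m <- km_median(times[i], events[i])
    data.frame(group = g, n = m$n, events = m$events, median = m$median,
               lower = m$lower, upper = m$upper, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Univariate Cox hazard ratios against a reference group
#'
#' Fits a proportional-hazards model with group indicators; the reference
#' group has hazard ratio 1 by construction. Groups with zero observed
#' events are kept in the output but flagged unstable (their partial-
#' likelihood estimate diverges).
#'
#' @param times,events as in [km_median()].
#' @param groups group label per observation.
#' @param reference label of the reference group.
#' @return data frame with one row per group: `group`, `n`, `events`, `hr`,
#'   `lower`, `upper`, `p`, `unstable`; the fitted `coxph` model is
#'   attached as attribute `"fit"`.
#' @export
cox_hr <- function(times, events, groups, reference) {
  groups <- as.character(groups)
  if (!reference %in% groups) stop("reference group not present: ", reference)
  g <- stats::relevel(factor(groups), ref = reference)
  if (nlevels(g) < 2) stop("need at least two groups")
  fit <- survival::coxph(survival::Surv(times, events) ~ g)
  s <- summary(fit)
  lv <- levels(g)
  events_per <- tapply(events, g, sum)
  n_per <- tapply(events, g, length)
  out <- data.frame(group = lv,
                    n = as.integer(n_per[lv]),
                    events = as.integer(events_per[lv]),
                    hr = NA_real_, lower = NA_real_, upper = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  out$hr[1] <- 1
  idx <- match(paste0("g", lv[-1]), rownames(s$coefficients))
  out$hr[-1] <- s$coefficients[idx, "exp(coef)"]
  out$lower[-1] <- s$conf.int[idx, "lower .95"]
  out$upper[-1] <- s$conf.int[idx, "upper .95"]
  out$p[-1] <- s$coefficients[idx, "Pr(>|z|)"]
  out$unstable <- out$events == 0
  if (any(out$unstable))
    warning("group(s) with zero events: ",
            paste(out$group[out$unstable], collapse = ", "),
            "; hazard ratio unstable")
  attr(out, "fit") <- fit
  out
}

.p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", ""))))
}

#' All-pairs log-rank comparison of survival groups
#'
#' Computes the log-rank test p-value and the pairwise Cox hazard ratio for
#' every unordered pair of groups. Star coding follows the conventional
#' thresholds (`*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001).
#' Benjamini-Hochberg adjustment is available; the default is unadjusted,
#' matching how pairwise survival grids are usually reported.
#'
#' @param times,events as in [km_median()].
#' @param groups group label per observation.
#' @param alpha significance level for the significant-fraction summary.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return object of class `pairwise_logrank`: list with symmetric matrices
#'   `p` (and `p_adjusted`), `hr` (HR of row group vs column group, so
#'   `hr[i, j] == 1 / hr[j, i]`), `stars`, plus `alpha`, `adjust` and the
#'   long-format `pairs` data frame.
#' @export
pairwise_logrank <- function(times, events, groups, alpha = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) < 2) stop("need at least two groups")
  G <- length(lv)
  p <- hr <- lo <- hi <- matrix(NA_real_, G, G, dimnames = list(lv, lv))
  rows <- list()
  for (i in seq_len(G - 1)) for (j in seq(i + 1, G)) {
    sel <- groups %in% c(lv[i], lv[j])
    if (!sum(groups == lv[i]) || !sum(groups == lv[j])) next
    ti <- times[sel]; ev <- events[sel]
    gg <- factor(groups[sel], levels = c(lv[j], lv[i]))  # column group = ref
    sd <- survival::survdiff(survival::Surv(ti, ev) ~ gg)
    pv <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    cx <- tryCatch(summary(survival::coxph(survival::Surv(ti, ev) ~ gg)),
                   error = function(e) NULL)
    h <- if (!is.null(cx)) unname(cx$conf.int[1, c(1, 3, 4)]) else rep(NA_real_, 3)
    p[i, j] <- p[j, i] <- pv
    hr[i, j] <- h[1]; hr[j, i] <- 1 / h[1]
    lo[i, j] <- h[2]; hi[i, j] <- h[3]
    lo[j, i] <- 1 / h[3]; hi[j, i] <- 1 / h[2]
    rows[[length(rows) + 1L]] <-
      data.frame(group1 = lv[i], group2 = lv[j], hr = h[1], lower = h[2],
                 upper = h[3], p = pv, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  p_adj <- p
  if (adjust == "BH" && !is.null(pairs)) {
    adj <- stats::p.adjust(pairs$p, method = "BH")
    pairs$p_adjusted <- adj
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$group1[r]; j <- pairs$group2[r]
      p_adj[i, j] <- p_adj[j, i] <- adj[r]
    }
  }
  structure(list(p = p, p_adjusted = p_adj, hr = hr, hr_lower = lo,
                 hr_upper = hi, stars = .p_stars(p_adj), pairs = pairs,
                 alpha = alpha, adjust = adjust, groups = lv),
            class = "pairwise_logrank")
}

#' @export
print.pairwise_logrank <- function(x, ...) {
  cat(sprintf("Pairwise log-rank over %d groups (%d pairs, adjust = %s)\n",
              length(x$groups), nrow(x$pairs), x$adjust))
  sf <- significant_fraction(x)
  cat(sprintf("  significant at alpha = %g: %d/%d (%d%%)\n",
              x$alpha, sf$n_sig, sf$n_pairs, sf$percent))
  invisible(x)
}

#' Fraction of significant pairwise survival differences
#'
#' Summarizes a pairwise log-rank matrix as the share of group pairs whose
#' overall-survival difference is significant, the headline statistic for
#' comparing the prognostic resolution of two classification schemes.
#'
#' @param pw a `pairwise_logrank` object.
#' @param alpha significance level (default: the one stored in `pw`).
#' @return list with `n_sig`, `n_pairs`, `percent` (rounded to a whole
#'   percent).
#' @export
significant_fraction <- function(pw, alpha = NULL) {
  stopifnot(inherits(pw, "pairwise_logrank"))
  if (is.null(alpha)) alpha <- pw$alpha
  pvals <- pw$pairs[[if (pw$adjust == "BH") "p_adjusted" else "p"]]
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) stop("no evaluable pairs")
  n_sig <- sum(pvals <= alpha)
  list(n_sig = n_sig, n_pairs = length(pvals),
       percent = as.integer(round(100 * n_sig / length(pvals))))
}

#' Full survival comparison of diagnosis groups
#'
#' Convenience wrapper combining per-group Kaplan-Meier medians, Cox hazard
#' ratios against a reference, and the pairwise log-rank grid with its
#' significant-fraction summary.
#'
#' @param times,events,groups as in [cox_hr()].
#' @param reference reference group for the Cox model.
#' @param alpha significance level for the pairwise summary.
#' @return object of class `survival_summary` with components `medians`,
#'   `cox`, `pairwise`, `significant`.
#' @export
survival_summary <- function(times, events, groups, reference,
                             alpha = 0.05) {
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[keep]; events <- events[keep]
  groups <- as.character(groups)[keep]
  med <- km_median_by_group(times, events, groups)
  cox <- cox_hr(times, events, groups, reference)
  pw <- pairwise_logrank(times, events, groups, alpha = alpha)
  structure(list(medians = med, cox = cox, pairwise = pw,
                 significant = significant_fraction(pw),
                 reference = reference, n = sum(keep)),
            class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf("Survival comparison over %d cases, reference = %s\n",
              x$n, x$reference))
  med <- x$medians
  med$median <- round(med$median, 1)
  cat("\nMedian overall survival (months):\n")
  print(med, row.names = FALSE)
  cox <- x$cox
  cox[c("hr", "lower", "upper")] <- lapply(cox[c("hr", "lower", "upper")],
                                           round, 2)
  cox$p <- signif(cox$p, 2)
  cat("\nCox hazard ratios vs reference:\n")
  print(cox, row.names = FALSE)
  cat("\n")
  print(x$pairwise)
  invisible(x)
}

#' Risk-score split of a cohort
#'
#' Scores each patient as the coefficient-weighted sum of the model genes'
#' expression, splits the cohort at the median score into high- and
#' low-risk halves, and reports the Cox hazard ratio of high versus low.
#' The default gene set is the four stiffness-related signature genes
#' (FN1, ITGA5, OSMR, NGFR); coefficients must be supplied (they come from
#' the originating risk-model publication or from a refit).
#'
#' @param coefficients named numeric vector (names = gene symbols); at
#'   least one coefficient must be nonzero.
#' @param expr gene-by-sample expression matrix containing every model
#'   gene.
#' @param times,events survival data aligned with `colnames(expr)`.
#' @return list with `scores`, `risk` (factor high/low), `hr`, `lower`,
#'   `upper`, `p` and the underlying `coxph` fit.
#' @export
risk_split <- function(coefficients, expr, times, events) {
  stopifnot(is.matrix(expr), length(times) == ncol(expr),
            length(events) == ncol(expr))
  if (all(coefficients == 0)) stop("all coefficients are zero")
  missing_genes <- setdiff(names(coefficients), rownames(expr))
  if (length(missing_genes))
    stop("model gene(s) absent from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  scores <- drop(crossprod(expr[names(coefficients), , drop = FALSE],
                           coefficients))
  if (length(unique(scores)) == 1)
    stop("all risk scores identical; median split impossible")
  risk <- factor(ifelse(scores > stats::median(scores), "high", "low"),
                 levels = c("low", "high"))
  fit <- survival::coxph(survival::Surv(times, events) ~ risk)
  s <- summary(fit)
  list(scores = stats::setNames(scores, colnames(expr)), risk = risk,
       hr = unname(s$conf.int[1, 1]),
       lower = unname(s$conf.int[1, 3]),
       upper = unname(s$conf.int[1, 4]),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       fit = fit)
}
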