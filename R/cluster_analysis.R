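## Unsupervised structure discovery: consensus k-means over subsampled
## cohorts, Ward dendrograms, and quantitative agreement (ARI / NMI)
## between cluster assignments and diagnosis labels.

#' Consensus k-means clustering of samples
#'
#' Runs k-means repeatedly on random subsamples of the samples (columns),
#' accumulates for every sample pair the frequency of co-clustering among
#' the iterations where both were drawn, and derives the final assignment
#' by Ward (`ward.D2`) hierarchical clustering of `1 - consensus` cut at
#' `k`. Feature pre-filtering to the most variable rows is applied first
#' (cohort-scale matrices carry mostly uninformative genes).
#'
#' @param mat numeric feature-by-sample matrix (samples in columns).
#' @param k number of clusters (`2 <= k <=` number of samples).
#' @param iterations number of subsampled k-means runs (default 1000).
#' @param subsample_fraction fraction of samples drawn per iteration
#'   (default 0.8).
#' @param top_var keep only this many most-variable rows (default 2000;
#'   `Inf` keeps all).
#' @param seed integer seed making the run reproducible.
#' @return an object of class `consensus_result`: list with `k`,
#'   `consensus` (sample x sample matrix in `[0, 1]`, diagonal 1),
#'   `assignment` (named integer vector), `degenerate` flag, and the run
#'   parameters.
#' @export
consensus_kmeans <- function(mat, k, iterations = 1000,
                             subsample_fraction = 0.8, top_var = 2000,
                             seed = 1L) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  if (!is.numeric(k) || k < 2 || k > ncol(mat))
    stop("k must satisfy 2 <= k <= number of samples")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  if (any(!is.finite(mat))) stop("matrix must be finite")
  if (is.finite(top_var) && nrow(mat) > top_var) {
    v <- apply(mat, 1L, stats::var)
    mat <- mat[order(v, decreasing = TRUE)[seq_len(top_var)], , drop = FALSE]
  }
  x <- t(mat)                      # samples in rows for kmeans
  n <- nrow(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))

  degenerate <- nrow(unique(x)) < k
  co <- matrix(0, n, n)
  both <- matrix(0, n, n)
  m <- max(2L, round(subsample_fraction * n))

  set.seed(seed)
  if (!degenerate) {
    for (b in seq_len(iterations)) {
      idx <- sort(sample.int(n, m))
      sub <- x[idx, , drop = FALSE]
      if (nrow(unique(sub)) < k) next
      cl <- tryCatch(
        stats::kmeans(sub, centers = k, nstart = 3, iter.max = 50)$cluster,
        error = function(e) NULL)
      if (is.null(cl)) next
      same <- outer(cl, cl, "==")
      co[idx, idx] <- co[idx, idx] + same
      both[idx, idx] <- both[idx, idx] + 1
    }
  }
  consensus <- ifelse(both > 0, co / both, 0)
  diag(consensus) <- 1
  dimnames(consensus) <- list(ids, ids)

  if (degenerate) {
    assignment <- stats::setNames(rep(1L, n), ids)
  } else {
    tree <- stats::hclust(stats::as.dist(1 - consensus), method = "ward.D2")
    assignment <- stats::cutree(tree, k = k)
    names(assignment) <- ids
    if (length(unique(assignment)) < k) degenerate <- TRUE
  }
  structure(list(k = k, consensus = consensus, assignment = assignment,
                 degenerate = degenerate, iterations = iterations,
                 subsample_fraction = subsample_fraction, seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus k-means: k = %d, %d samples, %d iterations (%.0f%% subsampling, seed %d)\n",
              x$k, length(x$assignment), x$iterations,
              100 * x$subsample_fraction, x$seed))
  if (x$degenerate) cat("  DEGENERATE: fewer than k distinct clusters\n")
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Ward dendrogram of samples
#'
#' Hierarchical clustering of the sample columns on Euclidean distances
#' with Ward (`ward.D2`) linkage.
#'
#' @param mat numeric feature-by-sample matrix.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`).
#' @return an `hclust` object (merge heights non-decreasing, leaf order
#'   deterministic).
#' @export
cluster_dendrogram <- function(mat, linkage = "ward.D2") {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  if (any(!is.finite(mat))) stop("matrix must be finite")
  stats::hclust(stats::dist(t(mat)), method = linkage)
}

#' Agreement between a cluster assignment and reference labels
#'
#' Computes the adjusted Rand index (chance-corrected pairwise agreement)
#' and normalized mutual information (arithmetic-mean normalization) between
#' two labelings of the same samples, plus their contingency table. Samples
#' with `NA` in either labeling are excluded pairwise and counted.
#'
#' @param assignment vector of cluster labels, named by sample (or aligned
#'   with `labels`).
#' @param labels vector of reference labels (may contain `NA`).
#' @return list with `ari`, `nmi`, `table`, `n_used`, `n_excluded`.
#' @export
label_agreement <- function(assignment, labels) {
  if (!is.null(names(assignment)) && !is.null(names(labels))) {
    common <- intersect(names(assignment), names(labels))
    if (!length(common)) stop("assignment and labels share no samples")
    assignment <- assignment[common]
    labels <- labels[common]
  } else if (length(assignment) != length(labels)) {
    stop("assignment and labels have different lengths and no names to match")
  }
  keep <- !is.na(assignment) & !is.na(labels)
  n_excluded <- sum(!keep)
  a <- factor(assignment[keep])
  b <- factor(labels[keep])
  tab <- table(a, b)
  list(ari = .adjusted_rand(tab), nmi = .nmi(tab),
       table = tab, n_used = sum(keep), n_excluded = n_excluded)
}

## Adjusted Rand index from a contingency table (Hubert & Arabie form).
.adjusted_rand <- function(tab) {
  n <- sum(tab)
  if (n < 2) return(NA_real_)
  sum_comb <- function(x) sum(choose(x, 2))
  sum_nij <- sum_comb(tab)
  sum_a <- sum_comb(rowSums(tab))
  sum_b <- sum_comb(colSums(tab))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_nij == expected) 1 else 0)
  as.numeric((sum_nij - expected) / (max_index - expected))
}

## Normalized mutual information, NMI = 2 I(A;B) / (H(A) + H(B)).
.nmi <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(NA_real_)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  h <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0)
      mi <- mi + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  denom <- (h(pa) + h(pb)) / 2
  if (denom == 0) return(if (mi == 0) 1 else NA_real_)
  as.numeric(mi / denom)
}

#' Report cases whose aliquots fall into different clusters
#'
#' Multiple expression (or methylation) profiles of one case need not land
#' in the same cluster; this lists the cases for which they do not, a direct
#' readout of intratumoral heterogeneity.
#'
#' @param assignment named cluster vector (names are aliquot ids).
#' @param aliquot_to_case named character vector mapping aliquot id to case
#'   id.
#' @return data frame with columns `case_id`, `n_aliquots`, `n_clusters`,
#'   restricted to cases with aliquots split across clusters.
#' @export
split_aliquot_report <- function(assignment, aliquot_to_case) {
  stopifnot(!is.null(names(assignment)))
  case <- unname(aliquot_to_case[names(assignment)])
  if (anyNA(case)) stop("every aliquot must map to a case")
  per_case <- split(unname(assignment), case)
  multi <- per_case[lengths(per_case) > 1]
  nclust <- vapply(multi, function(v) length(unique(v)), integer(1))
  res <- data.frame(case_id = names(multi),
                    n_aliquots = lengths(multi),
                    n_clusters = unname(nclust),
                    stringsAsFactors = FALSE)
  res[res$n_clusters > 1, , drop = FALSE]
}
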