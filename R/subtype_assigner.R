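## Glioblastoma transcriptional subtype assignment (Proneural / Classical /
## Mesenchymal) from per-subtype signature gene lists, via Ward hierarchical
## clustering of standardized signature-gene expression.

.subtype_names <- c("Proneural", "Classical", "Mesenchymal")

#' Read subtype signature gene lists
#'
#' Expects a TSV with columns `subtype` and `gene`. Subtype gene lists must
#' be disjoint.
#'
#' @param path TSV file path.
#' @return a named list of character vectors, one per subtype.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("subtype", "gene") %in% names(df)))
    stop("signature file must have columns: subtype, gene")
  sig <- lapply(split(df$gene, df$subtype), unique)
  if (anyDuplicated(unlist(sig)))
    stop("subtype signatures must be disjoint gene lists")
  sig
}

#' Standardize an expression matrix over signature genes
#'
#' Restricts the matrix to the signature genes it contains, then transforms
#' each gene to zero mean and unit variance across samples. The default
#' transform order is `log2(x + 1)` followed by the per-gene Z-score;
#' `order = "z_log"` applies the Z-score first and then a shifted log2
#' (values translated to be >= 1 before logging), for comparison with
#' pipelines that standardize before logging. Absent and zero-variance
#' genes are dropped with a message.
#'
#' @param expr non-negative gene-by-sample expression matrix.
#' @param signatures named list of signature gene vectors (see
#'   [read_signatures()]).
#' @param order `"log_z"` (default) or `"z_log"`.
#' @return the standardized signature-gene matrix; dropped genes are listed
#'   in attribute `"dropped"`.
#' @export
preprocess_signature_matrix <- function(expr, signatures,
                                        order = c("log_z", "z_log")) {
  order <- match.arg(order)
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  sig_genes <- unique(unlist(signatures))
  absent <- setdiff(sig_genes, rownames(expr))
  present <- intersect(sig_genes, rownames(expr))
  if (!length(present)) stop("no signature gene present in the matrix")
  if (length(absent))
    message(length(absent), " signature gene(s) absent from matrix: ",
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ...")
  m <- expr[present, , drop = FALSE]
  zscore <- function(x) {
    sds <- apply(x, 1L, stats::sd)
    keep <- sds > 0
    x <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) /
      sds[keep]
    attr(x, "zero_var") <- rownames(m)[!keep]
    x
  }
  if (order == "log_z") {
    out <- zscore(log2(m + 1))
  } else {
    sds <- apply(m, 1L, stats::sd)
    keep <- sds > 0
    z <- (m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) / sds[keep]
    ## shift so every value is >= 1 before logging: keeps the transform
    ## defined while preserving the original pipeline's ordering
    out <- log2(z - min(z) + 1)
    attr(out, "zero_var") <- rownames(m)[!keep]
  }
  zero_var <- attr(out, "zero_var")
  if (length(zero_var))
    message(length(zero_var), " zero-variance gene(s) dropped")
  attr(out, "dropped") <- c(absent, zero_var)
  out
}

#' Assign transcriptional subtypes by Ward clustering
#'
#' Clusters samples by Ward-linkage (`ward.D2`) hierarchical clustering on
#' Euclidean distances over the standardized signature matrix, cuts the tree
#' at `k` clusters, and labels each cluster with the subtype whose signature
#' genes show the highest mean standardized expression among the cluster's
#' samples. When two clusters claim the same subtype, the cluster with the
#' higher score keeps it and the other takes its best remaining subtype,
#' with a warning. Sample columns are processed in lexicographic id order so
#' the result does not depend on input column order.
#'
#' @param std standardized matrix from [preprocess_signature_matrix()].
#' @param signatures named list of signature gene vectors.
#' @param k number of clusters (default 3, one per subtype).
#' @return a named character vector of subtype labels (one per sample) with
#'   attributes `"cluster"` (integer cluster ids), `"scores"` (cluster x
#'   subtype mean-signature matrix) and `"tree"` (the `hclust` object).
#' @export
assign_subtypes <- function(std, signatures, k = 3) {
  stopifnot(is.matrix(std), ncol(std) >= k)
  ord <- order(colnames(std))
  std <- std[, ord, drop = FALSE]
  tree <- stats::hclust(stats::dist(t(std)), method = "ward.D2")
  cl <- stats::cutree(tree, k = k)

  scores <- matrix(NA_real_, k, length(signatures),
                   dimnames = list(NULL, names(signatures)))
  for (s in names(signatures)) {
    genes <- intersect(signatures[[s]], rownames(std))
    if (!length(genes)) next
    gm <- colMeans(std[genes, , drop = FALSE])
    scores[, s] <- vapply(seq_len(k), function(i) mean(gm[cl == i]),
                          numeric(1))
  }
  ## greedy one-to-one assignment by descending score; when k exceeds the
  ## number of subtypes, leftover clusters take their best-scoring subtype
  label_of <- rep(NA_character_, k)
  sc <- scores
  while (anyNA(label_of) && any(is.finite(sc))) {
    idx <- which(sc == max(sc, na.rm = TRUE), arr.ind = TRUE)[1L, , drop = TRUE]
    i <- idx[["row"]]; s <- colnames(sc)[idx[["col"]]]
    label_of[i] <- s
    sc[i, ] <- NA_real_
    sc[, s] <- NA_real_
  }
  for (i in which(is.na(label_of)))
    label_of[i] <- colnames(scores)[which.max(scores[i, ])]
  naive <- vapply(seq_len(k),
                  function(i) colnames(scores)[which.max(scores[i, ])],
                  character(1))
  if (anyDuplicated(naive))
    warning("two clusters claimed the same subtype; ",
            "resolved by assignment score")
  labels <- stats::setNames(label_of[cl], colnames(std))
  attr(labels, "cluster") <- cl
  attr(labels, "scores") <- scores
  attr(labels, "tree") <- tree
  labels
}
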