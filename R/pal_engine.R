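## Pathway activation level (PAL) scoring.
##
## PAL_p(s) = sum_n ARR_n * log10(CNR_n(s)) * 100 / sum_n |ARR_n|,
## where CNR is the case-to-normal expression ratio against a reference
## profile and ARR in {-1, -0.5, 0, 0.5, 1} encodes the gene product's
## activator/repressor role in the pathway. The |ARR| denominator follows
## the established PAL methodology; a literal signed-sum denominator is
## available for comparison but can be zero on balanced pathways.

.arr_levels <- c(-1, -0.5, 0, 0.5, 1)

#' Construct a pathway definition
#'
#' @param name pathway name.
#' @param genes character vector of member gene symbols (unique).
#' @param arr numeric vector of activator/repressor roles, one per gene,
#'   each in `{-1, -0.5, 0, 0.5, 1}`: positive for activators, negative for
#'   repressors, 0 for members with an ambiguous role.
#' @return an object of class `pathway_definition`.
#' @export
pathway_definition <- function(name, genes, arr) {
  genes <- as.character(genes)
  arr <- as.numeric(arr)
  if (length(genes) != length(arr)) stop("genes and arr lengths differ")
  if (anyDuplicated(genes)) stop("duplicate gene symbols in pathway ", name)
  if (!all(arr %in% .arr_levels))
    stop("ARR values must be in {-1, -0.5, 0, 0.5, 1}")
  if (all(arr == 0)) stop("pathway ", name, " has no member with ARR != 0")
  structure(list(name = name, genes = genes, arr = stats::setNames(arr, genes)),
            class = "pathway_definition")
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat(sprintf("Pathway '%s': %d genes (%d activators, %d repressors, %d neutral)\n",
              x$name, length(x$genes), sum(x$arr > 0), sum(x$arr < 0),
              sum(x$arr == 0)))
  invisible(x)
}

#' Read pathway definitions from a TSV file
#'
#' Expects columns `pathway`, `gene`, `arr` (one row per pathway member).
#'
#' @param path TSV file path.
#' @return a named list of `pathway_definition` objects.
#' @export
read_pathways <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("pathway", "gene", "arr")
  if (!all(need %in% names(df)))
    stop("pathway file must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$pathway), function(d)
    pathway_definition(d$pathway[1L], d$gene, d$arr))
}

#' Compute case-to-normal expression ratios
#'
#' Divides each gene's expression by its level in a reference profile. By
#' default the reference is the "artificial normal": the gene-by-gene
#' average over all samples of the cohort, so a sample equal to the cohort
#' mean has CNR 1 for every gene. A pseudocount (added to numerator and
#' reference alike) keeps ratios finite for zero counts.
#'
#' @param expr non-negative gene-by-sample matrix of normalized counts.
#' @param reference `"cohort_average"` or a named numeric vector covering
#'   every gene of `expr`.
#' @param pseudocount non-negative value added to both sides of the ratio
#'   (default 1, suitable for normalized count scales).
#' @return a gene-by-sample matrix of positive CNR values, with the
#'   reference profile attached as attribute `"reference"`.
#' @export
compute_cnr <- function(expr, reference = "cohort_average", pseudocount = 1) {
  stopifnot(is.matrix(expr), nrow(expr) > 0, ncol(expr) > 0)
  if (any(!is.finite(expr)) || any(expr < 0))
    stop("expression values must be finite and non-negative")
  if (identical(reference, "cohort_average")) {
    ref <- rowMeans(expr)
  } else {
    if (is.null(names(reference)) || !all(rownames(expr) %in% names(reference)))
      stop("explicit reference must be a named vector covering all genes")
    ref <- reference[rownames(expr)]
  }
  if (pseudocount == 0 && any(ref == 0))
    stop("reference is zero for some gene(s); use a positive pseudocount")
  cnr <- (expr + pseudocount) / (ref + pseudocount)
  attr(cnr, "reference") <- ref
  cnr
}

#' Compute the pathway activation level for samples
#'
#' Evaluates the signed, ARR-weighted average of log10 CNR values over the
#' pathway members present in the matrix, scaled by 100. Members absent
#' from the matrix are excluded from numerator and denominator and counted
#' in the returned coverage.
#'
#' @param pathway a `pathway_definition`.
#' @param cnr a CNR matrix from [compute_cnr()].
#' @param samples columns to evaluate (default: all).
#' @param denominator `"abs"` (default; sum of |ARR|) or `"signed"`
#'   (literal signed sum, which errors on balanced pathways).
#' @return a named numeric vector of PAL values (one per sample) with
#'   attributes `"coverage"` (fraction of pathway members found) and
#'   `"n_used"`.
#' @export
compute_pal <- function(pathway, cnr, samples = colnames(cnr),
                        denominator = c("abs", "signed")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(pathway, "pathway_definition"), is.matrix(cnr))
  present <- intersect(pathway$genes, rownames(cnr))
  if (!length(present))
    stop("no member of pathway '", pathway$name, "' present in the matrix")
  arr <- pathway$arr[present]
  denom <- if (denominator == "abs") sum(abs(arr)) else sum(arr)
  if (denom == 0)
    stop("zero denominator for pathway '", pathway$name,
         "' (all present members have ARR = 0",
         if (denominator == "signed") " or signed roles balance out", ")")
  sub <- log10(cnr[present, samples, drop = FALSE])
  pal <- drop(crossprod(sub, arr)) * 100 / denom
  pal <- stats::setNames(as.numeric(pal), samples)
  attr(pal, "coverage") <- length(present) / length(pathway$genes)
  attr(pal, "n_used") <- length(present)
  pal
}

#' Compute PAL for a list of pathways
#'
#' @param pathways a list of `pathway_definition` objects.
#' @param cnr a CNR matrix from [compute_cnr()].
#' @inheritParams compute_pal
#' @return a pathway-by-sample numeric matrix; rows for pathways that fail
#'   (no member present, zero denominator) are all-`NA` with a warning, so
#'   one bad pathway does not poison the batch.
#' @export
batch_pal <- function(pathways, cnr, denominator = c("abs", "signed")) {
  denominator <- match.arg(denominator)
  nms <- vapply(pathways, function(p) p$name, character(1))
  out <- matrix(NA_real_, length(pathways), ncol(cnr),
                dimnames = list(nms, colnames(cnr)))
  for (i in seq_along(pathways)) {
    res <- tryCatch(
      compute_pal(pathways[[i]], cnr, denominator = denominator),
      error = function(e) {
        warning("pathway '", nms[i], "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(res)) out[i, ] <- res
  }
  out
}
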