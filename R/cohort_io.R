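## Canonical factor levels of the cohort annotation schema. Order matters for
## the canonical TSV round trip and for reclassification table margins.
.histology_levels <- c("astrocytoma", "oligoastrocytoma", "oligodendroglioma",
                       "glioblastoma", "unknown")
.grade_levels     <- c("II", "III", "IV", "unknown")
.mut_levels       <- c("mutant", "wildtype", "unknown")
.yn_levels        <- c("yes", "no", "unknown")
.h3_levels        <- c("K27M", "G34_mut", "wildtype", "unknown")

.cohort_columns <- c(
  "case_id", "histology", "hist_grade", "idh_status", "codel_1p19q",
  "atrx", "tertp", "egfr_amp", "gain7_loss10", "cdkn2ab_hd", "h3_status",
  "age_at_diagnosis", "os_time", "os_event")

.cohort_level_map <- list(
  histology    = .histology_levels,
  hist_grade   = .grade_levels,
  idh_status   = .mut_levels,
  codel_1p19q  = .yn_levels,
  atrx         = .mut_levels,
  tertp        = .mut_levels,
  egfr_amp     = .yn_levels,
  gain7_loss10 = .yn_levels,
  cdkn2ab_hd   = .yn_levels,
  h3_status    = .h3_levels)

## Map a character vector onto canonical levels; anything unrecognized
## (including NA / empty / "NA" in any case) becomes "unknown".
.canonical_level <- function(x, levels, column) {
  x <- as.character(x)
  x[is.na(x) | trimws(x) == "" | toupper(trimws(x)) == "NA"] <- "unknown"
  x <- trimws(x)
  bad <- !(x %in% levels)
  if (any(bad)) {
    warning(sprintf("%d value(s) in column '%s' not among {%s}; mapped to 'unknown' (e.g. '%s')",
                    sum(bad), column, paste(levels, collapse = ", "),
                    x[bad][1L]), call. = FALSE)
    x[bad] <- "unknown"
  }
  x
}

.num_or_na <- function(x) {
  x <- as.character(x)
  x[trimws(x) == "" | toupper(trimws(x)) == "NA"] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read a glioma cohort annotation table
#'
#' Reads a per-case clinical/molecular annotation TSV into a validated cohort
#' data frame. The file must carry a header with the documented schema
#' columns: `case_id`, `histology`, `hist_grade`, `idh_status`,
#' `codel_1p19q`, `atrx`, `tertp`, `egfr_amp`, `gain7_loss10`,
#' `cdkn2ab_hd`, `h3_status`, `age_at_diagnosis`, `os_time`, `os_event`.
#' Extra columns are ignored. Missing values may be encoded as an empty
#' string or `"NA"` (case-insensitive). Categorical tokens outside the
#' documented level sets are mapped to `"unknown"` with a warning, so that a
#' cohort read never fails on exotic annotation strings.
#'
#' @param path path to a tab-separated annotation file.
#' @return a `data.frame` of class `glioma_cohort`, one row per case, with
#'   canonical factor-free character columns plus numeric
#'   `age_at_diagnosis`, `os_time` (months) and integer `os_event`.
#' @seealso [write_cohort()], [classify_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols))
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(case_id = trimws(raw$case_id), stringsAsFactors = FALSE)
  if (anyDuplicated(out$case_id))
    stop("duplicate case_id in cohort: ",
         paste(unique(out$case_id[duplicated(out$case_id)]), collapse = ", "))
  for (col in names(.cohort_level_map))
    out[[col]] <- .canonical_level(raw[[col]], .cohort_level_map[[col]], col)
  out$age_at_diagnosis <- .num_or_na(raw$age_at_diagnosis)
  out$os_time  <- .num_or_na(raw$os_time)
  out$os_event <- as.integer(.num_or_na(raw$os_event))
  if (any(!is.na(out$os_time) & out$os_time < 0))
    stop("negative os_time in cohort")
  if (any(!out$os_event %in% c(0L, 1L, NA_integer_)))
    stop("os_event must be 0, 1 or missing")
  out <- out[, .cohort_columns]
  class(out) <- c("glioma_cohort", "data.frame")
  out
}

#' Write a glioma cohort annotation table
#'
#' Writes the canonical TSV representation of a cohort: fixed column order,
#' tab separation, `NA` for missing numerics, no quoting. Reading the output
#' back with [read_cohort()] reproduces the cohort exactly.
#'
#' @param cohort a `glioma_cohort` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  utils::write.table(cohort[, .cohort_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate a cohort data frame assembled in code
#'
#' Applies the same canonicalization and invariant checks as [read_cohort()]
#' to an in-memory data frame.
#'
#' @param df a data frame with the cohort schema columns.
#' @return a `glioma_cohort` data frame.
#' @export
as_glioma_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.cohort_columns, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$case_id)) stop("duplicate case_id")
  out <- data.frame(case_id = as.character(df$case_id),
                    stringsAsFactors = FALSE)
  for (col in names(.cohort_level_map))
    out[[col]] <- .canonical_level(df[[col]], .cohort_level_map[[col]], col)
  out$age_at_diagnosis <- as.numeric(df$age_at_diagnosis)
  out$os_time  <- as.numeric(df$os_time)
  out$os_event <- as.integer(df$os_event)
  class(out) <- c("glioma_cohort", "data.frame")
  out
}

## ---------------------------------------------------------------------------
## MAF handling

#' Read a somatic mutation table in MAF format
#'
#' Reads the four columns of a Mutation Annotation Format file that hotspot
#' status extraction needs: `Hugo_Symbol`, `Variant_Classification`,
#' `HGVSp_Short` and `Tumor_Sample_Barcode`. Comment lines starting with
#' `#` (the usual MAF version header) are skipped.
#'
#' @param path path to a tab-separated MAF file (uncompressed).
#' @return a `data.frame` with columns `sample_id`, `hugo_symbol`,
#'   `variant_classification`, `protein_change`.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  need <- c("Hugo_Symbol", "Variant_Classification", "HGVSp_Short",
            "Tumor_Sample_Barcode")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("MAF is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  data.frame(sample_id = raw$Tumor_Sample_Barcode,
             hugo_symbol = raw$Hugo_Symbol,
             variant_classification = raw$Variant_Classification,
             protein_change = raw$HGVSp_Short,
             stringsAsFactors = FALSE)
}

.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

## Parse an HGVS p. short form ("p.R132H" or "p.Arg132His") into
## list(ref, pos, alt) with one-letter codes, or NULL when unparseable.
.parse_hgvsp <- function(p) {
  if (is.na(p) || !nzchar(p)) return(NULL)
  m <- regmatches(p, regexec(
    "^p\\.\\(?([A-Z][a-z]{2}|[A-Z])([0-9]+)([A-Z][a-z]{2}|[A-Z]|\\*|=)\\)?$",
    p))[[1]]
  if (length(m) != 4L) return(NULL)
  ref <- m[2]; alt <- m[4]
  if (nchar(ref) == 3L) {
    if (!ref %in% names(.aa3to1)) return(NULL)
    ref <- .aa3to1[[ref]]
  }
  if (nchar(alt) == 3L) {
    if (!alt %in% names(.aa3to1)) return(NULL)
    alt <- .aa3to1[[alt]]
  }
  list(ref = ref, pos = as.integer(m[3]), alt = alt)
}

.maf_for_sample <- function(records, sample_id) {
  stopifnot(is.data.frame(records))
  records[records$sample_id == sample_id, , drop = FALSE]
}

## Scan records of one sample for a hotspot: gene set, ref residue, allowed
## positions, alt residue (NULL alt = any substitution). Missense rows only.
.has_hotspot <- function(rows, genes, ref, positions, alt = NULL) {
  rows <- rows[rows$hugo_symbol %in% genes &
               rows$variant_classification == "Missense_Mutation", ,
               drop = FALSE]
  if (!nrow(rows)) return(FALSE)
  for (i in seq_len(nrow(rows))) {
    pc <- .parse_hgvsp(rows$protein_change[i])
    if (is.null(pc)) {
      warning(sprintf("unparseable protein change '%s' (%s); record skipped",
                      rows$protein_change[i], rows$hugo_symbol[i]),
              call. = FALSE)
      next
    }
    if (pc$ref == ref && pc$pos %in% positions &&
        (is.null(alt) || pc$alt == alt)) return(TRUE)
  }
  FALSE
}

#' Extract IDH mutation status for one sample from MAF records
#'
#' A sample is `mutant` when it carries a missense mutation in IDH1 at codon
#' 132 or in IDH2 at codon 172 (the hotspots that define IDH-mutant status
#' under WHO CNS5); otherwise `wildtype`. The caller is responsible for
#' distinguishing "sample absent from the MAF universe" (no genomic data,
#' status unknown) from "present with no qualifying record" (wildtype); this
#' function implements the latter convention.
#'
#' @param records a MAF data frame from [read_maf()].
#' @param sample_id the tumor sample barcode to scan.
#' @return `"mutant"` or `"wildtype"`.
#' @export
extract_idh_status <- function(records, sample_id) {
  rows <- .maf_for_sample(records, sample_id)
  if (.has_hotspot(rows, "IDH1", "R", 132L) ||
      .has_hotspot(rows, "IDH2", "R", 172L)) "mutant" else "wildtype"
}

#' Extract histone H3 hotspot status for one sample from MAF records
#'
#' Looks for the two pediatric-type high-grade glioma hotspots: K27M
#' (Lys-to-Met in H3-3A/H3F3A, H3C2/HIST1H3B or H3C3/HIST1H3C) and G34R
#' (Gly-to-Arg in H3-3A/H3F3A). Both residue numbering conventions are
#' accepted: mature-protein (27/34, as in the WHO names) and initiator-Met
#' (28/35, as MAF annotation pipelines emit). If both hotspots are present,
#' K27M wins and a conflict warning is raised.
#'
#' @inheritParams extract_idh_status
#' @return `"K27M"`, `"G34_mut"` or `"wildtype"`.
#' @export
extract_h3_status <- function(records, sample_id) {
  rows <- .maf_for_sample(records, sample_id)
  k27_genes <- c("H3-3A", "H3F3A", "H3C2", "HIST1H3B", "H3C3", "HIST1H3C")
  g34_genes <- c("H3-3A", "H3F3A")
  k27 <- .has_hotspot(rows, k27_genes, "K", c(27L, 28L), "M")
  g34 <- .has_hotspot(rows, g34_genes, "G", c(34L, 35L), "R")
  if (k27 && g34)
    warning("sample ", sample_id,
            " carries both K27M and G34R; reporting K27M", call. = FALSE)
  if (k27) "K27M" else if (g34) "G34_mut" else "wildtype"
}

#' Fill unknown IDH / H3 statuses from MAF records
#'
#' For every case whose annotated `idh_status` (or `h3_status`) is unknown,
#' looks the case up in the MAF: a case absent from the MAF sample universe
#' has no genomic data and stays unknown; a case present is assigned the
#' extracted status. This mirrors the rescue step applied to cohort cases
#' whose clinical annotation lacks mutation calls.
#'
#' @param cohort a `glioma_cohort` data frame.
#' @param maf a MAF data frame from [read_maf()]. Sample barcodes are matched
#'   to `case_id` by prefix (a barcode matches the case it starts with), so
#'   TCGA-style aliquot barcodes resolve to their case.
#' @return the cohort with statuses updated, plus an attribute
#'   `"maf_resolved"` counting the cases filled in per field.
#' @export
apply_maf_statuses <- function(cohort, maf) {
  stopifnot(inherits(cohort, "glioma_cohort"))
  samples <- unique(maf$sample_id)
  find_sample <- function(case_id) {
    hit <- samples[startsWith(samples, case_id)]
    if (length(hit)) hit[1L] else NA_character_
  }
  resolved <- c(idh = 0L, h3 = 0L)
  for (i in seq_len(nrow(cohort))) {
    sid <- find_sample(cohort$case_id[i])
    if (is.na(sid)) next
    if (cohort$idh_status[i] == "unknown") {
      cohort$idh_status[i] <- extract_idh_status(maf, sid)
      resolved["idh"] <- resolved["idh"] + 1L
    }
    if (cohort$h3_status[i] == "unknown") {
      cohort$h3_status[i] <- extract_h3_status(maf, sid)
      resolved["h3"] <- resolved["h3"] + 1L
    }
  }
  attr(cohort, "maf_resolved") <- resolved
  cohort
}

## ---------------------------------------------------------------------------
## Expression / methylation matrices

#' Read a gene-by-sample numeric matrix from TSV
#'
#' First column holds gene (or probe) identifiers, remaining columns one
#' sample each. Duplicate row identifiers are an error for expression input;
#' probe-level methylation may carry duplicates only after mapping.
#'
#' @param path TSV file path.
#' @param allow_duplicates keep duplicated row names (probe-level input).
#' @return a numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path, allow_duplicates = FALSE) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  ids <- as.character(raw[[1L]])
  if (!allow_duplicates && anyDuplicated(ids))
    stop("duplicate row identifiers in ", path)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a gene-by-sample matrix from MatrixMarket triplet files
#'
#' @param mtx path to the `.mtx` triplet file.
#' @param genes path to a one-column text file of row (gene) identifiers.
#' @param samples path to a one-column text file of column (sample)
#'   identifiers.
#' @return a dense numeric matrix.
#' @export
read_matrix_mtx <- function(mtx, genes, samples) {
  m <- as.matrix(Matrix::readMM(mtx))
  rn <- readLines(genes)
  cn <- readLines(samples)
  if (nrow(m) != length(rn) || ncol(m) != length(cn))
    stop("MTX dimensions do not match sidecar gene/sample lists")
  dimnames(m) <- list(rn, cn)
  m
}

#' Aggregate probe-level methylation beta values to gene level
#'
#' Each output gene row is the summary (arithmetic mean by default) of its
#' probes' beta values, computed per sample with missing probes excluded.
#' Probes mapping to no gene are dropped and counted.
#'
#' @param betas probe-by-sample matrix of beta values in `[0, 1]` (missing
#'   values allowed).
#' @param probe_to_gene a data frame with columns `probe` and `gene`, or a
#'   named character vector (names = probes, values = genes).
#' @param fun aggregation statistic, `"mean"` (default) or `"median"`.
#' @return a gene-by-sample matrix of aggregated betas, with attribute
#'   `"n_unmapped"` giving the number of dropped probes.
#' @export
aggregate_methylation <- function(betas, probe_to_gene, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  stopifnot(is.matrix(betas))
  if (any(betas < 0 | betas > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene$gene),
                           as.character(probe_to_gene$probe))
  } else map <- probe_to_gene
  gene <- unname(map[rownames(betas)])
  unmapped <- is.na(gene) | gene == ""
  if (any(unmapped))
    message(sum(unmapped), " probe(s) mapped to no gene; dropped")
  betas <- betas[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  if (!nrow(betas)) stop("no probes left after mapping")
  agg_fun <- if (fun == "mean") {
    function(x) colMeans(x, na.rm = TRUE)
  } else {
    function(x) apply(x, 2L, stats::median, na.rm = TRUE)
  }
  genes <- sort(unique(gene))
  out <- matrix(NA_real_, length(genes), ncol(betas),
                dimnames = list(genes, colnames(betas)))
  idx <- split(seq_along(gene), gene)
  for (g in genes)
    out[g, ] <- agg_fun(betas[idx[[g]], , drop = FALSE])
  out[is.nan(out)] <- NA_real_
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}
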