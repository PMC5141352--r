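# Readers and writers for the three input tables and the result tables.
# All files are tab-separated with a header row; decimal point, no thousands
# separators. Gene and sample identifiers are opaque strings matched exactly.

KARYOTYPE_LEVELS <- c("normal", "intermediate_abnormal", "complex", "other", "unknown")

#' Read a gene-by-sample RPKM expression matrix
#'
#' Parses a tab-separated file whose header row holds sample identifiers and
#' whose first column holds gene identifiers (genes-as-rows orientation; no
#' auto-detection). Every cell must be a finite, non-negative number.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix of RPKM values with gene identifiers as row names
#'   and sample identifiers as column names.
#' @seealso [write_expression_matrix()], [lrpkm_transform()]
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    colClasses = "character", stringsAsFactors = FALSE
  )
  if (ncol(raw) < 2L) {
    stop_validation("expression matrix '%s' needs a gene-id column plus at least one sample column", path)
  }
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop_validation("duplicated gene id(s) in '%s': %s", path, paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop_validation("duplicated sample id(s) in '%s': %s", path, paste(dup_s, collapse = ", "))
  }
  values <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop_validation(
        "non-numeric or non-finite value '%s' at gene '%s', sample '%s'",
        raw[[j + 1L]][bad[1L]], gene_ids[bad[1L]], sample_ids[j]
      )
    }
    values[, j] <- v
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop_validation(
      "negative RPKM value %g at gene '%s', sample '%s'",
      values[neg[1L, 1L], neg[1L, 2L]], gene_ids[neg[1L, 1L]], sample_ids[neg[1L, 2L]]
    )
  }
  validate_expression_matrix(values)
}

#' @rdname read_expression_matrix
#' @param m Numeric gene-by-sample matrix to validate or write.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_validation("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_validation("expression matrix must carry gene row names and sample column names")
  }
  if (anyDuplicated(rownames(m))) stop_validation("duplicated gene ids")
  if (anyDuplicated(colnames(m))) stop_validation("duplicated sample ids")
  if (any(!is.finite(m))) stop_validation("expression matrix contains non-finite values")
  if (any(m < 0)) stop_validation("expression matrix contains negative values")
  m
}

#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m)
  out <- data.frame(gene_id = rownames(m), apply(m, 2L, num_fmt),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(m) == 1L) colnames(out)[2L] <- colnames(m)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Serialize doubles at 17 significant digits so write-then-read round trips
# are bit exact.
num_fmt <- function(x) sprintf("%.17g", x)

#' Read a receptor-to-subfamily classification table
#'
#' The table must be tab-separated with a header naming the columns
#' `receptor_id` and `subfamily`, and must map every receptor to exactly one
#' subfamily (the IUPHAR/GRAFS-style scheme uses 18 subfamilies over 772
#' receptors; any consistent partition is accepted).
#'
#' @param path Path to the TSV file.
#' @return A named character vector: `names()` are receptor identifiers,
#'   values are subfamily labels.
#' @export
read_classification <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
    colClasses = "character", stringsAsFactors = FALSE
  )
  if (!all(c("receptor_id", "subfamily") %in% colnames(raw))) {
    stop_validation("classification '%s' must have columns receptor_id and subfamily", path)
  }
  if (nrow(raw) == 0L) stop_validation("classification '%s' is empty", path)
  raw <- unique(raw[c("receptor_id", "subfamily")])
  conflict <- unique(raw$receptor_id[duplicated(raw$receptor_id)])
  if (length(conflict)) {
    stop_validation(
      "receptor(s) assigned to more than one subfamily: %s",
      paste(conflict, collapse = ", ")
    )
  }
  stats::setNames(raw$subfamily, raw$receptor_id)
}

#' Read a sample annotation table
#'
#' Expects a tab-separated file with columns `sample_id`, `cohort`,
#' `subgroups` (semicolon-separated genetic-subgroup flags; empty for none;
#' the literal `NA` marks missing annotation) and `karyotype`. Valid cohort
#' labels are `AML`, `CD34_reference` and `normal_population:<name>`; only
#' AML samples may carry subgroup flags.
#'
#' @param path Path to the TSV file.
#' @return A data frame with one row per sample and class
#'   `sample_annotation`.
#' @export
read_sample_annotation <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
    colClasses = "character", stringsAsFactors = FALSE, na.strings = "NA"
  )
  need <- c("sample_id", "cohort", "subgroups", "karyotype")
  if (!all(need %in% colnames(raw))) {
    stop_validation("annotation '%s' must have columns %s", path, paste(need, collapse = ", "))
  }
  raw$subgroups[is.na(raw$subgroups)] <- NA_character_
  raw$subgroups[!is.na(raw$subgroups) & raw$subgroups == ""] <- ""
  validate_sample_annotation(raw[need])
}

#' @rdname read_sample_annotation
#' @param ann Data frame to validate as a sample annotation.
#' @export
validate_sample_annotation <- function(ann) {
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup)) {
    stop_validation("duplicated sample id(s): %s", paste(dup, collapse = ", "))
  }
  ok_cohort <- ann$cohort %in% c("AML", "CD34_reference") |
    startsWith(ann$cohort, "normal_population:")
  if (any(!ok_cohort)) {
    stop_validation("unknown cohort label(s): %s",
                    paste(unique(ann$cohort[!ok_cohort]), collapse = ", "))
  }
  bad_k <- !(ann$karyotype %in% KARYOTYPE_LEVELS)
  if (any(bad_k)) {
    stop_validation("unknown karyotype label(s): %s",
                    paste(unique(ann$karyotype[bad_k]), collapse = ", "))
  }
  flagged <- !is.na(ann$subgroups) & nzchar(ann$subgroups)
  bad <- flagged & ann$cohort != "AML"
  if (any(bad)) {
    stop_validation(
      "non-AML sample(s) carry genetic-subgroup flags: %s",
      paste(ann$sample_id[bad], collapse = ", ")
    )
  }
  rownames(ann) <- NULL
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

#' @rdname read_sample_annotation
#' @export
write_sample_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Per-sample list of subgroup flags; NA annotation -> NA element.
subgroup_flag_list <- function(ann) {
  lapply(ann$subgroups, function(s) {
    if (is.na(s)) return(NA_character_)
    if (!nzchar(s)) return(character(0L))
    strsplit(s, ";", fixed = TRUE)[[1L]]
  })
}

#' Sample identifiers carrying (or annotated as lacking) a subgroup flag
#'
#' @param ann A `sample_annotation` data frame.
#' @param subgroup Subgroup flag label, e.g. `"FLT3_ITD"`.
#' @return `samples_with_flag()` returns the sample ids whose annotation
#'   contains the flag; `samples_without_flag()` those explicitly annotated
#'   without it. Samples whose subgroup field is missing (`NA`) appear in
#'   neither set.
#' @export
samples_with_flag <- function(ann, subgroup) {
  fl <- subgroup_flag_list(ann)
  has <- vapply(fl, function(f) !anyNA(f) && subgroup %in% f, logical(1L))
  ann$sample_id[has]
}

#' @rdname samples_with_flag
#' @export
samples_without_flag <- function(ann, subgroup) {
  fl <- subgroup_flag_list(ann)
  lacks <- vapply(fl, function(f) !anyNA(f) && !(subgroup %in% f), logical(1L))
  ann$sample_id[lacks]
}

#' @rdname samples_with_flag
#' @export
aml_samples <- function(ann) ann$sample_id[ann$cohort == "AML"]

#' @rdname samples_with_flag
#' @export
reference_samples <- function(ann) ann$sample_id[ann$cohort == "CD34_reference"]

#' @rdname samples_with_flag
#' @export
population_samples <- function(ann, population) {
  lab <- paste0("normal_population:", population)
  ids <- ann$sample_id[ann$cohort == lab]
  if (!length(ids)) stop_validation("unknown normal population '%s'", population)
  ids
}

#' @rdname samples_with_flag
#' @export
normal_population_labels <- function(ann) {
  co <- unique(ann$cohort[startsWith(ann$cohort, "normal_population:")])
  sub("^normal_population:", "", co)
}

# Result-table writer: numeric columns serialized at full precision so
# repeated runs are byte identical and re-reads lose nothing.
write_result_table <- function(df, path) {
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- num_fmt(v)
      s[is.na(v)] <- "NA"
      out[[j]] <- s
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
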