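# The end-to-end screen: one entry point returning a classed object, plus the
# file-based orchestration that writes every result table and a run manifest.

#' Threshold configuration for the screen
#'
#' All thresholds live in one namespace with the study defaults: 1 lRPKM for
#' "expressed", 3.5 for "highly expressed", 6.7 for "very highly expressed",
#' a 0.5 (50%) coefficient-of-variation cutoff, a 1 lRPKM median-difference
#' cutoff for differential calls, a 1.5 lRPKM mean-difference cutoff for
#' subgroup fingerprints, and alpha 0.05 for every t test.
#'
#' @param delta_median Median-difference cutoff (lRPKM) for up/down calls.
#' @param delta_mean Mean-difference cutoff (lRPKM) for fingerprints.
#' @param alpha Two-sided significance level for t tests.
#' @param cv_threshold Coefficient-of-variation cutoff for the
#'   low-variability class.
#' @param tier_cuts Expression-tier cut points (lRPKM), inclusive at the
#'   lower edge.
#' @param var_equal Use the pooled-variance Student's t (default) rather
#'   than Welch's form.
#' @return A list of class `screen_control`.
#' @export
screen_control <- function(delta_median = 1, delta_mean = 1.5, alpha = 0.05,
                           cv_threshold = 0.5, tier_cuts = c(1, 3.5, 6.7),
                           var_equal = TRUE) {
  structure(list(
    delta_median = delta_median, delta_mean = delta_mean, alpha = alpha,
    cv_threshold = cv_threshold, tier_cuts = tier_cuts, var_equal = var_equal
  ), class = "screen_control")
}

#' Run the receptor expression screen on a cohort
#'
#' The full analysis on one cohort: lRPKM transform; per-gene AML medians,
#' ranking and expression tiers; coefficient-of-variation variability;
#' median-difference differential calls against the CD34+ reference;
#' two-tailed Fisher subfamily enrichment of the up and down sets (with the
#' background excluding all differential genes); per-subgroup expression
#' fingerprints; and, when normal populations are present, nomination of
#' subgroup-overexpressed receptors against every population. Genes absent
#' from the subfamily classification are dropped from the enrichment
#' universe and reported in `dropped_from_enrichment`.
#'
#' @param expression Gene-by-sample RPKM matrix (see
#'   [read_expression_matrix()]), or a `gpcr_cohort` from
#'   [simulate_cohort()] (in which case `annotation` and `classification`
#'   are taken from it).
#' @param annotation `sample_annotation` data frame covering the matrix
#'   columns; must contain AML and CD34_reference samples.
#' @param classification Named character vector mapping receptor id to
#'   subfamily.
#' @param subgroups Subgroup flags to fingerprint (default: all observed).
#' @param control A [screen_control()].
#' @return An object of class `gpcr_screen`; see the package vignette for
#'   the component tables.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 7))
#' fit <- gpcr_screen(cohort)
#' summary(fit)
#' @export
gpcr_screen <- function(expression, annotation = NULL, classification = NULL,
                        subgroups = NULL, control = screen_control()) {
  if (inherits(expression, "gpcr_cohort")) {
    annotation <- annotation %||% expression$annotation
    classification <- classification %||% expression$classification
    expression <- expression$expression
  }
  stopifnot(inherits(control, "screen_control"))
  expression <- validate_expression_matrix(expression)
  annotation <- validate_sample_annotation(as.data.frame(annotation))
  missing_ann <- setdiff(colnames(expression), annotation$sample_id)
  if (length(missing_ann)) {
    stop_validation("sample(s) missing from the annotation: %s",
                    paste(utils::head(missing_ann, 5L), collapse = ", "))
  }
  case <- intersect(aml_samples(annotation), colnames(expression))
  ref <- intersect(reference_samples(annotation), colnames(expression))
  if (!length(case) || !length(ref)) {
    stop_validation("screen needs both AML and CD34_reference samples")
  }

  lm <- lrpkm_transform(expression)
  tiers <- expression_tiers(lm, case, cuts = control$tier_cuts)
  ranking <- rank_by_median(lm, case)
  vrec <- variability(lm, case, cv_threshold = control$cv_threshold)
  calls <- call_differential(lm, case, ref, delta = control$delta_median)

  universe <- intersect(rownames(lm), names(classification))
  dropped <- setdiff(rownames(lm), universe)
  enrichment <- rbind(
    subfamily_enrichment(calls, "up", classification, universe),
    subfamily_enrichment(calls, "down", classification, universe)
  )

  fp <- fingerprint_subgroups(lm, annotation, subgroups,
                              delta = control$delta_mean,
                              alpha = control$alpha,
                              var_equal = control$var_equal)
  pops <- normal_population_labels(annotation)
  nominations <- nominate_targets(lm, annotation, fp, populations = pops,
                                  alpha = control$alpha,
                                  var_equal = control$var_equal)

  structure(list(
    lrpkm = lm, annotation = annotation, classification = classification,
    case_samples = case, reference_samples = ref,
    tiers = tiers, ranking = ranking, variability = vrec,
    calls = calls, enrichment = enrichment,
    fingerprints = fp, nominations = nominations,
    dropped_from_enrichment = dropped,
    control = control
  ), class = "gpcr_screen")
}

#' @export
print.gpcr_screen <- function(x, ...) {
  st <- table(x$calls$status)
  cat("Receptor expression screen\n")
  cat(sprintf("  %d genes, %d AML vs %d reference samples\n",
              nrow(x$lrpkm), length(x$case_samples), length(x$reference_samples)))
  cat(sprintf("  differential calls (|delta median| > %g lRPKM): %d up, %d down\n",
              x$control$delta_median, st[["up"]], st[["down"]]))
  cat(sprintf("  fingerprint records: %d; nominated targets: %d\n",
              nrow(x$fingerprints),
              length(unique(x$nominations$gene_id[x$nominations$nominated]))))
  invisible(x)
}

#' @export
summary.gpcr_screen <- function(object, ...) {
  tier_counts <- table(object$tiers$tier)
  st <- table(object$calls$status)
  enr <- object$enrichment
  sig <- enr[enr$a > 0 & enr$p_value < object$control$alpha, , drop = FALSE]
  nom <- unique(object$nominations[object$nominations$nominated,
                                   c("subgroup", "gene_id")])
  structure(list(
    n_genes = nrow(object$lrpkm),
    n_case = length(object$case_samples),
    n_reference = length(object$reference_samples),
    tier_counts = tier_counts,
    n_low_variability = sum(object$variability$low_variability, na.rm = TRUE),
    status_counts = st,
    enriched = sig[order(sig$p_value), c("direction", "subfamily", "a", "b",
                                         "c", "d", "p_value", "bh_q")],
    n_fingerprint = nrow(object$fingerprints),
    nominated = nom,
    control = object$control
  ), class = "summary.gpcr_screen")
}

#' @export
print.summary.gpcr_screen <- function(x, ...) {
  cat(sprintf("Receptor expression screen: %d genes, %d AML vs %d reference samples\n",
              x$n_genes, x$n_case, x$n_reference))
  cat("Expression tiers (AML median lRPKM):\n")
  print(x$tier_counts)
  cat(sprintf("Low-variability genes (CV < %g): %d\n",
              x$control$cv_threshold, x$n_low_variability))
  cat("Differential calls vs CD34+ reference:\n")
  print(x$status_counts)
  if (nrow(x$enriched)) {
    cat("Enriched subfamilies (Fisher two-tailed p <", x$control$alpha, "):\n")
    print(x$enriched, row.names = FALSE, digits = 3)
  } else {
    cat("No subfamily enrichment at alpha", x$control$alpha, "\n")
  }
  cat(sprintf("Fingerprint records: %d\n", x$n_fingerprint))
  if (nrow(x$nominated)) {
    cat("Nominated subgroup-specific targets:\n")
    print(x$nominated, row.names = FALSE)
  } else {
    cat("No nominated subgroup-specific targets\n")
  }
  invisible(x)
}

#' Scatter of AML versus reference median expression
#'
#' Plots each gene's AML median lRPKM against its reference median, colouring
#' up (blue) and down (green) calls; the dashed lines mark the
#' median-difference cutoffs.
#'
#' @param x A `gpcr_screen` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gpcr_screen <- function(x, ...) {
  calls <- x$calls
  col <- c(up = "#2166ac", down = "#1b7837", unchanged = "grey40")[as.character(calls$status)]
  graphics::plot(calls$median_reference, calls$median_case, col = col,
                 pch = 16, cex = 0.6,
                 xlab = "median lRPKM, CD34+ reference",
                 ylab = "median lRPKM, AML", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::abline(x$control$delta_median, 1, lty = 2, col = "#2166ac")
  graphics::abline(-x$control$delta_median, 1, lty = 2, col = "#1b7837")
  invisible(x)
}

#' Run the screen from input files and write every result table
#'
#' File-based orchestration: reads the three input tables, runs
#' [gpcr_screen()], optionally cross-validates the fingerprints against a
#' secondary cohort's fingerprint table, and writes `tiers.tsv`,
#' `variability.tsv`, `differential_calls.tsv`, `enrichment.tsv`,
#' `fingerprints.tsv`, `nominations.tsv` and a `run_metadata.txt` manifest
#' recording the effective thresholds and input checksums. Output is
#' deterministic: identical inputs give byte-identical tables.
#'
#' @param matrix_path,annotation_path,classification_path Input TSV paths.
#' @param out_dir Output directory (created if needed).
#' @param control A [screen_control()].
#' @param subgroups Passed to [gpcr_screen()].
#' @param secondary_fingerprints Optional path to a secondary cohort's
#'   `fingerprints.tsv` for cross-cohort validation.
#' @return The `gpcr_screen` object, invisibly.
#' @export
run_screen <- function(matrix_path, annotation_path, classification_path,
                       out_dir, control = screen_control(), subgroups = NULL,
                       secondary_fingerprints = NULL) {
  expression <- read_expression_matrix(matrix_path)
  annotation <- read_sample_annotation(annotation_path)
  classification <- read_classification(classification_path)
  fit <- gpcr_screen(expression, annotation, classification,
                     subgroups = subgroups, control = control)
  if (!is.null(secondary_fingerprints)) {
    sec <- utils::read.delim(secondary_fingerprints, stringsAsFactors = FALSE)
    fit$fingerprints <- cross_validate(fit$fingerprints, sec)
  }
  write_screen_results(fit, out_dir, inputs = c(
    matrix = matrix_path, annotation = annotation_path,
    classification = classification_path
  ))
  invisible(fit)
}

#' @rdname run_screen
#' @param fit A `gpcr_screen` object.
#' @param inputs Optional named character vector of input paths; their MD5
#'   checksums are recorded in the manifest.
#' @export
write_screen_results <- function(fit, out_dir, inputs = NULL) {
  stopifnot(inherits(fit, "gpcr_screen"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_result_table(fit$tiers, file.path(out_dir, "tiers.tsv"))
  write_result_table(fit$variability, file.path(out_dir, "variability.tsv"))
  write_result_table(fit$calls, file.path(out_dir, "differential_calls.tsv"))
  write_result_table(fit$enrichment, file.path(out_dir, "enrichment.tsv"))
  write_result_table(fit$fingerprints, file.path(out_dir, "fingerprints.tsv"))
  write_result_table(fit$nominations, file.path(out_dir, "nominations.tsv"))
  ctl <- fit$control
  lines <- c(
    "gpcrscreen run manifest",
    sprintf("delta_median_lrpkm\t%g", ctl$delta_median),
    sprintf("delta_mean_lrpkm\t%g", ctl$delta_mean),
    sprintf("alpha\t%g", ctl$alpha),
    sprintf("cv_threshold\t%g", ctl$cv_threshold),
    sprintf("tier_cuts_lrpkm\t%s", paste(ctl$tier_cuts, collapse = ",")),
    sprintf("t_test\t%s", if (ctl$var_equal) "student_pooled" else "welch"),
    sprintf("n_case\t%d", length(fit$case_samples)),
    sprintf("n_reference\t%d", length(fit$reference_samples)),
    sprintf("dropped_from_enrichment\t%d", length(fit$dropped_from_enrichment))
  )
  if (!is.null(inputs)) {
    sums <- tools::md5sum(inputs)
    lines <- c(lines, sprintf("md5_%s\t%s", names(inputs), unname(sums)))
  }
  writeLines(lines, file.path(out_dir, "run_metadata.txt"))
  invisible(out_dir)
}
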