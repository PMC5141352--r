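# Genetic-subgroup expression fingerprints, cross-cohort validation and
# nomination of subgroup-specific overexpressed receptors against normal
# blood and bone-marrow populations.

# Subgroups analysed within normal-karyotype AML only (recurrent mutations);
# cytogenetic subgroups use the whole AML cohort.
MUTATION_SUBGROUPS <- c("NPM1", "FLT3_ITD", "DNMT3A")

#' Two-sample Student's t test
#'
#' Classical pooled-variance (equal-variance) two-sample t with
#' `n1 + n2 - 2` degrees of freedom and a two-sided p-value; Welch's
#' unequal-variance form is available via `var_equal = FALSE`. A zero pooled
#' variance yields a flagged degenerate result (`degenerate = TRUE`, p-value
#' `NA`), never a numeric zero.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance statistic (default `TRUE`).
#' @return List with `statistic`, `df`, `p_value`, `degenerate`.
#' @export
student_t_two_sample <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop_validation("each group needs at least 2 values")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 <= 0) {
      return(list(statistic = NA_real_, df = n1 + n2 - 2,
                  p_value = NA_real_, degenerate = TRUE))
    }
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    if (v1 + v2 <= 0) {
      return(list(statistic = NA_real_, df = NA_real_,
                  p_value = NA_real_, degenerate = TRUE))
    }
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (mean(x) - mean(y)) / se
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Default comparison scope for a genetic subgroup
#'
#' Recurrent-mutation subgroups (NPM1, FLT3-ITD, DNMT3A) are compared within
#' normal-karyotype AML samples only; cytogenetic subgroups within the whole
#' AML cohort.
#'
#' @param subgroup Subgroup label.
#' @return `"normal_karyotype"` or `"all"`.
#' @export
default_subgroup_scope <- function(subgroup) {
  ifelse(subgroup %in% MUTATION_SUBGROUPS, "normal_karyotype", "all")
}

#' Expression fingerprint of a genetic subgroup
#'
#' Compares mean lRPKM between AML samples with and without a genetic
#' abnormality, inside the chosen scope. A gene enters the fingerprint when
#' the absolute mean difference is at least `delta` (default 1.5 lRPKM) and
#' the Student's t p-value is below `alpha`; its direction is the sign of the
#' difference. Samples whose subgroup annotation is missing are excluded
#' from the "without" group rather than counted in it. A Benjamini-Hochberg
#' q-value over all genes tested is emitted as a labelled extension.
#'
#' @param lm lRPKM matrix.
#' @param ann `sample_annotation` data frame covering the matrix columns.
#' @param subgroup Genetic-subgroup flag to fingerprint.
#' @param scope `"all"` AML samples or `"normal_karyotype"` only; the
#'   default picks [default_subgroup_scope()].
#' @param delta Minimum absolute mean difference in lRPKM (default 1.5).
#' @param alpha Significance cutoff for the t test (default 0.05).
#' @param var_equal Passed to [student_t_two_sample()].
#' @return Data frame with columns `subgroup`, `gene_id`, `mean_with`,
#'   `mean_without`, `delta_mean`, `p_value`, `bh_q`, `direction`,
#'   `validated` (`NA` until [cross_validate()] is applied).
#' @export
fingerprint <- function(lm, ann, subgroup,
                        scope = default_subgroup_scope(subgroup),
                        delta = 1.5, alpha = 0.05, var_equal = TRUE) {
  scope <- match.arg(scope, c("all", "normal_karyotype"))
  in_scope <- ann$cohort == "AML"
  if (scope == "normal_karyotype") in_scope <- in_scope & ann$karyotype == "normal"
  scoped <- ann[in_scope, , drop = FALSE]
  with_s <- intersect(samples_with_flag(scoped, subgroup), colnames(lm))
  without_s <- intersect(samples_without_flag(scoped, subgroup), colnames(lm))
  if (length(with_s) < 2L || length(without_s) < 2L) {
    stop_validation(
      "subgroup '%s' needs >=2 samples with and without the flag in scope '%s' (found %d / %d)",
      subgroup, scope, length(with_s), length(without_s)
    )
  }
  xw <- lm[, with_s, drop = FALSE]
  xo <- lm[, without_s, drop = FALSE]
  mw <- rowMeans(xw); mo <- rowMeans(xo)
  tt <- lapply(rownames(lm), function(g) student_t_two_sample(xw[g, ], xo[g, ], var_equal))
  p <- vapply(tt, function(r) r$p_value, numeric(1L))
  degen <- vapply(tt, function(r) r$degenerate, logical(1L))
  q <- rep(NA_real_, length(p))
  q[!degen] <- stats::p.adjust(p[!degen], method = "BH")
  dm <- mw - mo
  keep <- !degen & abs(dm) >= delta & p < alpha
  data.frame(
    subgroup = rep(subgroup, sum(keep)),
    gene_id = rownames(lm)[keep],
    mean_with = unname(mw[keep]), mean_without = unname(mo[keep]),
    delta_mean = unname(dm[keep]),
    p_value = p[keep], bh_q = q[keep],
    direction = ifelse(dm[keep] > 0, "up", "down"),
    validated = rep(NA, sum(keep)),
    stringsAsFactors = FALSE
  )
}

#' Fingerprints for several subgroups at once
#'
#' Runs [fingerprint()] per subgroup with its default scope, skipping (with
#' a message) subgroups that lack two samples on either side of the split.
#'
#' @inheritParams fingerprint
#' @param subgroups Character vector of subgroup flags; defaults to every
#'   flag observed in the annotation.
#' @return Row-bound fingerprint data frame.
#' @export
fingerprint_subgroups <- function(lm, ann, subgroups = NULL,
                                  delta = 1.5, alpha = 0.05, var_equal = TRUE) {
  if (is.null(subgroups)) {
    fl <- subgroup_flag_list(ann[ann$cohort == "AML", , drop = FALSE])
    subgroups <- sort(unique(unlist(fl[!vapply(fl, anyNA, logical(1L))])))
  }
  out <- lapply(subgroups, function(sg) {
    tryCatch(
      fingerprint(lm, ann, sg, delta = delta, alpha = alpha, var_equal = var_equal),
      gpcrscreen_validation_error = function(e) {
        message("skipping subgroup '", sg, "': ", conditionMessage(e))
        NULL
      }
    )
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) {
    return(data.frame(
      subgroup = character(0), gene_id = character(0),
      mean_with = numeric(0), mean_without = numeric(0),
      delta_mean = numeric(0), p_value = numeric(0), bh_q = numeric(0),
      direction = character(0), validated = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

#' Cross-cohort validation of fingerprint records
#'
#' A primary-cohort fingerprint record is validated when the same
#' (subgroup, gene) pair appears in the secondary cohort's fingerprints
#' with the same direction.
#'
#' @param primary,secondary Fingerprint data frames sharing gene and
#'   subgroup vocabularies.
#' @return `primary` with its `validated` column set.
#' @export
cross_validate <- function(primary, secondary) {
  key <- function(df) paste(df$subgroup, df$gene_id, df$direction, sep = "\r")
  primary$validated <- key(primary) %in% key(secondary)
  primary
}

#' Nominate subgroup-specific overexpressed receptors
#'
#' For each upregulated fingerprint record, compares the subgroup's AML
#' samples against every named normal blood/bone-marrow population. A gene
#' is nominated when, for every population, the subgroup mean exceeds the
#' population mean (strictly) with a Student's t p-value below `alpha`; a
#' degenerate comparison blocks nomination.
#'
#' @inheritParams fingerprint
#' @param fingerprints Fingerprint data frame; only `direction == "up"`
#'   records are considered.
#' @param populations Normal-population labels (must exist in `ann`);
#'   defaults to every population present.
#' @return Long data frame with one row per (subgroup, gene, population):
#'   `subgroup`, `gene_id`, `population`, `delta_mean`, `p_value`,
#'   `nominated` (constant within a (subgroup, gene) record).
#' @export
nominate_targets <- function(lm, ann, fingerprints,
                             populations = normal_population_labels(ann),
                             alpha = 0.05, var_equal = TRUE) {
  empty <- data.frame(
    subgroup = character(0), gene_id = character(0), population = character(0),
    delta_mean = numeric(0), p_value = numeric(0), nominated = logical(0),
    stringsAsFactors = FALSE
  )
  up <- fingerprints[fingerprints$direction == "up", , drop = FALSE]
  if (!nrow(up) || !length(populations)) return(empty)
  pop_samples <- lapply(populations, function(p) {
    ids <- intersect(population_samples(ann, p), colnames(lm))
    if (length(ids) < 2L) stop_validation("population '%s' needs >=2 samples", p)
    ids
  })
  names(pop_samples) <- populations
  rows <- vector("list", nrow(up))
  for (i in seq_len(nrow(up))) {
    sg <- up$subgroup[i]; g <- up$gene_id[i]
    scope <- default_subgroup_scope(sg)
    in_scope <- ann$cohort == "AML"
    if (scope == "normal_karyotype") in_scope <- in_scope & ann$karyotype == "normal"
    sg_samples <- intersect(samples_with_flag(ann[in_scope, , drop = FALSE], sg),
                            colnames(lm))
    per_pop <- lapply(populations, function(p) {
      xs <- lm[g, sg_samples]; ys <- lm[g, pop_samples[[p]]]
      tt <- student_t_two_sample(xs, ys, var_equal)
      data.frame(subgroup = sg, gene_id = g, population = p,
                 delta_mean = mean(xs) - mean(ys),
                 p_value = tt$p_value, degenerate = tt$degenerate,
                 stringsAsFactors = FALSE)
    })
    per_pop <- do.call(rbind, per_pop)
    per_pop$nominated <- all(!per_pop$degenerate &
                               per_pop$delta_mean > 0 &
                               per_pop$p_value < alpha)
    rows[[i]] <- per_pop[setdiff(colnames(per_pop), "degenerate")]
  }
  do.call(rbind, rows)
}
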