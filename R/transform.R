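# Elementary statistics of the screen: the lRPKM transform, group medians and
# ranking, expression tiers, and coefficient-of-variation variability.

TIER_LEVELS <- c("not_expressed", "expressed", "high", "very_high")

#' Transform an RPKM matrix to lRPKM
#'
#' Applies `log2(RPKM + 1)` elementwise; the +1 offset damps the relative
#' variation of very small rates and keeps zero at zero. `rpkm_from_lrpkm()`
#' is the exact inverse, `2^l - 1`.
#'
#' @param m Non-negative numeric gene-by-sample RPKM matrix.
#' @return A matrix of the same shape and dimnames on the lRPKM scale.
#' @export
lrpkm_transform <- function(m) {
  m <- validate_expression_matrix(m)
  log2(m + 1)
}

#' @rdname lrpkm_transform
#' @param l lRPKM values.
#' @export
rpkm_from_lrpkm <- function(l) 2^l - 1

check_sample_set <- function(lm, samples, min_n = 1L) {
  if (length(samples) < min_n) {
    stop_validation("sample set must contain at least %d sample(s)", min_n)
  }
  missing <- setdiff(samples, colnames(lm))
  if (length(missing)) {
    stop_validation("sample id(s) not in matrix: %s", paste(missing, collapse = ", "))
  }
  invisible(samples)
}

#' Per-gene median lRPKM over a sample set
#'
#' Even-sized sets use the mean of the two central order statistics.
#'
#' @param lm lRPKM matrix.
#' @param samples Non-empty character vector of sample ids in `lm`.
#' @return Named numeric vector of per-gene medians.
#' @export
median_by_group <- function(lm, samples) {
  check_sample_set(lm, samples)
  apply(lm[, samples, drop = FALSE], 1L, stats::median)
}

#' Rank genes by median expression, highest first
#'
#' Ties are broken lexicographically by gene id (C locale) so the ordering is
#' reproducible across platforms.
#'
#' @inheritParams median_by_group
#' @return Character vector of gene ids, highest median first.
#' @export
rank_by_median <- function(lm, samples) {
  med <- median_by_group(lm, samples)
  names(med)[order(-med, names(med), method = "radix")]
}

#' Assign expression tiers from median lRPKM
#'
#' Cut points default to 1 (expressed), 3.5 (highly expressed) and 6.7 (very
#' highly expressed) lRPKM; each boundary is inclusive at its lower edge, so
#' a median of exactly 3.5 is `high`.
#'
#' @param median Numeric vector of non-negative median lRPKM values.
#' @param cuts Increasing cut points (length 3).
#' @return Factor with levels `not_expressed`, `expressed`, `high`,
#'   `very_high`.
#' @export
assign_tier <- function(median, cuts = c(1, 3.5, 6.7)) {
  if (any(!is.finite(median)) || any(median < 0)) {
    stop_validation("tier assignment requires finite, non-negative medians")
  }
  if (length(cuts) != 3L || is.unsorted(cuts, strictly = TRUE)) {
    stop_validation("tier cuts must be 3 strictly increasing values")
  }
  cut(median, breaks = c(-Inf, cuts, Inf), labels = TIER_LEVELS, right = FALSE)
}

#' Per-gene tier table over a sample set
#'
#' @inheritParams median_by_group
#' @inheritParams assign_tier
#' @return Data frame with columns `gene_id`, `median`, `tier`.
#' @export
expression_tiers <- function(lm, samples, cuts = c(1, 3.5, 6.7)) {
  med <- median_by_group(lm, samples)
  data.frame(
    gene_id = names(med), median = unname(med),
    tier = assign_tier(unname(med), cuts),
    stringsAsFactors = FALSE
  )
}

#' Coefficient-of-variation variability classification
#'
#' For each gene over a sample set, computes the mean and sample (n-1)
#' standard deviation of lRPKM and their ratio (CV). Genes with CV below
#' `cv_threshold` are classed as stably expressed. A zero mean leaves the CV
#' and the low-variability flag undefined (`NA`), never a numeric value.
#'
#' @inheritParams median_by_group
#' @param cv_threshold CV below which a gene counts as low variability
#'   (default 0.5, i.e. 50%).
#' @return Data frame with columns `gene_id`, `mean`, `sd`, `cv`,
#'   `low_variability`.
#' @export
variability <- function(lm, samples, cv_threshold = 0.5) {
  check_sample_set(lm, samples, min_n = 2L)
  x <- lm[, samples, drop = FALSE]
  mu <- rowMeans(x)
  sdev <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  cv <- ifelse(mu > 0, sdev / mu, NA_real_)
  data.frame(
    gene_id = rownames(lm), mean = unname(mu), sd = unname(sdev),
    cv = unname(cv), low_variability = unname(cv < cv_threshold),
    stringsAsFactors = FALSE
  )
}
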