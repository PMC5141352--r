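# Median-difference differential calls against the CD34+ reference and
# receptor-subfamily enrichment of the directional sets.

#' Call differential genes by median difference
#'
#' A gene is `up` when its case-minus-reference median lRPKM difference
#' exceeds `delta`, `down` when it falls below `-delta`, and `unchanged`
#' otherwise. The three status sets partition the genes.
#'
#' @param lm lRPKM matrix.
#' @param case_samples,reference_samples Disjoint, non-empty sample-id sets.
#' @param delta Median-difference threshold in lRPKM (default 1).
#' @return Data frame with columns `gene_id`, `median_case`,
#'   `median_reference`, `delta_median`, `status`.
#' @export
call_differential <- function(lm, case_samples, reference_samples, delta = 1) {
  check_sample_set(lm, case_samples)
  check_sample_set(lm, reference_samples)
  overlap <- intersect(case_samples, reference_samples)
  if (length(overlap)) {
    stop_validation("case and reference sample sets overlap: %s",
                    paste(overlap, collapse = ", "))
  }
  if (!is.finite(delta) || delta < 0) stop_validation("delta must be non-negative")
  mc <- median_by_group(lm, case_samples)
  mr <- median_by_group(lm, reference_samples)
  dm <- mc - mr
  status <- ifelse(dm > delta, "up", ifelse(dm < -delta, "down", "unchanged"))
  data.frame(
    gene_id = rownames(lm),
    median_case = unname(mc), median_reference = unname(mr),
    delta_median = unname(dm),
    status = factor(status, levels = c("up", "down", "unchanged")),
    stringsAsFactors = FALSE
  )
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `(a, b; c, d)` under fixed margins,
#' by the point-probability rule: the hypergeometric probabilities of all
#' tables sharing the observed margins are summed when they do not exceed
#' the observed table's probability (a relative tolerance of `1e-7` on the
#' comparison guards against floating-point ties). Terms are accumulated on
#' the log-factorial scale so margins in the hundreds stay finite.
#'
#' @param a,b,c,d Non-negative integer counts. `a + b` and `c + d` are the
#'   row margins (e.g. directional DE set and background), `a + c` the first
#'   column margin (subfamily membership).
#' @return A p-value in (0, 1]; the all-zero table returns 1 by convention.
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_validation("Fisher table counts must be non-negative integers")
  }
  if (all(counts == 0)) return(1)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[k == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Receptor-subfamily enrichment of a directional differential set
#'
#' For each subfamily F the 2x2 table is: `a` = directional genes in F,
#' `b` = directional genes outside F, `c` = background genes in F, `d` =
#' background genes outside F, where the background is the universe minus
#' all differentially expressed genes (both directions). Subfamilies with
#' no directional member are still reported. Alongside the raw two-tailed
#' Fisher p-value, a Benjamini-Hochberg q-value across subfamilies is
#' emitted as a labelled extension.
#'
#' @param calls Output of [call_differential()].
#' @param direction `"up"` or `"down"`.
#' @param classification Named character vector mapping receptor id to
#'   subfamily (see [read_classification()]).
#' @param universe Gene universe for the test; defaults to every classified
#'   receptor. Must contain all called genes it is asked to test.
#' @return Data frame with columns `direction`, `subfamily`, `a`, `b`, `c`,
#'   `d`, `p_value`, `bh_q`.
#' @export
subfamily_enrichment <- function(calls, direction = c("up", "down"),
                                 classification, universe = names(classification)) {
  direction <- match.arg(direction)
  universe <- unique(universe)
  called <- calls$gene_id[calls$status != "unchanged"]
  called <- intersect(called, universe)
  missing_cls <- setdiff(universe, names(classification))
  if (length(missing_cls)) {
    stop_validation("gene(s) missing from the subfamily classification: %s",
                    paste(utils::head(missing_cls, 5L), collapse = ", "))
  }
  dir_set <- intersect(calls$gene_id[calls$status == direction], universe)
  background <- setdiff(universe, called)
  fams <- sort(unique(unname(classification[universe])))
  res <- lapply(fams, function(f) {
    in_f <- names(classification)[classification == f]
    a <- length(intersect(dir_set, in_f))
    b <- length(dir_set) - a
    cc <- length(intersect(background, in_f))
    d <- length(background) - cc
    data.frame(direction = direction, subfamily = f,
               a = a, b = b, c = cc, d = d,
               p_value = fisher_exact_two_tailed(a, b, cc, d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$bh_q <- stats::p.adjust(res$p_value, method = "BH")
  res
}
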