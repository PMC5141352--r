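# Independent oracles and tiny fixture builders used across the suite.

# Brute-force two-tailed Fisher p: explicit enumeration of every table with
# the observed margins, point probabilities as direct factorial products.
# Deliberately shares no code with fisher_exact_two_tailed().
fisher_oracle <- function(a, b, c, d, rel_tol = 1e-7) {
  if (a + b + c + d == 0) return(1)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  f <- factorial
  probs <- vapply(ks, function(k) {
    f(r1) * f(r2) * f(c1) * f(c2) /
      (f(n) * f(k) * f(r1 - k) * f(c1 - k) * f(r2 - c1 + k))
  }, numeric(1))
  p_obs <- probs[ks == a]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

# Small lRPKM matrix with named axes.
lmat <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples),
         byrow = TRUE, dimnames = list(genes, samples))
}

# Write a gene-by-sample TSV fixture; `rows` is a list of character vectors.
write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path, useBytes = TRUE)
  path
}

# Minimal valid annotation data frame.
make_annotation <- function(aml = character(0), ref = character(0),
                            subgroups = rep("", length(aml)),
                            karyotype = rep("normal", length(aml)),
                            populations = list()) {
  ann <- data.frame(
    sample_id = c(aml, ref),
    cohort = c(rep("AML", length(aml)), rep("CD34_reference", length(ref))),
    subgroups = c(subgroups, rep("", length(ref))),
    karyotype = c(karyotype, rep("unknown", length(ref))),
    stringsAsFactors = FALSE
  )
  for (p in names(populations)) {
    ann <- rbind(ann, data.frame(
      sample_id = populations[[p]],
      cohort = paste0("normal_population:", p),
      subgroups = "", karyotype = "unknown", stringsAsFactors = FALSE
    ))
  }
  validate_sample_annotation(ann)
}
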