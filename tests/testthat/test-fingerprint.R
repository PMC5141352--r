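test_that("pooled-variance t matches the classical formula and stats::t.test", {
  r <- student_t_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  x <- c(5.1, 4.9, 5.0, 5.2, 4.8); y <- c(3.1, 2.9, 3.0, 3.2, 2.8)
  r2 <- student_t_two_sample(x, y)
  expect_equal(r2$df, 8)
  expect_lt(r2$p_value, 1e-6)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(r2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-12)

  set.seed(13)
  for (i in 1:50) {
    a <- rnorm(sample(2:12, 1), sd = runif(1, 0.2, 2))
    b <- rnorm(sample(2:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.2, 2))
    mine <- student_t_two_sample(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    minew <- student_t_two_sample(a, b, var_equal = FALSE)
    refw <- stats::t.test(a, b)
    expect_equal(minew$p_value, refw$p.value, tolerance = 1e-10)
  }
})

test_that("zero pooled variance is flagged degenerate, never p = 0", {
  r <- student_t_two_sample(c(1, 1, 1), c(1, 1, 1))
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
  expect_error(student_t_two_sample(1, c(1, 2)),
               class = "gpcrscreen_validation_error")
})

fp_cohort <- function(seed, effects = NULL) {
  simulate_cohort(sim_config(
    n_aml = 115L, n_up = 0L, n_down = 0L, noise_sd = 0.3,
    subgroup_prevalence = c(t_8_21 = 15 / 115),
    mutation_prevalence = c(NPM1 = 0.4),
    subgroup_effects = effects, seed = seed
  ))
}

test_that("fingerprint recovers a planted +2 subgroup shift and gates on both cutoffs", {
  eff <- data.frame(subgroup = "t_8_21", gene_id = "GPCR0010", delta = 2,
                    stringsAsFactors = FALSE)
  hits <- vapply(1:20, function(s) {
    co <- fp_cohort(400 + s, eff)
    fp <- fingerprint(lrpkm_transform(co$expression), co$annotation, "t_8_21")
    "GPCR0010" %in% fp$gene_id[fp$direction == "up"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # no planted shift: the gene is absent
  co <- fp_cohort(1)
  fp0 <- fingerprint(lrpkm_transform(co$expression), co$annotation, "t_8_21")
  expect_false("GPCR0010" %in% fp0$gene_id)

  # +1.0 shift at near-zero noise: p << 0.05 but delta < 1.5 gates the call
  eff1 <- data.frame(subgroup = "t_8_21", gene_id = "GPCR0010", delta = 1,
                     stringsAsFactors = FALSE)
  cfg <- sim_config(n_aml = 115L, n_up = 0L, n_down = 0L, noise_sd = 0.01,
                    subgroup_prevalence = c(t_8_21 = 15 / 115),
                    subgroup_effects = eff1, seed = 5)
  co1 <- simulate_cohort(cfg)
  lm1 <- lrpkm_transform(co1$expression)
  fp1 <- fingerprint(lm1, co1$annotation, "t_8_21")
  expect_false("GPCR0010" %in% fp1$gene_id)
  w <- samples_with_flag(co1$annotation, "t_8_21")
  o <- setdiff(aml_samples(co1$annotation), w)
  expect_lt(student_t_two_sample(lm1["GPCR0010", w], lm1["GPCR0010", o])$p_value, 0.05)
})

test_that("fingerprint threshold endpoints behave as limits", {
  co <- fp_cohort(2)
  lm <- lrpkm_transform(co$expression)
  all_in <- fingerprint(lm, co$annotation, "t_8_21", delta = 0, alpha = 1.1)
  expect_setequal(all_in$gene_id, rownames(lm))
  none <- fingerprint(lm, co$annotation, "t_8_21", delta = Inf)
  expect_identical(nrow(none), 0L)
  expect_error(fingerprint(lm, co$annotation, "no_such_subgroup"),
               regexp = "no_such_subgroup",
               class = "gpcrscreen_validation_error")
})

test_that("mutation subgroups are scoped to normal-karyotype AML by default", {
  expect_identical(unname(default_subgroup_scope(c("NPM1", "t_8_21"))),
                   c("normal_karyotype", "all"))
  co <- fp_cohort(3)
  lm <- lrpkm_transform(co$expression)
  fp <- fingerprint(lm, co$annotation, "NPM1", delta = 0, alpha = 1.1)
  # the implied comparison uses only normal-karyotype samples
  nk <- co$annotation$sample_id[co$annotation$karyotype == "normal" &
                                  co$annotation$cohort == "AML"]
  w <- intersect(samples_with_flag(co$annotation, "NPM1"), nk)
  g <- fp$gene_id[1]
  expect_equal(fp$mean_with[1], mean(lm[g, w]), tolerance = 1e-12)
})

test_that("cross-cohort validation requires same subgroup, gene and direction", {
  rec <- function(sg, g, dir) data.frame(
    subgroup = sg, gene_id = g, mean_with = 3, mean_without = 1,
    delta_mean = ifelse(dir == "up", 2, -2), p_value = 0.01, bh_q = 0.02,
    direction = dir, validated = NA, stringsAsFactors = FALSE
  )
  prim <- rbind(rec("MLL", "GPR126", "up"), rec("MLL", "GPR174", "down"),
                rec("inv16", "ACKR3", "up"))
  sec <- rbind(rec("MLL", "GPR126", "up"), rec("MLL", "GPR174", "up"))
  out <- cross_validate(prim, sec)
  expect_identical(out$validated, c(TRUE, FALSE, FALSE))
  # detection is symmetric: swapping cohorts validates the same triples
  key <- function(df) with(df[df$validated, ], paste(subgroup, gene_id, direction))
  expect_setequal(key(out), key(cross_validate(sec, prim)))
})

test_that("nomination requires overexpression against every normal population", {
  eff <- data.frame(subgroup = "t_8_21", gene_id = "GPCR0010", delta = 2,
                    stringsAsFactors = FALSE)
  co <- fp_cohort(6, eff)
  lm <- lrpkm_transform(co$expression)
  fp <- fingerprint(lm, co$annotation, "t_8_21")
  nom <- nominate_targets(lm, co$annotation, fp)
  g <- nom[nom$gene_id == "GPCR0010", ]
  expect_identical(nrow(g), 5L)  # one row per population
  expect_true(all(g$nominated))
  expect_true(all(g$delta_mean > 0 & g$p_value < 0.05))

  # force one population to the subgroup's own level: nomination is blocked
  w <- samples_with_flag(co$annotation, "t_8_21")
  gran <- population_samples(co$annotation, "granulocytes")
  lm2 <- lm
  lm2["GPCR0010", gran] <- mean(lm["GPCR0010", w])
  nom2 <- nominate_targets(lm2, co$annotation, fp)
  expect_false(any(nom2$nominated[nom2$gene_id == "GPCR0010"]))

  # empty fingerprint input -> empty output
  empty <- fp[0, ]
  expect_identical(nrow(nominate_targets(lm, co$annotation, empty)), 0L)
  expect_error(
    nominate_targets(lm, co$annotation, fp, populations = "plasma_cells"),
    class = "gpcrscreen_validation_error"
  )
})
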