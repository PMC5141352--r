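screen_fixture_dirs <- function(seed = 12, effects = NULL) {
  cfg <- sim_config(
    n_aml = 60L, n_reference = 8L, n_genes = 120L,
    subfamily_sizes = c(chemokine = 20L, adhesion = 20L, amine = 30L,
                        peptide = 30L, orphan = 20L),
    n_up = 6L, n_down = 4L,
    family_bias_up = c(chemokine = 0.5), family_bias_down = c(adhesion = 0.5),
    normal_populations = c(wbc = 4L, t_cells = 4L),
    subgroup_prevalence = c(t_8_21 = 0.2),
    mutation_prevalence = c(NPM1 = 0.4),
    subgroup_effects = effects, seed = seed
  )
  dir <- tempfile("cohort")
  write_cohort(simulate_cohort(cfg), dir)
  dir
}

test_that("run_screen writes every schema-valid result table plus a manifest", {
  dir <- screen_fixture_dirs()
  out <- tempfile("results")
  fit <- run_screen(file.path(dir, "expression.tsv"),
                    file.path(dir, "annotation.tsv"),
                    file.path(dir, "classification.tsv"), out)
  files <- c("tiers.tsv", "variability.tsv", "differential_calls.tsv",
             "enrichment.tsv", "fingerprints.tsv", "nominations.tsv",
             "run_metadata.txt")
  expect_true(all(file.exists(file.path(out, files))))
  calls <- read.delim(file.path(out, "differential_calls.tsv"))
  expect_named(calls, c("gene_id", "median_case", "median_reference",
                        "delta_median", "status"))
  enr <- read.delim(file.path(out, "enrichment.tsv"))
  expect_named(enr, c("direction", "subfamily", "a", "b", "c", "d",
                      "p_value", "bh_q"))
  expect_setequal(unique(enr$direction), c("up", "down"))
  meta <- readLines(file.path(out, "run_metadata.txt"))
  expect_true(any(grepl("^delta_median_lrpkm\t1$", meta)))
  expect_true(any(grepl("^md5_matrix\t[0-9a-f]{32}$", meta)))
})

test_that("every written number is reproducible from the module operations", {
  dir <- screen_fixture_dirs(seed = 13)
  out <- tempfile("results")
  run_screen(file.path(dir, "expression.tsv"), file.path(dir, "annotation.tsv"),
             file.path(dir, "classification.tsv"), out)
  m <- read_expression_matrix(file.path(dir, "expression.tsv"))
  ann <- read_sample_annotation(file.path(dir, "annotation.tsv"))
  lm <- lrpkm_transform(m)
  direct <- call_differential(lm, aml_samples(ann), reference_samples(ann))
  written <- read.delim(file.path(out, "differential_calls.tsv"))
  expect_equal(written$delta_median, direct$delta_median, tolerance = 1e-12)
  expect_identical(written$status, as.character(direct$status))
  vr <- variability(lm, aml_samples(ann))
  wv <- read.delim(file.path(out, "variability.tsv"))
  expect_equal(wv$cv, vr$cv, tolerance = 1e-12)
})

test_that("an extreme call threshold empties the tables without failing", {
  dir <- screen_fixture_dirs(seed = 14)
  out <- tempfile("results")
  fit <- run_screen(file.path(dir, "expression.tsv"),
                    file.path(dir, "annotation.tsv"),
                    file.path(dir, "classification.tsv"), out,
                    control = screen_control(delta_median = 999))
  expect_identical(sum(fit$calls$status != "unchanged"), 0L)
  enr <- read.delim(file.path(out, "enrichment.tsv"))
  expect_true(all(enr$a == 0L))
  expect_true(all(enr$p_value == 1))
})

test_that("identical inputs give byte-identical outputs", {
  dir <- screen_fixture_dirs(seed = 15)
  out1 <- tempfile("r1"); out2 <- tempfile("r2")
  for (o in c(out1, out2)) {
    run_screen(file.path(dir, "expression.tsv"), file.path(dir, "annotation.tsv"),
               file.path(dir, "classification.tsv"), o)
  }
  for (f in list.files(out1)) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))), label = f)
  }
})

test_that("secondary-cohort fingerprints set the validated flags", {
  eff <- data.frame(subgroup = "t_8_21", gene_id = "GPCR0005", delta = 2.5,
                    stringsAsFactors = FALSE)
  dir1 <- screen_fixture_dirs(seed = 16, effects = eff)
  dir2 <- screen_fixture_dirs(seed = 17, effects = eff)
  out2 <- tempfile("sec")
  run_screen(file.path(dir2, "expression.tsv"), file.path(dir2, "annotation.tsv"),
             file.path(dir2, "classification.tsv"), out2)
  out1 <- tempfile("prim")
  fit <- run_screen(file.path(dir1, "expression.tsv"),
                    file.path(dir1, "annotation.tsv"),
                    file.path(dir1, "classification.tsv"), out1,
                    secondary_fingerprints = file.path(out2, "fingerprints.tsv"))
  rec <- fit$fingerprints[fit$fingerprints$gene_id == "GPCR0005", ]
  expect_identical(nrow(rec), 1L)
  expect_true(rec$validated)
})

test_that("screen object methods print and plot without error", {
  co <- simulate_cohort(sim_config(
    n_aml = 40L, n_reference = 6L, n_genes = 60L,
    subfamily_sizes = c(chemokine = 30L, amine = 30L),
    n_up = 3L, n_down = 2L, family_bias_up = c(chemokine = 1),
    family_bias_down = NULL, normal_populations = c(wbc = 3L),
    subgroup_prevalence = c(MLL = 0.25), mutation_prevalence = c(NPM1 = 0.4),
    seed = 18
  ))
  fit <- gpcr_screen(co)
  expect_s3_class(fit, "gpcr_screen")
  expect_output(print(fit), "differential calls")
  expect_output(print(summary(fit)), "Expression tiers")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
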