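# Seeded generator of synthetic screening cohorts with planted ground truth:
# an AML cohort with genetic-subgroup labels, a small CD34+ reference, normal
# blood/bone-marrow populations, per-gene baselines on the lRPKM scale, and
# planted median shifts, subfamily-concentrated differential genes and
# subgroup-restricted mean shifts.

#' Default receptor-subfamily sizes
#'
#' An 18-subfamily partition of 772 receptors shaped like the human GPCR
#' repertoire (a large olfactory block, taste and vomeronasal receptors,
#' and the ligand-defined class A/adhesion/secretin/frizzled subfamilies).
#'
#' @return Named integer vector summing to 772.
#' @export
default_subfamily_sizes <- function() {
  c(olfactory = 370L, taste = 24L, vomeronasal = 4L, chemokine = 23L,
    adhesion = 33L, amine = 42L, peptide = 90L, lipid = 40L, purine = 12L,
    protease_activated = 4L, frizzled = 11L, glutamate = 22L, secretin = 15L,
    glycoprotein_hormone = 8L, melatonin = 3L, opsin = 10L, prostanoid = 9L,
    orphan = 52L)
}

#' Configuration for a synthetic screening cohort
#'
#' Defaults reproduce the shape of the study cohort the screen is built for:
#' 148 AML samples against 12 CD34+ reference samples, 772 receptors in 18
#' subfamilies, 30 planted upregulated and 19 planted downregulated genes at
#' |delta| = `effect_size` lRPKM with the planted up-set biased toward the
#' chemokine-, adhesion- and purine-like subfamilies (6/4/2 genes) and the
#' down-set toward adhesion, protease-activated and frizzled (5/2/2).
#'
#' @param n_genes Number of genes.
#' @param subfamily_sizes Named integer vector of subfamily sizes; must sum
#'   to `n_genes`.
#' @param n_aml,n_reference AML and CD34+ reference cohort sizes.
#' @param normal_populations Named integer vector of normal-population
#'   sample counts.
#' @param subgroup_prevalence Per-AML-sample prevalence of the mutually
#'   exclusive cytogenetic subgroups.
#' @param mutation_prevalence Prevalence of the (co-occurring) mutation
#'   subgroups among normal-karyotype AML samples.
#' @param karyotype_probs Karyotype class probabilities for AML samples
#'   without a cytogenetic subgroup (cytogenetic subgroups imply an
#'   abnormal karyotype, recorded as `other`).
#' @param baseline_location,baseline_scale Normal location/scale of the
#'   per-gene baseline mean on the lRPKM scale (truncated at 0).
#' @param planted_location,planted_scale Baseline distribution for planted
#'   genes (floored at 2 lRPKM so downward shifts remain observable above
#'   the zero floor).
#' @param noise_sd Per-sample Gaussian noise sd on the lRPKM scale (> 0).
#' @param n_up,n_down Numbers of planted up/down genes (ignored when
#'   `planted_up`/`planted_down` are given explicitly).
#' @param effect_size Absolute planted median shift in lRPKM.
#' @param family_bias_up,family_bias_down Named fractions of the planted set
#'   drawn from specific subfamilies.
#' @param planted_up,planted_down Optional data frames (`gene_id`, `delta`)
#'   overriding the sampled planted sets.
#' @param subgroup_effects Optional data frame (`subgroup`, `gene_id`,
#'   `delta`) of subgroup-restricted mean shifts.
#' @param seed Integer root seed; all randomness derives from it through
#'   fixed per-stage streams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 772L,
                       subfamily_sizes = default_subfamily_sizes(),
                       n_aml = 148L, n_reference = 12L,
                       normal_populations = c(granulocytes = 5L, b_cells = 5L,
                                              t_cells = 5L, monocytes = 5L,
                                              wbc = 5L),
                       subgroup_prevalence = c(t_8_21 = 0.08, inv16 = 0.08,
                                               MLL = 0.10),
                       mutation_prevalence = c(NPM1 = 0.45, FLT3_ITD = 0.40,
                                               DNMT3A = 0.30),
                       karyotype_probs = c(normal = 0.60,
                                           intermediate_abnormal = 0.20,
                                           complex = 0.15, other = 0.05),
                       baseline_location = 2, baseline_scale = 1.5,
                       planted_location = 4, planted_scale = 0.75,
                       noise_sd = 0.5,
                       n_up = 30L, n_down = 19L, effect_size = 2,
                       family_bias_up = c(chemokine = 6 / 30,
                                          adhesion = 4 / 30, purine = 2 / 30),
                       family_bias_down = c(adhesion = 5 / 19,
                                            protease_activated = 2 / 19,
                                            frizzled = 2 / 19),
                       planted_up = NULL, planted_down = NULL,
                       subgroup_effects = NULL,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), subfamily_sizes = subfamily_sizes,
    n_aml = as.integer(n_aml), n_reference = as.integer(n_reference),
    normal_populations = normal_populations,
    subgroup_prevalence = subgroup_prevalence,
    mutation_prevalence = mutation_prevalence,
    karyotype_probs = karyotype_probs,
    baseline_location = baseline_location, baseline_scale = baseline_scale,
    planted_location = planted_location, planted_scale = planted_scale,
    noise_sd = noise_sd,
    n_up = as.integer(n_up), n_down = as.integer(n_down),
    effect_size = effect_size,
    family_bias_up = family_bias_up, family_bias_down = family_bias_down,
    planted_up = planted_up, planted_down = planted_down,
    subgroup_effects = subgroup_effects,
    seed = as.integer(seed)
  )
  if (sum(cfg$subfamily_sizes) != cfg$n_genes) {
    stop_validation("subfamily sizes sum to %d, not n_genes = %d",
                    sum(cfg$subfamily_sizes), cfg$n_genes)
  }
  prev <- c(cfg$subgroup_prevalence, cfg$mutation_prevalence)
  if (any(prev < 0 | prev > 1)) stop_validation("prevalences must lie in [0, 1]")
  if (sum(cfg$subgroup_prevalence) > 1) {
    stop_validation("cytogenetic subgroup prevalences must sum to <= 1")
  }
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stop_validation("noise_sd must be > 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Independent per-stage streams from one root seed, so stages can be
# regenerated without replaying earlier ones.
stage_seed <- function(root, stage) {
  as.integer((abs(as.numeric(root)) %% 1e8) * 16 + stage) %% 2147483647L
}

sim_gene_ids <- function(n) sprintf("GPCR%04d", seq_len(n))

#' Generate a synthetic screening cohort
#'
#' Draws per-gene baseline means from the configured truncated-normal
#' distribution, adds planted effects (additive on the lRPKM scale, the
#' scale of every screen threshold) to the affected samples, adds Gaussian
#' noise, truncates at 0, and emits RPKM as `2^lRPKM - 1`. Cytogenetic
#' subgroup flags are mutually exclusive; mutation flags may co-occur and
#' are restricted to normal-karyotype AML samples. Output is deterministic
#' under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `gpcr_cohort` with elements `expression` (RPKM
#'   matrix), `annotation`, `classification`, `truth` (planted gene sets,
#'   subgroup effect table, biased subfamily labels) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_ids(config$n_genes)
  classification <- stats::setNames(
    rep(names(config$subfamily_sizes), config$subfamily_sizes), genes
  )

  # stage 1: planted gene sets (biased family members first, remainder uniform)
  set.seed(stage_seed(config$seed, 1L))
  pick_planted <- function(n, bias, exclude) {
    pool <- setdiff(genes, exclude)
    picked <- character(0)
    for (fam in names(bias)) {
      k <- round(bias[[fam]] * n)
      fam_pool <- setdiff(pool[classification[pool] == fam], picked)
      picked <- c(picked,
                  fam_pool[sample.int(length(fam_pool), min(k, length(fam_pool)))])
    }
    # remainder drawn outside the biased subfamilies so the planted
    # concentration is exactly the configured one
    rest <- setdiff(pool[!(classification[pool] %in% names(bias))], picked)
    c(picked, rest[sample.int(length(rest), n - length(picked))])
  }
  if (is.null(config$planted_up)) {
    up_genes <- if (config$n_up > 0) {
      pick_planted(config$n_up, config$family_bias_up, character(0))
    } else character(0)
    planted_up <- data.frame(gene_id = up_genes,
                             delta = rep(config$effect_size, length(up_genes)),
                             stringsAsFactors = FALSE)
  } else {
    planted_up <- config$planted_up
  }
  if (is.null(config$planted_down)) {
    down_genes <- if (config$n_down > 0) {
      pick_planted(config$n_down, config$family_bias_down, planted_up$gene_id)
    } else character(0)
    planted_down <- data.frame(gene_id = down_genes,
                               delta = rep(-config$effect_size, length(down_genes)),
                               stringsAsFactors = FALSE)
  } else {
    planted_down <- config$planted_down
  }
  sg_eff <- config$subgroup_effects %||%
    data.frame(subgroup = character(0), gene_id = character(0),
               delta = numeric(0), stringsAsFactors = FALSE)
  planted_ids <- c(planted_up$gene_id, planted_down$gene_id, sg_eff$gene_id)
  unknown <- setdiff(planted_ids, genes)
  if (length(unknown)) {
    stop_validation("planted gene id(s) outside the simulated gene set: %s",
                    paste(unknown, collapse = ", "))
  }

  # stage 2: per-gene baseline means (lRPKM)
  set.seed(stage_seed(config$seed, 2L))
  mu <- pmax(stats::rnorm(config$n_genes, config$baseline_location,
                          config$baseline_scale), 0)
  names(mu) <- genes
  planted_ids <- unique(planted_ids)
  mu[planted_ids] <- pmax(stats::rnorm(length(planted_ids),
                                       config$planted_location,
                                       config$planted_scale), 2)

  # stage 3: sample annotation
  set.seed(stage_seed(config$seed, 3L))
  aml_ids <- sprintf("AML_%03d", seq_len(config$n_aml))
  cyto_levels <- names(config$subgroup_prevalence)
  cyto <- sample(c(cyto_levels, "none"), config$n_aml, replace = TRUE,
                 prob = c(config$subgroup_prevalence,
                          1 - sum(config$subgroup_prevalence)))
  karyo <- ifelse(cyto != "none", "other",
                  sample(names(config$karyotype_probs), config$n_aml,
                         replace = TRUE, prob = config$karyotype_probs))
  flags <- lapply(seq_len(config$n_aml), function(i) {
    f <- if (cyto[i] != "none") cyto[i] else character(0)
    if (karyo[i] == "normal") {
      for (m in names(config$mutation_prevalence)) {
        if (stats::runif(1) < config$mutation_prevalence[[m]]) f <- c(f, m)
      }
    }
    f
  })
  ann <- data.frame(
    sample_id = aml_ids, cohort = "AML",
    subgroups = vapply(flags, paste, character(1L), collapse = ";"),
    karyotype = karyo, stringsAsFactors = FALSE
  )
  ref_ids <- sprintf("CD34_%02d", seq_len(config$n_reference))
  ann <- rbind(ann, data.frame(
    sample_id = ref_ids, cohort = "CD34_reference", subgroups = "",
    karyotype = "unknown", stringsAsFactors = FALSE
  ))
  pop_ids <- list()
  for (p in names(config$normal_populations)) {
    ids <- sprintf("%s_%02d", p, seq_len(config$normal_populations[[p]]))
    pop_ids[[p]] <- ids
    ann <- rbind(ann, data.frame(
      sample_id = ids, cohort = paste0("normal_population:", p),
      subgroups = "", karyotype = "unknown", stringsAsFactors = FALSE
    ))
  }
  ann <- validate_sample_annotation(ann)

  # stage 4: expression values
  set.seed(stage_seed(config$seed, 4L))
  all_ids <- ann$sample_id
  lmat <- matrix(mu, nrow = config$n_genes, ncol = length(all_ids),
                 dimnames = list(genes, all_ids))
  if (nrow(planted_up)) lmat[planted_up$gene_id, aml_ids] <-
    lmat[planted_up$gene_id, aml_ids] + planted_up$delta
  if (nrow(planted_down)) lmat[planted_down$gene_id, aml_ids] <-
    lmat[planted_down$gene_id, aml_ids] + planted_down$delta
  if (nrow(sg_eff)) {
    for (i in seq_len(nrow(sg_eff))) {
      target <- intersect(samples_with_flag(ann, sg_eff$subgroup[i]), aml_ids)
      lmat[sg_eff$gene_id[i], target] <- lmat[sg_eff$gene_id[i], target] +
        sg_eff$delta[i]
    }
  }
  lmat <- pmax(lmat + stats::rnorm(length(lmat), 0, config$noise_sd), 0)
  rpkm <- rpkm_from_lrpkm(lmat)

  structure(list(
    expression = rpkm,
    annotation = ann,
    classification = classification,
    truth = list(
      planted_up = planted_up, planted_down = planted_down,
      subgroup_effects = sg_eff,
      biased_subfamilies = union(names(config$family_bias_up),
                                 names(config$family_bias_down))
    ),
    config = config
  ), class = "gpcr_cohort")
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits `expression.tsv` (genes-as-rows RPKM), `annotation.tsv`,
#' `classification.tsv` and `ground_truth.tsv`.
#'
#' @param cohort A `gpcr_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gpcr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_sample_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  utils::write.table(
    data.frame(receptor_id = names(cohort$classification),
               subfamily = unname(cohort$classification)),
    file.path(dir, "classification.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  tr <- cohort$truth
  gt <- rbind(
    data.frame(kind = "up", subgroup = NA_character_,
               gene_id = tr$planted_up$gene_id, delta = tr$planted_up$delta,
               stringsAsFactors = FALSE),
    data.frame(kind = "down", subgroup = NA_character_,
               gene_id = tr$planted_down$gene_id, delta = tr$planted_down$delta,
               stringsAsFactors = FALSE),
    if (nrow(tr$subgroup_effects)) {
      data.frame(kind = "subgroup", subgroup = tr$subgroup_effects$subgroup,
                 gene_id = tr$subgroup_effects$gene_id,
                 delta = tr$subgroup_effects$delta, stringsAsFactors = FALSE)
    }
  )
  write_result_table(gt, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
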