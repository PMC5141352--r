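---
title: "Methods: receptor expression screening in AML cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor expression screening in AML cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrscreen)
```

## The screening model

The package screens a receptor repertoire (typically the ~772 human GPCRs in
an 18-subfamily IUPHAR/GRAFS-style partition) across a bulk RNA-seq AML
cohort against a small normal CD34+ reference. Everything operates on the
lRPKM scale, `log2(RPKM + 1)`: the offset keeps zero at zero, bounds the
influence of near-zero rates, and makes additive differences interpretable
as fold changes of shifted abundances. The transform is strictly monotone
and exactly invertible (`2^l - 1`), which the tests exercise on fuzzed
matrices.

The screen is deliberately a *threshold* analysis rather than a count-model
fit. Its stages, each an exported function and each re-run by the pipeline
entry `gpcr_screen()`:

1. **Tiers and ranking.** Per-gene AML medians (even-sized groups: mean of
   the two central order statistics) are cut into four tiers at 1, 3.5 and
   6.7 lRPKM and ranked highest first, ties broken lexicographically by gene
   id in the C locale so orderings are machine-independent.
2. **Variability.** CV = sd/mean on lRPKM, with the sample (n − 1) standard
   deviation — material for a reference group of 12 — and a 0.5 cutoff for
   the "stably expressed" class.
3. **Differential calls.** `status` is `up` when
   median(case) − median(reference) > 1 lRPKM, `down` below −1, else
   `unchanged`; the three sets partition the genes and the call set is
   monotone in the threshold (tested).
4. **Subfamily enrichment.** For each subfamily, a 2×2 table of the
   directional set against the background of all classified receptors minus
   *both* directional sets, tested with a two-tailed Fisher's exact test.
5. **Subgroup fingerprints.** Mean difference between AML samples with and
   without a genetic flag; a record requires |Δmean| ≥ 1.5 lRPKM *and*
   Student's t p < 0.05 — either gate alone is insufficient, so a tiny but
   ultra-significant shift is not a fingerprint. Cross-cohort validation
   intersects (subgroup, gene, direction) triples between two cohorts'
   records and is symmetric in which cohort is primary.
6. **Nomination.** An upregulated fingerprint gene is nominated only when
   its subgroup mean strictly exceeds the mean of every normal population
   tested at p < 0.05; the strictness reflects the goal of receptors
   overexpressed on leukemic cells relative to all normal compartments.

## Tunable parameters

All thresholds live in `screen_control()` with the study defaults; units
are lRPKM unless noted.

| parameter | default | role |
|---|---|---|
| `tier_cuts` | 1, 3.5, 6.7 | expressed / high / very-high tier boundaries |
| `cv_threshold` | 0.5 (ratio) | low-variability class |
| `delta_median` | 1 | up/down call cutoff vs the reference |
| `delta_mean` | 1.5 | fingerprint effect-size gate |
| `alpha` | 0.05 | two-sided significance for every t test |
| `var_equal` | TRUE | pooled-variance Student's t; Welch behind the switch |

`run_screen()` records the effective values, group sizes and input MD5
checksums in `run_metadata.txt`, so results are self-describing, and its
outputs are byte-identical across runs on identical inputs.

## Numerical and boundary conventions

* **Tier boundaries** are inclusive at the lower edge: "at least 1 lRPKM" is
  explicit in the screen's definition of *expressed*, and the same reading
  is applied at 3.5 and 6.7 for consistency, so a median of exactly 3.5 is
  *high*. The choice is configurable only through the cut points themselves.
* **3.5 lRPKM in RPKM units** is 2^3.5 − 1 ≈ 10.31. Descriptions of this
  type of screen sometimes quote 10.35, which corresponds to 2^3.5 without
  the −1; the package implements the formula and notes the 0.04 discrepancy
  here rather than matching the rounded figure.
* **Fisher two-tailed rule.** The p-value sums the hypergeometric
  probabilities of all same-margin tables whose point probability does not
  exceed the observed one, with a relative tolerance of 1e-7 on the
  comparison to absorb floating-point ties — the dominant convention among
  exact-test implementations (including `stats::fisher.test`, which the
  tests use as an independent cross-check alongside an explicit
  factorial-product enumeration oracle). Terms are accumulated as
  log-factorials (`lchoose`) so margins in the hundreds stay finite. The
  all-zero table returns p = 1 by convention.
* **Degenerate inputs** are flagged, never silently numeric: zero pooled
  variance gives a t record with `degenerate = TRUE` and `NA` p-value
  (blocking fingerprint membership and nomination), and a zero mean leaves
  the CV and its low-variability flag `NA`.
* **Missing subgroup annotation** (`NA` in the subgroups field) excludes a
  sample from the "without" group of a fingerprint comparison instead of
  counting it as a negative; an empty field is a genuine empty flag set.

## Design choices at genuinely open points

* **Enrichment universe.** Whether to test against all classified receptors
  or only the expressed subset is not dictated by the screen's definition;
  the default is the full classified universe (it is the natural
  "representation in the repertoire" baseline and keeps the background
  definition independent of the tier thresholds), and `universe` is an
  argument. Genes present in a matrix but absent from the classification
  are dropped from the universe and reported (`dropped_from_enrichment`);
  identifiers are matched exactly, with no fuzzy aliasing.
* **CV scale.** The CV is computed on lRPKM, the scale of every other
  statistic in the screen, keeping one consistent scale; the function
  accepts any matrix, so a raw-scale CV is one transform away. The CV's
  scale-invariance under multiplication is tested.
* **Student vs Welch.** The fingerprint test is the classical
  pooled-variance Student's t — the named test of this screen family — but
  group sizes are often very unequal (e.g. 15 vs 100), where Welch is more
  robust; `var_equal = FALSE` switches every t test in the screen.
* **Fingerprint direction.** The 1.5 lRPKM gate is applied to |Δmean|, not
  only to positive shifts, because downregulated fingerprint members are
  meaningful (and only upregulated ones proceed to nomination).
* **Mutation-subgroup scope.** NPM1, FLT3-ITD and DNMT3A fingerprints are
  computed within normal-karyotype AML samples only — these mutations are
  characteristically analysed in that stratum, and restricting the "without"
  group avoids confounding by cytogenetic subtype — while cytogenetic
  subgroups use the whole cohort. `scope` overrides per call and the
  manifest records it.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort(sim_config())` draws per-gene baseline means on the lRPKM
scale from Normal(2, 1.5) truncated at 0 (a log-normal-like RPKM
distribution with a mass of near-silent genes; clearly a stand-in, since no
distributional form is claimed for real repertoires), adds planted effects
additively on the lRPKM scale — the scale of every screen threshold, so a
planted Δ maps directly onto a cutoff — then per-sample Gaussian noise
(sd 0.5 by default) and truncates at 0 (simple, and bias is negligible at
the default baselines). Planted genes' baselines come from Normal(4, 0.75)
floored at 2 so that downward shifts remain observable above the zero
floor. The default configuration is the study shape: 148 AML vs 12 CD34+
samples, five 5-sample normal populations, 772 genes in 18 subfamilies, 30
planted up and 19 planted down genes at |Δ| = 2 with the up-set concentrated
6/4/2 into the chemokine/adhesion/purine-like subfamilies and the down-set
5/2/2 into adhesion/protease-activated/frizzled; the remainder of each
planted set is drawn outside the biased subfamilies so the planted
concentration is exactly the configured one. Cytogenetic flags (t(8;21) 8%,
inv(16) 8%, MLL 10%) are mutually exclusive and imply an abnormal
karyotype; mutation flags (NPM1 45%, FLT3-ITD 40%, DNMT3A 30% of
normal-karyotype samples) may co-occur, mirroring real co-mutation. A
single root seed drives all randomness through fixed per-stage streams
(planted sets, baselines, annotation, noise), so any stage can be
regenerated without replaying the others and generation is bit-reproducible.

The generator does **not** emulate count-level sampling noise
(negative-binomial dispersion), gene–gene correlation, batch effects,
library-size artifacts or subtype-specific global shifts. Passing tests
therefore demonstrate that the screen's logic recovers effects of the
planted kind at the planted sizes under independent Gaussian lRPKM noise —
not that those effect sizes are detectable in any real cohort.

## Problem sizes used by the tests

The acceptance-style checks run the full study shape: an exhaustive sweep
of all 135,751 2×2 tables with N ≤ 40 against the enumeration oracle;
1e5 fuzzed values for the transform round trip (tolerance 1e-9 relative);
20 seeded replicates of the 772-gene, 148-vs-12 cohort for differential
recovery (planted |Δ| = 2, noise sd 0.5) and chemokine-enrichment
detection; and 20 replicates of a 115-sample cohort with a ~15-vs-100
subgroup split for the fingerprint null and recovery checks. Unit tests use
smaller cohorts (40–120 genes) built in code.

## Known limitations

* No multiple-testing correction is applied to the headline outputs — by
  design, matching the screen's definition; BH q-values are emitted
  alongside as labelled extensions and should be preferred for any
  repertoire-wide inference.
* Median-difference calling has no per-gene significance assessment; with a
  12-sample reference the median's sampling error (~0.2 lRPKM at noise
  sd 0.5) is well inside the ±1 threshold, but for noisier data a
  count-model method is the right tool.
* The screen intersects cohorts on exact identifiers; receptors renamed
  between annotations (e.g. CXCR7 vs ACKR3) must be reconciled upstream.
* Fingerprints for subgroups with fewer than two flagged (or two unflagged)
  samples in scope are refused rather than computed at n = 1.
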