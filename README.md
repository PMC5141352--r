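# gpcrscreen

Threshold-based expression screening of the G protein-coupled receptor
(GPCR) repertoire in bulk RNA-seq cohorts of acute myeloid leukemia (AML).

GPCRs are the largest family of cell-surface receptors (~800 human members)
and account for roughly a third of marketed drug targets, which makes
receptors overexpressed on leukemic cells attractive therapeutic leads. This
package implements, as tested and reusable R functions, a complete screen of
a receptor repertoire across an AML cohort against a small normal CD34+
hematopoietic stem/progenitor reference:

* **Working scale.** RPKM values are transformed to lRPKM = log2(RPKM + 1);
  the +1 offset damps the relative variation of near-zero rates and keeps
  zero at zero.
* **Expression tiers.** Per-gene AML medians are cut at 1 / 3.5 / 6.7 lRPKM
  into *expressed*, *highly expressed* and *very highly expressed* tiers
  (lower edges inclusive), and genes are ranked by median expression.
* **Variability.** The coefficient of variation CV = sd/mean (sample sd,
  n − 1) classifies genes with CV < 0.5 as stably expressed; a zero mean
  leaves the CV undefined rather than numeric.
* **Differential calls.** A gene is *up* (resp. *down*) when
  median(AML) − median(CD34+) on the lRPKM scale exceeds +1 (falls below −1).
* **Subfamily enrichment.** Each directional set is tested per receptor
  subfamily with a two-tailed Fisher's exact test (point-probability rule,
  log-factorial accumulation) against the background of all classified
  receptors excluding every differential gene; 2×2 table
  (a, b; c, d) = (direction ∩ F, direction ∖ F; background ∩ F,
  background ∖ F).
* **Subgroup fingerprints.** For each genetic subgroup (t(8;21), inv(16),
  MLL translocations; NPM1, FLT3-ITD, DNMT3A mutations within
  normal-karyotype AML) a gene is a fingerprint member when
  |mean(with) − mean(without)| ≥ 1.5 lRPKM with Student's t p < 0.05,
  validated across a second cohort by matching (subgroup, gene, direction).
* **Target nomination.** An upregulated fingerprint gene is nominated when
  the subgroup's mean expression strictly exceeds that of *every* normal
  blood/bone-marrow population tested at p < 0.05.

A seeded synthetic-cohort generator (`simulate_cohort()`) reproduces the
statistical shape these analyses assume — 148 AML vs 12 CD34+ samples, 772
receptors in 18 subfamilies, planted up/down median shifts with
subfamily-concentrated effects and subgroup-restricted mean shifts — so the
whole screen is testable end to end with planted ground truth and no
external data.

## Worked example

```r
library(gpcrscreen)

cohort <- simulate_cohort(sim_config(seed = 7))   # default study-shaped cohort
fit <- gpcr_screen(cohort)                        # full screen, one call
summary(fit)
```

```
Receptor expression screen: 772 genes, 148 AML vs 12 reference samples
Expression tiers (AML median lRPKM):

not_expressed     expressed          high     very_high 
          200           414           154             4 
Low-variability genes (CV < 0.5): 577
Differential calls vs CD34+ reference:

       up      down unchanged 
       30        19       723 
Enriched subfamilies (Fisher two-tailed p < 0.05 ):
 direction          subfamily a  b   c   d  p_value    bh_q
        up          chemokine 6 24  17 706 0.000150 0.00270
      down           adhesion 5 14  24 699 0.000508 0.00914
      down protease_activated 2 17   2 721 0.003619 0.03257
        up          olfactory 7 23 358 365 0.004954 0.04459
        up           adhesion 4 26  24 699 0.021508 0.12905
      down           frizzled 2 17   9 714 0.029790 0.17874
        up          glutamate 3 27  18 705 0.046726 0.20597
Fingerprint records: 0
No nominated subgroup-specific targets
```

The screen recovers exactly the 30 up and 19 down genes the generator
planted (at |Δ| = 2 lRPKM, noise sd 0.5), and the chemokine subfamily — into
which 6 of the 30 planted up genes were concentrated — is the top enrichment
(6 of 30 up genes vs 17 of 723 background genes, p = 1.5e-4). The enrichment
is two-tailed, so strongly under-represented subfamilies (here the large
olfactory block, which contributes almost no planted signal) can also reach
significance; `bh_q` is a Benjamini–Hochberg adjusted value emitted as a
labelled extension — the headline screen applies no multiple-testing
correction. No subgroup effects were planted, so the fingerprint and
nomination tables are empty; plant some with
`sim_config(subgroup_effects = data.frame(subgroup = "t_8_21",
gene_id = "GPCR0010", delta = 2))` to see them fill in.

`run_screen()` performs the same analysis from three TSV inputs (expression
matrix, sample annotation, subfamily classification) and writes every result
table plus a `run_metadata.txt` manifest recording the effective thresholds
and input checksums; `write_cohort()` emits a simulated cohort in exactly
that input format. Thresholds live in one place, `screen_control()`.

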