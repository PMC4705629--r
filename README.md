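# copdexome

Burden scoring, feature selection and screen statistics for
extreme-phenotype exome studies of chronic obstructive pulmonary disease
(COPD).

Only 15–20% of smokers develop COPD. An extreme-phenotype design contrasts
exomes of severely affected young smokers (susceptible, n = 62 in the
emulated design) with exceptionally resistant elderly heavy smokers
(n = 30) to enrich rare, large-effect variation, then validates candidate
genes in vitro by siRNA knockdown of bronchial epithelial cells exposed to
cigarette smoke extract (CSE). `copdexome` implements the computational
chain of that design for analysts who have variant calls, annotations,
expression matrices and screen plate data in hand:

* **Variant filtering** — sites kept at VQSLOD ≥ 2 with DP ≥ 6 in ≥ 80% of
  samples; genotypes with DP < 6 or GQ < 30 masked to no-call
  (`filter_sites()`, `apply_genotype_nocalls()`, VCF 4.2 I/O).
* **Gene functional deficit score** — per gene and individual, the sum of
  class-weighted variant scores: indel/stop = 1, non-neutral nonsynonymous
  = |predictor score|/100, neutral = 0.055, synonymous = 0.05, heterozygous
  × 0.25 (`gene_scores()`), contrasted between cohorts with Welch t-tests
  under an ≥ 10-affected-per-cohort restriction (`cohort_ttest()`).
* **FCBF feature selection** — symmetrical uncertainty
  SU(X,Y) = 2·I(X;Y)/(H(X)+H(Y)) on MDL-discretized scores, redundancy
  pruning, and leave-one-out merit aggregation (`fcbf()`, `loo_fcbf()`).
* **Candidate panel** — FPKM abundance (mean ≥ 1.0) and tenfold-variability
  (IQR of log10 ≤ 1.0, ≥ 2-zero exclusion) rules, prioritizer rank-list
  intersection (both 5% lists, rank < 300), and provenance-tracking panel
  merge (`abundance_filter()`, `variability_stats()`,
  `ranklist_intersect()`, `merge_panel()`).
* **Screen statistics** — the gene–environment interaction ratio
  (D̄/C̄)/(B̄/Ā) over the four screen conditions, robust one-sample Z-scores
  with pseudo-SD = IQR/1.35, one-sided normal p-values, and two-tailed
  Benjamini–Hochberg calls at BH(j) = αj/n (`screen_pipeline()`).
* **Synthetic data** — generators for every input with planted ground
  truth (`generate_cohort()`, `generate_fpkm()`, `generate_screen()`), so
  the whole pipeline is testable without protected exome data.

## Worked example

Simulate a cohort with five deleterious-enriched genes, run the variant
and burden stages, and look at the strongest contrasts:

```r
library(copdexome)

co <- generate_cohort(cohort_spec(n_genes = 200, n_planted_genes = 5,
                                  planted_effect = 8, seed = 1))
vt    <- apply_genotype_nocalls(filter_sites(co$variants))
calls <- join_annotations(vt, co$annotations)
sc    <- gene_scores(calls, genes = sprintf("gene%04d", 1:200),
                     samples = names(co$phenotype))
ct    <- cohort_ttest(sc, co$phenotype, min_affected_per_cohort = 2)
head(ct[order(ct$p_value), c("gene_id", "t_statistic", "p_value")], 5)
#>    gene_id t_statistic      p_value
#> 1 gene0001    7.066879 1.216732e-09
#> 2 gene0002    5.795307 9.946042e-08
#> 5 gene0005    5.623466 2.692212e-07
#> 4 gene0004    5.063117 2.506080e-06
#> 3 gene0003    3.892923 1.936266e-04
```

The five planted genes (gene0001–gene0005) head the ranking. The screen
stage works the same way: simulate plates with two planted augmenting
genes, one protecting gene and three alone-effect genes, then run the full
statistic:

```r
planted <- setNames(rep(1, 81), sprintf("g%02d", 1:81))
planted[c("g01", "g02", "g03")] <- c(0.196, 0.614, 1.334)
alone <- setNames(rep(1, 81), names(planted))
alone[c("g04", "g05", "g06")] <- c(0.49, 0.49, 0.53)
scr <- generate_screen(screen_spec(planted_interactions = planted,
                                   planted_alone = alone, seed = 1))
res <- screen_pipeline(scr$plate)
res
#> screen_result: 81 genes analysed (alpha = 0.05, per_gene scope, pointwise rule)
#>   interaction tails: 41 augmenting, 40 protecting
#>   significant: 8 augmenting, 6 protecting, 7 alone-effect
```

All six planted effects are recovered at the most extreme ratios
(`summary(res)` lists them: g01 at ratio 0.196 with z −257.0, g02 at
0.627, g03 protecting at 1.404, and g04–g06 in the alone analysis near
ratio 0.5); the extra calls among the 75 null genes — ratios all within a
few percent of 1 — reflect the heavy-tailed triplicate Z statistic, whose
false-positive behaviour is characterised by the null-calibration
simulation in the test suite (see the vignette).

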