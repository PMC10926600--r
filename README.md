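# airrstat

Statistics for multi-chain adaptive immune receptor repertoires
(AIRR-seq). Starting from chain-resolved clonotype tables — one row per
(sample, chain, CDR3 amino-acid sequence, V/J call, isotype) with
UMI-deduplicated counts — `airrstat` builds repertoire features and
tests them for association with phenotypes using models that tolerate
the extreme zero inflation of clone abundance data.

The package is aimed at immunogenomics analysts working with
case–control or paired (pre/post treatment) repertoire cohorts across
the seven receptor chains (TRA, TRB, TRD, TRG, IGH, IGK, IGL).

## What it computes

* **Features** — clone, V/J-segment, meta-clone (communities of clones
  differing by at most one amino acid in the CDR3 similarity network)
  and 4-mer count matrices; per-sample diversity (D20, D50,
  Gini–Simpson, Inverse-Simpson, Shannon), chain and segment usage with
  PCA, clone-length distribution comparisons, publicity rarefaction,
  and IGH isotype measures (usage, class switching, somatic
  hypermutation, percent mutated IgD/M).
* **Association** — the core test is a two-part *hurdle* model per
  feature on log-CPM values: a logistic detection part and a Gaussian
  abundance part over detected samples, both adjusted for the Clone
  Detection Rate (CDR; the standardized per-sample fraction of features
  detected), age and sex, combined as a chi-square sum:

      log2cpm = log2(1e6 * count / library + 1)
      discrete:    detect ~ phenotype + CDR + age + sex     (score chi2)
      continuous:  log2cpm | detect ~ phenotype + CDR + age + sex  (F -> chi2)
      hurdle chi2  = chi2_disc + chi2_cont,  df = df_disc + df_cont

  plus Benjamini–Hochberg FDR, baseline logistic/negative-binomial
  models, longitudinal mixed models with subject random intercepts, and
  contraction/expansion dynamics summaries (Fisher and Wilcoxon tests).
* **Clone-set characterization** — degree-centrality permutation tests
  against resampled random repertoires, physicochemical property
  vectors (charge, pI, GRAVY, aliphatic and Boman indices, molecular
  weight, residue-class fractions), the Biochemical Enrichment Score
  `BES = -log10(p_enrich) + log10(p_deplete)`, and length-adjusted
  logistic contrasts between clone sets.
* **Classification** — leave-one-out cross-validated random forests
  with per-tree class down-sampling, performance metrics, importance
  tables, and a feature-block aggregation search.
* **Synthetic cohorts** — a seeded generator with power-law clonality,
  low clone publicity, chain-specific richness/depth, isotype and SHM
  models, and planted differential clones / k-mer motifs / longitudinal
  fold changes, with ground-truth labels for recovery studies.

## Worked example

```r
library(airrstat)

# a small synthetic case-control cohort with 10 planted clones
cfg <- cohort_config(
  n_cases = 40, n_controls = 40,
  chains = list(TRB = list(richness = 300, depth = 6000,
                           len_mean = 14.5, len_sd = 1.5,
                           n_v = 45, n_j = 13)),
  spike = list(chain = "TRB", n_clones = 10,
               detection_p0 = 0.3, detection_odds = 4, log2fc = 1.5),
  seed = 7)
sim <- generate_cohort(cfg)

fm <- build_feature_matrix(sim$records, "clone", chain = "TRB",
                           samples = sort(sim$metadata$sample_id))
lg <- cpm_log_transform(filter_low_detection(fm))
res <- hurdle_test(lg, setNames(sim$metadata$group, sim$metadata$sample_id),
                   sim$metadata)

sum(res$q < 0.05, na.rm = TRUE)
#> [1] 10
planted <- sim$truth$differential_clones$cdr3_aa
head(res[order(res$p_hurdle), c("feature", "p_disc", "p_cont", "p_hurdle", "q")], 3)
#>               feature    p_disc    p_cont  p_hurdle         q
#> 7213   CTLWVTWYHQHSSF 3.578e-03 1.365e-09 1.528e-10 1.001e-06
#> 7706   CVQHARPEYGMRHF 1.468e-02 7.042e-10 2.841e-10 1.001e-06
#> 7368 CTVFLYYGPKPYHSGF 2.046e-06 4.528e-06 3.444e-10 1.001e-06
mean(planted %in% res$feature[res$q < 0.05])   # recovery of planted clones
#> [1] 1
```

All ten planted clones are recovered at FDR < 0.05, with zero false
positives among the 8,710 null clones tested alongside them; each hit
combines a detection-rate shift (`p_disc`) with an abundance shift
(`p_cont`).

The end-to-end pipelines are driven by a config list or YAML file:

```r
run_case_control(list(simulate = list(n_cases = 20, n_controls = 20),
                      seed = 1), out_dir = "out_cc")
```

which writes diversity/usage tables, per-chain hurdle results for
clones, meta-clones and k-mers, isotype profiles and a manifest; reruns
with the same config and seed are byte-identical. A thin CLI wrapper
lives at `inst/cli/airrstat.R`
(`Rscript airrstat.R case-control --config run.yaml --seed 1 --out DIR`).

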