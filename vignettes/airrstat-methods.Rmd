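---
title: "Statistical methods behind airrstat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind airrstat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airrstat)
```

# Scope and data model

`airrstat` analyzes chain-resolved adaptive immune receptor repertoires
(AIRR): for each sample, the set of clones — unique CDR3 amino-acid
sequences — observed on each of the seven receptor chains (TRA, TRB, TRD,
TRG, IGH, IGK, IGL), with UMI-deduplicated molecule counts as abundances.
The package starts from rearrangement-level TSV tables (AIRR Community
column naming, or any mapping via `schema_map`); everything upstream —
read processing, UMI collapsing, V(D)J alignment, frame/stop filtering —
is assumed done and is out of scope. Clones are keyed by
`(chain, cdr3_aa)`; V/J calls and isotype are annotations. Chains are
always analyzed separately: no feature ever pools sequence information
across chains.

# Repertoire features

**Diversity.** Five complementary indices per (sample, chain): D20 and
D50 (number of dominant clones reaching 20% / 50% of cumulative
frequency; ties broken by descending frequency then lexicographic CDR3,
so results are reproducible), Gini–Simpson `1 − Σp²` (optionally
log-transformed; the transform is undefined for a single-clone repertoire
and returns `NA` with a warning), Inverse-Simpson `1/Σp²`, and Shannon
entropy in natural-log units (nats; divide by `log(2)` for bits).

**Usage.** Chain usage is the proportion of a sample's UMIs per chain,
plus the IGK share of light-chain molecules `IGK/(IGK+IGL)`. Segment
usage (V, J, VJ) is the within-chain frequency of each segment; the PCA
of segment usage centers (by default does not scale) the usage
proportions and takes the first two singular vectors. Rarely used
segments are removed first. The "usage below 5%" filter is interpreted
as *detected in fewer than 5% of samples* — a literal mean-usage-below-5%
reading would discard nearly every segment of a multi-segment chain, so
the detection reading is the default and the literal one remains
available via `filter = "mean_usage"`.

**k-mers and meta-clones.** CDR3 sequences are decomposed into
overlapping 4-mers. k-mer counts are UMI-weighted with window
multiplicity by default (a clone `AAAAA` with 2 UMIs contributes 4 to
`AAAA`); a presence mode counts each distinct k-mer once per clone. The
similarity network connects clones differing by at most one amino acid;
the default metric is Levenshtein (includes single indels between
length-adjacent CDR3s) with a Hamming-only mode available, since either
convention is found in repertoire network tools. Meta-clones are
communities of this network found by directly optimizing modularity:
exact enumeration for connected components of up to 8 nodes (communities
cannot span components, so small components can be solved outright) and
fast-greedy agglomeration plus a deterministic local refinement
(single-node moves and community merges accepted only when modularity
increases) for larger components. Meta-clone expression is the per-sample
sum of member clone counts; totals are conserved exactly.

# Normalization, filtering and the CDR

Counts are normalized per sample as `log2(1e6 · count/library + 1)`
(log-CPM). Base 2 with a pseudocount of one keeps zeros at exactly zero,
which the hurdle model's detection part relies on. Features detected in
fewer than 1% of samples are removed; a feature at exactly 1% is kept.

The Clone Detection Rate (CDR) is the standardized (sample-sd, n−1
denominator) per-sample fraction of matrix features detected. It proxies
sampling depth, RNA input and other global influences on clone detection
and enters the hurdle model as a covariate on both parts.

# The hurdle association test

Clone, meta-clone and k-mer abundances are extremely zero-inflated:
most features are observed in a handful of samples. The hurdle model
treats each feature's log-CPM vector as two coupled observations — a
detection indicator and a positive abundance — and tests the phenotype
in both:

* **Discrete part** — logistic regression of detection on phenotype +
  CDR + age + sex. The part's chi-square is the Rao score statistic at
  the covariate-only null fit. This is a deliberate numerical choice:
  for features detected in only a few samples the likelihood-ratio
  statistic is markedly anti-conservative (direct simulation at 200
  samples and 2–6 detections gives a type-I rate near 0.10 at the 0.05
  level, versus 0.05 for the score statistic), and the score statistic
  needs no full-model MLE, making it immune to separation in the tested
  term. When the *null* fit itself degenerates (nuisance separation
  with a handful of events), it is refit by Firth penalization before
  the statistic is formed — this removes the rare exploding statistics
  that otherwise produce spurious extreme p-values. Effect sizes
  (log-odds) still come from the full ML fit, with a ridge-penalized
  (1e-4) fallback under separation, flagged in the output.
* **Continuous part** — Gaussian regression of log-CPM on the same
  covariates over detected samples only (a two-part, not censored,
  model, following the single-cell hurdle lineage). Its p-value is
  taken from the exact F reference — the raw `n·log(RSS0/RSS1)`
  statistic is anti-conservative at the small detected-sample counts
  typical here — and mapped back to the equivalent chi-square.
* **Combination** — the hurdle statistic is the sum of the two
  chi-squares with summed degrees of freedom, the convention of the
  two-part single-cell models this design follows.

Features detected in every sample have no discrete part (the combined
test reduces to the continuous part, flagged `all_detected`); features
with fewer than 3 detected samples in either group have no continuous
part. FDR control is Benjamini–Hochberg over non-missing p-values;
`NA` p-values propagate as `NA` q-values rather than inflating the
correction size. In the pipelines, FDR is applied within each
(feature level × chain) family, with the clone/meta-clone/k-mer tables
written separately per chain.

Baseline per-measure associations use the family matched to the
measure's distribution: logistic regression of the phenotype on a
continuous measure, or negative-binomial regression of a count measure
on the phenotype with a log-depth offset and ML-estimated dispersion.
Longitudinal designs use subject-level random intercepts: `lmer` fit by
maximum likelihood (REML off, Satterthwaite p-values) for Gaussian
measures, `glmer` (Laplace) for binary, `glmer.nb` for counts. Paired
structure is validated up front and unpaired subjects are reported by
name.

# Clone-set characterization

The degree-centrality permutation test asks whether a set of clones is
more sequence-similar than chance: the observed mean node degree of the
set's internal similarity network is compared against sets of identical
size resampled uniformly (without replacement, each clone equally
likely) from the same chain's observed clones. Empirical p-values carry
the `+1` pseudocount and are therefore never zero and super-uniform
under the null.

The Biochemical Enrichment Score (BES) applies the same resampling idea
to physicochemical properties: per property,
`BES = −log10(p_enrich) + log10(p_deplete)`, positive for enrichment,
bounded by `±log10(n_resamples + 1)`. The property set covers net
charge at pH 7 (Henderson–Hasselbalch with the EMBOSS pKa constants),
isoelectric point (root of the charge function), GRAVY hydrophobicity
(Kyte–Doolittle), aliphatic index (Ikai), Boman protein-interaction
index, average molecular weight, residue-class fractions (acidic {D,E},
basic {K,R,H}, polar = uncharged polar {S,T,N,Q,Y,C} plus charged) and
length. The observed set statistic is the unweighted mean over clones —
each clone counts once, matching the clone-set framing of these
analyses. Direct contrasts between clone sets (e.g. expanded vs
contracted) are logistic regressions of set membership on a property
adjusted for CDR3 length; the weighted variant multiplies each clone's
likelihood contribution by the magnitude of its frequency change,
normalized to mean one so that equal weights reduce exactly to the
unweighted contrast. The magnitude of clonal change is defined as
`|log2((f_post + ε)/(f_pre + ε))|` with `ε = 1/(2·min depth)` — a
half-molecule pseudo-frequency at the shallowest sample.

# Isotype measures

IGH constant-region measures are clonotype-based (unique VDJ =
`(cdr3_aa, v_call, j_call)`), so UMI counts do not enter: per-isotype
usage percentages (summing to 100 over observed isotypes), the
class-switch index (clonotypes observed under both isotypes of a pair,
divided — by default — by the union of the two isotypes' clonotype
sets; a conditional denominator is available since the convention is
genuinely ambiguous), the SHM rate (mean V-region mutations per unique
clonotype, also available for IGK/IGL) and the percent of mutated
IgD/M clonotypes (threshold ≥1 mutation by default, configurable).
Mutation counts are inputs from the upstream pipeline; recomputing them
from germline alignments is out of scope.

# The repertoire classifier

The multi-chain classifier is a random forest evaluated by
leave-one-out cross-validation. Class imbalance is handled by per-tree
balanced down-sampling: each tree draws the minority-class count from
every class without replacement (class-wise sampling fractions), which
keeps the advertised down-sampling behavior while averaging over many
balanced draws instead of fixing one per fold. NA features are
median-imputed inside the training fold only. Metrics (accuracy,
sensitivity, specificity, precision, FPR) are recomputed from the
out-of-fold confusion matrix; ROC-AUC uses the trapezoid rule and
PR-AUC step interpolation over descending score thresholds. Variable
importance (permutation / mean-decrease-accuracy and Gini) comes from
full-data forests with seeds derived from the report seed. The
feature-block aggregation search evaluates block combinations (all
non-empty subsets by default) and ranks them by accuracy, or by
specificity when the minority class is the clinical target.

# The synthetic cohort generator

The generator produces the data regime the statistics assume, with
ground truth for recovery studies. Per chain, a clone pool of size
`n_samples × richness` (scalable via `pool_scale`) carries rank weights
`r^(−0.8)`; each sample draws its clones by weighted sampling without
replacement. This yields the hallmark publicity structure: the median
observed clone is private to one subject, with a small public tail.
Within a sample, clone frequencies follow a power law `rank^(−1.5)`
over a random permutation, and counts are multinomial at the sample's
depth — totals therefore match the depth exactly. Depth varies
lognormally (CV 0.3) around the chain's configured depth, driving
realistic CDR variation. CDR3 sequences use the canonical C…F scaffold
with normally distributed lengths per chain; defaults give each chain
its distinct richness, depth and length profile (e.g. short IGK loops,
long IGH loops, scarce TRD/TRG). Planted effects are generated *inside*
the multinomial draw, so depth conditioning is preserved: differential
clones get a control detection probability `p0` and a case detection
probability shifted by the configured odds ratio, plus an abundance
weight multiplied by `2^lfc` in cases; k-mer motifs are substituted
into designated clone sequences at a random interior position (never
the first two residues, reflecting conserved flanks). The TRD
case-length shift is implemented by exponential tilting of the case
sampling weights, moving the mean length by the configured amount
(default +1 aa in cases). IGH records receive an isotype mixture
(IgM .45, IgD .10, IgG .30, IgA .13, IgE .02), a 10% chance for a
clonotype with ≥2 UMIs to appear under a second isotype (count split),
and negative-binomial V-mutation counts with isotype-specific means
(unswitched low, switched high); light chains get intermediate means;
TCR chains have no SHM. Longitudinal cohorts resample week-12 counts
multinomially from baseline frequencies multiplied by `2^lfc` for
labeled clones; contraction is more frequent on BCR than TCR chains and
contracted clones carry stochastically larger |log2FC| than expanded
ones (means 3 vs 2, sd 0.8).

What the generator does **not** emulate: sequencing error and UMI
collisions, V(D)J recombination biology (CDR3s are random within a
length model, so germline-encoded motif sharing is absent), HLA-driven
convergence, batch effects beyond depth, and clone-level correlation
between chains of one cell. Passing recovery tests therefore shows the
statistics behave correctly in the assumed regime, not that any
specific biological effect is detectable in a given real cohort.

# Calibration evidence and problem sizes

The acceptance-level tests exercise the machinery at case-control
scale, with sizes chosen as a compromise between statistical resolution
and the cost of a routine test run: null calibration of the hurdle test
on 100+100-sample single-chain cohorts (richness 400, depth 8000;
about 8,000–9,000 clones pass the 1% filter, of which 1,000 are tested
per seed, across 50 seeds), planted-clone recovery with 50 spiked
clones (detection odds ratio 3, abundance log2FC 1.5) among 5,000
features over 20 seeds, permutation-test uniformity over 200
repetitions of 1,000 permutations, and classifier chance-level checks
on 500-sample null datasets over 20 seeds. `scripts/acceptance.R`
recomputes the same quantities end to end (at reduced seed counts) and
writes them as JSON.

# Known limitations

* The hurdle test's discrete part is conservative for features at the
  detection floor (2–3 detected samples out of 200): such features can
  essentially never reach significance, which is the honest behavior of
  any exact-minded test at those counts.
* Wald tests under the ridge separation fallback (biochemical
  contrasts) lose power when separation is complete; the flag column
  marks affected results.
* `glmer.nb` longitudinal fits can be slow and fragile on small
  repertoire measures; the Gaussian family on log-transformed indices
  is the recommended default.
* The exhaustive meta-clone search applies to components of ≤8 clones;
  larger components rely on greedy-plus-refinement, which carries no
  optimality guarantee (modularity maximization is NP-hard).
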