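---
title: "Detecting mislabelled samples in case-control cohorts with an annotation-guided sparse network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mislabelled samples in case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Case-control cohorts for psychiatric disorders carry a known rate of wrong
labels. For schizophrenia, registry-based diagnoses agree with structured
re-evaluation at roughly 75% under a strict definition and ~94% under a
broad schizophrenia-spectrum definition, so a registered case pool is
expected to contain a non-negligible fraction of samples whose genetics do
not match their label; symmetrically, population controls include
undiagnosed cases at roughly the disease prevalence. Supervised classifiers
trained on such cohorts learn a blurred genetic boundary, and their
attainable AUC is capped below what heritability would allow.

`cohortsieve` implements a two-stage remedy:

1. **Score.** Train an ensemble of annotation-guided sparse networks on the
   *entire* cohort and predict on the *same* samples (test-on-train, a
   deliberate non-standard choice). Because the model is pushed to separate
   the two labelled groups, samples whose genetic profile deviates from
   their labelled class persistently land on the wrong side of the 0.5
   threshold even though the model has seen them during training.
2. **Sieve and re-evaluate.** Exclude the top-scoring controls (candidate
   undiagnosed cases) and bottom-scoring cases (candidate misdiagnoses) in
   numbers dictated by *external clinical knowledge* — prevalence for the
   control pool, literature misdiagnosis rates for the case pool — then
   retrain on stratified splits of the filtered cohort and compare test
   AUCs with a pooled two-sample t-test.

The exclusion quotas are not estimated from the data: the whole point is
that the data cannot tell you how many labels are wrong, but the clinical
literature can.

## The network

The classifier is intentionally shallow and interpretable. With additive
genotype codes $x_v \in \{0, 1, 2\}$ (alternative-allele counts), a
topology table assigns every variant $v$ to exactly one gene $g(v)$. Each
gene node computes

$$h_g = \mathrm{act}\Big(\sum_{v:\,g(v)=g} w_v\, x_v + b_g\Big),$$

and the output is a logistic regression on the gene values,

$$P(\text{case}) = \sigma\Big(\sum_g u_g\, h_g + c\Big).$$

The default gene activation is linear, so the gene nodes are literally
parallel regressions of their variants and the output layer a logistic
regression on gene burdens; `tanh` is available by configuration for a
saturating variant of the same architecture. The parameter count is
`n_variants + 2 * n_genes + 1` — at the scale of a screened exome cohort
(18,970 variants on 9,160 genes) that is 37,291 trainable scalars, small
enough to train on a laptop CPU and sparse enough that gene-level weights
are directly interpretable. Gene importances are the ensemble means of the
output-layer weights $u_g$; because the sign of a hidden unit is not
identifiable across independently initialised runs, a `magnitude` option
ranks by mean absolute weight instead.

Training minimises mean binary cross-entropy with mini-batch Adam
(batch 64, learning rate $10^{-3}$ by default). The full-cohort scoring
stage trains for a hard cap of epochs with no validation split (there is
nothing to validate against — every sample is a training sample by
design); the evaluation stage uses validation-loss early stopping
(patience 20 by default) under the same cap. Initialisation is a
small-variance normal for weights and zeros for biases; no explicit
regularisation is applied by default, with an optional L1 penalty on the
variant weights. All randomness (initialisation, batch order, splits,
per-run seeds) derives deterministically from user-supplied seeds, so the
entire two-stage pipeline is bit-reproducible.

### Missing genotypes

QC guarantees a call rate of at least 90% per retained site, which bounds
the damage any imputation rule can do. The network fills missing codes
with 0 (the reference genotype) by default; per-variant mean imputation is
available via `missing_fill = "mean"`.

## Exclusion arithmetic

Quotas are `floor(rate × pool size)`:

* controls at prevalence 0.34%: `floor(0.0034 × 6245) = 21`;
* cases at the narrow-definition misdiagnosis rate 19%:
  `floor(0.19 × 4969) = 944`.

For the broad definition (6%), `floor` gives 298 while the round figure
300 is sometimes quoted; `exclusion_quota()` therefore accepts an explicit
`override` so either count is reachable, and the discrepancy is surfaced
rather than hidden. Selection is by mean ensemble score with ties broken
by sample id. In **narrow** mode a case is only *eligible* for exclusion
if it was misclassified (score `< 0.5`) in at least half of the ensemble
runs; the excluded set is then the eligible cases with the lowest mean
scores up to the quota, and if eligibility is the binding constraint the
function warns and excludes all eligible cases. Scores exactly at 0.5
count as case-side classifications.

## The cohort simulator

The reference cohort this methodology targets is controlled-access, so the
package ships a first-class simulator whose defaults define the study
conditions for every recovery experiment:

* **Genotypes.** Independent biallelic autosomal SNPs in Hardy–Weinberg
  proportions. MAFs are drawn log-uniformly on `[0.005, 0.5]`, giving the
  rare-variant-heavy spectrum typical of screened exome data (roughly half
  the sites below 1%).
* **Phenotype.** A liability-threshold model on *gene burdens*: per-gene
  standardised sums of genotype codes, a random subset of `n_causal_genes`
  genes with effects drawn from `Normal(0, effect_sd²)`, plus standard
  normal environmental noise. Samples above the upper-`prevalence`
  quantile of liability are cases. Gene-level (rather than variant-level)
  effects were chosen because the network aggregates per gene, which makes
  gene-importance recovery directly assertable. The generator's
  `prevalence` defaults to 0.5: it calibrates the *ascertained* cohort's
  liability threshold and yields balanced pools at tractable simulation
  sizes. Population prevalence belongs to the exclusion stage, not the
  generator.
* **Label noise.** A "flipped case" is a member of the *case pool* whose
  genetics are control — exactly the sample a misdiagnosis produces and
  the exclusion step should recover. It is created by relabelling a true
  control into the case pool (and symmetrically for flipped controls).
  Flip counts are `round(rate × pool size)` under round-half-even, which
  reproduces the published arithmetic (944 of 4,969 at 19%; 21 of 6,245
  at 0.34%). `simulate_cohort()` compensates the requested pool sizes so
  the final cohort lands exactly on the configured composition. The
  alternative reading — flipping true cases *out* of the case pool — was
  rejected because under it the excluded-case set could never contain a
  mislabelled sample, making recovery untestable.
* **Default scale.** 1,200 cases + 1,200 controls, 400 variants on 120
  genes, 30 causal genes with `effect_sd = 1` (genetic-oracle AUC above
  0.9). These sizes keep a full two-stage run with a 5-model ensemble in
  the tens of seconds on one CPU while leaving enough signal-to-noise for
  the recovery properties to be sharp.

What the simulator deliberately omits: linkage disequilibrium, population
structure, relatedness, sex chromosomes, and realistic InDel/multi-allelic
complexity beyond what the QC tests need. Passing recovery tests on these
cohorts therefore demonstrates that the *mechanism* works when mislabelled
samples are genetically distinct; it says nothing about cohorts where
labels fail for non-genetic reasons or where structure confounds the
classifier.

## Quality control and association screening

`qc_cohort()` re-implements the variant-level QC chain: per-site metric
recomputation from the genotypes actually present (mean depth over
non-missing depths, call rate, allele frequency among called alleles),
multi-allelic splitting in which any genotype carrying an allele foreign
to a child record is set missing, and threshold filtering. Boundary
semantics follow the exclusion wording: a site is *excluded* when QUAL
`<= 30`, mean depth `< 8`, or call rate `< 0.90` — so mean depth exactly 8
and call rate exactly 0.90 survive while QUAL exactly 30 does not.
Half-called genotypes count as missing; a called genotype with a missing
depth still counts as called (depth and genotype are independent tags).
External variant recalibration is out of scope; a whitelist hook accepts
its output instead. Metrics are recomputed after phenotype-based sample
removal, so call-rate denominators reflect the retained samples.

Association screening is a per-variant Pearson chi-squared test on the
2 × 3 class-by-genotype table (missing genotypes excluded; zero-total
genotype columns dropped with the degrees of freedom reduced accordingly).
Selection keeps `p < 0.05` with *no* multiple-testing correction — the
screen is a dimensionality-reduction device whose liberality is by design,
and the package mirrors that choice. InDels and sex-chromosome variants
are removed first; unrecognised chromosome names are conservatively kept
and reported.

## Over-representation analysis

`ora_test()` is a one-sided hypergeometric over-representation test with
the WebGestalt-style enrichment ratio `(k/n)/(K/N)` and Benjamini–Hochberg
FDR computed within each collection separately. The reference universe
size is a required input — "the whole genome" is not a number, and no
default is safe. When an explicit reference gene list is supplied, list
genes outside it are dropped with a warning and `n` shrinks accordingly.

## Validation strategy and problem sizes

The test suite validates every analytic primitive against an independent
oracle: the chi-squared statistic against the textbook Pearson formula on
1,000 random tables, AUC against exhaustive pairwise enumeration, BH
against the step-up definition, and the hypergeometric tail against
complete enumeration of draws for universes up to 12 genes. Architecture
properties (parameter count, analytic gradients against finite
differences, gradient locality) are checked on randomised topologies. The
label-noise recovery experiment runs at the simulator's default scale over
five master seeds with a 5-model ensemble capped at 50 epochs and 5
evaluation repeats capped at 30 epochs; null calibration uses 600 + 600
samples with `effect_sd = 0`. These sizes are the package's chosen
validation conditions: large enough for sharp property checks, small
enough to run routinely.

Known limitations: the published real-data AUC trajectory of the original
cohort is not reproducible without controlled access and is not a target
of this package; exclusion quotas inherit whatever error the clinical
rates carry; and test-on-train scoring deliberately overfits, so stage-1
scores must never be interpreted as calibrated probabilities — they are an
ordering device for the sieve.
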