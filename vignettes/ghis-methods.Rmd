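---
title: "Methods: genome-wide haploinsufficiency scoring"
author: "ghis package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide haploinsufficiency scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghis)
```

# The problem and the model

A gene is haploinsufficient (HIS) when one functional copy is not enough
for a normal phenotype. `ghis` estimates, for every gene, the probability
that it is HIS, using only features that are measured genome-wide and are
therefore not confounded by how intensively individual genes have been
studied. This vignette records the model, its assumptions, the defaults,
and the design decisions that were genuinely open.

## Variant depletion: NoVaDs and the reference RVIS

Variants are classified by pooled minor allele frequency (MAF, a
fraction in [0, 0.5] after folding) and functional annotation. The
defaults follow exome-server conventions:

* *rare*: MAF ≤ 0.001; *common*: MAF > 0.001. The boundary value itself
  is rare — the convention is "≤ cutoff is rare", so exactly 0.1% counts
  as rare.
* *non-synonymous* labels: `missense`, `missense-near-splice`,
  `splice-3`, `splice-5`, `stop-gained`, `stop-gained-near-splice`,
  `stop-lost`, `stop-lost-near-splice`; *synonymous*:
  `coding-synonymous`, `coding-synonymous-near-splice`. Everything else
  is counted only in the per-gene total.

NoVaDs is the per-gene ratio (common non-synonymous)/(rare
non-synonymous). Strong purifying selection keeps functional variants
rare, so intolerant genes have low NoVaDs. Because it is a ratio of
counts from the same gene, the expected value does not grow with coding
sequence (CDS) length. A gene with *no* rare non-synonymous variants has
an undefined ratio; we record it as missing rather than infinite (an
infinity would dominate any downstream standardization) and let feature
assembly impute the median.

The reference RVIS is the studentized residual of an OLS regression of
the common non-synonymous count on the total variant count. We use
*internally* studentized residuals (`stats::rstandard`): the original
description says only "studentized", internal studentization is the
common default, and at genome scale the distinction is numerically
immaterial. When the regression fits exactly (residual standard error
below `1e-10 * (1 + max |y|)`), all residuals are reported as 0 rather
than dividing noise by noise.

The package's null simulation (`rvis_null()`) makes the structural
difference visible: totals are Poisson with intensity proportional to
CDS, and each gene's common proportion is drawn from a Beta(4, 8) and
permuted across genes, so no true CDS–intolerance relationship exists.
Because the count variance still grows with the total, |RVIS| inherits a
strong positive CDS correlation while NoVaDs stays uncorrelated — the
motivation for preferring the ratio.

## Co-expression proximity

From a genes × samples RPKM-like matrix we (1) remove genes below 1 RPKM
in strictly more than 95% of samples (">95%" is strict, so exactly 95%
is kept); (2) compute all pairwise Pearson correlations, optionally with
per-sample weights (weighted means, variances and covariance; uniform
weights reduce exactly to plain Pearson — the default, since no
canonical weighting scheme is bundled); (3) keep links with *signed*
r ≥ 0.3. The threshold is applied to signed correlation, not |r|:
co-expression evidence for shared function is positive correlation, and
keeping strong negative links would reward anti-correlated genes.
A gene's proximity to the known-HIS seed set is the sum of its 20
largest link weights to seed members (all of them if fewer). Seed genes'
links to other seed members count; self-links never exist. Genes with
zero expression variance yield no links and are counted in the
`n_undefined` attribute rather than erroring.

Proximity is deliberately robust to the `top_k` choice (rank agreement
between k = 10/20/30 above 0.9 on synthetic networks) and correlates
with network degree — both properties are asserted in the test suite.

## The remaining features and imputation

* dN/dS with zero rates replaced by 0.001 (so 0/0 → 1, a gene with no
  observed substitutions is treated as neutral).
* F2A = median fetal / median adult expression; a zero adult median
  yields a missing value (then mean-imputed), not infinity.

Feature assembly over the catalog's gene universe imputes: network
proximities → 0 (absence from a network is evidence of no measured
co-expression, not missingness at random); NoVaDs and dN/dS → median;
F2A → mean. The statistics are computed over *all* catalog genes before
imputation — the reference population for the median/mean is not
specified by precedent, and using the full scored universe (rather than
training genes only) is the choice that keeps imputation independent of
the training labels; the constants are recorded in the `imputation`
attribute so the choice is auditable. Every imputed cell is flagged in a
logical mask.

## The ensemble

Per randomization *i* of `n_randomizations` (default 100):

1. a child seed derived from `(seed, i)` initializes the stream, so the
   ensemble is reproducible and insensitive to execution order;
2. the HS pool is subsampled, without replacement, to the HIS set size —
   class-balancing the otherwise very unbalanced problem;
3. `cv_repeats` (default 30) class-stratified 90/10 splits are drawn; a
   linear SVM (`e1071::svm`, cost 1) is fit on each training part with
   features standardized to that part's mean/variance, and held-out HIS
   probabilities are recorded. Per-gene predictions are averaged over
   the repeats in which the gene was tested; genes never held out
   (probability ≈ 0.9^30 ≈ 4% each) get one dedicated held-out
   prediction so the average is defined for everyone. A strict
   stratified 10-fold mode (`cv_mode = "kfold"`) is available; the
   default random-split mode follows the repeated-90/10 description of
   the protocol. One ROC AUC is computed from the averaged values;
4. the SVM is refit on the full balanced set and predicts a calibrated
   positive-class probability for every gene in the feature universe,
   standardized with the balanced set's statistics.

Randomizations with CV AUC strictly greater than 0.5 are kept (exactly
0.5 is dropped); the GHIS is the per-gene mean over kept randomizations,
hence always in [0, 1]. Zero kept randomizations is a hard error — it
means the features carry no detectable signal. We average *probabilities*
rather than decision values because probabilities are bounded and
comparable across randomizations; the choice between the two is not
fixed by precedent and decision values would only change the score
monotonically within each randomization. Zero-variance features are
dropped before fitting; if no feature varies at all, every gene receives
the uninformative 0.5 (training sets are balanced by construction), which
makes the degenerate case exactly tied instead of solver-noise-ordered.

## Evaluation

*Matched null sets.* Disease gene sets are longer than average, and some
scores (RVIS) correlate with CDS length, so raw comparisons against
random genes flatter length-confounded scores. For each target gene the
universe is ranked by |CDS difference| (ties broken by gene ID), the 100
nearest genes form a candidate pool, and one is drawn uniformly; draws
within one null set are without replacement, and target genes are
excluded from the pools (a null set containing the target itself would
be trivially conservative). 100 such sets are drawn per evaluation.

*MCC at top 25%.* The 25% of scored genes with the highest score (cutoff
over each score's own covered universe; ties broken deterministically by
gene ID) are "predicted HIS". TP = predicted-HIS disease genes, TN =
predicted-HS random genes, FP/FN their complements, and
MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as 0 when
any marginal is empty.

*AUC.* Midrank Mann–Whitney form, U/(n₁n₂), identical to the
trapezoidal area with half-credit for ties; the test suite checks it
against exhaustive pairwise enumeration.

*Score comparisons.* Per-set MCC/AUC vectors are compared pairwise with
two-sided Mann–Whitney tests (normal approximation) and BH q-values;
when the pooled metric values are all tied the statistic is undefined
and p = 1 is reported.

*Best-case expectation.* For a candidate set of which a fraction
`p_causal` is truly causal: causal genes always land in the top
fraction, everything else at the background rate, giving rates
tp = p + (1−p)·f, fn = 1−tp, fp = f, tn = 1−f and
AUC = p + (1−p)/2. At (0.5, 0.25) this yields MCC ≈ 0.378 and AUC 0.75 —
the ceiling against which candidate-gene evaluations should be read.

*Study-bias profile.* Spearman correlations (midranks,
pairwise-complete per covariate) of any index with publication counts,
dN/dS and NoVaDs, plus |ρ(pubmed)/ρ(dN/dS)| and |ρ(pubmed)/ρ(NoVaDs)|;
a zero denominator yields an undefined (NA) ratio, not infinity. An
index that predicts biology rather than attention should have ratios
well below 1.

# The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the method assumes:
log-normal CDS (meanlog 7.3, sdlog 0.6 — median ≈ 1.5 kb), Poisson
variant counts at 20 expected variants/kb of CDS (the scale of a
several-thousand-exome call set), a 30% baseline common probability
multiplied by `depletion_effect = 0.4` for non-synonymous variants in
HIS genes, log-normal expression with a shared latent factor of loading
0.6 among HIS genes (about 0.48 pairwise correlation on the RPKM scale,
comfortably above the 0.3 link threshold), 5% of genes expressed below
the RPKM filter, and log-scale shifts of 0.7 for dN/dS (down) and fetal
expression (up) in HIS genes. Default size: 2000 genes, 5% HIS, with
60% of HIS genes used for training and disjoint held-out HIS/HS
evaluation sets. Common/rare status is generated directly through a
per-gene common-probability rather than from a demographic
site-frequency model: the method consumes only the dichotomized counts,
and a frequency-level simulator would add structure nothing downstream
can verify.

What passing tests on these cohorts show: the pipeline recovers a
planted multivariate signal, is calibrated on a signal-free null, and
its metrics behave correctly. What they cannot show: performance on real
exomes and expression atlases, where effect sizes are far smaller,
features are correlated with confounders in ways the generator does not
model (population stratification, annotation error, tissue composition),
and the co-expression structure is not a single clean module.

# Problem sizes and runtime choices

The acceptance-level tests run the full ensemble at 25 randomizations
(instead of the default 100) on the default 2000-gene cohort, which
keeps a pipeline run under a minute while leaving the ensemble average
well-populated; the CDS-null contrast uses 5000 genes; metric oracles
run 1000 random small instances. Matched-set validity uses 100
independent 500-gene trials. These sizes are the package's own
trade-off between statistical resolution and a test suite that runs in
well under a minute per file.

# Known limitations

* The training HIS genes in real applications are themselves
  well-studied, so a score trained on them can only partially escape
  study bias; the features, not the labels, are unbiased.
* NoVaDs does not model per-gene differences in the mutational
  opportunity for synonymous vs non-synonymous changes.
* The SVM is linear with fixed cost 1; no hyperparameter search is
  performed (a radial kernel is available as a config option).
* Genes absent from the feature universe are not scored; no
  extrapolation is attempted.
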