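---
title: "Decoupling cell composition from intrinsic disease effects: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoupling cell composition from intrinsic disease effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodecon)
```

## The problem and the model

Bulk expression differences between diseased and control brain tissue mix
two signals: changed cell composition (chiefly neuronal loss) and changed
expression inside cells. `neurodecon` estimates each sample's cell-type
mRNA fractions from its bulk transcriptome using a single-cell-derived
signature matrix, then puts the estimated neuronal proportion into the
per-gene linear model alongside disease status, so the disease coefficient
is conditioned on composition:

GEx = β0 + βDisease·Disease + βRIN·RIN + βNeuronal·Neuronal + βAge·Age +
βSex·Sex + βInteraction·(Disease_c × Neuronal_c) + ε

Disease and neuronal proportion are mean-centered before the interaction
is formed; this moves the model's reference point to the average sample
and reduces the collinearity between the disease and interaction columns
(a property the test suite checks on unbalanced cohorts). Two variant
profiles drop the interaction: an RNA-seq profile with an unknown batch
covariate, and a microarray profile with a dichotomized RNA-degradation
covariate instead of RIN.

Key assumptions: expression mixes approximately linearly in mRNA shares on
the CPM scale; the log2 model is locally linear in the neuronal share over
the observed range; composition variation is dominated by a single
(neuronal) axis; and one residual-variance moderation per gene serves all
coefficients.

## Fractions are mRNA shares, not cell counts

Neurons carry roughly twice the mRNA of glia, so a deconvolution of bulk
mRNA estimates each type's share of mRNA. The generator models this
explicitly (`mrna_content`, neuron 2.0 vs glia 1.0, configurable) and no
correction back to cell counts is attempted anywhere — the neuronal
covariate in the models is an mRNA share, which is also the quantity the
signature can actually identify. This is why low-mRNA microglia are
systematically underestimated when mixture proportions are interpreted as
cell fractions: the acceptance benchmark constructs exactly that situation
(microglial content 0.5) and observes the negative bias.

## The synthetic-data generator: what it emulates

The generator is first-class, tested code; its defaults are the study
conditions every acceptance check runs under.

* **Cohort sizes** default to the targeted study designs: AD-like 71/32
  discovery and 9/14 validation; PD-like 15/26 discovery and a male-only
  8/10 microarray-like validation.
* **Composition.** Neuronal cell fractions are Beta-distributed per arm
  (AD-like diseased mean 0.60 vs control 0.70; PD-like arms equal at
  0.65), concentration 10, giving a 95% range of roughly 0.4–0.95 — the
  broad spread real degenerating-brain cohorts show, wide enough that the
  <0.40 neuronal-fraction sample filter occasionally fires on control
  samples. The glial remainder is split by a concentration-150 Dirichlet,
  so neuronal loss is the dominant composition axis and glial shares rise
  roughly proportionally as neurons are lost. An earlier flat-Dirichlet
  design let glial fractions fluctuate independently; that contradicts the
  single-dominant-axis regime the model assumes (and real cohorts show,
  with PC1 essentially tracking neuronal content), and made markers of
  non-neuronal types load only weakly on the neuronal covariate, so the
  hierarchical model was adopted and frozen.
* **Counts.** Negative binomial with per-gene dispersion (default 0.05,
  `size = 1/dispersion`; 0 recovers Poisson). The count model is a package
  choice — the statistics downstream only require approximate log-scale
  homoscedasticity after normalization.
* **Effect classes.** Each gene belongs to exactly one of:
  composition-driven (20%, cell-type markers, 8-fold elevated in their own
  type), systemic (5%, ±1 log2 disease effect), interaction (3%, ±3
  log2-per-unit on the centered product), covariate-only (5%), null
  (remainder). Marker fold, effect sizes and class fractions are
  configurable; the planted truth table is sufficient to score every
  downstream stage.
* **Mixtures.** Chimeric-library construction is emulated at count level by
  nested multinomial sampling (types at the proportion row, genes at the
  pooled per-type profile) — equivalent in distribution at gene resolution
  to read-level pooling, at the default scaled depth of 3.5×10⁵ in place
  of 35 M reads. Mixture proportion designs use Dirichlet draws; the
  concentration is the caller's choice since "a diverse range" is all the
  emulated protocol specifies.
* **Perturbagens.** Reversers/mimickers are ∓2×standardized disease scores
  plus noise (the first reverser noise-free as an exact anti-rank control);
  neuronal confounders mix −0.85 disease with +0.4 neuronal structure;
  neutrals are unit noise. Planted compounds are "launched" so the status
  filter does not hide them.
* **Sex** is simulated for AD-like cohorts only; the emulated PD cohorts
  were male-only.

What the generator does **not** emulate: sequence-level artifacts, probe
effects, ambient RNA, batch structure in the single-cell reference,
between-gene correlation beyond composition, and cross-platform gene
mismatches. Passing tests therefore demonstrate correctness of the
machinery and calibration of the statistics under the stated generative
model, not robustness to every artifact of real tissue data.

## Single-cell QC and the signature

Cells are removed when robust z-scores (deviation from the median in
1.4826-scaled MAD units; library size and gene counts on the log2 scale)
fall below −3 for library size or expressed genes, or above +3 for the
mitochondrial fraction. A zero-MAD metric yields z = 0 at the median and
±Inf elsewhere, and is flagged. Re-filtering after recomputing metrics can
remove more cells (medians move); this non-idempotence is documented and
tested. Genes are kept at mean CPM > 1 (strict inequality at the
boundary).

The variance of log2(CPM+1) is decomposed against a loess mean–variance
trend (degree 1, symmetric family, span 0.5); biological = total −
technical exactly. "Significantly biological" is operationalised as a
positive biological component plus a one-sided F-ratio of total to trend
variance with conservative df (cells − 1 on both sides) at BH FDR < 0.05 —
the upstream tool this mirrors does not state a test, so the package fixes
one. Misclassified cells are flagged by a nearest-shrunken-centroid
classifier (uniform priors, ties to the first type in label order,
cross-validated shrinkage default). The signature is the per-type mean CPM
over retained genes that pass a deterministic one-vs-rest specificity rule
(top type ≥ 2× second); this replaces a proprietary marker-selection step
with a testable criterion.

## Deconvolution

NNLS (Lawson–Hanson active set, implemented in the package) is the default
backend; coefficients are renormalized to the simplex, making fractions
invariant to positive rescaling of the sample. The ν-SVR backend
(linear kernel, ν ∈ {0.25, 0.5, 0.75} by fit correlation, standardized
genes, negative weights clipped) reproduces the support-vector flavour of
the reference tool; its batch-normalization modes are not reproduced, so
cross-platform deconvolution should be treated with caution.
Significance: permute the sample's gene values, re-deconvolve, and report
p = (1 + #{null fit ≥ observed})/(1 + n_perm) — the +1 keeps p away from
zero. Samples under 0.40 neuronal fraction are removed by default; a
"keep" policy covers the small-cohort exception (the pipeline applies it
below 12 samples).

## Moderated statistics

The gene-wise residual variances s² with d degrees of freedom are modeled
as scaled inverse-chi-square draws around a prior (d0, s0²), estimated by
moment matching on log s² with trigamma inversion (Newton, tolerance
1e-8). Posterior variances are the convex combination
(d0·s0² + d·s²)/(d0 + d); moderated t uses d0 + d df, capped at the summed
residual df so the d0 = ∞ branch (no excess spread; full pooling to the
mean variance) stays finite. The B statistic uses prior proportion 0.01
and a coefficient prior variance estimated from the top decile of
|moderated t| — conventional defaults, stated here because only the name
of the statistic is pinned by the emulated analysis. The independent
cross-check in the test suite is limma's `squeezeVar`/`eBayes`, which the
implementation matches to 1e-8 on shared ground; the package path never
calls it.

## Permutation statistics

Cross-dataset consistency multiplies each gene's disease-coefficient
moderated t from two cohorts and compares the product to a null built by
shuffling disease labels within each cohort (covariates stay attached to
samples; the interaction column is recomputed), refitting and
re-moderating; each gene is compared to its own null, so FDRs sit on the
grid {0, 1/n_perm, …}. Per-cohort permutation streams are derived from the
seed and a hash of the cohort matrix, making the result exactly invariant
to which cohort is "first". An exhaustive mode enumerates all label
assignments for small cohorts and is tested against an independent oracle.

"More extreme" defaults to absolute-value comparison. The sign-directional
alternative (null ≥ obs for positive observations) is available via
`directional = TRUE`, but doubles the null FDR < 0.05 call rate by
construction (each 5% tail qualifies separately), which conflicts with the
calibration this package treats as the defining property of the test;
contradictory genes are zeroed by the combined score regardless. Combined
scores are ±log10(max(FDR, 1e-5)) — the floor is half the resolution of a
5000-permutation FDR — positive only when both t's are positive, negative
only when both are negative, zero otherwise, hence bounded by |5|.

Cross-disease concordance multiplies the two diseases' combined scores and
pools the null across genes within each permutation (one score vector is
shuffled; shuffling one is distributionally equivalent to shuffling both).
Counting runs in chunks against sorted null values, so the 10⁶-permutation
default never materialises the n_perm × genes null vector. Label
permutations shuffle disease status only, leaving covariates aligned — the
literal reading of the emulated procedure; a Freedman–Lane scheme is
deliberately not used.

## GSEA and the drug screen

Enrichment uses the weighted Kolmogorov–Smirnov running sum on the ranked
statistic (weight 1 default; weight 0 is the classical KS statistic and is
invariant to monotone transforms), with gene-label permutation nulls
shared across sets of equal size, separate positive- and negative-tail
p-values, and BH across sets within each direction. Ranking ties break by
gene identifier for a stable order.

The drug screen computes per-condition Spearman correlations over shared
genes, averages doses/times within a cell line, then cell lines within a
compound; the neuronal-confound filter averages |ρ| per condition first
(the stricter reading) and excludes compounds at ≥ 0.05 before top-k
selection (filter-then-rank). Reversal candidates must be strictly
negative and induction candidates strictly positive — with small panels an
unconstrained "k most negative" could label a positively-correlated
compound a reverser. Ties break by compound id; candidate sets are
disjoint.

## Numerical and policy choices

* Quantile normalization (ties averaged) of log2(CPM + 0.5) is the
  normalization contract; precision weights of the emulated pipeline are
  not reproduced because the downstream models are ordinary least squares
  on normalized values.
* Strict inequalities at every published threshold: CPM > 10/L in ≥ N
  samples, FDR < 0.05 (0.11 for the microarray profile), neuronal fraction
  < 0.40, confound |ρ| < 0.05, RIN "high" strictly above the cut (8.5,
  7.3 or 7.8 by profile; a sample exactly at the cut is low), degradation
  slope high strictly above 5.
* The "unknown batch" of the PD profile enters as a user-declared
  categorical covariate; a PC-sign heuristic for suggesting a split is
  deliberately left out of the model path.
* Gene identifiers match across cohorts by exact string; cross-platform
  harmonization is the caller's responsibility.

## Problem sizes used by the tests

The default acceptance-scale runs use 2000 genes, 600 reference cells, the
71/32 AD-like cohort, 300 mixtures at depth 3.5×10⁵, 1000 label
permutations for the t-product calibration (500 genes), 10⁵ pooled
permutations for the cross-disease calibration (2000 genes), 400
permutations × 200 random sets for GSEA calibration, and a 200-compound
panel. These sizes give Monte-Carlo standard errors comfortably inside the
tolerances asserted while keeping a full run around a minute; all are
configurable upward.

## Known limitations

Estimated neuronal proportion is a noisy covariate, so attenuation leaks a
small amount of composition signal into other coefficients (measured at
well under the null call rate in the acceptance checks, but not zero).
The signature assumes four major cell types; rare populations fold into
whichever profile they resemble. Microglial signal is close to the noise
floor at realistic abundances. The permutation refits under the null are
plain label shuffles, exchangeable only when disease is independent of the
retained covariates under H0 — the generator satisfies this, real cohorts
may not. Combined scores censor contradictory genes to zero, which is a
hard decision boundary: a gene marginally inconsistent between cohorts
contributes nothing downstream.
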