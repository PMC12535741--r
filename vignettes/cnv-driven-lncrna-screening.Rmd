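---
title: "Screening for CNV-driven prognostic lncRNAs with lnccnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for CNV-driven prognostic lncRNAs with lnccnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnccnv)
```

## The problem

Copy-number gains and losses alter the expression of the genes they cover.
When the affected gene is a long non-coding RNA (lncRNA) with a role in
tumor biology, the aberration can propagate into patient outcome. `lnccnv`
looks for exactly this chain of evidence in a cohort with three matched
measurements per sample: gene-level expression counts, absolute copy-number
states, and right-censored survival. A lncRNA is called a *prognostic
CNV-driven* signature feature when (i) its expression tracks its copy
number, (ii) its expression predicts survival in a univariate Cox model,
(iii) its expression differs across copy-number groups, and (iv) it retains
an independent contribution in a joint multivariate Cox model.

## Inputs and harmonization

Expression and CNV matrices are tab-delimited features x samples tables;
the clinical table needs `Sample_ID`, `Survival_Time` (any consistent unit,
typically days) and `Status` (1 = death/event). The three sources rarely
agree on their sample sets, so every analysis runs on the sorted
intersection, in identical order in all components; the cohort constructor
asserts this invariant on every build. Gene identifiers are matched after
stripping Ensembl-style version suffixes, because expression, CNV and
annotation files in the wild disagree on versions; the original identifier
is kept for reporting. Duplicate gene rows in expression input are summed
(a re-aggregation of fragment counts); duplicate CNV rows keep the first
occurrence, since copy-number states cannot be meaningfully summed.
Fractional "absolute" copy-number calls do occur in portal exports; they
are rounded half-to-even with a warning.

Gene classes come from the GTF biotype: the six long non-coding biotypes
(`lincRNA`, `antisense`, `sense_intronic`, `sense_overlapping`,
`processed_transcript` — the plural spelling is also accepted —
`3prime_overlapping_ncRNA`) map to lncRNA, `protein_coding` to PCG, and
everything else to `other`, which is excluded from the screen.

## Count normalization

Counts are normalized with a variance-stabilizing transformation built from
a negative-binomial dispersion trend. Per-sample size factors use the
median-of-ratios estimator over genes positive in every sample, rescaled to
geometric mean 1 to remove the scale indeterminacy (a pseudocount of 1 is
used for factor estimation only if no all-positive gene exists). Gene-wise
dispersions are method-of-moments estimates on scaled counts; the trend
`alpha(mu) = a1/mu + a0` is fitted by iteratively reweighted least squares
(weights `1/fit^2`, 10 iterations) on genes with mean at least 1 and
positive dispersion; a non-positive asymptotic dispersion is floored at
1e-8. The closed-form transform

```
vst(q) = log2((1 + a1 + 2 a0 q + 2 sqrt(a0 q (1 + a1 + a0 q))) / (4 a0))
```

is monotone in the scaled count `q` and approaches `log2(q)` for large `q`,
so a doubling of expression adds one unit. The test suite verifies the
monotonicity and doubling properties directly and checks that per-bin
variances across mean deciles are flat (max/min ratio below 3) where
`log2(x + 1)` is several-fold worse; the trend coefficients are recovered
within +/-50% from self-generated cohorts of 2,000 genes by 60 samples.

Genes with scaled count >= 5 in fewer than 10% of samples are dropped
before fitting (both knobs configurable). This filter, and the minimum
cohort size of 20 samples, have no reference values in the field; they are
explicit defaults chosen to keep the Cox and rank tests away from
degenerate inputs.

## The screening cascade

**Correlation.** Each lncRNA present in both compartments gets a Pearson
*r* between normalized expression and raw absolute copy number, with the
two-sided *t*-based *p*-value. Copy numbers enter as numbers, not
categories, since the correlation is defined on numeric vectors. Features
with constant copy number (for example, all-diploid) are flagged
`degenerate` and excluded from counts rather than silently reported as
*r* = 0. The observed *r* distribution is contrasted with a permutation
null: sample labels of the CNV matrix are shuffled as whole columns — the
same shuffle for all features, preserving inter-feature CNV structure — and
all coefficients recomputed, 1,000 times by default (floor 100). A
Kolmogorov–Smirnov statistic and histogram table summarize the shift.

**Cox screen.** One univariate proportional-hazards fit per lncRNA, on
z-scored expression so coefficients are per-SD and comparable across
features (raw scale available). Ties use the Efron approximation, the more
accurate of the standard choices. Fits that do not converge — including
monotone-likelihood separation — fail the screen rather than pass with an
inflated statistic. The per-feature fit is verified against a grid-search
maximization of the explicitly written Efron partial likelihood to 1e-6.

**Kruskal–Wallis screen.** Cox survivors are tested for expression
differences across CNV groups: copy number < 2 is a deletion, 2 diploid,
> 2 an amplification. Groups below 3 members are dropped; with fewer than
two eligible groups the feature is untestable and fails. The default is the
3-group test; `collapse_aberrant = TRUE` merges deletion and amplification
into one aberrant group for the 2-group reading. Both stage cut-offs
default to raw p < 0.05 with no multiple-testing correction, matching
common practice for this cascade; `fdr = TRUE` adds Benjamini–Hochberg
columns as an extension. The cascade order is fixed (Cox first, then KW),
so attrition is monotone: passing both never exceeds passing Cox.

## Risk model

Survivors of both screens enter a joint Cox model. Near-duplicate features
(pairwise |r| > 0.95) are pruned first; the joint fit is refined by
backward elimination of the largest Wald *p* until all retained features
have *p* < 0.05 — a transparent alternative to penalized selection whose
result is directly interpretable as a refit coefficient vector. If the
joint fit fails to converge, a ridge-stabilized fit (penalty 1e-4 on the
z-scale) is used with a warning; if nothing survives, the run stops with
advice to relax the threshold. A univariate-only path (`no_multivariate`)
bypasses the joint refinement.

The risk score is the Cox linear predictor, the sum of coefficient times
z-scored expression over the signature. Patients at or below the median
score are `low` risk, the rest `high` — the median split guarantees
balanced groups, and ties go low. The groups are compared with
Kaplan–Meier curves and the two-group log-rank test. Discrimination is
summarized by the rank-based AUC against observed event status over full
follow-up (ties count one half), with a seeded percentile bootstrap CI over
samples (1,000 resamples by default). Counting censored patients as
non-events is a deliberate, documented simplification; a time-horizon
variant would require excluding patients censored before the horizon and is
left out of the default path.

## Offline enrichment

PCGs whose normalized expression correlates with any signature lncRNA at
max |r| >= 0.5 (or a top-k rule, since "highly correlated" has no canonical
cut-off) form the target set. Each term of a user-supplied GMT collection
is tested by the hypergeometric upper tail against the universe of all
filtered cohort PCGs — the standard over-representation universe — with
Benjamini–Hochberg adjustment within each collection. Symbol matching is
case-insensitive and unmatched symbols are counted and reported. Running
against local GMT files keeps the stage fully offline and reproducible; a
20-term toy collection ships in `inst/extdata`.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a TCGA-style cohort; its
defaults are 300 samples, 500 lncRNAs, 2,000 PCGs, 10% of lncRNAs with
aberrant copy number, and 30% of those prognostic. Aberrant features draw
integer states from a categorical distribution over 0–4
(0.05/0.20/0.35/0.25/0.15 by default); counts are negative binomial with
mean `mu_g (cn/2)^gamma sf_s` (gamma = 1, i.e. proportional dosage) and
dispersion trend a0 = 0.05, a1 = 3 — values typical of bulk tumor RNA-seq.
Survival is exponential (baseline hazard 1/1000 per day) with per-SD
log-hazard 0.8 acting through the *latent*, noise-free log2 expression of
prognostic features, so recovery rates measure the screen's handling of
count noise rather than generator leakage. Censoring is uniform, tuned to a
30% target. Linked target PCGs inherit their lncRNA's latent profile plus
Gaussian noise (SD 0.75, putting the latent correlation near 0.8). All
randomness flows from one seed; identical configurations produce
byte-identical files.

The generator deliberately omits several features of real tumor data:
segmental (regionally correlated) CNV, batch effects, tumor purity,
non-proportional hazards and gene-length biases. Passing tests on this
generator therefore demonstrate the statistical machinery under its stated
model, not robustness to those artifacts.

`make_null_cohort()` is the calibration generator: it keeps the aberrant
copy-number states but sets the dosage exponent and the survival effect to
zero, so copy number, expression and survival are mutually independent and
the Cox and Kruskal–Wallis screens should reject at their nominal 5%. (A
generator with *no* CNV variation would leave the Kruskal–Wallis stage
untestable, which is why the null keeps the states and removes only the
coupling.)

## Validation strategy and problem sizes

The acceptance suite checks, at sizes chosen to keep the default test run
in minutes: exact agreement of every core statistic (Pearson,
Kruskal–Wallis, log-rank, hypergeometric, Cox beta) with independent
brute-force oracles; 5% +/- 2% type-I error of both screens and the
log-rank test across eight null cohorts of 300 samples (2,000 Cox features,
1,000 KW features, 200 log-rank replicates) plus KS-uniformity of the
log-rank p-values; recovery of Cox beta = 0.7 within 0.05 (200 replicates,
n = 400), of the dispersion trend within +/-50% (2,000 genes x 60 samples),
and of planted prognostic lncRNAs with sensitivity >= 0.8 (gamma = 1,
beta = 0.8, n = 300, 50 replicates); risk-model AUC >= 0.75 with log-rank
p < 0.05 in >= 90% of 50 strongly planted cohorts (two features,
beta = 1/SD, n = 400) against ~0.5 AUC on nulls; byte-identical outputs
under a fixed seed with standalone stages reproducing the one-shot run; and
hypergeometric calibration (~5% of terms significant for random selections;
the exact 1/252 worked example).

## Numerical notes and limitations

Newton-type Cox fitting can diverge under separation; such fits are flagged
and treated as non-significant rather than dropped silently. All-tied
Kruskal–Wallis inputs define H = 0, p = 1. Risk-score ties at the median go
to the low group; an all-zero coefficient vector yields a degenerate
grouping and a warning. Doubles are serialized with 17 significant digits
so save/load round trips are exact and reruns byte-identical. The pipeline
performs no batch correction, purity adjustment, covariate-adjusted
screening, time-dependent ROC, or genome-segmentation of CNV calls —
absolute gene-level states are taken as given.
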