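# lnccnv

Copy-number variation (CNV) can drive the dysregulation of long non-coding
RNAs (lncRNAs), and CNV-driven lncRNAs are a rich source of prognostic
biomarkers in cancer cohorts. `lnccnv` integrates three matched data types —
a raw gene-level expression count matrix, an absolute copy-number matrix and
a clinical survival table — and carries them through a complete discovery
pipeline:

1. **Preprocessing** — harmonize the common samples across the three inputs,
   normalize counts with a negative-binomial variance-stabilizing
   transformation (VST), classify genes into lncRNA / protein-coding (PCG)
   classes from a GTF annotation, and extract lncRNA-level CNV profiles.
2. **Correlation** — per-lncRNA Pearson correlation *r* between normalized
   expression and absolute copy number, contrasted against a
   label-permutation null distribution.
3. **Survival screen** — univariate Cox proportional-hazards regression per
   lncRNA (Wald *p* < 0.05), followed by a Kruskal–Wallis test of expression
   across CNV groups (deletion / diploid / amplification, *p* < 0.05).
4. **Risk model** — multivariate Cox refinement with backward elimination;
   per-sample risk score Σᵢ βᵢ·zᵢ (z-scored expression of the signature
   lncRNAs); median-split into high/low risk groups; Kaplan–Meier curves,
   log-rank test and a bootstrap-CI AUC.
5. **Enrichment** — PCGs highly correlated with the signature lncRNAs
   (max |r| ≥ 0.5) tested for over-representation in user-supplied GMT gene
   sets with the hypergeometric upper tail and Benjamini–Hochberg FDR,
   entirely offline.

A seeded synthetic-cohort generator (`simulate_cohort()`) emits
TCGA-shaped cohorts with known ground truth — negative-binomial counts with
integer CNV dosage effects, exponential survival driven by planted
prognostic lncRNAs, and linked target PCGs — so every stage is testable
without any download.

## Worked example

```r
library(lnccnv)

sim <- simulate_cohort(sim_config(n_samples = 200, n_lnc = 150, n_pcg = 400,
                                  seed = 11))
res <- run_pipeline(run_config(
  expr = sim$expr, cnv = sim$cnv, clinical = sim$clinical,
  gtf = sim$annotation,
  gmt = system.file("extdata", "toy_pcg_sets.gmt", package = "lnccnv"),
  n_permutations = 500, seed = 11))

res$screen[res$screen$passed_cox & res$screen$passed_kw,
           c("lncRNA_id", "r", "cox_beta", "cox_p", "kw_p")]
#>  lncRNA_id     r cox_beta    cox_p     kw_p
#>    LNC0022 0.838    0.517 2.20e-06 1.90e-31
#>    LNC0075 0.846    0.564 7.25e-07 1.30e-32
#>    LNC0096 0.842    0.358 3.00e-04 3.59e-33
#>    LNC0143 0.826    0.561 3.77e-06 1.11e-33
```

The four lncRNAs passing both filters are exactly the four prognostic
CNV-driven features planted by the generator (`sim$truth$prognostic_ids`).
Each row reports the expression–copy-number Pearson *r*, the per-SD
univariate Cox log-hazard ratio with its Wald *p*, and the Kruskal–Wallis
*p* across CNV groups. The fitted risk model summarizes as:

```r
res$evaluation$auc
#> AUC 0.847 (95% CI 0.787-0.905), log-rank p = 2.26e-21
res$risk_model$pr_lncRNAs
#> "LNC0022" "LNC0075" "LNC0096" "LNC0143"
```

i.e. the risk score separates high- and low-risk patients sharply, and the
AUC is the probability that a random deceased patient outscores a random
surviving one. On real data, replace the simulated objects with file paths
(`expr = "counts.tsv"`, `cnv = "absolute_cn.tsv"`,
`clinical = "clinical.tsv"`, `gtf = "gencode.gtf"`).

A thin command-line front end mirrors the stages
(`run | simulate | preprocess | correlate | screen | model | enrich`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","lnccnv",package="lnccnv"))')" \
  run --expr counts.tsv --cnv cn.tsv --clinical clin.tsv --gtf genes.gtf \
  --out results/ --seed 7
```

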