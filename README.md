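# wntstrat

Stratification of colorectal tumours by Wnt ligand dependence.

Nearly all colorectal cancers constitutively activate Wnt signalling, but
they do it through two mechanistically distinct routes with opposite
therapeutic implications:

- **Ligand-independent (LI)** tumours mutate the downstream transduction
  machinery — truncating *APC* or activating *CTNNB1* at its exon-3
  phosphodegron — and no longer need extracellular Wnt ligand.
- **Ligand-dependent (LD)** tumours disrupt the R-Spondin axis —
  loss-of-function *RNF43* mutations, *RSPO2*/*RSPO3* gene fusions, or
  stromal R-Spondin overexpression ("RSPO-high") — which amplifies
  endogenous ligand signalling and therefore remains druggable with Wnt
  ligand inhibitors such as Porcupine inhibitors.

`wntstrat` implements the full molecular stratification pipeline for
transcriptomic, mutational and methylation data, together with a synthetic
multi-omic cohort generator with planted ground truth, so every stage is
testable at desk scale. It is aimed at computational biologists who want a
reproducible, self-contained implementation of this stratification logic,
either to apply to their own matrices or to study its statistical
behaviour.

## What it computes

**Ground truthing.** RSPO fusions are detected by exact matching of
breakpoint-spanning junction windows in RNA-seq reads (a read supports a
fusion if it, or its reverse complement, contains the `2 * min_overlap`
bases around the breakpoint). Driver mutations are interpreted by functional
class (APC/RNF43 truncation, CTNNB1 hotspot missense). RSPO-high samples
are outliers with cohort-relative z ≥ 2 for *RSPO2/3* log-CPM and no
fusion. Samples with both LD and LI evidence, or neither, are excluded (EX).

**Expression.** Counts are normalised to `log2(1 + CPM)`; differential
expression between LD and LI uses the Welch t statistic with
Welch–Satterthwaite degrees of freedom and Benjamini–Hochberg FDR control.
The five Wnt negative regulators (*AXIN2*, *NKD1*, *APCDD1*, *NOTUM*,
*DKK4*) are expected LI-high.

**Enrichment.** Weighted Kolmogorov–Smirnov running-sum enrichment
(exponent 1): a hit at rank *i* adds `|t_i| / N_R`, a miss subtracts
`1/(N − N_hits)`; ES is the extremum of the running sum. Significance and
NES come from phenotype permutation, and the leading edge is the set
members before (positive ES) or after (negative ES) the peak.

**Methylation.** Gene-level mean beta over mapped probes; differentially
methylated probes (Welch on beta, LD-relative direction); CIMP-stratified
comparisons; Pearson correlation between mean beta and log-CPM. In the
generator, *AXIN2*/*NKD1* methylation is linearly coupled to expression on
the logit scale (target correlation ≈ −0.7) while *NOTUM*/*APCDD1* are
CIMP-driven and bimodal.

**Biomarker.** Single-gene ROC analysis with LD as the positive class and
low expression as the decision score: AUC by pairwise concordance
(`P(x_LI > x_LD)`, ties at ½), a stratified percentile-bootstrap confidence
interval, and the expression threshold τ maximising sensitivity +
specificity (call LD when expression < τ; the boundary goes to LI).

## Worked example

```r
library(wntstrat)

cfg <- simulation_config(seed = 42)   # 600 tumours, 11.3% LD
sim <- simulate_cohort(cfg)
cls <- classify_cohort(sim$bundle)
table(cls$labels$label)
#>  EX  LD  LI
#>  20  80 500

norm   <- log_cpm(sim$bundle$expression)
labels <- setNames(cls$labels$label, cls$labels$sample_id)
labels <- labels[labels %in% c("LD", "LI")]

derive_biomarker(norm, labels, n_boot = 2000, seed = 1)
#> AXIN2 biomarker (LD vs LI, n = 80 vs 500)
#> AUC 0.973 (95% CI 0.958 to 0.986; stratified percentile bootstrap, 2000 replicates)
#> call LD when AXIN2 expression < 12.995 (sens 87.5%, spec 95.2%)

meth_expr_correlation(mean_beta_per_gene(sim$bundle$methylation), norm)
#>     gene       r        p   n
#> 1  AXIN2 -0.6987 4.87e-89 600
#> 2   NKD1 -0.6938 2.61e-87 600
#> 3  NOTUM -0.0431 2.92e-01 600
#> 4 APCDD1 -0.0164 6.89e-01 600
```

The classifier recovers every planted label when drivers are mutually
exclusive (the 20 EX calls above are the planted co-occurring or
double-flagged samples), the AXIN2 AUC sits at the value implied by the
generator's class-conditional Gaussians (`theoretical_auc(cfg, "AXIN2")`
≈ 0.968), and the methylation–expression anticorrelation reproduces the
generator's coupling target of −0.7 for the two coupled genes while the
CIMP-driven genes show none.

A command-line wrapper is installed at
`system.file("cli", "wntstrat", package = "wntstrat")` with subcommands
`simulate`, `detect-fusions`, `classify`, `expression`, `gsea`,
`methylation`, `biomarker` and `full`; `full` chains the whole pipeline
and writes `report.json`.

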