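---
title: "Methods: stratifying colorectal tumours by Wnt ligand dependence"
author: "wntstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying colorectal tumours by Wnt ligand dependence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wntstrat)
```

## The stratification problem

Colorectal tumours activate Wnt signalling either downstream of the
receptor complex — truncating *APC* or stabilising β-catenin through
*CTNNB1* exon-3 missense mutations (ligand-independent, LI) — or at the
receptor level, by disabling the E3 ligase *RNF43*, acquiring an
*RSPO2*/*RSPO3* fusion, or recruiting stromal R-Spondin (ligand-dependent,
LD). Only the LD route still requires secreted Wnt ligand, so only LD
tumours are candidates for ligand-blocking therapy. The package turns this
biology into a deterministic labelling procedure plus the statistics needed
to derive a practical single-gene surrogate biomarker.

## Ground truthing

A sample's evidence is summarised in five boolean driver flags:

| flag | evidence |
|---|---|
| `apc_lof` | *APC* nonsense / frameshift / splice-site mutation |
| `ctnnb1_act` | *CTNNB1* missense at a phosphodegron hotspot |
| `rnf43_lof` | *RNF43* nonsense / frameshift / splice-site mutation |
| `rspo_fusion` | junction-spanning reads for a known RSPO fusion |
| `rspo_high` | *RSPO2/3* log-CPM z ≥ 2 without a fusion call |

LI evidence is `apc_lof ∨ ctnnb1_act`; LD evidence is
`rnf43_lof ∨ rspo_fusion ∨ rspo_high`. Samples with both kinds of evidence
("concurrent") or neither ("no driver") are excluded (EX) rather than
forced into a class; EX samples are carried through reporting but never
into fitting or evaluation. LD samples with more than one LD flag are kept
in the class but flagged `AMBIGUOUS` at the subtype level.

Design choices made where the procedure was genuinely open:

- **Hotspots.** The CTNNB1 hotspot set defaults to the exon-3
  phosphodegron codons {32, 33, 34, 35, 37, 41, 45}. Published cohorts
  differ in their exact functional filters; the set is a configurable
  argument, not a constant.
- **Fusion matching is exact.** A read supports a fusion iff it (or its
  reverse complement) contains, as an exact substring, the window of
  `min_overlap = 10` bases on each side of the breakpoint. At 50-base
  reads a 20-mer window makes chance matches in decoy sequence vanishingly
  unlikely (≈ 4⁻²⁰ per position) while leaving a generous placement range.
  Error-tolerant matching is deliberately out of scope: the package
  consumes desk-scale, error-free reads; real-data users would run a
  dedicated fusion caller and feed calls in as a table.
- **RSPO-high is cohort-relative.** z-scores are computed across all
  samples of the analysed matrix with the sample (n−1) standard deviation,
  and the threshold is inclusive (z ≥ 2). Whether outliers should be
  computed within histological strata is unresolvable from first
  principles; cohort-wide is the simplest defensible choice and is the
  documented contract.

## Expression and enrichment

Counts are normalised as `log2(1 + CPM)`. The pseudo-count-inside-the-log
form maps zero counts to exactly zero and keeps the transform monotone per
sample; the prior count is exposed (`prior_count`) for users who prefer
other variants.

Differential expression uses the Welch two-sample t statistic with
Welch–Satterthwaite degrees of freedom and two-sided p-values, corrected by
Benjamini–Hochberg over exactly the tested genes. A moderated/shrinkage t
(limma-style) would be preferable at very small group sizes, but Welch is
self-contained, exactly testable against textbook formulas, and adequate at
the simulated group sizes (hundreds of samples); it is a documented
stand-in, not a claim about what any particular study used. Genes with zero
variance in both groups are reported with t = 0, p = 1 and flagged rather
than dropped.

Gene-set enrichment is the weighted Kolmogorov–Smirnov running sum with
exponent 1 on the Welch-t ranking (ties broken alphabetically so the
ranking is deterministic). Significance uses phenotype permutation — label
shuffling preserves inter-gene correlation, which gene-set permutation
would destroy — with NES defined as ES divided by the mean |ES| of
same-sign permutations and a +1 pseudo-count in the nominal p so that
finite permutation counts never produce p = 0. When fewer than 10
permutations share the observed sign the NES is reported as `NA` with a
warning instead of dividing by a near-zero mean. Because the ranking
metric, weighting and permutation scheme are package choices, NES
magnitudes are not comparable across implementations and are not treated
as reproduction targets anywhere in the test suite.

## Methylation

Probe-level beta values are averaged unweighted within genes (no
weighting scheme is defensible without array annotation, which the package
deliberately does not model). Differential methylation uses Welch on the
beta scale — betas are what the comparisons of interest are stated in — and
an M-value analysis can be obtained by transforming the input matrix.
Direction is LD-relative: `hyper` means higher beta in LD. CIMP-stratified
comparisons test CIMP⁺ vs CIMP⁻ within each class separately and mark
strata with fewer than two samples `testable = FALSE` instead of silently
dropping them. Methylation–expression coupling is the Pearson correlation
between gene-level mean beta and log-CPM with the t-transform p-value on
n − 2 degrees of freedom.

## The biomarker

The positive class is LD and the decision score is *low* AXIN2: the rule
is "call LD when expression < τ". Candidate thresholds are midpoints
between consecutive distinct scores plus ±∞ sentinels, which makes the
rule well defined off the training grid and symmetric in the data. The AUC
is pairwise concordance `P(x_LI > x_LD) + ½P(x_LI = x_LD)`, which equals
the trapezoidal area under the midpoint-threshold curve (the suite checks
this identity to 1e-12). τ maximises sensitivity + specificity, with ties
broken towards higher specificity (a false LD call sends a patient towards
an inappropriate therapy) and then towards lower τ. The confidence
interval is a stratified percentile bootstrap: resampling within class
keeps both class sizes fixed and the procedure exactly reproducible under
a seed. Samples scoring exactly τ go to LI, the more prevalent class.
Thresholds are cohort- and unit-specific; `apply_classifier` warns when a
rule is applied to a matrix declared in a different expression space.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` plants, per sample: class (LD with probability
`ld_fraction = 0.113`), LD subtype (45% fusion / 20% RSPO-high / 35%
RNF43), the corresponding driver mutation or junction reads, rare
opposite-class co-drivers (`co_occurrence_rate = 0.02`), silent passenger
mutations, CIMP status (prevalence 0.2), class-conditional Gaussian log2
expression, Poisson counts around a compositional mean with log-normal
library sizes, logit-linear methylation coupling for *AXIN2*/*NKD1* and
CIMP-driven bimodal methylation for *NOTUM*/*APCDD1*, an RSPO2/3 shift
large enough that the z ≥ 2 rule fires in expectation, and a
cancer-associated-fibroblast signature shift in RSPO-high (stroma-rich)
samples.

Key calibration choices, fixed once and documented here:

- **AXIN2 effects** default to mu_ld = 4.2, mu_li = 6.3, sigma = 0.8 log2
  units, chosen so the implied two-Gaussian AUC
  `Φ((mu_li − mu_ld)/(σ√2)) ≈ 0.968` sits inside the validation AUC range
  reported for this class of biomarker. Effects for the other four
  negative regulators are plausibility choices of the same order; no study
  publishes per-gene effect sizes to estimate them from.
- **Methylation coupling noise** (logit-scale sd 0.65 for *AXIN2*, 0.67
  for *NKD1*, with slope 0.35 per log2 unit and 3 probes per gene) was
  solved numerically once so that the generating-model correlation between
  mean probe beta and log2 expression is −0.70 at the default class
  mixture; the parameter-recovery tests then ask the *estimated* r to land
  near that target, which makes them sensitive to bugs in either the
  generator or the estimator.
- **RSPO shift = 7 log2 units** with baseline sd 0.5: large enough that
  under the default mixture the planted outliers essentially never fall
  below z = 2 and unshifted samples essentially never exceed it, which is
  what lets the exclusivity-free recovery test demand exactly 100%
  agreement rather than a high percentage.
- **Counts are Poisson**, not negative-binomial, around the compositional
  mean: every downstream analysis operates on log-CPM where the planted
  Gaussian structure is the quantity of interest, and at the simulated
  depths (≈ 3×10⁵ per sample over a 100-gene panel) the extra count noise
  is negligible against the planted sigmas. An `overdispersion` multiplier
  is accepted for users who want heavier-tailed counts but defaults off.
- **One RNG stream per layer** (classes, mutations, expression,
  methylation, reads), seeded as `seed + offset`, so regenerating one
  layer never perturbs another's draws and identical configs are
  bit-identical end to end.

The generator does **not** attempt realistic transcriptome dimensions,
sequencing error, batch effects, copy number, or the correlation structure
of real methylation arrays. Passing tests therefore demonstrate that the
pipeline's statistics recover known planted structure under its own
modelling assumptions — a necessary condition, not evidence about any real
cohort.

## Problem sizes and numerical conventions in the test suite

The suite exercises oracle equivalence on hundreds of random small
instances (AUC and threshold selection vs brute-force enumeration, ES vs
step-by-step running sums, Welch/BH vs textbook formulas), and runs the
recovery properties at the default cohort size n = 600 (10 seeds for exact
label recovery, 25 for AUC recovery), the methylation-cohort size n = 440
(20 seeds for coupling, 100 for the CIMP null), and reduced sizes (n =
60–150) for permutation-null calibration and end-to-end determinism, which
keeps the default run in the minutes range on one core. Floating-point
conventions worth knowing: the running-sum peak is the first position of
maximal |deviation| (two positions can tie in exact arithmetic; either is
a valid extremum and the tests compare peak magnitudes, not indices);
write/read round trips are exact for counts and 12-significant-digit for
normalised values; and all randomised operations take explicit integer
seeds.

## Known limitations

- Mutation interpretation is rule-based on variant class and position; it
  does not model missed *RNF43* microsatellite-slippage calls or rare
  epigenetic drivers, both of which inflate the EX class in real data.
- The fusion detector requires a library of known junctions; it performs
  no split-read discovery of novel breakpoints.
- CIMP status and CMS labels are consumed as annotation, never computed.
- The biomarker threshold does not transfer across expression platforms;
  per-cohort re-derivation is the supported workflow, mirroring how such
  thresholds are reported per cohort in practice.
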