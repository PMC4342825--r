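---
title: "Reference-gene stability analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

# The problem

Relative RT-qPCR quantification reports the expression of a gene of
interest (GOI) as a ratio to a normalization factor built from reference
genes. The choice of reference genes is circular: a candidate's
stability can only be judged against some normalization, which itself
needs stable genes. The workflow implemented here breaks the circle the
standard way: candidates are pre-selected *in silico* from transcriptome
data, measured by qPCR over a wide panel of conditions, ranked by a
ratio-based stability statistic that needs no prior normalization, and
the practical cost of bad choices is quantified as a normalization bias.

# From Cq to quantities

## Model

A qPCR reaction with amplification efficiency $E$ multiplies template by
$1+E$ per cycle, so the quantification cycle relates to the initial
amount $Q$ by $Cq = Cq_{cal} - \log_{1+E} Q$. The package works with

$$Q = (1+E)^{\,Cq_{cal} - Cq},$$

where $Cq_{cal}$ is a per-gene calibration point. By default the
calibration point is the gene's minimum Cq, so the best-expressed sample
gets $Q = 1$ and all quantities lie in $(0, 1]$. Because every
downstream statistic (M, V, NF, fold changes) is ratio-based, the anchor
is mathematically irrelevant; any fixed per-gene Cq may be supplied
instead.

Efficiencies come from dilution-series standard curves:
$E = 10^{-1/\text{slope}} - 1$ for the least-squares slope of Cq against
$\log_{10}$ relative concentration. A slope of $-3.3219$ is 100%
efficiency. Estimation is exact on noiseless series for any $E$;
efficiency tables are validated to $(0, 2)$ with a warning outside the
usual assay-acceptance window $[0.85, 1.15]$.

## Technical structure

Technical replicates are collapsed to a mean Cq with a sample
(n−1 denominator) standard deviation — the convention is not universal,
so it is fixed here and exposed as a switch where it matters. Cells with
a replicate SD above 0.5 cycles are flagged; the threshold is ordinary
qPCR QC practice. Replicate SDs propagate to the log2 scale as
$SD_{Cq}\cdot\log_2(1+E)$.

Runs (plates) are aligned with inter-run calibrators: for each
(run, assay), the offset of the run's calibrator Cq from the across-run
mean calibrator Cq is subtracted. With noiseless calibrators this
removes planted run offsets exactly; with noisy calibrators the residual
error is the calibrator's technical noise. A multi-run table lacking a
calibrator for a needed (run, assay) is an error naming the pair, not a
silent pass-through.

Genomic-DNA contamination is screened with a ValidPrime-style assay
(VPA) that targets a non-transcribed region. With
$\Delta Cq_a = Cq_a(\text{gDNA}) - Cq_{VPA}(\text{gDNA})$ from a gDNA
control, the gDNA-attributable fraction of assay $a$'s signal in sample
$s$ is $2^{\,Cq_a(s) - Cq_{VPA}(s) - \Delta Cq_a}$, capped at 1. The
base defaults to 2 because the VPA's own efficiency is typically not
measured. Fractions above 1% are flagged; samples with no VPA
amplification report fraction 0 with an `undetected` status.

Missing Cq cells (no amplification) stay missing all the way through;
the stability functions refuse incomplete matrices and list the missing
cells rather than imputing, because silent imputation can corrupt a
stability ranking.

# The stability statistics

For genes $j, k$ with quantities $Q_j, Q_k$ across samples, the pairwise
variation is $V_{jk} = SD_s\!\left(\log_2 Q_j/Q_k\right)$ and the
stability measure is $M_j = \frac{1}{N-1}\sum_{k \ne j} V_{jk}$.
Co-regulated or stable genes give small $M$; the conventional
suitability threshold is $M < 1.5$. Ranking proceeds by stepwise
exclusion of the highest-M gene down to two genes, which are reported as
an unordered best pair — with only two genes left, $M_1 = M_2 = V_{12}$
and they cannot be ordered. Exact ties are broken towards the
lexicographically smallest gene id and the tie is recorded in the
output; this keeps the ranking deterministic.

Normalization factors $NF_n$ are per-sample geometric means of the $n$
most stable genes, added best-first. The series
$V_{n/n+1} = SD_s\!\left(\log_2 NF_n/NF_{n+1}\right)$ measures what the
$(n{+}1)$-th gene changes; the optimal count is the smallest $n$ with
$V_{n/n+1} < 0.15$. When no value passes the cutoff the full panel size
is returned with an explicit warning status instead of a guess.

All ratios use log base 2 throughout. M and V are invariant under
per-sample global scaling (loading differences) and per-gene scaling
(calibration anchor), which the test suite asserts as properties.

# Normalization bias

For a reference set $R$ and an alternative set $A$, the per-sample bias
is $\log_2 NF_A / NF_R$, averaged within condition (one point per
condition, matching how such audits are read). The sign convention —
positive means the alternative over-normalizes, i.e. under-estimates GOI
expression — is recorded in the output. Zones are labelled by the
absolute fold bias $2^{|bias|}$: below 1.5-fold (`yellow`), 1.5–2
(`green`), 2–3 (`blue`), 3–8 (`red`), and an `extreme` zone beyond
8-fold added because observed biases can exceed the conventional bins.
The quantile profile pairs sorted signed biases with cumulative
fractions $i/n$; whether such plots use $i/n$ or $(i-0.5)/n$ is a
convention, so it is configurable with $i/n$ as default.

Geometric averaging is the point of the exercise: a regulated gene
contributes only a third of its log-deviation to a 3-gene NF, so the
mean absolute bias of a trio containing one regulated gene is
essentially always below the solo bias of that gene. The acceptance
suite verifies this on 100 simulated panels.

# Nested variance decomposition

Log2 relative expression (each gene expressed against its mean in a
stated control condition) is partitioned by a three-level fully nested
random-effects ANOVA: genes, conditions within genes, biological
replicates within conditions. With $a$ genes, $b$ conditions per gene
and $n$ replicates per cell, the method-of-moments estimators follow
from the expected mean squares,

$$\hat\sigma^2_{rep} = MS_{rep},\qquad
\hat\sigma^2_{cond} = (MS_{cond} - MS_{rep})/n,\qquad
\hat\sigma^2_{gene} = (MS_{gene} - MS_{cond})/(bn),$$

with negative estimates truncated to zero before percentages — standard
method-of-moments practice. Only balanced designs are accepted: the
closed form is exact there, the motivating experimental design
(duplicated conditions) is balanced, and an unbalanced table is rejected
with a suggestion to subset rather than silently approximated. REML
would handle unbalance but adds no value for balanced data and is out of
scope. Truncation biases the average recovered share of a genuinely
zero component slightly upward (about 2 points in the default test
design); this is a property of the estimator, not a defect of the
implementation.

# Cross-dataset meta-analysis

Fold changes are $\log_2(RPKM_{interest}/RPKM_{control})$ per dataset;
cells with a zero or missing RPKM on either side are missing, never
zero-filled. Candidate pre-selection applies, in order: antisense
transcription, alternative-splicing evidence, expression below 15 RPKM
anywhere, and |log2 FC| beyond a tolerance anywhere. The first failing
rule is reported per gene. The tolerance defaults to 0.25 log2 units
(≈1.19-fold) — "fold change close to one" needs a band, and 0.25 is
tight enough to keep only plausibly unregulated genes while tolerant of
RPKM quantification noise; it is configurable.

Per-gene summaries use linear-interpolation quantiles (R type 7) for the
median and IQR, plus a Shapiro–Wilk normality flag at α = 0.05 — the
choice of test is a design decision; only the binary flag is consumed
downstream. Genes with fewer than 4 values get no IQR and are flagged.

Classification standardizes (median, IQR) to z-scores across genes and
applies the classical Ward minimum-variance criterion on squared
Euclidean distances (`hclust(method = "ward.D")` on `dist()^2`), cut
into $k = 5$ classes by default. Centroids are reported on the original
(median, IQR) scale, which is the scale on which the classes are
interpreted. The agglomeration history is kept on the result for audit.
When all genes coincide the standardization degenerates; the split is
then deterministic but arbitrary and the result is flagged.

Heat-map export clips log2 FC at ±3.5 (12-fold and beyond saturate),
anchors 0 to the neutral colour and preserves missing cells.

# The synthetic-data generators

`simulate_cq_dataset()` emulates the reference-gene validation design:
its defaults are 12 candidate genes — 8 stable, 4 regulated — over 33
conditions in biological duplicate and technical triplicate on 4 plates.
The generative model is the Cq model above with planted parameters:

- stable genes vary across conditions with SD 0.15 log2 units
  (`stable_sd_log2`);
- regulated genes carry ±2 log2-unit effects (`condition_effect_log2`)
  in 3 randomly chosen conditions each — sporadic regulation, the
  realistic failure mode of "housekeeping" genes, rather than uniform
  shifts;
- biological replicates add 0.10 log2 units (`bio_sd_log2`); published
  validation studies rarely report this magnitude, so it is a free
  parameter chosen as a plausible within-condition culture variability,
  not a calibrated value;
- technical noise is 0.10 cycles, run offsets have SD 0.5 cycles, and
  gDNA contamination is planted at 0.1% of signal — comfortably under
  the 1% screening level, as in a clean experiment;
- per-gene efficiencies are drawn from [0.90, 1.05], the range of
  validated assays.

One pseudo-random stream is consumed in a documented field order, so a
config + seed pair reproduces a dataset exactly. The generator does not
emulate amplification curves, melt curves, RNA degradation, inhibitors,
or between-gene co-regulation; passing tests therefore demonstrate the
statistical machinery, not robustness to those artefacts. Planted truth
(effects, true log2 quantities, run offsets, labels) is returned
alongside the data, which is what makes recovery tests possible.

`simulate_fc_matrix()` plants stability classes as (median, IQR) blobs:
per gene, a target median and IQR are jittered around the class centre
(`blob_sd`, default 0.1) and the gene's log2 FCs are drawn normally with
$\sigma = IQR / (2\,\Phi^{-1}(0.75))$. The default five-class geometry
mirrors the qualitative classes seen in cross-species compilations: a
tight near-zero class, a moderate class, a high-variance class, and
down- and up-biased classes over ~92 conditions and 28 genes. One
practical caveat found while validating the clustering: classes that
differ in the median but share the same IQR are *not* cleanly separable
after standardization, because the IQR axis then carries pure amplified
noise — planted classes should be blobs in both variables.

`simulate_nested_dataset()` draws directly from the three-level
random-effects model and is the ground truth for the ANOVA recovery
tests.

# Problem sizes and tolerances

The test and acceptance runs use sizes chosen to make sampling
statements stable while staying quick: 200 random panels (3–10 genes ×
4–20 samples) for oracle equivalence at 1e-12; 100 seeded default-design
simulations for rank recovery (the 4 planted regulated genes must take
the 4 worst ranks in ≥95); 100 panels for the bias-averaging property
(≥99); 200 nested simulations of a 6 × 8 × 2 design for variance-share
recovery within ±5 points of the planted 0/50/50; 50 five-class
fold-change simulations (8 genes per class, 200 conditions) for
clustering recovery (ARI ≥ 0.9 in ≥45). Exact arithmetic claims
(efficiency round-trips, quantity inversion) are held to 1e-9 relative;
brute-force agreement of sums of squares to 1e-10.

# Known limitations

- The geNorm applet's historical SD convention is undocumented; the
  sample SD (n−1) is used and switchable, so absolute M values may
  differ marginally from other implementations while rankings rarely do.
- Different stability algorithms (model-based estimators, ΔCt
  comparisons, Bestkeeper-style correlations) legitimately disagree on
  nearly uniformly stable panels; only the M/V framework is implemented
  here, and none of the others are approximated.
- The ValidPrime correction is used for screening only; no Cq correction
  for contaminated samples is applied.
- The nested ANOVA provides point estimates of variance components, no
  significance tests or intervals.
- RPKM fold changes inherit all upstream normalization choices of the
  source datasets; the meta-analysis treats them as given.
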