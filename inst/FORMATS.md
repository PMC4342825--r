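# refstab table formats

All tabular artifacts are TSV with a header row, dot decimal separator and
the literal token `NA` for missing cells. Nested results are JSON.

## Cq table (`cq_table.tsv`, input/output)

Long format, one row per qPCR reaction well.

| column | meaning |
|---|---|
| `sample_id` | unique sample identifier (`<condition>_b<replicate>` for unknowns) |
| `condition_id` | culture condition |
| `bio_replicate` | biological replicate index (1-based) |
| `run_id` | qPCR run / plate |
| `assay_id` | gene assay, or `VPA` for the ValidPrime assay |
| `tech_rep` | technical replicate index |
| `cq` | quantification cycle; `NA` = no amplification |
| `sample_kind` | `unknown`, `NTC`, `gDNA_control` or `interrun_calibrator` |

## Efficiency table (`efficiencies.tsv`)

`assay_id`, and `efficiency` (fraction, 1.0 = 100%) or
`efficiency_percent`. The derived amplification factor is
`amp_factor = 1 + efficiency`.

## Aggregated Cq table (`cq_aggregated.tsv`)

One row per (sample, assay, run) cell: `cq` (mean of technical
replicates), `cq_sd` (n-1 denominator), `n_used` (non-missing
replicates), `high_sd` (SD above the QC threshold, default 0.5 cycles).

## Quantity matrix (`quantity_matrix.tsv`)

Genes in rows (first column `id`), samples in columns; efficiency-
corrected relative quantities, max 1 per gene under minimum-Cq
calibration.

## Stability outputs

- `ranking.tsv`: `rank_worst_first`, `gene`, `m_at_exclusion`,
  `initial_M`.
- `v_series.tsv`: `comparison` (`V2/3`, ...), `v`.
- `stability.json`: full stability result (M values, ranking, best pair,
  V series, optimal gene count, cutoffs, tie records).

## Contamination report (`contamination.tsv`)

Per (sample, assay): `cq`, `cq_vpa`, `delta_cq`, `gdna_fraction`
(fraction of signal attributable to gDNA, capped at 1),
`exceeds_threshold`, `status` (`quantified` / `undetected`).

## Bias audit (`bias.tsv`, `bias.json`)

Per alternative gene set and condition: `log2_bias`
(log2 of alternative NF over reference NF, averaged within condition)
and the fold-bias `zone` (`yellow` < 1.5-fold, `green` 1.5-2, `blue`
2-3, `red` 3-8, `extreme` > 8). The JSON carries zone counts and the
quantile-profile fractions. Sign convention: positive = the alternative
NF over-normalizes (under-estimates expression of genes of interest).

## Nested ANOVA (`anova.json`)

Per level (gene, condition, replicate): sum of squares, degrees of
freedom, mean square, variance component, percentage of total.

## Fold-change matrix (`fc_matrix.tsv`, `heatmap.tsv`)

Conditions in rows (first column `id`), genes in columns, values are
log2 fold changes versus the dataset's control condition; `heatmap.tsv`
is clipped at the saturation magnitude (default 3.5) with the colour
scale in `heatmap_scale.json`.

## Gene summaries and classes

- `gene_summary.tsv`: per gene `n`, `mean`, `median`, `q1`, `q3`, `iqr`,
  `normal` (Shapiro-Wilk at alpha 0.05), `too_few`.
- `classification.json`: Ward stability classes, centroids on the
  original (median, IQR) scale.

## Manifest (`manifest.json`)

Package and R version, UTC timestamp, seed, stages, stage parameters and
the list of written artifacts. The timestamp lives only here, so re-runs
with the same configuration and seed are otherwise byte-identical.
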