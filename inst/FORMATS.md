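# File formats

All machine-readable frequencies are fractions in [0, 1]; percentages
appear only in human-readable reports.

## Fluorescence CSV (input; `read_fluorescence_csv()` / `write_fluorescence_csv()`)

Long format, header required.

| column       | type    | notes                                   |
|--------------|---------|-----------------------------------------|
| well         | string  | plate-unique well label                 |
| cycle        | integer | consecutive 1..n within a well/channel  |
| channel      | string  | `FAM` or `VIC` (case-insensitive)       |
| fluorescence | numeric | raw units, no baseline subtraction      |

Duplicate (well, channel, cycle) rows are rejected.

## Sample sheet CSV (input; `read_sample_sheet()` / `write_sample_sheet()`)

| column    | type    | notes                                          |
|-----------|---------|------------------------------------------------|
| well      | string  | unique; must exist in the fluorescence CSV     |
| role      | string  | `STANDARD` or `UNKNOWN` (case-insensitive)     |
| x_true    | numeric | required for STANDARD: VIC-allele fraction     |
| sample_id | string  | required for UNKNOWN                           |
| tissue    | string  | required for UNKNOWN                           |
| replicate | integer | technical replicate index                      |

## Reference standards TSV (packaged; `reference_standards()`)

`inst/extdata/reference_standards.tsv`: columns `assay` (cDNA/gDNA),
`x_true_percent`, `k_mean` (replicate-averaged k'), `cv_percent`.
The same schema (with `x_true` as a fraction accepted too) feeds
`calibrate_from_kprime()`.

## Pipeline outputs (`write_ase_results()`)

- `kprime.tsv` — per well: `well`, `branch` (EQ1/EQ2/TIE), `r_prime`,
  `k_prime`, `a_fam`..`c_vic`, `note`.
- `standards.tsv` — per standard: `x_true`, `n_replicates`, `k_mean`,
  `cv_percent`.
- `estimates.tsv` — per sample: `sample_id`, `tissue`, `n_replicates`,
  `k_mean`, `x_hat`, `x_hat_sd`, `clamped`.
- `log.tsv` — per well: convergence, truncation cycle, fallback and
  failure notes for both channels, branch, k'.
- `report.json` — standard-curve summary and coefficients, per-tissue
  statistics, ANOVA table and post-hoc matrix, full precision.

## Promoter FASTA

Standard multi-record FASTA via Biostrings; record ids are the first
whitespace-delimited word of each header. Variant tables: `position`
(1-based on the first sequence), `kind` (SNP/INSERTION/DELETION),
`allele_a`, `allele_b`. Island tables: `start`, `end` (1-based inclusive),
`length`, `gc_fraction`, `obs_exp_cpg`.
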