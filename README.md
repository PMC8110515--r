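# bwfbiopsy

Multi-compartment liquid-biopsy analysis for extensive-stage small cell
lung cancer (ES-SCLC). Bronchial washing fluid (BWF), collected during
bronchoscopy and separated into a cell-free supernatant (BWFs) and a
cellular precipitate (BWFp), is a candidate liquid-biopsy medium
alongside plasma for patients whose tumors are hard to re-biopsy. Given
matched per-patient somatic call sets from tissue, BWFs, BWFp,
pre-/post-treatment plasma and a peripheral-blood-lymphocyte (PBL)
germline reference, this package implements the downstream analysis a
concordance study of those compartments needs:

- **Somatic filtering** — support/quality rules (≥ 5 supporting reads,
  mean mapQ > 30, mean baseQ > 30), germline subtraction against the
  matched PBL sample, and population-SNP exclusion.
- **Cross-compartment concordance** — count-weighted detection rates
  (`100·Σᵢ|Rᵢ∩Qᵢ| / Σᵢ|Rᵢ|`), intersection-over-union concordance,
  multi-way overlap tables and driver-gene concordance.
- **Panel TMB** — non-synonymous SNVs and indels at ≥ 3% VAF per
  megabase of captured genome (1.6 Mb default), TMB-high at ≥ 9 Muts/Mb,
  with the threshold-vs-bin boundary ambiguity surfaced, never silently
  resolved.
- **mTBI** (molecular tumor burden index) — the mean VAF of a sample's
  clonal mutations (VAF strictly above 70% of the sample's maximal VAF),
  and the treatment decrease rate `(mTBIpre − mTBIpost)/mTBIpre`.
- **Cohort statistics** — exact small-sample Wilcoxon signed-rank and
  Mann–Whitney tests, Pearson correlation, Kaplan–Meier stratification
  with the log-rank test, tumor-marker sensitivity vs sequencing
  detection.
- **Synthetic cohorts** — a seeded binomial ctDNA-shedding simulator
  (clone fractions diluted through per-compartment tumor-content factors
  and depths) plus deterministic fixtures that meet printed cohort count
  totals exactly.

Variant calling itself is out of scope; inputs are VCF v4.2 or MAF-like
TSV call sets, a sample sheet, a panel definition and a clinical table.

## Worked example

Reproduce a cohort detection rate from count totals, and the mTBI
arithmetic:

```r
library(bwfbiopsy)

# 19 matched patients, 204 tissue alterations of which 189 are also seen
# in BWFs (which carries 24 private alterations)
fx <- fixture_from_counts(19, 204, 189, 24)
detection_rate(fx, "tissue", "bwfs")
#> <concordance_result> 19 patients: ref 204, query 213, shared 189,
#>   union 228 | detection 92.6%, concordance 82.9%

# mTBI: clonal = VAFs strictly above 70% of the sample MVAF
ex <- call_table("1", c(100, 200, 300), "A", "G",
                 alt_reads = c(40, 35, 10), depth = 100)
compute_mtbi(ex)
#>   mvaf clonal_threshold n_clonal  mtbi
#>    0.4             0.28        2 0.375      # mean of 0.40 and 0.35

mtbi_decrease_rate(0.375, 0.09)
#>   mtbi_pre mtbi_post decrease_rate
#>      0.375      0.09          0.76          # 76% molecular clearance

# TMB-high: inclusive >= 9 threshold vs strictly-above-9 bins; a cohort
# with one sample at exactly 9 Muts/Mb is 13/21 by one rule, 12/21 by
# the other -- the report keeps both
tmb_rule_report(bin_counts = list(tissue = c(6, 3, 10, 2)),
                n_at_threshold = c(tissue = 1))
#>   compartment  n n_high_threshold percent_threshold n_high_bins
#>        tissue 21               13              61.9          12
#>   percent_bins discrepant
#>          57.14       TRUE
```

The detection rate is the count-weighted cohort aggregate (189/204 =
92.6%), the mTBI example shows the strict 70%-of-MVAF clonality cut, and
the rule report makes the TMB-high boundary sample visible instead of
forcing one convention.

## Analysis workflow

`analysis/` holds the numbered pipeline over the package functions; each
stage reads its inputs from `results/` and writes tables there:

```sh
Rscript analysis/01_simulate_cohort.R   # seeded synthetic matched cohort
Rscript analysis/02_filter_somatic.R    # somatic filter chain via PBL
Rscript analysis/03_concordance.R       # detection/pairwise/driver + fixtures
Rscript analysis/04_tumor_burden.R      # TMB, bins, rule report, correlations
Rscript analysis/05_clonal_dynamics.R   # mTBI, decrease rates, paired tests
Rscript analysis/06_cohort_stats.R      # VAF tests, KM/log-rank, markers
```

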