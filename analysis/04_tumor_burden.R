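#!/usr/bin/env Rscript
# Stage 4: tumor mutational burden.
#
# Per-sample panel TMB (non-synonymous SNVs and indels at >= 3% VAF over
# 1.6 Mb), TMB-high classification under both the inclusive >= 9 Muts/Mb
# threshold and the strictly-above-9 reporting bins, the bins-by-
# compartment table, and tissue-vs-biofluid TMB correlations. The
# published bin counts are pushed through the same rule report to surface
# the threshold-vs-bin boundary discrepancy the study's own numbers carry.

library(bwfbiopsy)

out <- "results/tmb"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cohort <- read_sample_sheet("results/filtered/sample_sheet.tsv")

burden <- burden_table(cohort)
write_report(burden, file.path(out, "burden.tsv"), "tsv")
write_report(tmb_bin_table(burden), file.path(out, "tmb_bins.tsv"), "tsv")
rules <- tmb_rule_report(burden)
write_report(rules, file.path(out, "tmb_rules_synthetic.tsv"), "tsv")

cors <- NULL
tissue <- burden[burden$compartment == "tissue", c("patient_id", "tmb")]
for (cp in c("bwfs", "bwfp", "plasma_pre")) {
  q <- burden[burden$compartment == cp, c("patient_id", "tmb")]
  m <- merge(tissue, q, by = "patient_id")
  r <- correlation(m$tmb.x, m$tmb.y)
  cors <- rbind(cors, data.frame(comparison = paste0("tissue_vs_", cp),
                                 r = r$r, p_value = r$p_value, n = r$n))
}
write_report(cors, file.path(out, "tmb_correlations.tsv"), "tsv")
message("synthetic-cohort TMB correlations vs tissue:")
for (i in seq_len(nrow(cors)))
  message(sprintf("  %-22s r = %.3f (p = %.2g, n = %d)", cors$comparison[i],
                  cors$r[i], cors$p_value[i], cors$n[i]))

# published Table-2 bin counts through the same report
bins <- list(tissue = c(6, 3, 10, 2), bwfs = c(6, 2, 11, 1),
             bwfp = c(7, 4, 9, 1), plasma_pre = c(7, 0, 11, 2))
pub <- tmb_rule_report(bin_counts = bins,
                       n_at_threshold = c(tissue = 1, bwfs = 0, bwfp = 1,
                                          plasma_pre = 0))
write_report(pub, file.path(out, "tmb_rules_published_bins.tsv"), "tsv")
message("published bin counts: BWFs TMB-high 60% by bins;")
message("tissue 57.14% by bins vs 61.90% by the inclusive threshold and")
message("BWFp 47.62% vs 52.38% -- each differs by one boundary sample at")
message("exactly 9 Muts/Mb, surfaced in tmb_rules_published_bins.tsv")
message("wrote TMB tables under ", out)
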