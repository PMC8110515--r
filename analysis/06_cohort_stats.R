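#!/usr/bin/env Rscript
# Stage 6: cohort-level statistics.
#
# VAF location tests between compartments, survival stratification by the
# median BWFs and pre-treatment plasma mTBI (Kaplan-Meier + log-rank), and
# the tumor-marker sensitivity table against sequencing detection.

library(bwfbiopsy)

out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cohort <- read_sample_sheet("results/filtered/sample_sheet.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")

# paired VAF comparisons between compartments (shared variants only)
tests <- NULL
for (pair in list(c("tissue", "bwfs"), c("tissue", "plasma_pre"),
                  c("bwfs", "plasma_pre"), c("bwfs", "bwfp"))) {
  tab <- paired_burden_table(cohort, pair[1], pair[2], "vaf_all_calls")
  res <- paired_test(tab)
  res$comparison <- paste0("vaf_", pair[1], "_vs_", pair[2])
  res$direction <- ifelse(mean(tab$value_a - tab$value_b) > 0,
                          paste0(pair[1], "_higher"),
                          paste0(pair[2], "_higher"))
  tests <- rbind(tests, res)
  message(sprintf("  %-28s p = %-9.3g %s", res$comparison, res$p_value,
                  res$direction))
}
write_report(tests, file.path(out, "vaf_tests.tsv"), "tsv")

# survival stratification by mTBI median split
surv_rows <- NULL
for (cp in c("bwfs", "plasma_pre")) {
  score <- vapply(names(cohort), function(pid) {
    s <- cohort[[pid]]$samples[[cp]]
    if (is.null(s) || !nrow(s$calls)) NA_real_ else compute_mtbi(s)$mtbi
  }, numeric(1))
  ok <- !is.na(score) & names(score) %in% clinical$patient_id
  clin <- clinical[match(names(score)[ok], clinical$patient_id), ]
  for (ep in c("os", "pfs")) {
    sp <- survival_split(clin[[paste0(ep, "_months")]],
                         clin[[paste0(ep, "_event")]], score[ok])
    surv_rows <- rbind(surv_rows, data.frame(
      score = paste0("mtbi_", cp), endpoint = ep, cut = sp$cut,
      n_low = sum(sp$groups == "low"), n_high = sum(sp$groups == "high"),
      chisq = sp$chisq, p_value = sp$p_value))
    km <- sp$km
    km$score <- paste0("mtbi_", cp)
    km$endpoint <- ep
    write_report(km, file.path(out, sprintf("km_%s_%s.tsv", cp, ep)), "tsv")
  }
}
write_report(surv_rows, file.path(out, "survival_splits.tsv"), "tsv")
message("log-rank splits by median mTBI:")
for (i in seq_len(nrow(surv_rows)))
  message(sprintf("  %-18s %-4s chisq = %-6.3f p = %.3f",
                  surv_rows$score[i], surv_rows$endpoint[i],
                  surv_rows$chisq[i], surv_rows$p_value[i]))

# marker sensitivity vs sequencing detection (simulated marker flags)
ms <- marker_sensitivity(clinical, cohort)
write_report(ms, file.path(out, "marker_sensitivity.tsv"), "tsv")
message("marker positivity vs per-compartment sequencing detection written")
message("wrote cohort statistics under ", out)
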