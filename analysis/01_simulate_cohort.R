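#!/usr/bin/env Rscript
# Stage 1: generate the synthetic matched cohort.
#
# Simulates 21 ES-SCLC patients with matched tissue, BWF supernatant and
# precipitate, pre-/post-treatment plasma and a PBL germline reference
# under the binomial ctDNA-shedding model, then writes everything to disk
# in the same formats the readers accept (per-sample MAF-like TSVs, a
# sample sheet, a panel file, a clinical table and the truth tables), so
# the later stages run purely from files.

library(bwfbiopsy)

seed <- 20210426L
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = seed)
sim <- simulate_cohort(cfg)

sheet <- NULL
for (rec in sim$cohort) {
  for (s in rec$samples) {
    f <- file.path(out, sprintf("%s_%s.tsv", rec$patient_id, s$compartment))
    write_callset(s, f, "maf_tsv")
    sheet <- rbind(sheet, data.frame(patient_id = rec$patient_id,
                                     compartment = s$compartment, path = f))
  }
}
write.table(sheet, file.path(out, "sample_sheet.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_panel(cfg$panel, file.path(out, "panel.txt"))
clinical <- do.call(rbind, lapply(sim$cohort, `[[`, "clinical"))
write_report(clinical, file.path(out, "clinical.tsv"), "tsv")
write_report(sim$truth$mutations, file.path(out, "truth_mutations.tsv"), "tsv")
write_report(sim$truth$germline, file.path(out, "truth_germline.tsv"), "tsv")

n_samples <- sum(vapply(sim$cohort, function(r) length(r$samples), 1L))
message(sprintf("simulated %d patients / %d samples (seed %d)",
                length(sim$cohort), n_samples, seed))
message(sprintf("%d somatic truth mutations, %d germline SNPs per patient",
                nrow(sim$truth$mutations), cfg$germline_snps_per_patient))
message("wrote cohort files under ", out)
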