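# End-to-end orchestration: filter -> concordance -> TMB -> mTBI -> stats,
# with a combined TSV + JSON report bundle. The numbered scripts under
# analysis/ are thin drivers over this function and the module functions.

#' Run the full analysis chain on a raw cohort
#'
#' Applies the somatic filter chain, then computes the cross-compartment
#' concordance report, the per-sample burden table with the TMB-high
#' rule report, the mTBI dynamics table, and the cohort statistics
#' (paired pre/post plasma tests, TMB correlations against tissue, marker
#' sensitivity). Writes one TSV per table plus a combined JSON bundle when
#' `out_dir` is given.
#'
#' @param cohort Named list of raw [patient_record()]s (PBL included).
#' @param clinical Optional clinical data.frame (defaults to the clinical
#'   rows carried by the records).
#' @param filter A [filter_config()].
#' @param tmb A [tmb_config()].
#' @param clonal_fraction mTBI clonality cut (default 0.70).
#' @param out_dir Optional output directory for the report bundle.
#' @return List of result tables (invisibly written to `out_dir`).
#' @export
run_report <- function(cohort, clinical = NULL, filter = filter_config(),
                       tmb = tmb_config(), clonal_fraction = 0.70,
                       out_dir = NULL) {
  filtered <- filter_cohort(cohort, filter)
  if (is.null(clinical)) {
    clin_rows <- Filter(Negate(is.null), lapply(filtered, `[[`, "clinical"))
    clinical <- if (length(clin_rows)) do.call(rbind, clin_rows) else NULL
  }

  present <- unique(unlist(lapply(filtered, function(r) names(r$samples))))
  queries <- intersect(c("bwfs", "bwfp", "plasma_pre"), present)
  concord <- tryCatch(concordance_report(filtered, queries),
                      error = function(e) NULL)

  burden <- burden_table(filtered, tmb)
  bins <- tmb_bin_table(burden, tmb)
  rules <- tmb_rule_report(burden, config = tmb)

  dynamics <- tryCatch(mtbi_dynamics(filtered, clonal_fraction),
                       error = function(e) NULL)

  stats_rows <- list()
  add_test <- function(label, res) {
    res$comparison <- label
    stats_rows[[length(stats_rows) + 1L]] <<- res
  }
  for (metric in c("n_mutations", "mvaf", "mtbi")) {
    tab <- tryCatch(paired_burden_table(filtered, "plasma_pre",
                                        "plasma_post", metric),
                    error = function(e) NULL)
    if (!is.null(tab) && nrow(tab) >= 2L)
      tryCatch(add_test(paste0("plasma_pre_vs_post_", metric),
                        paired_test(tab)),
               error = function(e) NULL)
  }
  correlations <- NULL
  if (!is.null(burden)) {
    wide <- stats::reshape(burden[c("patient_id", "compartment", "tmb")],
                           idvar = "patient_id", timevar = "compartment",
                           direction = "wide")
    names(wide) <- sub("^tmb\\.", "", names(wide))
    cor_rows <- list()
    for (cp in intersect(c("bwfs", "bwfp", "plasma_pre"), names(wide))) {
      ok <- stats::complete.cases(wide[c("tissue", cp)])
      if (sum(ok) >= 3L) {
        r <- tryCatch(correlation(wide$tissue[ok], wide[[cp]][ok]),
                      error = function(e) NULL)
        if (!is.null(r))
          cor_rows[[cp]] <- data.frame(comparison = paste0("tmb_tissue_vs_", cp),
                                       r = r$r, p_value = r$p_value, n = r$n,
                                       stringsAsFactors = FALSE)
      }
    }
    if (length(cor_rows)) correlations <- do.call(rbind, cor_rows)
  }
  markers <- if (!is.null(clinical))
    marker_sensitivity(clinical, filtered) else NULL

  tables <- list(concordance = concord, burden = burden, tmb_bins = bins,
                 tmb_rules = rules, mtbi_dynamics = dynamics,
                 paired_tests = if (length(stats_rows))
                   do.call(rbind, stats_rows) else NULL,
                 tmb_correlations = correlations,
                 marker_sensitivity = markers)
  tables <- Filter(Negate(is.null), tables)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      write_report(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                   "tsv")
    jsonlite::write_json(tables, file.path(out_dir, "report.json"),
                         dataframe = "rows", digits = NA, na = "null")
  }
  invisible(tables)
}
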