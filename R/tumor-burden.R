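# Panel TMB, TMB-high classification, bin tables and per-sample VAF/MVAF
# summaries.

#' TMB configuration
#'
#' Non-synonymous SNVs and indels with allele frequency of at least
#' `min_vaf` (3% by default, inclusive) qualify; TMB is the qualifying
#' count divided by the captured panel size in Mb (1.6 by default). The
#' headline TMB-high call uses `tmb >= tmb_high_threshold` (9 Muts/Mb,
#' inclusive). Bin edges define the reporting bins
#' `<=6, (6,9], (9,20], >20`; note the bin rule puts a sample at exactly
#' 9 Muts/Mb in `(6,9]` while the threshold rule calls it TMB-high -- the
#' two rules deliberately coexist and [tmb_rule_report()] surfaces where
#' they disagree.
#'
#' @param min_vaf Minimum qualifying VAF, inclusive (default 0.03).
#' @param panel_size_mb Captured genome size in Mb (default 1.6).
#' @param tmb_high_threshold TMB-high cut in Muts/Mb, inclusive (default 9).
#' @param bin_edges Strictly increasing interior bin edges (default 6, 9, 20).
#' @return An object of class `tmb_config`.
#' @export
tmb_config <- function(min_vaf = 0.03, panel_size_mb = 1.6,
                       tmb_high_threshold = 9, bin_edges = c(6, 9, 20)) {
  if (min_vaf < 0 || min_vaf > 1) stop("min_vaf must be in [0, 1]")
  if (panel_size_mb <= 0) stop("panel_size_mb must be > 0")
  if (tmb_high_threshold <= 0) stop("tmb_high_threshold must be > 0")
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  structure(list(min_vaf = min_vaf, panel_size_mb = panel_size_mb,
                 tmb_high_threshold = tmb_high_threshold,
                 bin_edges = bin_edges),
            class = "tmb_config")
}

#' Bin labels for a TMB configuration
#' @param config A [tmb_config()].
#' @return Character vector of bin labels, lowest first.
#' @export
tmb_bin_labels <- function(config = tmb_config()) {
  e <- config$bin_edges
  c(sprintf("<=%g", e[1L]),
    sprintf("(%g,%g]", e[-length(e)], e[-1L]),
    sprintf(">%g", e[length(e)]))
}

#' Compute per-sample panel TMB and VAF summaries
#'
#' @param sample A filtered [compartment_sample()] (somatic calls only).
#' @param config A [tmb_config()].
#' @return A one-row data.frame (`burden_summary`): patient, compartment,
#'   `n_qualifying`, `tmb`, `tmb_high`, `bin`, `mvaf`, `mean_vaf`.
#' @export
compute_tmb <- function(sample, config = tmb_config()) {
  calls <- as_calls(sample)
  qual <- calls[calls$effect %in% c("nonsynonymous_snv", "indel") &
                  calls$vaf >= config$min_vaf, , drop = FALSE]
  tmb <- nrow(qual) / config$panel_size_mb
  cls <- classify_tmb(tmb, config)
  data.frame(
    patient_id = if (inherits(sample, "compartment_sample"))
      sample$patient_id else NA_character_,
    compartment = if (inherits(sample, "compartment_sample"))
      sample$compartment else NA_character_,
    n_qualifying = nrow(qual), tmb = tmb,
    tmb_high = cls$tmb_high, bin = cls$bin,
    mvaf = if (nrow(calls)) max(calls$vaf) else NA_real_,
    mean_vaf = if (nrow(calls)) mean(calls$vaf) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Classify a TMB value
#'
#' `tmb_high` is `tmb >= threshold` (the headline rule); `bin` follows the
#' reporting-bin edges, whose `(6,9]`/`(9,20]` boundary is open at 9.
#'
#' @param tmb TMB value(s) in Muts/Mb.
#' @param config A [tmb_config()].
#' @return List with `tmb_high` (logical) and `bin` (character).
#' @export
classify_tmb <- function(tmb, config = tmb_config()) {
  labels <- tmb_bin_labels(config)
  # bins are (lo, hi]: a value exactly on an edge belongs below it
  idx <- vapply(tmb, function(t) sum(t > config$bin_edges) + 1L, integer(1))
  list(tmb_high = tmb >= config$tmb_high_threshold, bin = labels[idx])
}

#' Maximal variant allele frequency of a sample
#'
#' The clonality reference used by the mTBI statistic: the maximum VAF over
#' the sample's somatic calls. Errors on an empty sample (undefined, not 0).
#'
#' @param sample A [compartment_sample()] or call table.
#' @return The maximal VAF (fraction).
#' @export
mvaf <- function(sample) {
  calls <- as_calls(sample)
  if (!nrow(calls)) stop("MVAF undefined for an empty sample")
  max(calls$vaf)
}

#' Proportion of TMB-high samples
#'
#' Two rules are supported. `by_threshold` takes TMB values and counts
#' `tmb >= threshold`; `by_bins` takes either TMB values or a vector of bin
#' counts (lowest bin first) and counts samples in bins strictly above the
#' threshold edge. The two disagree exactly for samples sitting on the
#' threshold.
#'
#' @param tmb TMB values (either rule), or `NULL` when using `bin_counts`.
#' @param rule `"by_threshold"` or `"by_bins"`.
#' @param bin_counts Integer vector of per-bin sample counts (by_bins only).
#' @param config A [tmb_config()].
#' @param digits Decimals for the percentage (default 1).
#' @return List: `n_high`, `n`, `percent`.
#' @export
tmb_high_proportion <- function(tmb = NULL, rule = c("by_threshold", "by_bins"),
                                bin_counts = NULL, config = tmb_config(),
                                digits = 1) {
  rule <- match.arg(rule)
  if (!is.null(bin_counts)) {
    if (rule != "by_bins") stop("bin counts only support the by_bins rule")
    if (length(bin_counts) != length(config$bin_edges) + 1L)
      stop("bin_counts must have one entry per bin")
    n <- sum(bin_counts)
    high_bins <- which(config$bin_edges >= config$tmb_high_threshold)[1L] + 1L
    n_high <- sum(bin_counts[high_bins:length(bin_counts)])
  } else {
    n <- length(tmb)
    n_high <- switch(rule,
      by_threshold = sum(tmb >= config$tmb_high_threshold),
      by_bins = sum(tmb > config$tmb_high_threshold))
  }
  if (n == 0) stop("undefined proportion: zero samples")
  list(n_high = n_high, n = n,
       percent = round_half_up(100 * n_high / n, digits))
}

#' Per-sample burden table for a cohort
#'
#' @param cohort Named list of filtered [patient_record()]s.
#' @param config A [tmb_config()].
#' @param compartments Compartments to include (default: all non-PBL).
#' @return Data.frame, one row per sample.
#' @export
burden_table <- function(cohort, config = tmb_config(),
                         compartments = setdiff(COMPARTMENTS, "pbl")) {
  rows <- list()
  for (rec in cohort)
    for (s in rec$samples)
      if (s$compartment %in% compartments)
        rows[[length(rows) + 1L]] <- compute_tmb(s, config)
  do.call(rbind, rows)
}

#' Bin-count summary table (bins x compartments)
#'
#' @param burden A [burden_table()] result.
#' @param config A [tmb_config()].
#' @return Data.frame with `bin` column and one count column per compartment.
#' @export
tmb_bin_table <- function(burden, config = tmb_config()) {
  labels <- tmb_bin_labels(config)
  comps <- unique(burden$compartment)
  out <- data.frame(bin = labels, stringsAsFactors = FALSE)
  for (cp in comps)
    out[[cp]] <- vapply(labels, function(b)
      sum(burden$compartment == cp & burden$bin == b), integer(1))
  out
}

#' Surface the threshold-vs-bin TMB-high discrepancy
#'
#' Reports, per compartment, the TMB-high proportion under both rules: the
#' inclusive threshold (`tmb >= 9`) and the reporting bins (strictly
#' `> 9`). A sample with TMB exactly on the threshold is TMB-high under the
#' first rule but sits in the `(6,9]` bin under the second; `discrepant`
#' flags compartments where the two counts differ, rather than silently
#' resolving the boundary.
#'
#' @param burden A [burden_table()] result, or `NULL` when using counts.
#' @param bin_counts Optional named list (compartment -> bin-count vector).
#' @param n_at_threshold Named integer vector: number of samples sitting
#'   exactly at the threshold per compartment (used with `bin_counts`).
#' @param config A [tmb_config()].
#' @param digits Decimals for percentages (default 2, resolving e.g. 52.38).
#' @return Data.frame: compartment, n, counts and percents under each rule,
#'   `discrepant`.
#' @export
tmb_rule_report <- function(burden = NULL, bin_counts = NULL,
                            n_at_threshold = NULL, config = tmb_config(),
                            digits = 2) {
  rows <- list()
  if (!is.null(burden)) {
    for (cp in unique(burden$compartment)) {
      t <- burden$tmb[burden$compartment == cp]
      by_thr <- tmb_high_proportion(t, "by_threshold", config = config,
                                    digits = digits)
      by_bin <- tmb_high_proportion(t, "by_bins", config = config,
                                    digits = digits)
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = cp, n = length(t),
        n_high_threshold = by_thr$n_high, percent_threshold = by_thr$percent,
        n_high_bins = by_bin$n_high, percent_bins = by_bin$percent,
        discrepant = by_thr$n_high != by_bin$n_high, stringsAsFactors = FALSE)
    }
  } else {
    if (is.null(bin_counts)) stop("provide burden or bin_counts")
    for (cp in names(bin_counts)) {
      by_bin <- tmb_high_proportion(rule = "by_bins",
                                    bin_counts = bin_counts[[cp]],
                                    config = config, digits = digits)
      at_thr <- if (!is.null(n_at_threshold) && cp %in% names(n_at_threshold))
        n_at_threshold[[cp]] else 0L
      n_thr <- by_bin$n_high + at_thr
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = cp, n = by_bin$n,
        n_high_threshold = n_thr,
        percent_threshold = round_half_up(100 * n_thr / by_bin$n, digits),
        n_high_bins = by_bin$n_high, percent_bins = by_bin$percent,
        discrepant = n_thr != by_bin$n_high, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
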